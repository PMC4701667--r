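test_that("speed summaries match the sorted-array quartile oracle", {
  set.seed(31)
  n <- 200
  traj <- data.frame(time_s = seq(0, by = 0.1, length.out = n),
                     speed_um_s = rexp(n, 1 / 300), valid = TRUE)
  w <- data.frame(label = c("a", "b"), t_start = c(0, 10), t_end = c(10, 20))
  s <- speed_summary(traj, w)
  for (i in 1:2) {
    sp <- traj$speed_um_s[traj$time_s >= w$t_start[i] &
                            traj$time_s < w$t_end[i]]
    sp <- sort(sp)
    # linear-interpolation quartile oracle (type 7): h = (n-1)p + 1
    qq <- function(p) {
      h <- (length(sp) - 1) * p + 1
      lo <- floor(h)
      sp[lo] + (h - lo) * (sp[min(lo + 1, length(sp))] - sp[lo])
    }
    expect_equal(s$q1[i], qq(0.25))
    expect_equal(s$median[i], qq(0.5))
    expect_equal(s$q3[i], qq(0.75))
    expect_equal(s$min[i], sp[1])
    expect_equal(s$max[i], sp[length(sp)])
  }
  # constant-speed track: min = median = max
  cst <- data.frame(time_s = 0:9, speed_um_s = 140, valid = TRUE)
  sc <- speed_summary(cst, data.frame(label = "c", t_start = 0, t_end = 20))
  expect_equal(sc$min, sc$max)
  expect_equal(sc$min, sc$median)
  # empty window errors with its label
  expect_error(speed_summary(cst, data.frame(label = "empty", t_start = 50,
                                             t_end = 60)), "empty")
  # overlapping windows rejected
  expect_error(speed_summary(cst, data.frame(label = c("x", "y"),
                                             t_start = c(0, 3),
                                             t_end = c(5, 8))), "overlap")
})

test_that("percent_of_baseline follows the ratio-of-maxima convention", {
  expect_equal(percent_of_baseline(890, 330), 100 * 890 / 330)
  expect_lt(abs(percent_of_baseline(890, 330) - 270), 0.4)
  expect_equal(percent_of_baseline(5, 5), 100)
  expect_equal(percent_of_baseline(10, 5), 200)
  expect_error(percent_of_baseline(100, 0), "baseline")
})

test_that("maze classification applies the strict 80% body rule", {
  maze <- maze_spec(left = c(-1000, 0, 300), right = c(1000, 0, 300))
  mk_mask <- function(frac_inside) {
    # 100-px body: frac_inside px at the left terminal, rest outside
    m <- matrix(FALSE, 60, 220)
    n_in <- round(100 * frac_inside)
    # left terminal centre at world (-1000, 0); origin puts it near col 7
    m[21:30, 3:(2 + n_in / 10)] <- TRUE
    if (n_in < 100) m[21:30, 150:(150 + (100 - n_in) / 10 - 1)] <- TRUE
    m
  }
  origin <- c(-1065, 145) # 10 um/px grid; cols 3..12 lie in the left region
  # fully inside -> LEFT at the first frame
  r <- maze_classify(list(mk_mask(1)), maze, times = 0, origin = origin,
                     um_per_px = 10)
  expect_equal(r$outcome, "LEFT")
  expect_equal(r$decision_time_s, 0)
  # 79% never more -> INCOMPLETE (strict threshold)
  r <- maze_classify(rep(list(mk_mask(0.79)), 10), maze, times = 0:9,
                     origin = origin, um_per_px = 10)
  expect_equal(r$outcome, "INCOMPLETE")
  # exactly 80% decides
  r <- maze_classify(list(mk_mask(0.80)), maze, times = 0, origin = origin,
                     um_per_px = 10)
  expect_equal(r$outcome, "LEFT")
  # monotone in threshold: lowering it never turns LEFT into INCOMPLETE
  maze70 <- maze_spec(left = c(-1000, 0, 300), right = c(1000, 0, 300),
                      body_fraction_threshold = 0.7)
  r70 <- maze_classify(list(mk_mask(0.80)), maze70, times = 0,
                       origin = origin, um_per_px = 10)
  expect_equal(r70$outcome, "LEFT")
  expect_error(maze_classify(list(), maze, numeric(0), origin, 10), "empty")
})

test_that("border-touching masks are classified as escapes", {
  maze <- maze_spec(left = c(-1000, 0, 300), right = c(1000, 0, 300),
                    escape_frames = 3)
  edge <- matrix(FALSE, 40, 40); edge[1, 5:20] <- TRUE; edge[2, 5:20] <- TRUE
  r <- maze_classify(rep(list(edge), 5), maze, times = 0:4,
                     origin = c(0, 0), um_per_px = 10)
  expect_equal(r$outcome, "ESCAPED")
  expect_equal(r$decision_frame, 3)
})

test_that("choice test: closed forms and brute-force pmf enumeration", {
  r <- choice_test(choice_tally(19, 19))
  expect_equal(r$proportion_left, 0.5)
  expect_equal(r$p_value, 1.0)
  # (38, 0): p = 2 * 0.5^38
  r <- choice_test(choice_tally(38, 0))
  expect_equal(r$p_value, min(1, 2 * 0.5^38))
  # enumeration oracle for all tallies with n <= 50 (every k at several n)
  for (n in c(1, 2, 7, 23, 38, 50)) {
    pmf <- dbinom(0:n, n, 0.5)
    for (k in 0:n) {
      p_oracle <- min(1, sum(pmf[pmf <= pmf[k + 1] + 1e-12]))
      expect_equal(choice_test(choice_tally(k, n - k))$p_value, p_oracle,
                   tolerance = 1e-12)
    }
  }
  # matches stats::binom.test (independent implementation)
  for (k in c(0, 10, 19, 30)) {
    expect_equal(choice_test(choice_tally(k, 38 - k))$p_value,
                 stats::binom.test(k, 38, 0.5)$p.value, tolerance = 1e-9)
    expect_equal(choice_test(choice_tally(k, 38 - k))$conf_int,
                 as.numeric(stats::binom.test(k, 38, 0.5)$conf.int),
                 tolerance = 1e-9)
  }
  expect_error(choice_test(choice_tally(0, 0)), "no decided")
  expect_equal(choice_test(choice_tally(10, 10, n_excluded = 4))$n_excluded, 4)
})

test_that("Kaplan-Meier matches the hand-computed product-limit table", {
  # deaths at days 2, 3, 3; censor at day 2 (4 subjects)
  rec <- survival_records(id = 1:4, day = c(2, 2, 3, 3),
                          status = c("died", "censored", "died", "died"),
                          reason = c(NA, "desiccation", NA, NA))
  km <- kaplan_meier(rec)
  # hand computation: S(2) = 1 * (1 - 1/4) = 0.75 (censored at risk on day 2)
  #                   S(3) = 0.75 * (1 - 2/2) = 0
  expect_equal(km$curve$surv[km$curve$day == 2], 0.75)
  expect_equal(km$curve$surv[km$curve$day == 3], 0)
  expect_equal(km$median, 3)
  expect_equal(km$n_events, 3)
  expect_equal(km$n_censored, 1)
  # curve properties: S(0)=1 implied, non-increasing
  expect_true(all(diff(km$curve$surv) <= 1e-12))
  expect_true(all(km$curve$surv <= 1))
  # no deaths: S = 1, median undefined
  alive <- survival_records(1:3, c(5, 6, 7), rep("censored", 3),
                            reason = "edge crawling")
  expect_warning(km0 <- kaplan_meier(alive), "median undefined")
  expect_true(all(km0$curve$surv == 1))
  expect_true(is.na(km0$median))
})

test_that("Kaplan-Meier and log-rank agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(77)
  n <- 60
  day <- c(rpois(n / 2, 14), rpois(n / 2, 18)) + 1
  status <- ifelse(runif(n) < 0.8, "died", "censored")
  grp <- rep(c("ctrl", "peg"), each = n / 2)
  rec <- survival_records(seq_len(n), day, status,
                          reason = ifelse(status == "censored", "other", NA),
                          group = grp)
  km <- kaplan_meier(rec)
  sf <- survival::survfit(survival::Surv(day, status == "died") ~ 1)
  expect_equal(km$curve$surv[km$curve$n_event > 0],
               sf$surv[sf$n.event > 0], tolerance = 1e-12)
  sd2 <- survival::survdiff(survival::Surv(day, status == "died") ~ grp)
  expect_equal(km$logrank$chisq, sd2$chisq, tolerance = 1e-9)
  # identical groups: chi-square 0, p = 1
  rec2 <- survival_records(1:20, rep(c(3, 5, 8, 12, 15), 4),
                           rep("died", 20),
                           group = rep(c("a", "b"), each = 10))
  lr <- kaplan_meier(rec2)$logrank
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p_value, 1)
})

test_that("survival records validate status/reason consistency", {
  expect_error(survival_records(1, 5, "died", reason = "desiccation"),
               "censor reason")
  expect_error(survival_records(1, -1, "died"))
})

test_that("three-stage confinement replay orders the maxima", {
  # open < pillars < channel (sequential confinement raises the maximum);
  # short stages (45 s, one speed plateau each) keep the test fast
  stage_max <- function(scenario, seed, peak) {
    tr <- NULL
    sim <- simulate_scenario(scenario, duration_s = 45, seed = seed,
                             params = list(peak_speed = peak),
                             sink = function(i, frame, t) {
                               if (is.null(tr)) tr <<- tracker_new(5)
                               tracker_feed(tr, frame, t)
                             }, keep_frames = FALSE)
    traj <- tracker_finish(tr, origin = sim$env$occupancy$origin)
    speed_summary(traj, data.frame(label = scenario, t_start = 0,
                                   t_end = 46))$max
  }
  m_open <- stage_max("open_frame", 31, 330)
  m_pill <- stage_max("pillars", 32, 600)
  m_chan <- stage_max("channel", 33, 890)
  expect_lt(m_open, m_pill)
  expect_lt(m_pill, m_chan)
})
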