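#' Per-window speed summaries
#'
#' Box-whisker style statistics of the smoothed speed within labelled,
#' non-overlapping time windows (assay configurations). Quartiles use linear
#' interpolation of the sorted sample (R quantile type 7).
#'
#' @param traj trajectory with `time_s`, `speed_um_s`, `valid` (from
#'   [derive_kinematics()]).
#' @param windows data.frame with `label`, `t_start`, `t_end` (s),
#'   non-overlapping and ordered.
#' @return data.frame: one row per window with `label`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max` (um/s).
#' @export
speed_summary <- function(traj, windows) {
  stopifnot(all(c("label", "t_start", "t_end") %in% names(windows)))
  if (nrow(windows) > 1) {
    o <- order(windows$t_start)
    if (any(windows$t_end[o][-nrow(windows)] > windows$t_start[o][-1]))
      .wf_stop("windows overlap")
  }
  out <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    keep <- traj$valid & !is.na(traj$speed_um_s) &
      traj$time_s >= w$t_start & traj$time_s < w$t_end
    if (!is.null(traj$full_support)) keep <- keep & traj$full_support
    sp <- traj$speed_um_s[keep]
    if (length(sp) < 3)
      .wf_stop("window '%s' contains %d valid frames (>= 3 required)",
               w$label, length(sp))
    q <- quantile(sp, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    data.frame(label = w$label, n = length(sp), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5])
  })
  do.call(rbind, out)
}

#' Maximum speed as a percent of a baseline maximum
#'
#' The ratio-of-maxima convention: 100 x confined / open (890 vs 330 um/s
#' reads as ~270%).
#'
#' @param max_confined,max_open maximum speeds, um/s.
#' @return percent.
#' @export
percent_of_baseline <- function(max_confined, max_open) {
  if (max_open <= 0) .wf_stop("zero or negative baseline maximum")
  100 * max_confined / max_open
}

#' Maze specification for outcome classification
#'
#' @param left,right terminal circular regions, each `(x, y, radius)` um.
#' @param entrance optional entrance region (same format), reporting only.
#' @param body_fraction_threshold fraction of body pixels that must lie in a
#'   terminal region to call the outcome (default 0.80).
#' @param escape_margin_um body pixels beyond this distance from the maze
#'   lumen count as out-of-maze.
#' @param escape_frames consecutive out-of-maze frames that mean ESCAPED.
#' @return object of class `wf_maze_spec`.
#' @export
maze_spec <- function(left, right, entrance = NULL,
                      body_fraction_threshold = 0.80,
                      escape_margin_um = 100, escape_frames = 5) {
  stopifnot(body_fraction_threshold > 0, body_fraction_threshold <= 1)
  d <- sqrt(sum((left[1:2] - right[1:2])^2))
  if (d <= left[3] + right[3]) .wf_stop("terminal regions must be disjoint")
  structure(list(left = left, right = right, entrance = entrance,
                 body_fraction_threshold = body_fraction_threshold,
                 escape_margin_um = escape_margin_um,
                 escape_frames = escape_frames), class = "wf_maze_spec")
}

#' Build a [maze_spec()] from a T-maze pattern
#' @param pattern a [pattern_t_maze()].
#' @inheritParams maze_spec
#' @export
maze_spec_from_pattern <- function(pattern, body_fraction_threshold = 0.80,
                                   escape_margin_um = 100,
                                   escape_frames = 5) {
  tm <- t_maze_terminals(pattern)
  spec <- maze_spec(tm$left, tm$right,
                    body_fraction_threshold = body_fraction_threshold,
                    escape_margin_um = escape_margin_um,
                    escape_frames = escape_frames)
  spec$pattern <- pattern
  spec
}

#' Classify a maze run from a body-mask series
#'
#' The outcome is decided at the first frame where at least
#' `body_fraction_threshold` (default 80%) of the worm's body pixels lie
#' inside a terminal circular region. A worm whose body stays out of the
#' maze lumen (further than `escape_margin_um` from it, when the maze
#' pattern is known) or touches the image border for `escape_frames`
#' consecutive frames has climbed out: ESCAPED. Otherwise INCOMPLETE.
#'
#' @param masks list of logical body masks (one per frame).
#' @param maze a [maze_spec()].
#' @param times frame times, s.
#' @param origin world `(x, y)` of the centre of mask pixel `[1, 1]`.
#' @param um_per_px mask pixel size, um.
#' @return list: `outcome` in `{"LEFT","RIGHT","ESCAPED","INCOMPLETE"}`,
#'   `decision_time_s`, `decision_frame`.
#' @export
maze_classify <- function(masks, maze, times, origin, um_per_px) {
  if (length(masks) == 0) .wf_stop("empty mask series")
  stopifnot(length(times) == length(masks))
  out_streak <- 0L
  lumen_d <- NULL
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    px <- which(m, arr.ind = TRUE)
    if (nrow(px) == 0) next
    x <- origin[1] + (px[, 2] - 1) * um_per_px
    y <- origin[2] - (px[, 1] - 1) * um_per_px
    fl <- mean((x - maze$left[1])^2 + (y - maze$left[2])^2 <= maze$left[3]^2)
    fr <- mean((x - maze$right[1])^2 + (y - maze$right[2])^2 <= maze$right[3]^2)
    if (fl >= maze$body_fraction_threshold)
      return(list(outcome = "LEFT", decision_time_s = times[i],
                  decision_frame = i))
    if (fr >= maze$body_fraction_threshold)
      return(list(outcome = "RIGHT", decision_time_s = times[i],
                  decision_frame = i))
    border <- any(px[, 1] %in% c(1L, nrow(m))) || any(px[, 2] %in% c(1L, ncol(m)))
    outside <- FALSE
    if (!is.null(maze$pattern)) {
      d <- .tmaze_lumen_dist(maze$pattern, x, y)
      outside <- mean(d > maze$escape_margin_um) > 0.5
    }
    out_streak <- if (border || outside) out_streak + 1L else 0L
    if (out_streak >= maze$escape_frames)
      return(list(outcome = "ESCAPED", decision_time_s = times[i],
                  decision_frame = i))
  }
  list(outcome = "INCOMPLETE", decision_time_s = NA_real_,
       decision_frame = NA_integer_)
}

#' Choice tally
#' @param n_left,n_right decided worms per side.
#' @param n_excluded escapers excluded from the test.
#' @return object of class `wf_choice_tally`.
#' @export
choice_tally <- function(n_left, n_right, n_excluded = 0) {
  stopifnot(n_left >= 0, n_right >= 0, n_excluded >= 0)
  structure(list(n_left = n_left, n_right = n_right,
                 n_excluded = n_excluded), class = "wf_choice_tally")
}

#' Exact binomial choice test against equal left/right probability
#'
#' Two-sided exact test (sum of tail probabilities not exceeding the
#' observed outcome's), with a Clopper-Pearson 95% confidence interval for
#' the left proportion. Excluded (escaped) worms are reported but never
#' tested.
#'
#' @param tally a [choice_tally()] (or two counts).
#' @param p null probability of LEFT (0.5).
#' @param conf_level confidence level for the Clopper-Pearson interval.
#' @return list: `n`, `n_left`, `proportion_left`, `p_value`, `conf_int`,
#'   `n_excluded`.
#' @export
choice_test <- function(tally, p = 0.5, conf_level = 0.95) {
  if (is.numeric(tally)) tally <- choice_tally(tally[1], tally[2])
  n <- tally$n_left + tally$n_right
  if (n < 1) .wf_stop("no decided worms to test")
  k <- tally$n_left
  pmf <- dbinom(0:n, n, p)
  pval <- min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
  a <- 1 - conf_level
  ci <- c(if (k == 0) 0 else qbeta(a / 2, k, n - k + 1),
          if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k))
  list(n = n, n_left = k, proportion_left = k / n, p_value = pval,
       conf_int = ci, n_excluded = tally$n_excluded)
}

# ---- survival --------------------------------------------------------------

#' Survival records
#'
#' Day 0 is the first day of adulthood; lifespan is the number of days
#' between day 0 and the last day scored alive. Worms removed for reasons
#' other than death (internally hatched eggs, desiccation, extruded gonad,
#' edge crawling) are censored at their removal day.
#'
#' @param id subject identifiers.
#' @param day event day (>= 0).
#' @param status `"died"` or `"censored"`.
#' @param reason optional censor reason (required consistency: reasons only
#'   on censored records).
#' @param group optional group label (for the two-group log-rank test).
#' @return data.frame of class `wf_survival`.
#' @export
survival_records <- function(id, day, status, reason = NA, group = NA) {
  stopifnot(all(day >= 0), all(status %in% c("died", "censored")))
  df <- data.frame(id = id, day = day, status = status, reason = reason,
                   group = group, stringsAsFactors = FALSE)
  if (any(df$status == "died" & !is.na(df$reason)))
    .wf_stop("death records must not carry a censor reason")
  class(df) <- c("wf_survival", "data.frame")
  df
}

#' Kaplan-Meier product-limit estimator
#'
#' Censored subjects remain at risk through their censor day. The survival
#' curve is right-continuous and non-increasing with S(0) = 1; the median
#' lifespan is the first day with S <= 0.5 (NA, with a warning, if the curve
#' never reaches 0.5). When `records` has two groups, a two-group log-rank
#' chi-square (1 df) is included.
#'
#' @param records a [survival_records()] data.frame.
#' @return list: `curve` (data.frame `day`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`), `median`, `n_events`, `n_censored`, and for two groups
#'   `logrank` (`chisq`, `p_value`).
#' @export
kaplan_meier <- function(records) {
  stopifnot(nrow(records) >= 1)
  km1 <- function(df) {
    days <- sort(unique(df$day))
    n_at_risk <- function(d) sum(df$day >= d)
    rows <- lapply(days, function(d) {
      data.frame(day = d, n_risk = n_at_risk(d),
                 n_event = sum(df$day == d & df$status == "died"),
                 n_censor = sum(df$day == d & df$status == "censored"))
    })
    cv <- do.call(rbind, rows)
    cv$surv <- cumprod(1 - cv$n_event / cv$n_risk)
    cv
  }
  cv <- km1(records)
  below <- cv$day[cv$surv <= 0.5 & cv$n_event > 0]
  med <- if (length(below)) min(below) else {
    .wf_warn("survival never drops to 0.5: median undefined")
    NA_real_
  }
  out <- list(curve = cv, median = med,
              n_events = sum(records$status == "died"),
              n_censored = sum(records$status == "censored"))
  grp <- unique(records$group[!is.na(records$group)])
  if (length(grp) == 2) out$logrank <- .logrank2(records, grp)
  out
}

# two-group log-rank test (1 df)
.logrank2 <- function(records, grp) {
  days <- sort(unique(records$day[records$status == "died"]))
  o1 <- e1 <- v <- 0
  for (d in days) {
    n <- sum(records$day >= d)
    n1 <- sum(records$day >= d & records$group == grp[1])
    dd <- sum(records$day == d & records$status == "died")
    d1 <- sum(records$day == d & records$status == "died" &
                records$group == grp[1])
    o1 <- o1 + d1
    e1 <- e1 + dd * n1 / n
    if (n > 1) v <- v + dd * (n1 / n) * (1 - n1 / n) * (n - dd) / (n - 1)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  list(chisq = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Run one synthetic T-maze trial end to end
#'
#' Simulates a maze navigation ([simulate_scenario()] `tmaze`), segments the
#' body in every frame against the median background, classifies the outcome
#' with the 80%-body rule and compares it against the simulator's ground
#' truth endpoint.
#'
#' @param seed RNG seed.
#' @param duration_s trial length.
#' @param camera a [camera_model()] (the default trades resolution for
#'   speed: 10 um/px at 5 fps).
#' @param p_left probability the simulated worm picks the left arm.
#' @param config a [tracker_config()].
#' @return list: `outcome`, `truth` (simulated endpoint, upper case),
#'   `match`, `decision_time_s`, `overlap_px` (worm-in-obstacle pixel count
#'   across the trial, 0 if non-penetration held).
#' @export
maze_trial <- function(seed, duration_s = 40,
                       camera = camera_model(um_per_px = 10, frame_rate = 5),
                       p_left = 0.5, config = tracker_config()) {
  sim <- simulate_scenario("tmaze", duration_s = duration_s, seed = seed,
                           camera = camera, params = list(p_left = p_left))
  bg <- background_model(sim$frames, config$background_k)
  masks <- lapply(sim$frames$frames, function(f) segment_body(f, bg, config))
  mz <- maze_spec_from_pattern(sim$maze)
  res <- maze_classify(masks, mz, sim$frames$times,
                       origin = sim$env$occupancy$origin,
                       um_per_px = camera$um_per_px)
  list(outcome = res$outcome, truth = toupper(sim$endpoint),
       match = identical(res$outcome, toupper(sim$endpoint)),
       decision_time_s = res$decision_time_s,
       overlap_px = sum(sim$truth$overlap_px, na.rm = TRUE))
}
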