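test_that("frame differencing: identity, crescents, noise floor", {
  cfg <- tracker_config()
  f <- matrix(200L, 120, 120)
  expect_equal(sum(frame_difference(f, f, cfg)), 0)
  expect_error(frame_difference(f, matrix(200L, 100, 120)), "mismatch")
  # disc translated by 10 px: two crescent regions bounding the displacement
  mk_disc <- function(cr, cc, r = 15, sz = 120, bg = 200L, fg = 60L) {
    m <- matrix(bg, sz, sz)
    co <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
    ro <- matrix(seq_len(sz), sz, sz)
    m[(ro - cr)^2 + (co - cc)^2 <= r^2] <- fg
    m
  }
  a <- mk_disc(60, 50); b <- mk_disc(60, 60)
  m <- frame_difference(b, a, tracker_config(close_radius = 0))
  px <- which(m, arr.ind = TRUE)
  expect_gt(nrow(px), 0)
  # motion confined to the union of the two disc footprints
  inside <- ((px[, 1] - 60)^2 + (px[, 2] - 50)^2 <= 16.5^2) |
            ((px[, 1] - 60)^2 + (px[, 2] - 60)^2 <= 16.5^2)
  expect_true(all(inside))
  expect_true(abs(mean(px[, 2]) - 55) < 3) # centroid between the two centres
  # pure Gaussian noise: < 0.1% pixels survive the default threshold+opening
  set.seed(99)
  n1 <- matrix(as.integer(pmax(pmin(round(200 + rnorm(300^2, 0, 3)), 255), 0)), 300)
  n2 <- matrix(as.integer(pmax(pmin(round(200 + rnorm(300^2, 0, 3)), 255), 0)), 300)
  m <- frame_difference(n1, n2, tracker_config(close_radius = 0))
  expect_lt(mean(m), 0.001)
})

test_that("blob moments equal brute-force pixel sums on random shapes", {
  set.seed(123)
  for (i in 1:100) {
    m <- random_blob(n = 40 + i)
    blobs <- detect_blobs(m, min_area = 1)
    # brute-force oracle over all set pixels of each 8-connected component
    lab <- wormfab:::.cc_label(m)
    for (b in blobs) {
      k <- lab[b$pixels[1, 1], b$pixels[1, 2]]
      px <- which(lab == k, arr.ind = TRUE)
      expect_identical(b$area, nrow(px))
      expect_equal(unname(b$centroid),
                   c(sum(px[, 1]) / nrow(px), sum(px[, 2]) / nrow(px)))
      mr <- mean(px[, 1]); mc <- mean(px[, 2])
      expect_equal(b$mu20, sum((px[, 2] - mc)^2))
      expect_equal(b$mu02, sum((px[, 1] - mr)^2))
      expect_equal(b$mu11, sum((px[, 2] - mc) * (px[, 1] - mr)))
    }
  }
  # empty image, square closed forms
  expect_length(detect_blobs(matrix(FALSE, 10, 10)), 0)
  sq <- matrix(FALSE, 30, 30); sq[10:14, 20:24] <- TRUE
  b <- detect_blobs(sq, min_area = 1)[[1]]
  expect_equal(b$area, 25L)
  expect_equal(unname(b$centroid), c(12, 22))
})

test_that("worm selection: largest first, nearest with gate afterwards", {
  mk <- function(area, r, c) list(area = area, centroid = c(row = r, col = c))
  expect_false(select_worm(list())$valid)
  one <- select_worm(list(mk(50, 10, 10)))
  expect_equal(one$blob$area, 50)
  # no previous: largest wins
  expect_equal(select_worm(list(mk(10, 5, 5), mk(99, 50, 50)))$blob$area, 99)
  # previous: nearer chosen even if smaller
  sel <- select_worm(list(mk(10, 12, 12), mk(99, 50, 50)),
                     prev_centroid = c(10, 10), max_jump_px = 20)
  expect_equal(sel$blob$area, 10)
  # nothing within the gate: invalid
  expect_false(select_worm(list(mk(99, 50, 50)), prev_centroid = c(0, 0),
                           max_jump_px = 10)$valid)
})

test_that("two-worm distractor: track stays on target beyond the gate", {
  cam <- camera_model(um_per_px = 10, frame_rate = 5, noise_sd = 2)
  env <- new_environment(NULL, c(-2500, 2500), c(-2500, 2500), um_per_px = 10)
  m <- worm_model(turn_sd_rad = 0)
  set.seed(4)
  target <- worm_init(m, env, position = c(-1200, 900), heading = 0)
  distract <- worm_init(m, env, position = c(-1200, -900), heading = 0)
  tr <- tracker_new(10, tracker_config(max_jump_um = 1000))
  truth <- NULL
  for (i in 1:40) {
    if (i > 1) {
      target <- worm_step(target, env, 0.2)
      distract <- worm_step(distract, env, 0.2)
    }
    rf <- render_frame(env, cam, list(worm_body(target), worm_body(distract)))
    tracker_feed(tr, rf$frame, (i - 1) * 0.2)
    truth <- rbind(truth, colMeans(worm_body(target)))
  }
  traj <- tracker_finish(tr, origin = env$occupancy$origin)
  v <- traj$valid
  err <- sqrt((traj$x_um - truth[, 1])^2 + (traj$y_um - truth[, 2])^2)
  expect_lt(max(err[v][-1], na.rm = TRUE), 500) # never hops to the distractor
})

test_that("segmentation recovers the body against a median background", {
  cam <- camera_model(um_per_px = 5, noise_sd = 2)
  sim <- simulate_scenario("open_frame", duration_s = 3, seed = 6,
                           camera = cam)
  bg <- background_model(sim$frames, k = 10)
  cfg <- tracker_config()
  i <- 25
  mask <- segment_body(sim$frames$frames[[i]], bg, cfg)
  expect_false(isTRUE(attr(mask, "empty")))
  expect_lt(abs(sum(mask) - sim$truth$area_px[i]) / sim$truth$area_px[i], 0.15)
  # frame equal to background -> empty mask
  m0 <- segment_body(matrix(200L, 50, 50), matrix(200, 50, 50), cfg)
  expect_true(isTRUE(attr(m0, "empty")))
})

test_that("moment orientation: analytic rectangles and unwrapping", {
  expect_equal(orientation_from_moments(rotated_rect_mask(0)), 0,
               tolerance = 1e-6)
  for (th in c(-60, -30, 10, 30, 45, 80)) {
    expect_lt(abs(orientation_from_moments(rotated_rect_mask(th)) - th), 0.5)
  }
  # degenerate circular mask: NA with warning
  disc <- (matrix(seq_len(61), 61, 61) - 31)^2 +
    (matrix(seq_len(61), 61, 61, byrow = TRUE) - 31)^2 <= 20^2
  expect_warning(a <- orientation_from_moments(disc), "degenerate")
  expect_true(is.na(a))
  # unwrapping removes 180-degree flips
  th <- c(80, 85, -89, -85) # continuation of 80, 85, 91, 95
  expect_equal(unwrap_orientation(th), c(80, 85, 91, 95))
})

test_that("kinematics: stationary, uniform motion, window errors", {
  cfg <- tracker_config()
  still <- data.frame(time_s = seq(0, 2, 0.1), x_um = 500, y_um = -200,
                      valid = TRUE)
  k <- derive_kinematics(still, cfg)
  expect_true(all(abs(k$speed_um_s) < 1e-9))
  expect_true(all(abs(k$accel_um_s2) < 1e-9))
  # uniform linear motion recovered within 1%
  tt <- seq(0, 5, 0.1)
  lin <- data.frame(time_s = tt, x_um = 100 + 180 * tt, y_um = 50 - 120 * tt,
                    valid = TRUE)
  k <- derive_kinematics(lin, cfg)
  v_true <- sqrt(180^2 + 120^2)
  expect_true(all(abs(k$speed_um_s - v_true) / v_true < 0.01))
  # window larger than track errors
  short <- data.frame(time_s = c(0, 1, 2), x_um = 1:3, y_um = 1:3,
                      valid = TRUE)
  expect_error(derive_kinematics(short, tracker_config(smooth_window = 9,
                                                       despike_window = 0)),
               NA) # window shrinks to the run; no error for valid runs >= 3
  expect_error(wormfab:::.sg_smooth(1:3, 9, 2), "window")
})

test_that("pipeline is pure: same frames + config give identical output", {
  sim <- simulate_scenario("open_frame", duration_s = 3, seed = 10)
  t1 <- track_frames(sim$frames, origin = sim$env$occupancy$origin)
  t2 <- track_frames(sim$frames, origin = sim$env$occupancy$origin)
  expect_identical(t1, t2)
})
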