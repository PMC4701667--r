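test_that("zero-speed worm does not move; constant speed covers v*T", {
  env <- new_environment(NULL, c(-3000, 3000), c(-3000, 3000), um_per_px = 10)
  still <- worm_model(base_speed_um_s = 0)
  st <- worm_init(still, env, position = c(0, 0))
  set.seed(7)
  c0 <- colMeans(worm_body(st))
  for (i in 1:50) st <- worm_step(st, env, 0.1)
  expect_lt(sqrt(sum((colMeans(worm_body(st)) - c0)^2)), 1e-6)
  # kinematic oracle: path length ~ v * T within 2% in an open arena
  mv <- worm_model(base_speed_um_s = 250, turn_sd_rad = 0.1)
  st <- worm_init(mv, env, position = c(0, 0), heading = pi / 4)
  set.seed(8)
  path_len <- 0
  prev <- st$trail$pts[nrow(st$trail$pts), ]
  for (i in 1:100) {
    st <- worm_step(st, env, 0.1)
    cur <- st$trail$pts[nrow(st$trail$pts), ]
    path_len <- path_len + sqrt(sum((cur - prev)^2))
    prev <- cur
  }
  expect_lt(abs(path_len - 250 * 10) / (250 * 10), 0.02)
})

test_that("confinement gain raises speed when clearance drops", {
  m <- worm_model(confinement = list(gain_max = 2.7, c0_um = 200,
                                     width_um = 30),
                  base_speed_um_s = 330, turn_sd_rad = 0)
  open_env <- new_environment(NULL, c(-3000, 3000), c(-3000, 3000),
                              um_per_px = 10)
  chan <- pattern_corrugated_channel(4000, 200, 0, 1000, 150)
  chan_env <- new_environment(chan, c(-2300, 2300), c(-600, 600),
                              um_per_px = 10)
  set.seed(1)
  st_open <- worm_init(m, open_env, position = c(0, 0))
  st_chan <- worm_init(m, chan_env, position = c(-1500, 0), heading = 0)
  v_open <- v_chan <- 0
  for (i in 1:30) {
    st_open <- worm_step(st_open, open_env, 0.1)
    st_chan <- worm_step(st_chan, chan_env, 0.1)
    v_open <- max(v_open, st_open$speed_now)
    v_chan <- max(v_chan, st_chan$speed_now)
  }
  expect_gt(v_chan, v_open)
  expect_lt(abs(v_open - 330) / 330, 0.05)
})

test_that("rendering: background, area oracle, determinism, non-penetration", {
  cam <- camera_model(um_per_px = 5, noise_sd = 0)
  env <- new_environment(NULL, c(-1000, 1000), c(-1000, 1000), um_per_px = 5)
  # no worm, no noise -> uniform background
  rf <- render_frame(env, cam, noise = FALSE)
  expect_true(all(rf$frame == cam$background_level))
  # body pixel count ~ body_length * body_width / um_per_px^2 within 10%
  m <- worm_model()
  st <- worm_init(m, env, position = c(500, 0), heading = pi)
  rf <- render_frame(env, cam, list(worm_body(st)),
                     body_width_um = m$body_width_um, noise = FALSE)
  expect_lt(abs(rf$worm_area_px - 1000 * 60 / 25) / (1000 * 60 / 25), 0.10)
  # fixed seed -> bit-identical frames and ground truth
  s1 <- simulate_scenario("pillars", duration_s = 2, seed = 5)
  s2 <- simulate_scenario("pillars", duration_s = 2, seed = 5)
  expect_identical(s1$frames$frames, s2$frames$frames)
  expect_identical(s1$truth, s2$truth)
  # non-penetration: zero worm pixels inside obstacles in every frame
  expect_true(all(s1$truth$overlap_px == 0))
})

test_that("open-arena recovered ground-truth speed matches the parameter", {
  sim <- simulate_scenario("open_frame", duration_s = 20, seed = 3,
                           params = list(peak_speed = 330, constant_speed = TRUE),
                           keep_frames = FALSE)
  # centroid displacement speed from ground truth
  d <- sqrt(diff(sim$truth$x_um)^2 + diff(sim$truth$y_um)^2) /
    diff(sim$truth$time_s)
  expect_lt(abs(stats::median(d) - 330) / 330, 0.06)
})

test_that("hinge angle only moves under braced contact, monotonically", {
  h <- hinge_pin(c(0, 0), lever_length = 600, lever_width = 100,
                 angle_deg = 6, contact_gain_deg_s = 5)
  env <- new_environment(pattern_frame(2400, 2400, 200),
                         c(-1400, 1400), c(-1400, 1400), um_per_px = 10)
  m <- worm_model()
  # far away worm: no contact over the full horizon
  far <- worm_init(m, env, position = c(-900, -900), heading = 0)
  h2 <- h
  for (i in 1:20) h2 <- hinge_step(h2, worm_body(far), env, 0.1)
  expect_equal(h2$angle_deg, 6)
  # scripted contact bouts: theta non-decreasing, stepwise
  body_touch <- cbind(seq(-1090, -10, length.out = 41),
                      rep(20, 41)) # spans wall (x ~ -1090) to lever
  h3 <- h
  angles <- numeric(0)
  for (cyc in 1:3) {
    for (i in 1:5) h3 <- hinge_step(h3, body_touch, env, 0.1)
    angles <- c(angles, h3$angle_deg)
    for (i in 1:5) h3 <- hinge_step(h3, worm_body(far), env, 0.1)
    angles <- c(angles, h3$angle_deg)
  }
  expect_true(all(diff(angles) >= 0))
  expect_equal(h3$angle_deg, 6 + 3 * 0.5 * 5) # 3 bouts x 0.5 s x 5 deg/s
})

test_that("lever schedule ramps 6 to 27 degrees over 6 s, stepwise monotone", {
  f <- lever_schedule()
  expect_equal(f(0), 6)
  expect_equal(f(6), 27)
  ts <- seq(0, 6, by = 0.05)
  expect_true(all(diff(f(ts)) >= -1e-12))
})

test_that("t-maze scenario ends at its sampled side and coils in terminal", {
  sim <- simulate_scenario("tmaze", duration_s = 30, seed = 21,
                           camera = camera_model(um_per_px = 10,
                                                 frame_rate = 5),
                           keep_frames = FALSE)
  expect_true(sim$endpoint %in% c("left", "right"))
  tm <- t_maze_terminals(sim$maze)[[sim$endpoint]]
  # the worm coils inside its sampled terminal at some point in the run
  # (it may back out again after bouncing off the path end)
  d <- sqrt((sim$truth$x_um - tm[1])^2 + (sim$truth$y_um - tm[2])^2)
  expect_lt(min(d), tm["radius"])
  other <- t_maze_terminals(sim$maze)[[setdiff(c("left", "right"),
                                               sim$endpoint)]]
  d2 <- sqrt((sim$truth$x_um - other[1])^2 + (sim$truth$y_um - other[2])^2)
  expect_gt(min(d2), other["radius"])
  expect_true(all(sim$truth$overlap_px == 0))
})
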