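test_that("rule validation happens at construction time", {
  expect_error(trigger_rule(at_time(1), pattern_disk(c(0, 0), 100),
                            exposure_time = 0.01), "shutter")
  expect_error(worm_in_region(c(0, 0)), "radius")
  expect_error(trigger_rule("later", pattern_disk(c(0, 0), 100)))
})

test_that("empty rule list leaves the environment unchanged", {
  res <- run_experiment(list(), duration_s = 2, seed = 3,
                        camera = cam_small(), worm = NULL)
  expect_equal(sum(res$env$occupancy$pixels), 0)
  expect_true(all(res$log$kind == "frame"))
})

test_that("sequential confinement script cures geometries in order", {
  # frame at t=0+ (1 s exposure), pillars 4 s later, channel afterwards
  rules <- list(
    trigger_rule(at_time(0), pattern_frame(3000, 2000, 200),
                 exposure_time = 1, label = "frame"),
    trigger_rule(at_time(4), pattern_pillar_array(100, 400, c(2000, 1200)),
                 exposure_time = 1, label = "pillars"),
    trigger_rule(at_time(8),
                 pattern_corrugated_channel(2500, 200, 50, 1200, 150),
                 exposure_time = 1, label = "channel"))
  res <- run_experiment(rules, duration_s = 12, seed = 5,
                        camera = cam_small(), worm = NULL,
                        arena = list(xlim = c(-2000, 2000),
                                     ylim = c(-1400, 1400)))
  cures <- res$log[res$log$kind == "cure_complete", ]
  expect_equal(cures$payload, c("frame", "pillars", "channel"))
  # cure_complete = exposure_start + exposure_time + cure_delay
  starts <- res$log[res$log$kind == "exposure_start", ]
  expect_equal(cures$t, starts$t + 1 + 1)
  # all three geometries present in the final environment
  direct <- rasterize_world(list(rules[[1]]$spec, rules[[2]]$spec,
                                 rules[[3]]$spec),
                            c(-2000, 2000), c(-1400, 1400), 10)
  expect_equal(sum(res$env$occupancy$pixels), sum(direct$pixels))
})

test_that("causality: obstacles act only after cure_complete", {
  rules <- list(trigger_rule(at_time(1), pattern_frame(2000, 1500, 200),
                             exposure_time = 1, label = "frame"))
  res <- run_experiment(rules, duration_s = 6, seed = 7,
                        camera = cam_small(),
                        arena = list(xlim = c(-1500, 1500),
                                     ylim = c(-1200, 1200)),
                        keep_frames = TRUE)
  cure_t <- res$log$t[res$log$kind == "cure_complete"]
  # frames before the cure show no obstacle pixels (uniform bg +- noise)
  pre <- res$frames$frames[[which(res$frames$times < cure_t)[2]]]
  post <- res$frames$frames[[length(res$frames)]]
  expect_gt(sum(post < 170), sum(pre < 170))
  # worm never embedded after cure
  expect_true(all(res$truth$overlap_px == 0, na.rm = TRUE))
})

test_that("rejected actions are logged and never cured", {
  rules <- list(trigger_rule(at_time(1), pattern_frame(2000, 1500, 30),
                             exposure_time = 1, label = "thinwall"))
  res <- run_experiment(rules, duration_s = 3, seed = 7,
                        camera = cam_small(), worm = NULL,
                        arena = list(xlim = c(-1500, 1500),
                                     ylim = c(-1200, 1200)))
  expect_true(any(res$log$kind == "rejection"))
  expect_false(any(res$log$kind == "cure_complete"))
  expect_equal(sum(res$env$occupancy$pixels), 0)
})

test_that("worm_in_region trigger fires exactly once after dwell", {
  # region centred on the worm start: dwell satisfied quickly
  rules <- list(trigger_rule(worm_in_region(c(0, 0, 1500), dwell_s = 0.6),
                             pattern_disk(c(2500, 2500), 200),
                             exposure_time = 1, label = "iso"))
  res <- run_experiment(rules, duration_s = 6, seed = 9,
                        camera = cam_small(),
                        arena = list(xlim = c(-3000, 3000),
                                     ylim = c(-3000, 3000)))
  fired <- res$log[res$log$kind == "trigger_fired", ]
  expect_equal(nrow(fired), 1)
  expect_gte(fired$t, 0.6)
})

test_that("freehand session: dots cure after latency + cure delay and a
           surrounding stroke shrinks reachable space", {
  tfp <- projection_transform(5, sample_um_per_dmd_px = 10,
                              dmd_shape = c(400L, 400L))
  # empty stream: no obstacles
  res0 <- freehand_session(stroke_stream(data.frame(x = numeric(0),
                                                    y = numeric(0),
                                                    t = numeric(0))), tfp,
                           camera = cam_small())
  expect_equal(sum(res0$env$occupancy$pixels), 0)
  # single dot: one disc obstacle at t + 0.25 + cure
  dot <- stroke_stream(data.frame(x = 0, y = 0, t = 2),
                       brush_radius_tablet = 5000)
  res1 <- freehand_session(dot, tfp, camera = cam_small())
  expect_equal(res1$log$t[res1$log$kind == "cure_complete"], 2 + 0.25 + 1)
  expect_equal(attr(wormfab:::.cc_label(res1$env$occupancy$pixels), "n"), 1)
  # spiral of dots around the arena centre: reachable area decreases
  th <- seq(0, 4 * pi, length.out = 40)
  r_tab <- 50000 + 12000 * th / (4 * pi)
  sp <- stroke_stream(data.frame(x = r_tab * cos(th), y = r_tab * sin(th),
                                 t = seq(0, 8, length.out = 40)),
                      brush_radius_tablet = 4000)
  res2 <- freehand_session(sp, tfp, camera = cam_small())
  a <- res2$areas$area_um2
  expect_true(all(diff(a) <= 1e-9))
  expect_lt(a[length(a)], a[1])
})

test_that("logs are replayable: same seed reproduces the run exactly", {
  rules <- list(trigger_rule(at_time(1), pattern_disk(c(800, 0), 150),
                             exposure_time = 1))
  r1 <- run_experiment(rules, duration_s = 3, seed = 42, camera = cam_small(),
                       arena = list(xlim = c(-1500, 1500),
                                    ylim = c(-1500, 1500)))
  r2 <- run_experiment(rules, duration_s = 3, seed = 42, camera = cam_small(),
                       arena = list(xlim = c(-1500, 1500),
                                    ylim = c(-1500, 1500)))
  expect_identical(r1$log, r2$log)
  expect_identical(r1$trajectory, r2$trajectory)
})
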