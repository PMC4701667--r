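#' Timed grayscale frame sequence
#'
#' @param frames list of integer matrices (8-bit gray, equal shapes).
#' @param times frame times, s, strictly increasing.
#' @param um_per_px pixel size, um.
#' @return object of class `wf_frames`.
#' @export
frame_sequence <- function(frames, times, um_per_px) {
  stopifnot(length(frames) == length(times), um_per_px > 0)
  if (length(times) > 1 && any(diff(times) <= 0))
    .wf_stop("frame times must be strictly increasing")
  if (length(frames) > 1) {
    d0 <- dim(frames[[1]])
    for (f in frames) if (!all(dim(f) == d0)) .wf_stop("non-uniform frame shapes")
  }
  structure(list(frames = frames, times = times, um_per_px = um_per_px),
            class = "wf_frames")
}

#' @export
print.wf_frames <- function(x, ...) {
  cat(sprintf("wf_frames: %d frames %s px, %g um/px, t = %.3g..%.3g s\n",
              length(x$frames),
              if (length(x$frames)) paste(dim(x$frames[[1]]), collapse = " x ")
              else "?",
              x$um_per_px, if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' @export
length.wf_frames <- function(x) length(x$frames)

#' Render one simulation frame
#'
#' Dark worm tube(s) on a light background, semi-opaque cured obstacles,
#' optional lever polygons, additive Gaussian noise, 8-bit quantization.
#' The camera grid must match the environment grid.
#'
#' @param env a `wf_env`.
#' @param camera a [camera_model()].
#' @param bodies list of body-point matrices ([worm_body()]).
#' @param body_width_um worm body width(s), um (recycled over `bodies`).
#' @param levers list of lever polygons (n x 2 world um) drawn as cured
#'   material.
#' @param noise add camera noise (draws from the R RNG stream).
#' @return list with `frame` (integer matrix), `worm_area_px` (pixels per
#'   worm) and `overlap_px` (worm pixels inside obstacles, per worm).
#' @export
render_frame <- function(env, camera, bodies = list(), body_width_um = 60,
                         levers = list(), noise = TRUE) {
  if (abs(camera$um_per_px - env$um_per_px) > 1e-9)
    .wf_stop("camera and environment grids differ (%g vs %g um/px)",
             camera$um_per_px, env$um_per_px)
  occ <- env$occupancy$pixels
  # base image (background + static obstacles) memoised per occupancy state
  key <- sprintf("%g_%g_%g", camera$background_level, camera$obstacle_level,
                 camera$worm_level)
  if (is.null(env$cache$base) || !identical(env$cache$key, key)) {
    base <- matrix(camera$background_level, nrow(occ), ncol(occ))
    base[occ] <- camera$obstacle_level
    env$cache$base <- base
    env$cache$key <- key
  }
  img <- env$cache$base
  for (poly in levers) {
    ax <- occupancy_axes(env$occupancy)
    s <- env$um_per_px
    cr <- round(range(1 + (poly[, 1] - ax$x[1]) / s)) + c(-2, 2)
    rr <- round(range(1 + (ax$y[1] - poly[, 2]) / s)) + c(-2, 2)
    rr <- pmin(pmax(rr, 1), nrow(occ)); cr <- pmin(pmax(cr, 1), ncol(occ))
    sub_x <- ax$x[cr[1]:cr[2]]; sub_y <- ax$y[rr[1]:rr[2]]
    X <- matrix(sub_x, length(sub_y), length(sub_x), byrow = TRUE)
    Y <- matrix(sub_y, length(sub_y), length(sub_x))
    m <- matrix(pattern_contains(pattern_polygon(poly), as.vector(X),
                                 as.vector(Y)), length(sub_y), length(sub_x))
    blk <- img[rr[1]:rr[2], cr[1]:cr[2]]
    blk[m] <- camera$obstacle_level
    img[rr[1]:rr[2], cr[1]:cr[2]] <- blk
  }
  body_width_um <- rep_len(body_width_um, max(1, length(bodies)))
  area <- overlap <- integer(length(bodies))
  for (i in seq_along(bodies)) {
    rc <- .world_to_grid_frac(env, bodies[[i]][, 1], bodies[[i]][, 2])
    rad <- body_width_um[i] / 2 / env$um_per_px
    # stamp in a local crop: the worm covers a tiny part of the frame
    r0 <- max(1L, floor(min(rc[, 1]) - rad - 1))
    r1 <- min(nrow(occ), ceiling(max(rc[, 1]) + rad + 1))
    c0 <- max(1L, floor(min(rc[, 2]) - rad - 1))
    c1 <- min(ncol(occ), ceiling(max(rc[, 2]) + rad + 1))
    sub <- .stamp_tube(matrix(0, r1 - r0 + 1, c1 - c0 + 1),
                       rc[, 1] - r0 + 1, rc[, 2] - c0 + 1, rad, 1) > 0
    blk <- img[r0:r1, c0:c1]
    blk[sub] <- camera$worm_level
    img[r0:r1, c0:c1] <- blk
    area[i] <- sum(sub)
    overlap[i] <- sum(sub & env$occupancy$pixels[r0:r1, c0:c1])
  }
  frame <- .noise_quantize(img, if (noise) camera$noise_sd else 0)
  list(frame = frame, worm_area_px = area, overlap_px = overlap)
}

# fractional grid coordinates (row, col) for stamping
.world_to_grid_frac <- function(env, x, y) {
  s <- env$um_per_px
  cbind(1 + (env$ylim[2] - s / 2 - y) / s, 1 + (x - env$xlim[1] - s / 2) / s)
}

# ---- scenarios -------------------------------------------------------------

.fig3_frame <- function(p) {
  pattern_frame(p$frame_w + 2 * p$wall, p$frame_h + 2 * p$wall, p$wall)
}

.scenario_setup <- function(scenario, params, camera) {
  p <- utils::modifyList(list(
    frame_w = 5000, frame_h = 3000, wall = 200,
    peak_speed = 330,
    pillar_diameter = 100, pillar_pitch = 250,
    channel_width = 200, ripple_amplitude = 60, ripple_period = 1500,
    channel_length = 4500, channel_wall = 150,
    stem_len = 1500, arm_len = 1500, maze_channel = 200, maze_wall = 150,
    terminal_radius = 300, p_left = 0.5,
    lever_length = 600, lever_width = 100,
    pin = c(0, 0), schedule = lever_schedule(),
    mod_period = 30), params)
  half_w <- p$frame_w / 2 + p$wall; half_h <- p$frame_h / 2 + p$wall
  pad <- 100
  mk_env <- function(specs, xlim, ylim, ...)
    new_environment(specs, xlim, ylim, um_per_px = camera$um_per_px, ...)
  out <- switch(scenario,
    open_frame = list(env = mk_env(.fig3_frame(p),
                                   c(-half_w - pad, half_w + pad),
                                   c(-half_h - pad, half_h + pad)),
                      mode = "free"),
    pillars = {
      pil <- pattern_pillar_array(p$pillar_diameter, p$pillar_pitch,
                                  region = c(p$frame_w - 200, p$frame_h - 200))
      list(env = mk_env(list(.fig3_frame(p), pil),
                        c(-half_w - pad, half_w + pad),
                        c(-half_h - pad, half_h + pad)),
           mode = "free")
    },
    channel = {
      ch <- pattern_corrugated_channel(p$channel_length, p$channel_width,
                                       p$ripple_amplitude, p$ripple_period,
                                       p$channel_wall)
      env <- mk_env(list(.fig3_frame(p), ch),
                    c(-half_w - pad, half_w + pad),
                    c(-half_h - pad, half_h + pad))
      list(env = env, mode = "path", path = channel_centerline(ch, 1024))
    },
    tmaze = {
      mz <- pattern_t_maze(p$stem_len, p$arm_len, p$maze_channel, p$maze_wall,
                           p$terminal_radius)
      ex <- p$arm_len + p$terminal_radius + p$maze_wall + pad
      ey_lo <- -p$stem_len - p$maze_wall - pad
      ey_hi <- p$maze_channel + p$terminal_radius + p$maze_wall + pad
      env <- mk_env(mz, c(-ex, ex), c(ey_lo, ey_hi))
      side <- if (runif(1) < p$p_left) "left" else "right"
      term <- t_maze_terminals(mz)[[side]]
      sgn <- if (side == "left") -1 else 1
      cw2 <- p$maze_channel / 2
      along <- cbind(seq(0, sgn * (p$arm_len - p$terminal_radius / 2),
                         length.out = 60), cw2)
      coil_r <- max(60, p$terminal_radius - 80)
      th <- seq(0, 2.5 * 2 * pi, length.out = 200)
      coil <- cbind(term["x"] + coil_r * cos(sgn * th + pi / 2 * sgn),
                    term["y"] + coil_r * sin(sgn * th + pi / 2 * sgn) * 0.9)
      stem <- cbind(0, seq(-p$stem_len + 50, cw2, length.out = 80))
      list(env = env, mode = "path",
           path = rbind(stem, along, coil), maze = mz, endpoint = side)
    },
    hinge = {
      env <- mk_env(list(pattern_frame(2400, 2400, p$wall),
                         pattern_disk(p$pin, p$lever_width / 3)),
                    c(-1300, 1300), c(-1300, 1300))
      list(env = env, mode = "lever",
           hinge = hinge_pin(p$pin, p$lever_length, p$lever_width),
           schedule = p$schedule)
    },
    .wf_stop("unknown scenario '%s'", scenario))
  out$params <- p
  out
}

#' Simulate a scenario and render ground-truthed frames
#'
#' Scenarios: `open_frame` (free swimming inside a photopatterned frame),
#' `pillars` (frame + micropillar array), `channel` (frame + corrugated
#' channel; the worm is path-constrained to the lumen centreline), `tmaze`
#' (maze navigation with a seeded left/right choice and terminal coiling) and
#' `hinge` (a rigid lever rotating about its pin following a schedule, no
#' worm). Peak speed is a direct parameter (`peak_speed`, um/s) applied with
#' a plateaued temporal modulation so the configured peak is actually
#' reached; set `params$constant_speed = TRUE` for unmodulated motion.
#'
#' @param scenario scenario name (see above).
#' @param duration_s simulated time.
#' @param seed RNG seed (the only randomness source; identical seeds give
#'   bit-identical frames and ground truth).
#' @param camera a [camera_model()].
#' @param worm a [worm_model()]; its `base_speed_um_s` is overridden by
#'   `params$peak_speed`.
#' @param params named list of scenario parameter overrides.
#' @param sink optional `function(i, frame, t)` called per rendered frame
#'   (streaming use; frames are then not retained unless `keep_frames`).
#' @param keep_frames retain frames in the result as a [frame_sequence()].
#' @param noise render camera noise.
#' @return list with `truth` (per-frame data.frame: `time_s`, `x_um`, `y_um`,
#'   `speed_um_s`, `theta_deg`, `area_px`, `overlap_px`), `env`, `camera`,
#'   `frames` (or NULL), `endpoint` (t-maze ground truth side or NA) and
#'   `maze` (the maze pattern, t-maze only).
#' @export
simulate_scenario <- function(scenario = c("open_frame", "pillars", "channel",
                                           "tmaze", "hinge"),
                              duration_s = 30, seed = 1,
                              camera = camera_model(),
                              worm = worm_model(), params = list(),
                              sink = NULL, keep_frames = is.null(sink),
                              noise = TRUE) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  sc <- .scenario_setup(scenario, params, camera)
  p <- sc$params
  worm$base_speed_um_s <- p$peak_speed
  if (is.null(worm$speed_mod) && !isTRUE(p$constant_speed))
    worm$speed_mod <- speed_plateau_profile(p$mod_period)
  dt <- 1 / camera$frame_rate
  nfr <- max(1L, round(duration_s * camera$frame_rate))
  state <- NULL
  if (sc$mode == "free") {
    state <- worm_init(worm, sc$env, heading = runif(1, 0, 2 * pi))
  } else if (sc$mode == "path") {
    state <- worm_init(worm, sc$env, position = .path_eval(.path_new(sc$path),
                         worm$body_length_um * 1.2)$p[1, ], path = sc$path)
  }
  frames <- if (keep_frames) vector("list", nfr) else NULL
  truth <- data.frame(time_s = numeric(nfr), x_um = NA_real_, y_um = NA_real_,
                      speed_um_s = NA_real_, theta_deg = NA_real_,
                      area_px = NA_real_, overlap_px = NA_real_)
  for (i in seq_len(nfr)) {
    t <- (i - 1) * dt
    bodies <- list(); levers <- list(); theta <- NA_real_
    if (!is.null(state)) {
      if (i > 1) state <- worm_step(state, sc$env, dt)
      b <- worm_body(state)
      bodies <- list(b)
      truth$x_um[i] <- mean(b[, 1]); truth$y_um[i] <- mean(b[, 2])
      truth$speed_um_s[i] <- state$speed_now
    }
    if (sc$mode == "lever") {
      theta <- sc$schedule(t)
      levers <- list(lever_polygon(sc$hinge, theta))
    }
    rf <- render_frame(sc$env, camera, bodies,
                       body_width_um = worm$body_width_um, levers = levers,
                       noise = noise)
    truth$time_s[i] <- t
    truth$theta_deg[i] <- theta
    if (length(rf$worm_area_px)) {
      truth$area_px[i] <- rf$worm_area_px[1]
      truth$overlap_px[i] <- rf$overlap_px[1]
    }
    if (!is.null(sink)) sink(i, rf$frame, t)
    if (keep_frames) frames[[i]] <- rf$frame
  }
  list(truth = truth, env = sc$env, camera = camera,
       frames = if (keep_frames)
         frame_sequence(frames, (seq_len(nfr) - 1) * dt, camera$um_per_px)
       else NULL,
       endpoint = if (!is.null(sc$endpoint)) sc$endpoint else NA_character_,
       maze = sc$maze)
}
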