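#' Closed-loop trigger rule
#'
#' A rule couples an observation condition to a patterning action in the
#' observe-decide-pattern cycle. Conditions: `at_time(t)`,
#' `worm_in_region(region, dwell_s)` (the tracked worm has dwelt in a
#' circular region for `dwell_s` seconds) or `manual(event_id)` (an external
#' event stream, e.g. a researcher's click). The action is an exposure of a
#' pattern; it is validated against the fabrication design rules when the
#' experiment starts, and rejected exposures are logged, not cured.
#'
#' @param condition one of [at_time()], [worm_in_region()], [manual_event()].
#' @param spec pattern (or list) to expose.
#' @param exposure_time exposure duration, s (>= 0.05, the shutter minimum).
#' @param once fire at most once (default TRUE).
#' @param label optional rule label used in the log.
#' @return object of class `wf_rule`.
#' @export
trigger_rule <- function(condition, spec, exposure_time = 1, once = TRUE,
                         label = NULL) {
  if (exposure_time < 0.05)
    .wf_stop("exposure_time %.3g s below the 0.05 s shutter minimum",
             exposure_time)
  stopifnot(inherits(condition, "wf_condition"))
  structure(list(condition = condition, spec = spec,
                 exposure_time = exposure_time, once = once,
                 label = if (is.null(label)) condition$type else label),
            class = "wf_rule")
}

#' @rdname trigger_rule
#' @param t firing time, s.
#' @export
at_time <- function(t) {
  structure(list(type = "at_time", t = t), class = "wf_condition")
}

#' @rdname trigger_rule
#' @param region circular region `(x, y, radius)` um.
#' @param dwell_s required continuous dwell time, s.
#' @export
worm_in_region <- function(region, dwell_s = 1) {
  if (length(region) != 3 || region[3] <= 0)
    .wf_stop("region must be (x, y, radius) with radius > 0")
  structure(list(type = "worm_in_region", region = as.numeric(region),
                 dwell_s = dwell_s), class = "wf_condition")
}

#' @rdname trigger_rule
#' @param event_id identifier matched against the `id` column of the
#'   `manual_events` data.frame given to [run_experiment()].
#' @export
manual_event <- function(event_id) {
  structure(list(type = "manual", event_id = event_id),
            class = "wf_condition")
}

.log_event <- function(log, t, kind, payload = "") {
  rbind(log, data.frame(t = t, kind = kind, payload = payload,
                        stringsAsFactors = FALSE))
}

# move the worm's spine to the nearest free spot if newly cured material
# overlaps it (a worm is never embedded in the hydrogel)
.relocate_worm <- function(state, env) {
  if (is.null(state$trail)) return(state) # path-constrained worms stay put
  b <- worm_body(state)
  margin <- state$model$body_width_um / 2 + env$um_per_px
  if (min(clearance_at(env, b[, 1], b[, 2])) >= margin) return(state)
  head_xy <- b[1, ]
  ok <- env$clearance_px * env$um_per_px >= margin + 2 * env$um_per_px
  if (!any(ok)) .wf_stop("no free lumen left to relocate the worm into")
  ax <- occupancy_axes(env$occupancy)
  idx <- which(ok, arr.ind = TRUE)
  d2 <- (ax$x[idx[, 2]] - head_xy[1])^2 + (ax$y[idx[, 1]] - head_xy[2])^2
  k <- which.min(d2)
  target <- c(ax$x[idx[k, 2]], ax$y[idx[k, 1]])
  # rebuild a straight body in a free lane at the target (the old trail may
  # thread through the newly cured material)
  st2 <- tryCatch(worm_init(state$model, env, position = target,
                            heading = state$heading),
                  error = function(e) NULL)
  if (is.null(st2)) .wf_stop("no free lane at the relocation target")
  state$trail <- st2$trail
  state$heading <- st2$heading
  state$amp_eff <- 0 # re-grow the undulation in the new spot
  state
}

#' Run a closed-loop virtual experiment
#'
#' Per frame: advance the worm, render, track, evaluate the rules and
#' schedule exposures. Newly exposed geometry becomes collidable only after
#' its cure completes (`cure_complete = exposure_start + exposure_time +
#' cure_delay`); a worm overlapping a footprint at cure time is pushed to
#' the nearest free lumen, never embedded. The log is complete and ordered.
#'
#' @param rules list of [trigger_rule()]s.
#' @param duration_s experiment duration, s.
#' @param seed RNG seed.
#' @param camera a [camera_model()].
#' @param worm a [worm_model()] (`NULL` for a worm-free run).
#' @param arena `(xlim, ylim)` list, world um.
#' @param initial_specs patterns already cured at t = 0 (the diffusion
#'   pre-wait is assumed satisfied before the run starts).
#' @param ctx a [fabrication_context()] used to validate rule actions.
#' @param objective objective magnification for validation.
#' @param cure_delay_s photopolymerization time after the exposure, s
#'   (~1 s).
#' @param manual_events optional data.frame `id`, `t` of external events.
#' @param sink optional per-frame callback `function(i, frame, t)`.
#' @param keep_frames retain rendered frames.
#' @return list: `log` (ordered event data.frame), `trajectory`, `truth`,
#'   `env` (final), `frames` (or NULL).
#' @export
run_experiment <- function(rules = list(), duration_s = 10, seed = 1,
                           camera = camera_model(), worm = worm_model(),
                           arena = list(xlim = c(-3000, 3000),
                                        ylim = c(-2000, 2000)),
                           initial_specs = NULL,
                           ctx = fabrication_context(),
                           objective = 5, cure_delay_s = 1,
                           manual_events = NULL, sink = NULL,
                           keep_frames = FALSE) {
  set.seed(seed)
  for (r in rules) stopifnot(inherits(r, "wf_rule"))
  env <- new_environment(initial_specs, arena$xlim, arena$ylim,
                         um_per_px = camera$um_per_px)
  state <- if (!is.null(worm)) worm_init(worm, env,
                                         heading = runif(1, 0, 2 * pi))
  log <- data.frame(t = numeric(0), kind = character(0),
                    payload = character(0), stringsAsFactors = FALSE)
  dt <- 1 / camera$frame_rate
  nfr <- max(1L, round(duration_s * camera$frame_rate))
  tr <- tracker_new(camera$um_per_px)
  pending <- list()   # scheduled cures: list(t_cure, spec, label)
  rulestate <- lapply(rules, function(r) list(fired = FALSE, dwell = 0))
  frames <- if (keep_frames) vector("list", nfr) else NULL
  truth <- data.frame(time_s = numeric(nfr), x_um = NA_real_,
                      y_um = NA_real_, overlap_px = NA_real_)
  for (i in seq_len(nfr)) {
    t <- (i - 1) * dt
    # cures due before this frame become collidable now
    due <- vapply(pending, function(p) p$t_cure <= t, TRUE)
    for (p in pending[due]) {
      env <- env_add_material(env, p$spec)
      log <- .log_event(log, p$t_cure, "cure_complete", p$label)
      if (!is.null(state)) state <- .relocate_worm(state, env)
    }
    pending <- pending[!due]
    bodies <- list()
    if (!is.null(state)) {
      if (i > 1) state <- worm_step(state, env, dt)
      b <- worm_body(state)
      bodies <- list(b)
      truth$x_um[i] <- mean(b[, 1]); truth$y_um[i] <- mean(b[, 2])
    }
    rf <- render_frame(env, camera, bodies,
                       body_width_um = if (is.null(state)) 60 else
                         worm$body_width_um)
    truth$time_s[i] <- t
    truth$overlap_px[i] <- if (length(rf$overlap_px)) rf$overlap_px[1] else 0
    tracker_feed(tr, rf$frame, t)
    log <- .log_event(log, t, "frame", sprintf("%d", i))
    if (!is.null(sink)) sink(i, rf$frame, t)
    if (keep_frames) frames[[i]] <- rf$frame
    # rule evaluation on the *tracked* position (the observe step)
    last <- tr$rows[[length(tr$rows)]]
    for (j in seq_along(rules)) {
      r <- rules[[j]]
      if (r$once && rulestate[[j]]$fired) next
      fire <- FALSE
      cond <- r$condition
      if (cond$type == "at_time") {
        fire <- t >= cond$t
      } else if (cond$type == "worm_in_region") {
        inside <- FALSE
        if (isTRUE(last$valid)) {
          xy <- c(env$occupancy$origin[1] + (last$col - 1) * camera$um_per_px,
                  env$occupancy$origin[2] - (last$row - 1) * camera$um_per_px)
          inside <- sum((xy - cond$region[1:2])^2) <= cond$region[3]^2
        }
        rulestate[[j]]$dwell <- if (inside) rulestate[[j]]$dwell + dt else 0
        fire <- rulestate[[j]]$dwell >= cond$dwell_s
      } else if (cond$type == "manual") {
        fire <- !is.null(manual_events) &&
          any(manual_events$id == cond$event_id & manual_events$t <= t)
      }
      if (!fire) next
      rulestate[[j]]$fired <- TRUE
      log <- .log_event(log, t, "trigger_fired", r$label)
      vr <- validate_feature(r$spec, ctx, objective)
      if (!vr$accepted) {
        log <- .log_event(log, t, "rejection",
                          paste(r$label, ":",
                                paste(vr$violations, collapse = "; ")))
        next
      }
      log <- .log_event(log, t, "exposure_start", r$label)
      pending[[length(pending) + 1]] <-
        list(t_cure = t + r$exposure_time + cure_delay_s, spec = r$spec,
             label = r$label)
    }
  }
  traj <- tracker_finish(tr, origin = env$occupancy$origin)
  list(log = log[order(log$t), ], trajectory = traj, truth = truth,
       env = env,
       frames = if (keep_frames)
         frame_sequence(frames, (seq_len(nfr) - 1) * dt, camera$um_per_px)
       else NULL)
}

#' Reachable free-space area around a point
#'
#' Flood fill of the non-obstacle pixels from the component containing
#' `point`; used to verify progressive confinement (e.g. a spiral drawn
#' around a worm).
#'
#' @param env a `wf_env`.
#' @param point world `(x, y)` um.
#' @return area in um^2 of the connected free region containing the point
#'   (0 if the point is inside an obstacle).
#' @export
reachable_area <- function(env, point) {
  lab <- .cc_label(!env$occupancy$pixels)
  rc <- .world_to_grid(env, point[1], point[2])
  r <- min(max(rc[1], 1), nrow(lab)); c <- min(max(rc[2], 1), ncol(lab))
  k <- lab[r, c]
  if (k == 0) return(0)
  sum(lab == k) * env$um_per_px^2
}

#' Replay a freehand drawing session against a simulated worm
#'
#' Each tablet stamp becomes cured material at
#' `t_event + latency + cure_delay`. Returns the experiment log, the final
#' environment and the reachable-free-space area after each cure (flood fill
#' from the worm position), which strictly decreases as a surrounding stroke
#' closes.
#'
#' @param stream a [stroke_stream()].
#' @param transform a [projection_transform()] mapping the scaled drawing to
#'   the sample.
#' @param duration_s session length, s.
#' @param seed RNG seed.
#' @param camera a [camera_model()].
#' @param worm a [worm_model()] or `NULL`.
#' @param arena arena bounds list.
#' @param cure_delay_s photopolymerization time, s.
#' @return list: `log`, `env`, `areas` (data.frame `t`, `area_um2`),
#'   `updates` (the compiled mask increments).
#' @export
freehand_session <- function(stream, transform, duration_s = NULL, seed = 1,
                             camera = camera_model(),
                             worm = NULL,
                             arena = list(xlim = c(-3000, 3000),
                                          ylim = c(-2000, 2000)),
                             cure_delay_s = 1) {
  set.seed(seed)
  updates <- stroke_to_mask_updates(stream, transform)
  env <- new_environment(NULL, arena$xlim, arena$ylim,
                         um_per_px = camera$um_per_px)
  state <- if (!is.null(worm)) worm_init(worm, env)
  wpos <- if (!is.null(state)) worm_body(state)[1, ] else c(0, 0)
  log <- data.frame(t = numeric(0), kind = character(0),
                    payload = character(0), stringsAsFactors = FALSE)
  areas <- data.frame(t = numeric(0), area_um2 = numeric(0))
  for (u in updates) {
    t_cure <- u$t_projected + cure_delay_s
    log <- .log_event(log, u$t_projected, "exposure_start", "stamp")
    env <- env_add_material(env, u$mask)
    if (!is.null(state)) state <- .relocate_worm(state, env)
    log <- .log_event(log, t_cure, "cure_complete", "stamp")
    areas <- rbind(areas,
                   data.frame(t = t_cure,
                              area_um2 = reachable_area(env, wpos)))
  }
  list(log = log, env = env, areas = areas, updates = updates)
}
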