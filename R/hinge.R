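#' Hinge-pin mechanism
#'
#' A free-floating rigid lever cured around an anchored pin. The lever can
#' rotate about the pin; its angle is measured in degrees from vertical
#' (clockwise positive in the image). The lever only moves while a worm
#' pushes it: quasi-static angle increments, no torque physics.
#'
#' @param pin_center `(x, y)` um of the anchored pin.
#' @param lever_length,lever_width lever rectangle dimensions, um; the pin
#'   sits `lever_width` from the lever's base end, on its long axis.
#' @param angle_deg initial angle from vertical, degrees.
#' @param contact_gain_deg_s rotation rate while in worm contact, deg/s.
#' @return object of class `wf_hinge`.
#' @export
hinge_pin <- function(pin_center, lever_length = 600, lever_width = 100,
                      angle_deg = 0, contact_gain_deg_s = 5) {
  stopifnot(lever_length > 0, lever_width > 0)
  structure(list(pin_center = as.numeric(pin_center),
                 lever_length = lever_length, lever_width = lever_width,
                 angle_deg = angle_deg,
                 contact_gain_deg_s = contact_gain_deg_s),
            class = "wf_hinge")
}

#' Lever outline polygon at the hinge's current angle
#'
#' @param hinge a [hinge_pin()].
#' @param angle_deg angle override, degrees from vertical.
#' @return 4 x 2 matrix of world um vertices.
#' @export
lever_polygon <- function(hinge, angle_deg = hinge$angle_deg) {
  th <- angle_deg * pi / 180
  axis <- c(sin(th), cos(th))      # from vertical (+y), clockwise positive
  perp <- c(cos(th), -sin(th))
  base <- hinge$pin_center - axis * hinge$lever_width
  tip <- base + axis * hinge$lever_length
  hw <- hinge$lever_width / 2
  rbind(base + perp * hw, tip + perp * hw, tip - perp * hw, base - perp * hw)
}

# distance from points to a convex polygon (0 inside)
.poly_dist <- function(poly, x, y) {
  inside <- pattern_contains(pattern_polygon(poly), x, y)
  n <- nrow(poly)
  d2 <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[i %% n + 1, ]
    ab <- b - a
    tt <- pmin(pmax(((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / sum(ab^2), 0), 1)
    d2 <- pmin(d2, (x - (a[1] + tt * ab[1]))^2 + (y - (a[2] + tt * ab[2]))^2)
  }
  ifelse(inside, 0, sqrt(d2))
}

#' Advance a hinge under worm contact
#'
#' The lever rotates (monotonically within a contact bout) while the worm is
#' braced: at least one body point touches the lever and another body point
#' is braced against fixed material (low clearance). Without contact the
#' angle is unchanged.
#'
#' @param hinge a [hinge_pin()].
#' @param body n x 2 worm body points ([worm_body()]).
#' @param env a `wf_env`.
#' @param dt time step, s.
#' @param body_width_um worm body width used as the contact distance.
#' @return updated `wf_hinge`.
#' @export
hinge_step <- function(hinge, body, env, dt, body_width_um = 60) {
  poly <- lever_polygon(hinge)
  d <- .poly_dist(poly, body[, 1], body[, 2])
  touching <- d <= body_width_um / 2 + 1
  braced <- clearance_at(env, body[, 1], body[, 2]) <= body_width_um
  if (any(touching) && any(braced & !touching))
    hinge$angle_deg <- hinge$angle_deg + hinge$contact_gain_deg_s * dt
  hinge
}

#' Stepwise lever rotation schedule
#'
#' Reproduces the characteristic worm-push kinematics: within each push
#' cycle the lever rotates during the contact phase (a `duty` fraction of
#' the cycle) and holds for the rest, stepping monotonically from
#' `angle0_deg` to `angle1_deg` over `duration_s`.
#'
#' @param angle0_deg,angle1_deg start and end angles, degrees from vertical.
#' @param duration_s total duration, s.
#' @param cycles number of push cycles.
#' @param duty fraction of each cycle spent rotating.
#' @return function of time t (s) returning the angle in degrees.
#' @export
lever_schedule <- function(angle0_deg = 6, angle1_deg = 27, duration_s = 6,
                           cycles = 6, duty = 0.6) {
  force(angle0_deg); force(angle1_deg)
  cyc_len <- duration_s / cycles
  step <- (angle1_deg - angle0_deg) / cycles
  function(t) {
    t <- pmin(pmax(t, 0), duration_s)
    k <- pmin(floor(t / cyc_len), cycles - 1)
    frac <- pmin((t - k * cyc_len) / (duty * cyc_len), 1)
    angle0_deg + step * (k + frac)
  }
}

#' Replay a scheduled lever rotation through the orientation tracker
#'
#' Renders a rigid lever rotating about its pin following `schedule`,
#' segments every frame against a lever-free background still, measures the
#' principal-axis angle from second central moments and unwraps it.
#'
#' @param schedule function of time returning the lever angle (degrees from
#'   vertical), e.g. [lever_schedule()].
#' @param duration_s rendered duration.
#' @param seed RNG seed (camera noise).
#' @param camera a [camera_model()].
#' @param config a [tracker_config()] (segmentation threshold).
#' @return data.frame with `time_s`, `theta_true_deg`, `theta_meas_deg`.
#' @export
hinge_replay <- function(schedule = lever_schedule(), duration_s = 6,
                         seed = 1, camera = camera_model(),
                         config = tracker_config()) {
  sim <- simulate_scenario("hinge", duration_s = duration_s, seed = seed,
                           camera = camera, params = list(schedule = schedule))
  # lever-free still: the same environment rendered with no lever
  bg <- render_frame(sim$env, camera, noise = FALSE)$frame
  th <- vapply(sim$frames$frames, function(f) {
    m <- segment_body(f, bg, config)
    if (isTRUE(attr(m, "empty"))) return(NA_real_)
    orientation_from_moments(m)
  }, 0)
  data.frame(time_s = sim$frames$times,
             theta_true_deg = sim$truth$theta_deg,
             theta_meas_deg = unwrap_orientation(th))
}
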