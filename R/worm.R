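#' Kinematic worm model parameters
#'
#' A phenomenological follow-the-leader model: the head advances along its
#' heading; the body spine follows the head's past path; a constant-amplitude
#' sinusoidal travelling wave is superimposed perpendicular to the spine.
#' The wavelength default (one body length, the swimming gait) keeps an
#' integer number of waves along the body, so the body centroid stays on the
#' smooth spine path, mimicking the approximately conserved centre of mass
#' of a real swimming worm; it also keeps the undulation wave speed
#' (frequency x wavelength = 2 mm/s) well above any translation speed, the
#' large-slip regime of real undulatory swimming. There is no force physics:
#' speed is prescribed (base speed x optional temporal modulation x
#' confinement gain) and collisions are resolved by steering.
#'
#' @param body_length_um body length (adult ~1000 um).
#' @param body_width_um body width (adult ~60 um; L1 ~15 um).
#' @param amplitude_um undulation amplitude (clipped automatically to the
#'   available clearance).
#' @param wavelength_um undulation wavelength.
#' @param frequency_hz undulation frequency (adult swimming ~2 Hz).
#' @param base_speed_um_s forward speed scale.
#' @param turn_sd_rad heading random-walk intensity (rad / sqrt(s)).
#' @param speed_mod optional function of time returning a multiplier in
#'   `(0, 1]`; `NULL` means constant speed.
#' @param confinement list `(gain_max, c0_um, width_um)`: speed multiplier
#'   `1 + (gain_max - 1) * plogis((c0 - clearance) / width)`, the
#'   phenomenological swim-faster-when-confined coupling.
#' @param food_bias_rad_s heading attraction rate towards the nearest food
#'   site (rad/s), 0 to disable.
#' @return object of class `wf_worm_model`.
#' @export
worm_model <- function(body_length_um = 1000, body_width_um = 60,
                       amplitude_um = 120, wavelength_um = body_length_um,
                       frequency_hz = 2, base_speed_um_s = 330,
                       turn_sd_rad = 0.15, speed_mod = NULL,
                       confinement = list(gain_max = 1, c0_um = 200,
                                          width_um = 50),
                       food_bias_rad_s = 0) {
  stopifnot(body_length_um > 0, body_width_um > 0, wavelength_um > 0)
  structure(as.list(environment()), class = "wf_worm_model")
}

#' Speed modulation with plateaus
#'
#' Deterministic burst-and-glide speed profile: a squared sinusoid clipped at
#' 1, so the configured peak speed is held for extended plateaus (making the
#' maximum well defined) and the floor is ~0.35.
#'
#' @param period_s modulation period.
#' @return function of time t (s).
#' @export
speed_plateau_profile <- function(period_s = 30) {
  force(period_s)
  function(t) pmin(1, 0.35 + 0.85 * sin(pi * t / period_s)^2)
}

#' Initialise a worm in an environment
#'
#' The worm starts with a straight body behind the head. Initialising inside
#' an obstacle (clearance below half the body width) is an error.
#'
#' @param model a [worm_model()].
#' @param env a `wf_env`.
#' @param position head position `(x, y)` um; default is the most open spot.
#' @param heading initial heading, rad (0 = +x, counter-clockwise).
#' @param path optional n x 2 polyline (um). When given the worm is
#'   path-constrained: it moves back and forth along the path instead of
#'   free-roaming (used for channel and maze scenarios).
#' @return object of class `wf_worm` (simulation state).
#' @export
worm_init <- function(model, env, position = NULL, heading = 0, path = NULL) {
  need <- model$body_width_um / 2 + 2 * env$um_per_px
  sarc <- seq(model$body_length_um * 1.2, 0, length.out = 24)
  lane_heading <- function(pos, h0) {
    # first heading whose straight initial body is fully clear; the grid
    # includes the cardinal directions (lattice environments have
    # axis-aligned lanes)
    cand <- c(h0 + seq(0, 2 * pi - 1e-6, by = pi / 18),
              0, pi / 2, pi, 3 * pi / 2)
    for (hh in cand) {
      back <- -c(cos(hh), sin(hh))
      px <- pos[1] + back[1] * sarc
      py <- pos[2] + back[2] * sarc
      if (min(clearance_at(env, px, py)) >= need) return(hh %% (2 * pi))
    }
    NA_real_
  }
  if (is.null(position)) {
    if (any(env$occupancy$pixels)) {
      ax <- occupancy_axes(env$occupancy)
      edge <- outer(pmin(ax$y - env$ylim[1], env$ylim[2] - ax$y),
                    pmin(ax$x - env$xlim[1], env$xlim[2] - ax$x), pmin)
      sc <- pmin(env$clearance_px * env$um_per_px, edge)
      nr <- nrow(sc)
      # try the most open spots in turn until one offers a free body lane
      for (try in 1:25) {
        i <- which.max(sc)
        pos <- c(ax$x[(i - 1) %/% nr + 1], ax$y[(i - 1) %% nr + 1])
        if (is.null(path) && sc[i] >= need) {
          hh <- lane_heading(pos, heading)
          if (!is.na(hh)) { position <- pos; heading <- hh; break }
        } else if (sc[i] >= need) {
          position <- pos
          break
        }
        # blank a neighbourhood and move on to the next candidate pocket
        rc <- .world_to_grid(env, pos[1], pos[2])
        rs <- max(1, rc[1] - 200):min(nr, rc[1] + 200)
        cs <- max(1, rc[2] - 200):min(ncol(sc), rc[2] + 200)
        sc[rs, cs] <- -Inf
      }
      if (is.null(position))
        .wf_stop("no free lane found for the initial worm body")
    } else {
      position <- c(mean(env$xlim), mean(env$ylim))
    }
  }
  if (clearance_at(env, position[1], position[2]) < model$body_width_um / 2)
    .wf_stop("worm initialised inside (or touching) an obstacle")
  st <- structure(list(model = model, heading = heading, t = 0,
                       amp_eff = 0, speed_now = 0), class = "wf_worm")
  if (is.null(path)) {
    hh <- lane_heading(position, heading)
    if (!is.na(hh)) heading <- hh
    st$heading <- heading
    st$trail <- .straight_trail(model, position, heading)
  } else {
    st$path <- .path_new(path)
    st$path_pos <- model$body_length_um * 1.2
    st$path_dir <- 1
  }
  st
}

# straight body trail ending at `position` pointing along `heading`
.straight_trail <- function(model, position, heading) {
  back <- -c(cos(heading), sin(heading))
  n0 <- 64
  .path_new(cbind(position[1] + back[1] * seq(model$body_length_um * 1.2, 0,
                                              length.out = n0),
                  position[2] + back[2] * seq(model$body_length_um * 1.2, 0,
                                              length.out = n0)))
}

# ---- polyline helpers ------------------------------------------------------

.path_new <- function(pts) {
  pts <- .as_xy_matrix(pts)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  list(pts = pts, cum = c(0, cumsum(seg)))
}

.path_len <- function(path) path$cum[length(path$cum)]

# points (and unit tangents) at arc positions s (clamped)
.path_eval <- function(path, s) {
  s <- pmin(pmax(s, 0), .path_len(path))
  i <- findInterval(s, path$cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), nrow(path$pts) - 1)
  seg <- path$cum[i + 1] - path$cum[i]
  f <- ifelse(seg > 0, (s - path$cum[i]) / seg, 0)
  p <- path$pts[i, , drop = FALSE] * (1 - f) +
       path$pts[i + 1, , drop = FALSE] * f
  tang <- path$pts[i + 1, , drop = FALSE] - path$pts[i, , drop = FALSE]
  nrm <- sqrt(rowSums(tang^2)); nrm[nrm == 0] <- 1
  list(p = p, tangent = tang / nrm)
}

.path_append <- function(path, pt) {
  n <- nrow(path$pts)
  d <- sqrt(sum((pt - path$pts[n, ])^2))
  path$pts <- rbind(path$pts, pt)
  path$cum <- c(path$cum, path$cum[n] + d)
  # trim far-behind history to keep the trail compact
  keepfrom <- which(path$cum >= path$cum[n + 1] - 4000)[1]
  if (!is.na(keepfrom) && keepfrom > 64) {
    path$pts <- path$pts[keepfrom:(n + 1), , drop = FALSE]
    path$cum <- path$cum[keepfrom:(n + 1)]
  }
  path
}

# ---- stepping --------------------------------------------------------------

#' Advance the worm state by dt seconds
#'
#' Free-roaming worms advance the head along the heading at
#' `base_speed * speed_mod(t) * confinement_gain(clearance)`, with heading
#' noise, optional food attraction and steering around obstacles (the head
#' never moves to a point whose clearance cannot hold the body half-width
#' plus the current undulation amplitude; if every direction is blocked the
#' worm reverses). Path-constrained worms advance along their path and bounce
#' at its ends. Uses the R RNG stream: seed before simulating.
#'
#' @param state a `wf_worm`.
#' @param env a `wf_env`.
#' @param dt time step, s.
#' @return updated `wf_worm`.
#' @export
worm_step <- function(state, env, dt) {
  m <- state$model
  t <- state$t
  mod <- if (is.null(m$speed_mod)) 1 else m$speed_mod(t)
  if (!is.null(state$path)) {
    v <- m$base_speed_um_s * mod
    state$speed_now <- v
    lo <- m$body_length_um * 1.05
    hi <- .path_len(state$path) - m$body_width_um
    # the speed parameter prescribes the *centroid* speed: on a curved path
    # the centroid moves at |mean body tangent| x (arc speed), so the arc
    # advance is compensated by that factor
    tang <- .path_eval(state$path,
                       state$path_pos - seq(0, m$body_length_um,
                                            length.out = 9))$tangent
    f <- sqrt(sum(colMeans(tang)^2))
    f <- max(f, 0.8)
    s2 <- state$path_pos + state$path_dir * (v / f) * dt
    if (s2 > hi) { state$path_dir <- -1; s2 <- hi - (s2 - hi) }
    if (s2 < lo) { state$path_dir <- 1; s2 <- lo + (lo - s2) }
    state$path_pos <- s2
    head_xy <- .path_eval(state$path, s2)$p[1, ]
  } else {
    head0 <- state$trail$pts[nrow(state$trail$pts), ]
    cl <- clearance_at(env, head0[1], head0[2])
    gain <- 1 + (m$confinement$gain_max - 1) *
      stats::plogis((m$confinement$c0_um - cl) / m$confinement$width_um)
    v <- m$base_speed_um_s * mod * gain
    state$speed_now <- v
    h <- state$heading + rnorm(1, 0, m$turn_sd_rad * sqrt(dt))
    if (m$food_bias_rad_s > 0 && !is.null(env$food_sites)) {
      fs <- env$food_sites
      d2 <- (fs[, "x"] - head0[1])^2 + (fs[, "y"] - head0[2])^2
      k <- which.min(d2)
      want <- atan2(fs[k, "y"] - head0[2], fs[k, "x"] - head0[1])
      dh <- ((want - h + pi) %% (2 * pi)) - pi
      h <- h + sign(dh) * min(abs(dh), m$food_bias_rad_s * dt * fs[k, "strength"])
    }
    margin <- m$body_width_um / 2 + state$amp_eff + 3 * env$um_per_px
    step_len <- v * dt
    cand <- c(0, as.vector(rbind(1, -1) %o% seq(0.2, 3, by = 0.2)))
    moved <- FALSE
    for (dth in cand) {
      hh <- h + dth
      p2 <- head0 + step_len * c(cos(hh), sin(hh))
      mid <- head0 + 0.5 * step_len * c(cos(hh), sin(hh))
      if (clearance_at(env, p2[1], p2[2]) >= margin &&
          clearance_at(env, mid[1], mid[2]) >= margin) {
        state$heading <- hh
        state$trail <- .path_append(state$trail, p2)
        moved <- TRUE
        break
      }
    }
    if (!moved) state$heading <- h + pi # boxed in: reverse, try next step
    head_xy <- state$trail$pts[nrow(state$trail$pts), ]
  }
  # adapt undulation amplitude to the clearance along the whole body plus a
  # short lookahead; shrink instantly (never swing into a wall), grow slowly
  sarc <- seq(0, m$body_length_um, length.out = 9)
  spine <- if (!is.null(state$path)) {
    .path_eval(state$path, state$path_pos - sarc)$p
  } else {
    .path_eval(state$trail, .path_len(state$trail) - sarc)$p
  }
  ahead <- if (!is.null(state$path)) {
    .path_eval(state$path, state$path_pos + state$path_dir * 300)$p
  } else {
    rbind(head_xy + 300 * c(cos(state$heading), sin(state$heading)))
  }
  cl <- min(clearance_at(env, c(spine[, 1], ahead[, 1]),
                         c(spine[, 2], ahead[, 2])))
  amp_target <- max(0, min(m$amplitude_um,
                           cl - m$body_width_um / 2 - 3 * env$um_per_px))
  state$amp_eff <- if (amp_target < state$amp_eff) amp_target else
    state$amp_eff + 0.25 * (amp_target - state$amp_eff)
  state$t <- t + dt
  state
}

#' Body spine points of a worm state
#'
#' Samples the spine at `n` arc positions behind the head along the trail (or
#' path) and adds the perpendicular undulation offset.
#'
#' @param state a `wf_worm`.
#' @param n number of body points (>= 11).
#' @return n x 2 matrix of world um, head first.
#' @export
worm_body <- function(state, n = 41) {
  m <- state$model
  sarc <- seq(0, m$body_length_um, length.out = n)
  if (!is.null(state$path)) {
    base <- .path_eval(state$path, state$path_pos - sarc)
  } else {
    stail <- .path_len(state$trail)
    base <- .path_eval(state$trail, stail - sarc)
  }
  off <- state$amp_eff *
    sin(2 * pi * sarc / m$wavelength_um - 2 * pi * m$frequency_hz * state$t)
  nx <- -base$tangent[, 2]; ny <- base$tangent[, 1]
  # zero-mean shape wave: internal shape changes must not move the centre
  # of mass (net propulsion is already encoded in the prescribed spine
  # translation), so the mean lateral displacement is subtracted
  dx <- off * nx; dy <- off * ny
  cbind(x = base$p[, 1] + dx - mean(dx), y = base$p[, 2] + dy - mean(dy))
}
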