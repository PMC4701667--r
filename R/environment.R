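#' Camera model for synthetic rendering
#'
#' Renders what the SLR sees through the imaging train: dark worm on a light
#' NGM background, semi-opaque cured hydrogel, additive Gaussian read noise,
#' 8-bit quantization.
#'
#' @param um_per_px pixel size at the sample, um (default 5).
#' @param frame_rate frames per second (default 10).
#' @param background_level,worm_level,obstacle_level gray levels in `[0,255]`;
#'   the worm must be darker than the background.
#' @param noise_sd additive Gaussian noise standard deviation (gray levels).
#' @return object of class `wf_camera`.
#' @export
camera_model <- function(um_per_px = 5, frame_rate = 10,
                         background_level = 200, worm_level = 60,
                         obstacle_level = 150, noise_sd = 3) {
  stopifnot(um_per_px > 0, frame_rate > 0,
            background_level >= 0, background_level <= 255,
            worm_level < background_level, worm_level >= 0, noise_sd >= 0)
  structure(list(um_per_px = um_per_px, frame_rate = frame_rate,
                 background_level = background_level,
                 worm_level = worm_level, obstacle_level = obstacle_level,
                 noise_sd = noise_sd), class = "wf_camera")
}

#' Simulation environment
#'
#' Holds the arena bounds, the cured-obstacle occupancy raster (on the same
#' grid the camera renders), a clearance map (distance to the nearest
#' obstacle or arena edge), optional food sites and hinge mechanisms.
#'
#' @param specs pattern or list of patterns cured at t = 0 (may be `NULL`).
#' @param xlim,ylim arena bounds, world um.
#' @param um_per_px grid/camera pitch, um.
#' @param food_sites optional matrix/data.frame with columns `x`, `y`,
#'   `strength`.
#' @param hinges optional list of [hinge_pin()] mechanisms.
#' @return object of class `wf_env`.
#' @export
new_environment <- function(specs = NULL, xlim, ylim, um_per_px = 5,
                            food_sites = NULL, hinges = list()) {
  occ <- if (is.null(specs)) {
    xs <- seq(xlim[1] + um_per_px / 2, xlim[2], by = um_per_px)
    ys <- seq(ylim[2] - um_per_px / 2, ylim[1], by = -um_per_px)
    new_occupancy(matrix(FALSE, length(ys), length(xs)),
                  origin = c(xs[1], ys[1]), um_per_px = um_per_px)
  } else {
    rasterize_world(specs, xlim, ylim, um_per_px)
  }
  env <- structure(list(occupancy = occ, xlim = xlim, ylim = ylim,
                        um_per_px = um_per_px,
                        food_sites = food_sites, hinges = hinges,
                        clearance_px = NULL), class = "wf_env")
  .env_refresh_clearance(env)
}

.env_refresh_clearance <- function(env) {
  px <- env$occupancy$pixels
  env$clearance_px <- if (any(px)) sqrt(.dist_transform_sq(px)) else
    matrix(Inf, nrow(px), ncol(px))
  env$cache <- new.env(parent = emptyenv()) # per-occupancy render memo
  env
}

#' Add cured material to an environment
#'
#' Used by the closed-loop driver when an exposure completes curing. The new
#' occupancy is OR-ed in (resampled from its own grid by nearest neighbour if
#' needed) and the clearance map is recomputed.
#'
#' @param env a `wf_env`.
#' @param what a pattern (or list), `wf_mask` + `stage_offset`, or
#'   `wf_occupancy`.
#' @param stage_offset `(x, y)` um translation applied to a mask's geometry.
#' @return updated `wf_env`.
#' @export
env_add_material <- function(env, what, stage_offset = c(0, 0)) {
  add <- if (inherits(what, "wf_occupancy")) {
    .resample_occupancy(what, env$occupancy)
  } else if (inherits(what, "wf_mask")) {
    .resample_occupancy(stitch(list(what), list(stage_offset)), env$occupancy)
  } else {
    rasterize_world(what, env$xlim, env$ylim, env$um_per_px)$pixels
  }
  env$occupancy$pixels <- env$occupancy$pixels | add
  .env_refresh_clearance(env)
}

# nearest-neighbour resample of occupancy `src` onto the grid of `dst`
.resample_occupancy <- function(src, dst) {
  ax <- occupancy_axes(dst)
  cs <- round(1 + (ax$x - src$origin[1]) / src$um_per_px)
  rs <- round(1 + (src$origin[2] - ax$y) / src$um_per_px)
  out <- matrix(FALSE, nrow(dst$pixels), ncol(dst$pixels))
  okc <- which(cs >= 1 & cs <= ncol(src$pixels))
  okr <- which(rs >= 1 & rs <= nrow(src$pixels))
  if (length(okc) && length(okr))
    out[okr, okc] <- src$pixels[rs[okr], cs[okc]]
  out
}

# world (x, y) -> (row, col) index on the environment/camera grid
.world_to_grid <- function(env, x, y) {
  s <- env$um_per_px
  cbind(row = round(1 + (env$ylim[2] - s / 2 - y) / s),
        col = round(1 + (x - env$xlim[1] - s / 2) / s))
}

#' Clearance (um) from world points to the nearest obstacle or arena edge
#'
#' @param env a `wf_env`.
#' @param x,y world coordinates, um.
#' @return numeric vector of clearances.
#' @export
clearance_at <- function(env, x, y) {
  rc <- .world_to_grid(env, x, y)
  nr <- nrow(env$clearance_px); nc <- ncol(env$clearance_px)
  r <- pmin(pmax(rc[, 1], 1), nr)
  c <- pmin(pmax(rc[, 2], 1), nc)
  d_obs <- env$clearance_px[cbind(r, c)] * env$um_per_px
  d_edge <- pmin(x - env$xlim[1], env$xlim[2] - x,
                 y - env$ylim[1], env$ylim[2] - y)
  pmin(d_obs, d_edge)
}
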