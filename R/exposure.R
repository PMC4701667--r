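#' Exposure/resolution calibration table
#'
#' Empirical anchors relating objective magnification and cured feature
#' height to the achievable line-pair resolution and the optimal exposure
#' time, plus the fabrication design-rule constants. The default table
#' carries only the text-anchored resolution values (thick 10-100 um films:
#' ~3 um at 50X, ~23 um at 5X; thin 1 um films: 0.7 um at 50X, 1 um at 20X);
#' exposure anchors are empty by default, in which case the parametric
#' fallback `t = k_obj / height` is used (inverse exposure-height
#' relationship, oxygen inhibition at the hydrogel/NGM interface), clamped at
#' the 50 ms mechanical shutter minimum.
#'
#' @param anchors data.frame with columns `objective`, `height_um`,
#'   `resolution_um`, `exposure_s` (`exposure_s` may be NA).
#' @param constants named list overriding any of `min_raised_feature_width`
#'   (50 um), `min_raised_aspect` (2), `diffusion_wait` (300 s),
#'   `min_shutter` (0.05 s), `k_exposure` (100 s.um, the fallback constant;
#'   1 s for a 100 um tall feature).
#' @return object of class `wf_calibration`.
#' @export
calibration_table <- function(anchors = NULL, constants = list()) {
  if (is.null(anchors)) {
    anchors <- data.frame(
      objective     = c(50, 50, 50, 5, 5, 20),
      height_um     = c(1, 10, 100, 10, 100, 1),
      resolution_um = c(0.7, 3, 3, 23, 23, 1),
      exposure_s    = NA_real_)
  }
  stopifnot(all(c("objective", "height_um", "resolution_um") %in% names(anchors)))
  if (is.null(anchors$exposure_s)) anchors$exposure_s <- NA_real_
  if (any(anchors$resolution_um <= 0, na.rm = TRUE) ||
      any(anchors$exposure_s <= 0, na.rm = TRUE))
    .wf_stop("resolutions and exposures must be > 0")
  cst <- list(min_raised_feature_width = 50, min_raised_aspect = 2,
              diffusion_wait = 300, min_shutter = 0.05, k_exposure = 100)
  cst[names(constants)] <- constants
  # optimal exposure must be non-increasing in height within each objective
  for (ob in unique(anchors$objective)) {
    a <- anchors[anchors$objective == ob & !is.na(anchors$exposure_s), ]
    if (nrow(a) >= 2) {
      a <- a[order(a$height_um), ]
      if (is.unsorted(rev(a$exposure_s)))
        .wf_stop("exposure anchors for objective %g are not non-increasing in height", ob)
    }
  }
  structure(list(anchors = anchors, constants = cst),
            class = "wf_calibration")
}

#' @export
print.wf_calibration <- function(x, ...) {
  cat("wf_calibration\n")
  print(x$anchors, row.names = FALSE)
  cat(sprintf("constants: %s\n",
              paste(names(x$constants), unlist(x$constants),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

.anchors_for <- function(cal, objective) {
  a <- cal$anchors[cal$anchors$objective == objective, , drop = FALSE]
  if (nrow(a) == 0)
    .wf_stop("unknown objective %g; available: %s", objective,
             paste(sort(unique(cal$anchors$objective)), collapse = ", "))
  a[order(a$height_um), , drop = FALSE]
}

# log-log interpolation with clamping (warn outside the anchored range)
.loglog_lookup <- function(h, hs, vs, what) {
  if (h < min(hs) || h > max(hs)) {
    .wf_warn("height %g um outside the anchored range [%g, %g]; clamping %s",
             h, min(hs), max(hs), what)
    h <- min(max(h, min(hs)), max(hs))
  }
  if (length(hs) == 1) return(vs)
  exp(approx(log(hs), log(vs), xout = log(h), ties = "ordered")$y)
}

#' Line-pair resolution for an objective and feature height
#'
#' Returns stored anchors exactly; log-log linear interpolation between
#' anchors of the same objective; clamps (with a warning) outside the
#' anchored height range.
#'
#' @param objective objective magnification (must be in the table).
#' @param height_um cured feature height, um.
#' @param cal a [calibration_table()].
#' @return line-pair resolution in um.
#' @export
resolution_lookup <- function(objective, height_um,
                              cal = calibration_table()) {
  stopifnot(height_um > 0)
  a <- .anchors_for(cal, objective)
  .loglog_lookup(height_um, a$height_um, a$resolution_um, "resolution")
}

#' Optimal exposure time for an objective and feature height
#'
#' Uses exposure anchors (log-log interpolated) when at least two exist for
#' the objective, otherwise the parametric fallback `t = k / height`. The
#' result never drops below the 50 ms mechanical shutter minimum and is
#' non-increasing in height.
#'
#' @inheritParams resolution_lookup
#' @return exposure time in seconds.
#' @export
optimal_exposure <- function(objective, height_um,
                             cal = calibration_table()) {
  stopifnot(height_um > 0)
  a <- .anchors_for(cal, objective)
  a <- a[!is.na(a$exposure_s), , drop = FALSE]
  t <- if (nrow(a) >= 2) {
    .loglog_lookup(height_um, a$height_um, a$exposure_s, "exposure")
  } else {
    cal$constants$k_exposure / height_um
  }
  max(t, cal$constants$min_shutter)
}

#' Check the diffusion-adhesion condition
#'
#' Cured features bond to the NGM only if the hydrogel has been allowed to
#' diffuse into the agar first; without the wait, exposed samples do not
#' adhere. The threshold is strict: exactly five minutes (300 s) of elapsed
#' diffusion is required.
#'
#' @param ctx a [fabrication_context()].
#' @return TRUE iff `diffusion_time_elapsed >= diffusion_wait` (300 s).
#' @export
adhesion_check <- function(ctx) {
  ctx$diffusion_time_elapsed >= calibration_table()$constants$diffusion_wait
}

#' Fabrication context
#'
#' @param gap_height_um cover-gap height defined by the spacer beads, um
#'   (limits cured feature height).
#' @param diffusion_time_elapsed seconds the hydrogel has diffused into the
#'   NGM before exposure.
#' @param polymer_fraction PEG-DA fraction in water (default 0.20).
#' @param exposure_time intended exposure, s.
#' @return object of class `wf_fab_context`.
#' @export
fabrication_context <- function(gap_height_um = 100,
                                diffusion_time_elapsed = 300,
                                polymer_fraction = 0.20,
                                exposure_time = 1) {
  stopifnot(gap_height_um >= 0, diffusion_time_elapsed >= 0,
            polymer_fraction > 0, polymer_fraction <= 1, exposure_time >= 0)
  structure(list(gap_height_um = gap_height_um,
                 diffusion_time_elapsed = diffusion_time_elapsed,
                 polymer_fraction = polymer_fraction,
                 exposure_time = exposure_time), class = "wf_fab_context")
}

# per-variant feature inventory: raised solid widths and negative channel
# widths, um
.pattern_features <- function(spec) {
  switch(spec$variant,
    frame = list(raised = c(wall = spec$wall_thickness), channels = numeric(0)),
    pillar_array = list(raised = c(pillar = spec$diameter),
                        channels = c(gap = spec$pitch - spec$diameter)),
    t_maze = list(raised = c(wall = spec$wall_thickness),
                  channels = c(channel = spec$channel_width)),
    spiral = list(raised = c(wall = spec$wall_thickness),
                  channels = c(channel = spec$channel_width)),
    corrugated_channel = list(raised = c(wall = spec$wall_thickness),
                              channels = c(channel = spec$width)),
    disk = list(raised = c(disk = 2 * spec$radius), channels = numeric(0)),
    polygon = list(raised = c(polygon = .polygon_min_width(spec$vertices)),
                   channels = numeric(0)),
    .wf_stop("unknown pattern variant '%s'", spec$variant))
}

# minimum width of a polygon measured by rasterizing at fine pitch and
# taking twice the maximum of the interior distance transform
.polygon_min_width <- function(v) {
  if (nrow(v) < 3) return(0)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  s <- max((xr[2] - xr[1]), (yr[2] - yr[1]), 1) / 400
  occ <- rasterize_world(pattern_polygon(v),
                         xr + c(-2, 2) * s, yr + c(-2, 2) * s, s)
  if (!any(occ$pixels)) return(0)
  d <- .dist_transform_sq(!occ$pixels)
  2 * sqrt(max(d[occ$pixels])) * s
}

#' Validate a pattern against the fabrication design rules
#'
#' Rules: raised (positive) solids narrower than the 50 um minimum raised
#' feature width break off the agar on rinsing (adhesion failure); negative
#' channels narrower than the line-pair resolution at this objective/height
#' are unresolvable; features taller than the bead-defined cover gap are
#' gap-limited; degenerate (non-positive) channel widths are rejected
#' outright. Every violating primitive is listed.
#'
#' @param spec a pattern or list of patterns.
#' @param ctx a [fabrication_context()]; the intended feature height is taken
#'   as `min(gap_height_um, height_um)`.
#' @param objective objective magnification.
#' @param height_um intended cured feature height, um.
#' @param cal a [calibration_table()].
#' @return list with `accepted` (logical) and `violations`
#'   (character vector of reasons, empty when accepted).
#' @export
validate_feature <- function(spec, ctx, objective, height_um = ctx$gap_height_um,
                             cal = calibration_table()) {
  specs <- if (inherits(spec, "wf_pattern")) list(spec) else spec
  viol <- character(0)
  if (height_um > ctx$gap_height_um)
    viol <- c(viol, sprintf(
      "gap-limited: feature height %g um exceeds the %g um cover gap",
      height_um, ctx$gap_height_um))
  res <- suppressWarnings(resolution_lookup(objective, height_um, cal))
  wmin <- cal$constants$min_raised_feature_width
  for (s in specs) {
    ft <- .pattern_features(s)
    for (nm in names(ft$raised)) {
      w <- ft$raised[[nm]]
      if (w < wmin)
        viol <- c(viol, sprintf(
          "%s/%s: raised width %g um below the %g um minimum (adhesion failure)",
          s$variant, nm, w, wmin))
    }
    for (nm in names(ft$channels)) {
      w <- ft$channels[[nm]]
      if (w <= 0)
        viol <- c(viol, sprintf("%s/%s: degenerate channel width %g um",
                                s$variant, nm, w))
      else if (w < res)
        viol <- c(viol, sprintf(
          "%s/%s: channel width %g um below the %g um line-pair resolution",
          s$variant, nm, w, signif(res, 3)))
    }
  }
  list(accepted = length(viol) == 0, violations = viol)
}
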