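#' Optical blur dose model
#'
#' The projected mask is not reproduced perfectly in the cured hydrogel: the
#' finite optical resolution of the objective softens edges and rounds sharp
#' corners. This is modelled with a single isotropic Gaussian kernel per
#' objective applied to the binary mask; thresholding the resulting dose at
#' 0.5 predicts the cured footprint. The 5X kernel width is a calibration
#' constant chosen once so that a right-angle wall corner rounds to a fitted
#' radius of 10 um; other objectives scale inversely with magnification.
#'
#' @param mask a `wf_mask` (binary).
#' @param objective objective magnification; defaults to the mask
#'   transform's.
#' @param sigma_um override the kernel standard deviation (um).
#' @return numeric matrix in `[0, 1]` of the same shape as the mask.
#' @export
apply_optical_blur <- function(mask, objective = NULL, sigma_um = NULL) {
  stopifnot(inherits(mask, "wf_mask"))
  if (is.null(objective)) objective <- mask$transform$objective_magnification
  if (is.null(sigma_um)) sigma_um <- blur_sigma_um(objective)
  s <- mask$transform$sample_um_per_dmd_px
  .gaussian_blur(matrix(as.numeric(mask$pixels), nrow(mask$pixels)),
                 sigma_um / s)
}

# One-time derived calibration: solving for the kernel width at which the
# shipped corner-fit procedure (fit_corner_radius, 1 um/px working grid)
# returns a 10 um radius on a right-angle wall corner gives sigma = 6.277 um
# for the 5X objective.
.SIGMA_5X_UM <- 6.277

#' Default blur kernel width per objective
#'
#' @param objective objective magnification.
#' @return Gaussian sigma in um at the sample plane.
#' @export
blur_sigma_um <- function(objective) {
  .SIGMA_5X_UM * 5 / objective
}

#' Fit the rounding radius of a blurred right-angle corner
#'
#' Expects the canonical corner orientation: the solid occupies
#' `{row >= corner_px[1] and col <= corner_px[2]}` near the corner, i.e. the
#' free space opens towards the upper-right of the image. Sub-pixel 0.5-level
#' crossings of the dose are collected along rows and columns near the
#' corner; points on the rounded arc (deviating from both ideal edges by more
#' than 0.15 sigma and within 3 sigma of the corner) are fitted with a
#' least-squares (Kasa) circle.
#'
#' @param dose numeric matrix in `[0, 1]`.
#' @param um_per_px pixel pitch, um.
#' @param corner_px `(row, col)` pixel coordinates of the ideal corner
#'   (fractional allowed).
#' @param sigma_um kernel width used to produce `dose` (sets the selection
#'   window).
#' @param level contour level, default 0.5.
#' @return fitted radius in um.
#' @export
fit_corner_radius <- function(dose, um_per_px, corner_px, sigma_um,
                              level = 0.5) {
  r0 <- corner_px[1]; c0 <- corner_px[2]
  s <- um_per_px
  win <- ceiling(4 * sigma_um / s)
  pts <- NULL
  # scan rows below the corner (v < 0): crossing along the column direction
  for (r in seq(max(1, floor(r0)), min(nrow(dose), floor(r0) + win))) {
    cc <- .level_crossing(dose[r, ], level,
                          from = max(1, floor(c0) - win),
                          to = min(ncol(dose), ceiling(c0) + win))
    if (!is.na(cc)) pts <- rbind(pts, c(u = (cc - c0) * s, v = (r0 - r) * s))
  }
  # scan columns left of the corner (u < 0): crossing along the row direction
  for (c in seq(max(1, floor(c0) - win), min(ncol(dose), floor(c0)))) {
    rr <- .level_crossing(dose[, c], level,
                          from = min(nrow(dose), ceiling(r0) + win),
                          to = max(1, floor(r0) - win))
    if (!is.na(rr)) pts <- rbind(pts, c(u = (c - c0) * s, v = (r0 - rr) * s))
  }
  if (is.null(pts) || nrow(pts) < 5)
    .wf_stop("could not extract a corner contour")
  keep <- pts[, "u"] < -0.15 * sigma_um & pts[, "v"] < -0.15 * sigma_um &
    sqrt(pts[, "u"]^2 + pts[, "v"]^2) <= 3 * sigma_um
  arc <- pts[keep, , drop = FALSE]
  if (nrow(arc) < 5) .wf_stop("too few arc points for a circle fit")
  .kasa_radius(arc[, "u"], arc[, "v"])
}

# first crossing of `level` walking from index `from` towards `to`
# (linear sub-index interpolation); NA if no crossing
.level_crossing <- function(v, level, from, to) {
  idx <- from:to
  x <- v[idx]
  above <- x >= level
  flip <- which(above[-length(above)] & !above[-1])
  if (length(flip) == 0) return(NA_real_)
  i <- flip[1]
  frac <- (x[i] - level) / (x[i] - x[i + 1])
  idx[i] + frac * (idx[i + 1] - idx[i])
}

# algebraic (Kasa) circle fit returning the radius
.kasa_radius <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}
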