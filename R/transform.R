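#' Projection transform between world and DMD pixel coordinates
#'
#' Describes how the digital micromirror device (DMD) plane maps onto the
#' sample plane through a given objective. World coordinates are in um, y-up,
#' origin at the centre of the projected field (plus an optional stage
#' offset); DMD coordinates are 1-based `(row, col)` pixel indices, y-down.
#'
#' @param objective_magnification objective magnification (2, 5, 20, 50, ...).
#' @param sample_um_per_dmd_px size of one DMD pixel at the sample plane, um.
#'   Default scales inversely with magnification from 5.5 um at 5X, so the
#'   1024-pixel field spans ~5.6 mm at 5X.
#' @param dmd_shape integer `(rows, cols)` of the DMD raster.
#' @param world_offset `(x, y)` um stage offset of the field centre.
#' @return an object of class `wf_transform`.
#' @export
projection_transform <- function(objective_magnification = 5,
                                 sample_um_per_dmd_px = NULL,
                                 dmd_shape = c(768L, 1024L),
                                 world_offset = c(0, 0)) {
  if (is.null(sample_um_per_dmd_px)) {
    sample_um_per_dmd_px <- 5.5 * 5 / objective_magnification
  }
  stopifnot(length(dmd_shape) == 2, length(world_offset) == 2)
  if (sample_um_per_dmd_px <= 0) .wf_stop("sample_um_per_dmd_px must be > 0")
  if (any(dmd_shape <= 0)) .wf_stop("dmd_shape components must be > 0")
  structure(list(objective_magnification = objective_magnification,
                 sample_um_per_dmd_px = sample_um_per_dmd_px,
                 dmd_shape = as.integer(dmd_shape),
                 world_offset = as.numeric(world_offset)),
            class = "wf_transform")
}

#' @export
print.wf_transform <- function(x, ...) {
  cat(sprintf(
    "wf_transform: %gX objective, %g um/DMD px, DMD %d x %d, field %.2f x %.2f mm\n",
    x$objective_magnification, x$sample_um_per_dmd_px,
    x$dmd_shape[1], x$dmd_shape[2],
    x$dmd_shape[2] * x$sample_um_per_dmd_px / 1000,
    x$dmd_shape[1] * x$sample_um_per_dmd_px / 1000))
  invisible(x)
}

.center_px <- function(transform) {
  # pixel whose centre is the world origin of the field
  c(row = floor(transform$dmd_shape[1] / 2) + 1,
    col = floor(transform$dmd_shape[2] / 2) + 1)
}

#' Map world points to DMD pixel coordinates
#'
#' Returns fractional `(row, col)` coordinates (pixel centres at integer
#' values). Points outside the projected field are returned as `NA` with a
#' warning, the package's out-of-field signal.
#'
#' @param points numeric `(x, y)` vector or an n x 2 matrix of world um.
#' @param transform a [projection_transform()].
#' @return n x 2 matrix with columns `row`, `col`.
#' @export
world_to_dmd <- function(points, transform) {
  p <- .as_xy_matrix(points)
  ctr <- .center_px(transform)
  s <- transform$sample_um_per_dmd_px
  col <- ctr["col"] + (p[, 1] - transform$world_offset[1]) / s
  row <- ctr["row"] - (p[, 2] - transform$world_offset[2]) / s
  out <- cbind(row = row, col = col)
  bad <- row < 0.5 | row > transform$dmd_shape[1] + 0.5 |
         col < 0.5 | col > transform$dmd_shape[2] + 0.5
  if (any(bad)) {
    .wf_warn("%d point(s) outside the projected field mapped to NA", sum(bad))
    out[bad, ] <- NA_real_
  }
  out
}

#' Map DMD pixel coordinates back to world um
#'
#' @param px `(row, col)` vector or n x 2 matrix (fractional allowed).
#' @param transform a [projection_transform()].
#' @return n x 2 matrix with columns `x`, `y` (um).
#' @export
dmd_to_world <- function(px, transform) {
  p <- if (is.matrix(px)) p <- px else matrix(px, ncol = 2)
  ctr <- .center_px(transform)
  s <- transform$sample_um_per_dmd_px
  x <- (p[, 2] - ctr["col"]) * s + transform$world_offset[1]
  y <- (ctr["row"] - p[, 1]) * s + transform$world_offset[2]
  cbind(x = x, y = y)
}

.as_xy_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    points
  } else {
    stopifnot(length(points) == 2)
    matrix(as.numeric(points), ncol = 2)
  }
}

#' World extent of the projected field
#'
#' @param transform a [projection_transform()].
#' @return list with `xlim`, `ylim` in world um (field edges).
#' @export
field_extent <- function(transform) {
  s <- transform$sample_um_per_dmd_px
  ctr <- .center_px(transform)
  nr <- transform$dmd_shape[1]; nc <- transform$dmd_shape[2]
  list(xlim = transform$world_offset[1] + c(0.5 - ctr[["col"]], nc + 0.5 - ctr[["col"]]) * s,
       ylim = transform$world_offset[2] + c(ctr[["row"]] - nr - 0.5, ctr[["row"]] - 0.5) * s)
}
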