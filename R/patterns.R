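#' Parametric assay pattern specifications
#'
#' Constructors for the pattern vocabulary used throughout the package. All
#' lengths are in um, world coordinates (y-up). A pattern describes the
#' *exposed* (cured, raised) solid: for confinement geometries that is the
#' wall or pillar material, never the lumen the worm swims in.
#'
#' @param outer_w,outer_h outer extent of a rectangular frame, um.
#' @param wall_thickness thickness of walls, um.
#' @param center `(x, y)` placement of the pattern centre/reference, um.
#' @name patterns
NULL

.new_pattern <- function(variant, fields) {
  lens <- unlist(fields[vapply(fields, is.numeric, TRUE)], use.names = FALSE)
  structure(c(list(variant = variant), fields),
            class = c(paste0("wf_pattern_", variant), "wf_pattern"))
}

#' @rdname patterns
#' @export
pattern_frame <- function(outer_w, outer_h, wall_thickness, center = c(0, 0)) {
  stopifnot(outer_w > 0, outer_h > 0, wall_thickness > 0,
            2 * wall_thickness < min(outer_w, outer_h))
  .new_pattern("frame", list(outer_w = outer_w, outer_h = outer_h,
                             wall_thickness = wall_thickness,
                             center = as.numeric(center)))
}

#' @rdname patterns
#' @param diameter pillar diameter, um.
#' @param pitch centre-to-centre lattice spacing, um (`pitch >= diameter`).
#' @param region `(w, h)` um rectangle (centred on `center`) the square
#'   lattice fills; pillar centres are kept `diameter/2` inside it.
#' @export
pattern_pillar_array <- function(diameter, pitch, region, center = c(0, 0)) {
  stopifnot(diameter > 0, pitch >= diameter, all(region > 0))
  .new_pattern("pillar_array", list(diameter = diameter, pitch = pitch,
                                    region = as.numeric(region),
                                    center = as.numeric(center)))
}

#' @rdname patterns
#' @param stem_len,arm_len lengths of the maze stem and of each arm, um.
#' @param channel_width lumen width, um.
#' @param terminal_radius radius of the circular terminal regions, um.
#' @export
pattern_t_maze <- function(stem_len, arm_len, channel_width, wall_thickness,
                           terminal_radius, center = c(0, 0)) {
  stopifnot(stem_len > 0, arm_len > 0, channel_width > 0, wall_thickness > 0,
            terminal_radius >= channel_width / 2)
  .new_pattern("t_maze", list(stem_len = stem_len, arm_len = arm_len,
                              channel_width = channel_width,
                              wall_thickness = wall_thickness,
                              terminal_radius = terminal_radius,
                              center = as.numeric(center)))
}

#' @rdname patterns
#' @param turns number of spiral turns.
#' @export
pattern_spiral <- function(turns, channel_width, wall_thickness,
                           center = c(0, 0)) {
  stopifnot(turns > 0, channel_width > 0, wall_thickness > 0)
  .new_pattern("spiral", list(turns = turns, channel_width = channel_width,
                              wall_thickness = wall_thickness,
                              center = as.numeric(center)))
}

#' @rdname patterns
#' @param length,width channel length and lumen width, um.
#' @param ripple_amplitude,ripple_period sinusoidal ripple of the channel
#'   centreline, um.
#' @export
pattern_corrugated_channel <- function(length, width, ripple_amplitude,
                                       ripple_period, wall_thickness = 100,
                                       center = c(0, 0)) {
  stopifnot(length > 0, width > 0, ripple_amplitude >= 0, ripple_period > 0,
            wall_thickness > 0)
  .new_pattern("corrugated_channel",
               list(length = length, width = width,
                    ripple_amplitude = ripple_amplitude,
                    ripple_period = ripple_period,
                    wall_thickness = wall_thickness,
                    center = as.numeric(center)))
}

#' @rdname patterns
#' @param radius disk radius, um.
#' @export
pattern_disk <- function(center, radius) {
  stopifnot(radius > 0)
  .new_pattern("disk", list(center = as.numeric(center), radius = radius))
}

#' @rdname patterns
#' @param vertices n x 2 matrix of polygon vertices (um, world coordinates);
#'   an empty (0-row) matrix is allowed and contains nothing.
#' @export
pattern_polygon <- function(vertices) {
  vertices <- if (length(vertices) == 0) matrix(numeric(0), ncol = 2) else
    .as_xy_matrix(vertices)
  .new_pattern("polygon", list(vertices = vertices, center = c(0, 0)))
}

#' @export
print.wf_pattern <- function(x, ...) {
  flds <- setdiff(names(x), c("variant", "vertices"))
  cat(sprintf("wf_pattern<%s>: %s\n", x$variant,
              paste(sprintf("%s=%s", flds,
                            vapply(x[flds], function(v)
                              paste(signif(v, 6), collapse = ","), "")),
                    collapse = ", ")))
  invisible(x)
}

# ---- point containment (pixel-centre sampling, no anti-aliasing) -----------

#' Test whether world points lie inside a pattern's exposed solid
#'
#' @param spec a pattern from the [patterns] constructors, or a list of them
#'   (union).
#' @param x,y equal-length world coordinates, um.
#' @return logical vector.
#' @export
pattern_contains <- function(spec, x, y) {
  if (!inherits(spec, "wf_pattern") && is.list(spec)) {
    out <- rep(FALSE, length(x))
    for (s in spec) out <- out | pattern_contains(s, x, y)
    return(out)
  }
  UseMethod("pattern_contains")
}

.in_rect <- function(x, y, cx, cy, w, h) {
  abs(x - cx) <= w / 2 & abs(y - cy) <= h / 2
}

.rect_dist <- function(x, y, cx, cy, w, h) {
  dx <- pmax(abs(x - cx) - w / 2, 0)
  dy <- pmax(abs(y - cy) - h / 2, 0)
  sqrt(dx^2 + dy^2)
}

#' @export
pattern_contains.wf_pattern_frame <- function(spec, x, y) {
  cx <- spec$center[1]; cy <- spec$center[2]
  .in_rect(x, y, cx, cy, spec$outer_w, spec$outer_h) &
    !.in_rect(x, y, cx, cy, spec$outer_w - 2 * spec$wall_thickness,
              spec$outer_h - 2 * spec$wall_thickness)
}

# lattice of pillar centres for a pillar_array spec
.pillar_centers <- function(spec) {
  w <- spec$region[1]; h <- spec$region[2]; r <- spec$diameter / 2
  nx <- max(0L, floor((w - 2 * r) / spec$pitch) + 1L)
  ny <- max(0L, floor((h - 2 * r) / spec$pitch) + 1L)
  if (nx == 0 || ny == 0) return(matrix(numeric(0), ncol = 2))
  xs <- spec$center[1] + (seq_len(nx) - (nx + 1) / 2) * spec$pitch
  ys <- spec$center[2] + (seq_len(ny) - (ny + 1) / 2) * spec$pitch
  cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
}

#' @export
pattern_contains.wf_pattern_pillar_array <- function(spec, x, y) {
  ctr <- .pillar_centers(spec)
  if (nrow(ctr) == 0) return(rep(FALSE, length(x)))
  p <- spec$pitch; r <- spec$diameter / 2
  xs <- sort(unique(ctr[, 1])); ys <- sort(unique(ctr[, 2]))
  # snap to nearest lattice centre, clamped to the lattice extent
  kx <- pmin(pmax(round((x - xs[1]) / p), 0), length(xs) - 1)
  ky <- pmin(pmax(round((y - ys[1]) / p), 0), length(ys) - 1)
  (x - (xs[1] + kx * p))^2 + (y - (ys[1] + ky * p))^2 <= r^2
}

# distance to the T-maze lumen (stem + bar + terminal discs); 0 inside
.tmaze_lumen_dist <- function(spec, x, y) {
  cx <- spec$center[1]; cy <- spec$center[2]
  cw <- spec$channel_width
  d_stem <- .rect_dist(x, y, cx, cy - spec$stem_len / 2, cw, spec$stem_len)
  d_bar  <- .rect_dist(x, y, cx, cy + cw / 2, 2 * spec$arm_len, cw)
  d_l <- pmax(sqrt((x - (cx - spec$arm_len))^2 + (y - (cy + cw / 2))^2) -
                spec$terminal_radius, 0)
  d_r <- pmax(sqrt((x - (cx + spec$arm_len))^2 + (y - (cy + cw / 2))^2) -
                spec$terminal_radius, 0)
  pmin(d_stem, d_bar, d_l, d_r)
}

#' @export
pattern_contains.wf_pattern_t_maze <- function(spec, x, y) {
  d <- .tmaze_lumen_dist(spec, x, y)
  wall <- d > 0 & d <= spec$wall_thickness
  # keep the stem entrance (bottom end) open
  entrance <- y < spec$center[2] - spec$stem_len &
    abs(x - spec$center[1]) < spec$channel_width / 2 + spec$wall_thickness
  wall & !entrance
}

#' Terminal regions of a T-maze
#'
#' @param spec a [pattern_t_maze()].
#' @return list with `left` and `right`, each `(x, y, radius)` um.
#' @export
t_maze_terminals <- function(spec) {
  stopifnot(inherits(spec, "wf_pattern_t_maze"))
  cy <- spec$center[2] + spec$channel_width / 2
  list(left = c(x = spec$center[1] - spec$arm_len, y = cy,
                radius = spec$terminal_radius),
       right = c(x = spec$center[1] + spec$arm_len, y = cy,
                 radius = spec$terminal_radius))
}

#' @export
pattern_contains.wf_pattern_spiral <- function(spec, x, y) {
  cx <- spec$center[1]; cy <- spec$center[2]
  pitch_r <- spec$channel_width + spec$wall_thickness # radial gain per turn
  a <- pitch_r / (2 * pi)
  r0 <- spec$wall_thickness
  rho <- sqrt((x - cx)^2 + (y - cy)^2)
  th <- atan2(y - cy, x - cx) %% (2 * pi)
  phimax <- 2 * pi * spec$turns
  best <- rep(Inf, length(x))
  for (k in 0:ceiling(spec$turns)) {
    phi <- th + 2 * pi * k
    ok <- phi <= phimax
    d <- abs(rho - (r0 + a * phi))
    best <- ifelse(ok, pmin(best, d), best)
  }
  best <= spec$wall_thickness / 2
}

#' @export
pattern_contains.wf_pattern_corrugated_channel <- function(spec, x, y) {
  cx <- spec$center[1]; cy <- spec$center[2]
  inx <- abs(x - cx) <= spec$length / 2
  yc <- cy + spec$ripple_amplitude * sin(2 * pi * (x - cx) / spec$ripple_period)
  off <- spec$width / 2 + spec$wall_thickness / 2
  wall <- abs(y - (yc + off)) <= spec$wall_thickness / 2 |
          abs(y - (yc - off)) <= spec$wall_thickness / 2
  inx & wall
}

#' Centreline of a corrugated channel lumen
#' @param spec a [pattern_corrugated_channel()].
#' @param n number of sample points.
#' @return n x 2 matrix of world um along the lumen centreline.
#' @export
channel_centerline <- function(spec, n = 512) {
  stopifnot(inherits(spec, "wf_pattern_corrugated_channel"))
  x <- spec$center[1] + seq(-spec$length / 2, spec$length / 2, length.out = n)
  y <- spec$center[2] +
    spec$ripple_amplitude * sin(2 * pi * (x - spec$center[1]) / spec$ripple_period)
  cbind(x = x, y = y)
}

#' @export
pattern_contains.wf_pattern_disk <- function(spec, x, y) {
  (x - spec$center[1])^2 + (y - spec$center[2])^2 <= spec$radius^2
}

#' @export
pattern_contains.wf_pattern_polygon <- function(spec, x, y) {
  v <- spec$vertices
  n <- nrow(v)
  if (n < 3) return(rep(FALSE, length(x)))
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Bounding box of a pattern's exposed solid
#'
#' @param spec pattern or list of patterns.
#' @return list with `xlim`, `ylim` in world um.
#' @export
pattern_extent <- function(spec) {
  if (!inherits(spec, "wf_pattern") && is.list(spec)) {
    es <- lapply(spec, pattern_extent)
    return(list(xlim = range(unlist(lapply(es, `[[`, "xlim"))),
                ylim = range(unlist(lapply(es, `[[`, "ylim")))))
  }
  cx <- spec$center[1]; cy <- spec$center[2]
  switch(spec$variant,
    frame = list(xlim = cx + c(-1, 1) * spec$outer_w / 2,
                 ylim = cy + c(-1, 1) * spec$outer_h / 2),
    pillar_array = list(xlim = cx + c(-1, 1) * spec$region[1] / 2,
                        ylim = cy + c(-1, 1) * spec$region[2] / 2),
    t_maze = {
      r <- spec$terminal_radius + spec$wall_thickness
      list(xlim = cx + c(-1, 1) * (spec$arm_len + r),
           ylim = c(cy - spec$stem_len - spec$wall_thickness,
                    cy + spec$channel_width / 2 + r))
    },
    spiral = {
      rmax <- spec$wall_thickness +
        (spec$channel_width + spec$wall_thickness) * spec$turns +
        spec$wall_thickness / 2
      list(xlim = cx + c(-1, 1) * rmax, ylim = cy + c(-1, 1) * rmax)
    },
    corrugated_channel = {
      h <- spec$width / 2 + spec$wall_thickness + spec$ripple_amplitude
      list(xlim = cx + c(-1, 1) * spec$length / 2, ylim = cy + c(-1, 1) * h)
    },
    disk = list(xlim = cx + c(-1, 1) * spec$radius,
                ylim = cy + c(-1, 1) * spec$radius),
    polygon = if (nrow(spec$vertices) == 0)
      list(xlim = c(0, 0), ylim = c(0, 0))
    else list(xlim = range(spec$vertices[, 1]),
              ylim = range(spec$vertices[, 2])),
    .wf_stop("unknown pattern variant '%s'", spec$variant))
}

# ---- rasterization ---------------------------------------------------------

#' Rasterize a pattern onto the DMD plane
#'
#' A DMD mirror (pixel) is ON iff its centre, mapped to the sample plane,
#' lies inside the pattern's exposed solid. The result is strictly binary and
#' bit-identical for identical `(spec, transform)`.
#'
#' @param spec a pattern or list of patterns (union of solids).
#' @param transform a [projection_transform()].
#' @param exposure_time seconds the mask will be projected for (metadata).
#' @param allow_clip if `FALSE` (default) a pattern extending beyond the
#'   projected field is an error (stitching must be requested explicitly).
#' @return an object of class `wf_mask`: list with integer 0/1 matrix
#'   `pixels`, the `transform` and `exposure_time`.
#' @export
rasterize <- function(spec, transform, exposure_time = 1, allow_clip = FALSE) {
  nr <- transform$dmd_shape[1]; nc <- transform$dmd_shape[2]
  w <- dmd_to_world(cbind(rep(1, nc), seq_len(nc)), transform)
  xs <- w[, 1]
  w <- dmd_to_world(cbind(seq_len(nr), rep(1, nr)), transform)
  ys <- w[, 2]
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  px <- matrix(as.integer(pattern_contains(spec, as.vector(X), as.vector(Y))),
               nr, nc)
  if (!allow_clip) {
    fe <- field_extent(transform)
    pe <- pattern_extent(spec)
    if (pe$xlim[1] < fe$xlim[1] || pe$xlim[2] > fe$xlim[2] ||
        pe$ylim[1] < fe$ylim[1] || pe$ylim[2] > fe$ylim[2])
      .wf_stop("pattern extends beyond the projected field; enlarge the field or stitch (allow_clip = TRUE)")
  }
  new_mask(px, transform, exposure_time)
}

#' @rdname rasterize
#' @param pixels integer/logical matrix matching `transform$dmd_shape`.
#' @export
new_mask <- function(pixels, transform, exposure_time = 1) {
  pixels <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  stopifnot(all(dim(pixels) == transform$dmd_shape))
  structure(list(pixels = pixels, transform = transform,
                 exposure_time = exposure_time), class = "wf_mask")
}

#' @export
print.wf_mask <- function(x, ...) {
  cat(sprintf("wf_mask: %d x %d px, %d on (%.1f%%), exposure %.3g s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels), x$exposure_time))
  invisible(x)
}

# ---- world-frame occupancy and stitching -----------------------------------

#' World-frame occupancy raster
#'
#' A binary raster of cured material in world coordinates: `pixels[r, c]` is
#' TRUE where material exists; the centre of pixel `[1, 1]` sits at world
#' `origin` (um) and rows run y-down.
#'
#' @param pixels logical matrix.
#' @param origin world `(x, y)` of the centre of pixel `[1, 1]`, um.
#' @param um_per_px pixel size, um.
#' @return object of class `wf_occupancy`.
#' @export
new_occupancy <- function(pixels, origin, um_per_px) {
  structure(list(pixels = pixels != 0, origin = as.numeric(origin),
                 um_per_px = um_per_px), class = "wf_occupancy")
}

#' @export
print.wf_occupancy <- function(x, ...) {
  cat(sprintf("wf_occupancy: %d x %d px at %g um/px, %d set\n",
              nrow(x$pixels), ncol(x$pixels), x$um_per_px, sum(x$pixels)))
  invisible(x)
}

#' World coordinates of occupancy pixel centres
#' @keywords internal
occupancy_axes <- function(occ) {
  list(x = occ$origin[1] + (seq_len(ncol(occ$pixels)) - 1) * occ$um_per_px,
       y = occ$origin[2] - (seq_len(nrow(occ$pixels)) - 1) * occ$um_per_px)
}

#' Rasterize patterns directly onto a world-frame grid
#'
#' Used by the simulator to build environments without DMD plumbing.
#'
#' @param spec pattern or list of patterns.
#' @param xlim,ylim world extent, um.
#' @param um_per_px grid pitch, um.
#' @return a [new_occupancy()] raster.
#' @export
rasterize_world <- function(spec, xlim, ylim, um_per_px) {
  xs <- seq(xlim[1] + um_per_px / 2, xlim[2], by = um_per_px)
  ys <- seq(ylim[2] - um_per_px / 2, ylim[1], by = -um_per_px)
  nr <- length(ys); nc <- length(xs)
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  px <- matrix(pattern_contains(spec, as.vector(X), as.vector(Y)), nr, nc)
  new_occupancy(px, origin = c(xs[1], ys[1]), um_per_px = um_per_px)
}

#' Stitch multiple exposures into one world-frame occupancy
#'
#' Exposed regions are OR-combined (idempotent union): exposing the same spot
#' twice cures it once.
#'
#' @param masks list of `wf_mask` objects.
#' @param stage_offsets list/matrix of `(x, y)` um stage offsets, one per
#'   mask (the mask's world geometry is translated by its offset).
#' @param resample allow masks with differing `sample_um_per_dmd_px` to be
#'   resampled onto the first mask's grid; if `FALSE` (default), differing
#'   grids are an error.
#' @return a [new_occupancy()] raster covering the union bounding box.
#' @export
stitch <- function(masks, stage_offsets = NULL, resample = FALSE) {
  stopifnot(length(masks) >= 1)
  if (is.null(stage_offsets))
    stage_offsets <- replicate(length(masks), c(0, 0), simplify = FALSE)
  if (is.matrix(stage_offsets))
    stage_offsets <- split(stage_offsets, row(stage_offsets)[, 1])
  stopifnot(length(stage_offsets) == length(masks))
  s0 <- masks[[1]]$transform$sample_um_per_dmd_px
  ss <- vapply(masks, function(m) m$transform$sample_um_per_dmd_px, 0)
  if (!resample && any(abs(ss - s0) > 1e-9))
    .wf_stop("masks have differing pixel grids; pass resample = TRUE to resample")
  # union bounding box in world coordinates
  xs_all <- ys_all <- numeric(0)
  for (i in seq_along(masks)) {
    fe <- field_extent(masks[[i]]$transform)
    off <- stage_offsets[[i]]
    xs_all <- c(xs_all, fe$xlim + off[1]); ys_all <- c(ys_all, fe$ylim + off[2])
  }
  xr <- range(xs_all); yr <- range(ys_all)
  xs <- seq(xr[1] + s0 / 2, xr[2], by = s0)
  ys <- seq(yr[2] - s0 / 2, yr[1], by = -s0)
  out <- matrix(FALSE, length(ys), length(xs))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  for (i in seq_along(masks)) {
    m <- masks[[i]]; off <- stage_offsets[[i]]
    px <- suppressWarnings(
      world_to_dmd(cbind(as.vector(X) - off[1], as.vector(Y) - off[2]),
                   m$transform))
    r <- round(px[, 1]); c <- round(px[, 2])
    ok <- !is.na(r) & r >= 1 & r <= nrow(m$pixels) &
      !is.na(c) & c >= 1 & c <= ncol(m$pixels)
    hit <- rep(FALSE, length(r))
    hit[ok] <- m$pixels[cbind(r[ok], c[ok])] > 0
    out <- out | matrix(hit, length(ys), length(xs))
  }
  new_occupancy(out, origin = c(xs[1], ys[1]), um_per_px = s0)
}
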