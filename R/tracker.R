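#' Tracker configuration
#'
#' The video-tracking pipeline is: frame differencing to find motion, blob
#' detection on the motion image, moment-based centroid of the selected worm
#' blob, then kinematics from the smoothed centroid track. Every threshold
#' the original Methods leave unstated is an explicit parameter here.
#'
#' @param diff_threshold absolute-difference threshold in gray levels;
#'   `NULL` (default) uses Otsu's method on the absolute-difference
#'   histogram with a floor of 5 gray levels.
#' @param min_blob_area minimum blob area, px.
#' @param max_jump_um maximum plausible centroid displacement between
#'   frames; worm association beyond this flags the frame invalid.
#' @param body_threshold gray-level drop below the background that counts as
#'   worm/structure body in [segment_body()].
#' @param background_k number of leading frames whose pixelwise median forms
#'   the background model.
#' @param smooth_window,smooth_order local polynomial (Savitzky-Golay style)
#'   smoothing of the centroid track before differentiation.
#' @param close_radius morphological closing radius (px) applied to the
#'   motion image after the speckle-removing opening. An undulating worm's
#'   frame difference fragments into one patch per half body wave; closing
#'   re-merges them into a single worm blob. The radius should exceed the
#'   internode gap, about a quarter undulation wavelength in pixels
#'   (default 15 px = 75 um at 5 um/px). 0 disables.
#' @param despike_window rolling-median window (odd) applied to the centroid
#'   track before polynomial smoothing; removes 1-2 frame association
#'   glitches (e.g. a transiently split motion blob). 0 disables.
#' @param gait_ma_window period-matched moving-average window(s), frames,
#'   applied in cascade before polynomial smoothing. A boxcar of length
#'   `frame_rate / undulation_frequency` has exact nulls at the gait
#'   frequency and its harmonics; a second, coprime window widens the stop
#'   band over the gait sidebands that turning modulation produces. Default
#'   `c(5, 7, 9)` covers a ~2 Hz gait filmed at 10 fps. 0 disables.
#' @param refine_body when TRUE (default) the selected motion blob is used
#'   to *locate* the worm and the reported centroid is refined from the
#'   dark-body segmentation around it (median-background subtraction). The
#'   body centre of mass is stable in the body frame, whereas the raw
#'   motion-blob centroid wanders with pose (head sweeps more area than the
#'   tail); set FALSE for the raw motion-blob centroid.
#' @param refine_pad_px padding (px) around the motion blob's bounding box
#'   for the body segmentation; should exceed one body length in pixels (a
#'   straight gliding worm's motion blob is only its head/tail cap).
#' @return object of class `wf_tracker_config`.
#' @export
tracker_config <- function(diff_threshold = NULL, min_blob_area = 20,
                           max_jump_um = 2000, body_threshold = 40,
                           background_k = 10, smooth_window = 5,
                           smooth_order = 2, close_radius = 15,
                           despike_window = 5, gait_ma_window = c(5, 7, 9),
                           refine_body = TRUE, refine_pad_px = 220) {
  structure(list(diff_threshold = diff_threshold,
                 min_blob_area = min_blob_area, max_jump_um = max_jump_um,
                 body_threshold = body_threshold,
                 background_k = background_k,
                 smooth_window = smooth_window, smooth_order = smooth_order,
                 close_radius = close_radius,
                 despike_window = despike_window,
                 gait_ma_window = gait_ma_window,
                 refine_body = refine_body,
                 refine_pad_px = refine_pad_px),
            class = "wf_tracker_config")
}

#' Otsu threshold of a non-negative integer image
#' @param x integer-valued matrix/vector.
#' @return threshold maximising between-class variance (gray levels).
#' @export
otsu_threshold <- function(x) {
  .otsu_from_hist(as.numeric(tabulate(as.integer(x) + 1L, nbins = 256L)))
}

.otsu_from_hist <- function(h) {
  n <- sum(h)
  lv <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lv)
  mt <- m0[256]
  between <- (mt * w0 - m0 * n)^2 / (w0 * (n - w0))
  between[!is.finite(between)] <- -1
  lv[which.max(between)]
}

#' Binary motion image from two frames
#'
#' `|f_t - f_prev|` thresholded (Otsu with a 5 gray-level floor by default)
#' then morphologically opened with a 1-px-radius (3 x 3 square) element to
#' drop speckle.
#'
#' @param f_t,f_prev integer matrices of equal shape.
#' @param config a [tracker_config()].
#' @return logical matrix of moving pixels.
#' @export
frame_difference <- function(f_t, f_prev, config = tracker_config()) {
  if (!all(dim(f_t) == dim(f_prev))) .wf_stop("frame shape mismatch")
  dh <- .abs_diff_hist(f_t, f_prev)
  d <- dh$d
  thr <- config$diff_threshold
  if (is.null(thr)) {
    h <- as.numeric(dh$hist)
    # Otsu can collapse into the noise mode when the moving object covers a
    # tiny pixel fraction; floor the threshold at 5 sigma of the difference
    # noise (sigma from the half-normal median), never below 5 gray levels
    med <- which(cumsum(h) >= sum(h) / 2)[1] - 1
    thr <- max(.otsu_from_hist(h), 5, ceiling(5 * med / 0.6745))
  }
  m <- d > thr
  if (!any(m)) return(m)
  # morphology on the padded bounding box of set pixels only (motion images
  # are sparse: full-frame structuring passes would dominate the runtime)
  pad <- config$close_radius + 2L
  idx <- which(m, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(m), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(m), max(idx[, 2]) + pad)
  sub <- .binary_open(m[r0:r1, c0:c1, drop = FALSE])
  if (config$close_radius > 0 && any(sub))
    sub <- .binary_close(sub, config$close_radius)
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[r0:r1, c0:c1] <- sub
  out
}

# Euclidean closing: dilate by r then erode by r (distance-transform based)
.binary_close <- function(m, r) {
  if (!any(m)) return(m)
  dil <- .dist_transform_sq(m) <= r^2
  .dist_transform_sq(!dil) > r^2
}

# morphological opening with the 3 x 3 square (1-px-radius) element --
# the OpenCV default structuring element
.binary_open <- function(m) {
  .dilate_sq3(.erode_sq3(m))
}

.erode_sq3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & .shift_mat(m, dr, dc, FALSE)
  }
  out
}

.dilate_sq3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | .shift_mat(m, dr, dc, FALSE)
  }
  out
}

.shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

.erode_cross <- function(m) {
  m & .shift_mat(m, 1, 0, FALSE) & .shift_mat(m, -1, 0, FALSE) &
    .shift_mat(m, 0, 1, FALSE) & .shift_mat(m, 0, -1, FALSE)
}

.dilate_cross <- function(m) {
  m | .shift_mat(m, 1, 0, FALSE) | .shift_mat(m, -1, 0, FALSE) |
    .shift_mat(m, 0, 1, FALSE) | .shift_mat(m, 0, -1, FALSE)
}

#' Detect blobs (8-connected components) in a binary image
#'
#' @param motion logical matrix.
#' @param min_area drop components smaller than this many pixels.
#' @return list of blobs; each has `area`, `centroid` (`row`, `col`, raw
#'   moments), central second moments `mu20`, `mu02`, `mu11`, `bbox`
#'   (rmin, rmax, cmin, cmax) and `pixels` (n x 2 row/col).
#' @export
detect_blobs <- function(motion, min_area = 20) {
  if (!any(motion)) return(list())
  # label only the bounding box of set pixels (cheap on sparse motion images)
  idx <- which(motion, arr.ind = TRUE)
  r0 <- max(1, min(idx[, 1]) - 1); r1 <- min(nrow(motion), max(idx[, 1]) + 1)
  c0 <- max(1, min(idx[, 2]) - 1); c1 <- min(ncol(motion), max(idx[, 2]) + 1)
  sub <- motion[r0:r1, c0:c1, drop = FALSE]
  lab <- .cc_label(sub)
  n <- attr(lab, "n")
  out <- list()
  for (k in seq_len(n)) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    r <- px[, 1] + r0 - 1; c <- px[, 2] + c0 - 1
    mr <- mean(r); mc <- mean(c)
    out[[length(out) + 1]] <- list(
      area = nrow(px), centroid = c(row = mr, col = mc),
      mu20 = sum((c - mc)^2), mu02 = sum((r - mr)^2),
      mu11 = sum((c - mc) * (r - mr)),
      bbox = c(min(r), max(r), min(c), max(c)),
      pixels = cbind(row = r, col = c))
  }
  out
}

#' Select the worm blob among candidates
#'
#' With a previous centroid: the nearest blob within `max_jump` (px); the
#' frame is invalid if none qualifies. Without: the largest blob.
#'
#' @param blobs list from [detect_blobs()].
#' @param prev_centroid `(row, col)` or `NULL`.
#' @param max_jump_px association gate, px.
#' @return list `(blob or NULL, valid)`.
#' @export
select_worm <- function(blobs, prev_centroid = NULL, max_jump_px = Inf) {
  if (length(blobs) == 0) return(list(blob = NULL, valid = FALSE))
  if (is.null(prev_centroid)) {
    areas <- vapply(blobs, function(b) b$area, 0)
    return(list(blob = blobs[[which.max(areas)]], valid = TRUE))
  }
  d <- vapply(blobs, function(b)
    sqrt(sum((b$centroid - prev_centroid)^2)), 0)
  k <- which.min(d)
  if (d[k] <= max_jump_px) list(blob = blobs[[k]], valid = TRUE)
  else list(blob = NULL, valid = FALSE)
}

#' Segment dark bodies against a background model
#'
#' Dark-object threshold (`background - frame > body_threshold`), opened,
#' largest 8-connected component kept.
#'
#' @param frame integer matrix.
#' @param background background model (matrix), e.g. the pixelwise median of
#'   the first `background_k` frames ([background_model()]).
#' @param config a [tracker_config()].
#' @param keep `"largest"` (default) or `"all"` components above
#'   `min_blob_area`.
#' @return logical body mask (empty, with attribute `empty = TRUE`, if no
#'   component reaches `min_blob_area`).
#' @export
segment_body <- function(frame, background, config = tracker_config(),
                         keep = "largest") {
  m <- .binary_open((background - frame) > config$body_threshold)
  if (!any(m)) return(structure(m, empty = TRUE))
  blobs <- detect_blobs(m, min_area = config$min_blob_area)
  if (length(blobs) == 0)
    return(structure(matrix(FALSE, nrow(m), ncol(m)), empty = TRUE))
  out <- matrix(FALSE, nrow(m), ncol(m))
  if (keep == "largest") {
    b <- blobs[[which.max(vapply(blobs, function(b) b$area, 0))]]
    out[b$pixels] <- TRUE
  } else {
    for (b in blobs) out[b$pixels] <- TRUE
  }
  out
}

#' Pixelwise-median background model
#'
#' @param frames list of integer matrices (or a `wf_frames`).
#' @param k number of leading frames to use.
#' @return numeric matrix.
#' @export
background_model <- function(frames, k = 10) {
  if (inherits(frames, "wf_frames")) frames <- frames$frames
  .stack_median(lapply(frames[seq_len(min(k, length(frames)))],
                       function(f) matrix(as.numeric(f), nrow(f))))
}

#' Principal-axis orientation of a binary mask, degrees from vertical
#'
#' Computed from second central moments; positive angles tilt the top of the
#' axis towards +col (clockwise on screen); range `(-90, 90]`. A degenerate
#' (circularly symmetric) mask has no defined axis and returns `NA` with a
#' warning.
#'
#' @param mask logical matrix (non-empty).
#' @return angle in degrees.
#' @export
orientation_from_moments <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0) .wf_stop("empty mask")
  r <- px[, 1]; c <- px[, 2]
  mu20 <- mean((c - mean(c))^2)   # about the column (x) axis
  mu02 <- mean((r - mean(r))^2)
  mu11 <- mean((c - mean(c)) * (r - mean(r)))
  if (abs(mu20 - mu02) < 1e-9 && abs(mu11) < 1e-9) {
    .wf_warn("degenerate (circular) mask: orientation undefined")
    return(NA_real_)
  }
  alpha <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi # from +col axis
  th <- alpha + 90
  ((th + 90) %% 180) - 90
}

#' Unwrap a time series of axis angles (mod 180)
#'
#' Picks for each angle the representative congruent mod 180 closest to its
#' predecessor, removing 180-degree principal-axis flips.
#'
#' @param theta_deg numeric vector (NA allowed).
#' @return unwrapped angles, degrees.
#' @export
unwrap_orientation <- function(theta_deg) {
  out <- theta_deg
  last <- NA_real_
  for (i in seq_along(out)) {
    if (is.na(out[i])) next
    if (!is.na(last)) {
      k <- round((last - out[i]) / 180)
      out[i] <- out[i] + 180 * k
    }
    last <- out[i]
  }
  out
}

# ---- kinematics ------------------------------------------------------------

# local polynomial (Savitzky-Golay) smoothing; one-sided windows at the ends
.sg_smooth <- function(x, window, order) {
  n <- length(x)
  if (window > n) .wf_stop("smoothing window (%d) larger than track (%d)",
                           window, n)
  hw <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - hw); hi <- min(n, i + hw)
    idx <- lo:hi
    ord <- min(order, length(idx) - 1)
    fit <- stats::lm.fit(outer(idx - i, 0:ord, `^`), x[idx])
    out[i] <- fit$coefficients[1]
  }
  out
}

#' Derive velocity, speed and acceleration from a centroid track
#'
#' Positions are smoothed by a local quadratic fit (window default 5
#' frames); velocity and acceleration are central differences of the
#' smoothed positions (one-sided at the track ends). Only runs of valid
#' frames are differentiated; kinematics are `NA` elsewhere.
#'
#' @param traj data.frame with `time_s`, `x_um`, `y_um`, `valid`.
#' @param config a [tracker_config()] (smoothing window/order).
#' @return the data.frame with added `vx_um_s`, `vy_um_s`, `speed_um_s`,
#'   `accel_um_s2`, smoothed `xs_um`, `ys_um`, and `full_support` (FALSE on
#'   the frames at each run boundary where the smoothing windows are
#'   truncated; summary statistics use only full-support frames).
#' @export
derive_kinematics <- function(traj, config = tracker_config()) {
  stopifnot(all(c("time_s", "x_um", "y_um", "valid") %in% names(traj)))
  n <- nrow(traj)
  traj$xs_um <- traj$ys_um <- traj$vx_um_s <- traj$vy_um_s <-
    traj$speed_um_s <- traj$accel_um_s2 <- NA_real_
  traj$full_support <- FALSE
  runs <- rle(traj$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (j in seq_along(runs$values)) {
    if (!runs$values[j]) next
    idx <- starts[j]:ends[j]
    if (length(idx) < 3) next
    w <- min(config$smooth_window, length(idx))
    if (w %% 2 == 0) w <- w - 1
    x0 <- traj$x_um[idx]; y0 <- traj$y_um[idx]
    dw <- min(config$despike_window, length(idx))
    if (dw %% 2 == 0) dw <- dw - 1
    if (dw >= 3) {
      x0 <- stats::runmed(x0, dw, endrule = "median")
      y0 <- stats::runmed(y0, dw, endrule = "median")
    }
    for (gw in config$gait_ma_window) {
      gw <- min(gw, length(idx))
      if (gw >= 2) {
        x0 <- .boxcar(x0, gw)
        y0 <- .boxcar(y0, gw)
      }
    }
    xs <- .sg_smooth(x0, w, config$smooth_order)
    ys <- .sg_smooth(y0, w, config$smooth_order)
    tt <- traj$time_s[idx]
    vx <- .central_diff(xs, tt); vy <- .central_diff(ys, tt)
    sp <- sqrt(vx^2 + vy^2)
    ax <- .central_diff(vx, tt); ay <- .central_diff(vy, tt)
    traj$xs_um[idx] <- xs; traj$ys_um[idx] <- ys
    traj$vx_um_s[idx] <- vx; traj$vy_um_s[idx] <- vy
    traj$speed_um_s[idx] <- sp
    traj$accel_um_s2[idx] <- sqrt(ax^2 + ay^2)
    # frames whose filter support is truncated by the run boundary carry
    # known-biased estimates (shrunken windows + one-sided differences)
    hs <- sum(floor(c(config$despike_window, config$gait_ma_window,
                      config$smooth_window) / 2)) + 1
    full <- rep(TRUE, length(idx))
    if (length(idx) > 2 * hs) {
      full[seq_len(hs)] <- FALSE
      full[(length(idx) - hs + 1):length(idx)] <- FALSE
    }
    traj$full_support[idx] <- full
  }
  traj
}

# centred moving average, shrinking symmetrically at the ends
.boxcar <- function(x, w) {
  n <- length(x)
  hw <- w %/% 2
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    h <- min(hw, i - 1, n - i)
    out[i] <- (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
  }
  out
}

.central_diff <- function(x, t) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) {
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  d
}

# motion blob locates the worm; the dark body segmented around it gives the
# reported centroid (NULL if no dark component is found there)
.refine_body_centroid <- function(frame, background, blob, cfg) {
  # pad by a body length: a straight gliding worm's motion blob is just the
  # head or tail cap, while the dark body extends ~1 mm beyond it
  pad <- as.integer(cfg$refine_pad_px)
  r0 <- max(1L, blob$bbox[1] - pad); r1 <- min(nrow(frame), blob$bbox[2] + pad)
  c0 <- max(1L, blob$bbox[3] - pad); c1 <- min(ncol(frame), blob$bbox[4] + pad)
  sub <- .binary_open((background[r0:r1, c0:c1, drop = FALSE] -
                         frame[r0:r1, c0:c1, drop = FALSE]) >
                        cfg$body_threshold)
  if (!any(sub)) return(NULL)
  bl <- detect_blobs(sub, min_area = cfg$min_blob_area)
  if (length(bl) == 0) return(NULL)
  b <- bl[[which.max(vapply(bl, function(b) b$area, 0))]]
  list(centroid = c(b$centroid[1] + r0 - 1, b$centroid[2] + c0 - 1),
       area = b$area)
}

# ---- online tracking accumulator ------------------------------------------

#' Create an online tracker (streaming interface)
#'
#' Feed frames one at a time with [tracker_feed()]; close with
#' [tracker_finish()]. Used both by [track_frames()] and by simulations too
#' large to hold in memory.
#'
#' @param um_per_px pixel size, um.
#' @param config a [tracker_config()].
#' @return mutable tracker object (environment).
#' @export
tracker_new <- function(um_per_px, config = tracker_config()) {
  e <- new.env(parent = emptyenv())
  e$um_per_px <- um_per_px
  e$config <- config
  e$prev_frame <- NULL
  e$prev_centroid <- NULL
  e$prev_t <- NA_real_
  e$rows <- list()
  e$bg_acc <- list()
  e$background <- NULL
  class(e) <- "wf_tracker"
  e
}

#' @rdname tracker_new
#' @param tr a `wf_tracker`.
#' @param frame integer matrix.
#' @param t frame time, s.
#' @export
tracker_feed <- function(tr, frame, t) {
  cfg <- tr$config
  if (cfg$refine_body) {
    if (is.null(tr$background)) {
      tr$bg_acc[[length(tr$bg_acc) + 1]] <- frame
      if (length(tr$bg_acc) == cfg$background_k) {
        tr$background <- background_model(tr$bg_acc, cfg$background_k)
        tr$bg_acc <- list()
      }
    } else {
      # running-max update erases the worm's own ghost from the median
      # background once it swims away (the worm is the only dark mover)
      tr$background <- pmax(tr$background, frame)
    }
  }
  if (is.null(tr$prev_frame)) {
    tr$prev_frame <- frame
    tr$prev_t <- t
    tr$rows[[length(tr$rows) + 1]] <-
      data.frame(time_s = t, row = NA_real_, col = NA_real_,
                 area_px = NA_real_, valid = FALSE)
    return(invisible(tr))
  }
  motion <- frame_difference(frame, tr$prev_frame, cfg)
  blobs <- detect_blobs(motion, min_area = cfg$min_blob_area)
  gate_px <- cfg$max_jump_um / tr$um_per_px
  sel <- select_worm(blobs, tr$prev_centroid, max_jump_px = gate_px)
  if (sel$valid) {
    ctr <- sel$blob$centroid
    area <- sel$blob$area
    if (cfg$refine_body && !is.null(tr$background)) {
      ref <- .refine_body_centroid(frame, tr$background, sel$blob, cfg)
      if (!is.null(ref)) { ctr <- ref$centroid; area <- ref$area }
    }
    tr$prev_centroid <- ctr
    tr$rows[[length(tr$rows) + 1]] <-
      data.frame(time_s = t, row = ctr[1], col = ctr[2],
                 area_px = area, valid = TRUE)
  } else {
    prev <- tr$prev_centroid
    tr$rows[[length(tr$rows) + 1]] <-
      data.frame(time_s = t,
                 row = if (is.null(prev)) NA_real_ else prev[1],
                 col = if (is.null(prev)) NA_real_ else prev[2],
                 area_px = NA_real_, valid = FALSE)
  }
  tr$prev_frame <- frame
  tr$prev_t <- t
  invisible(tr)
}

#' @rdname tracker_new
#' @param origin world `(x, y)` um of the centre of pixel `[1, 1]` (used to
#'   report world coordinates; default maps pixel centres to
#'   `(col * um_per_px, -row * um_per_px)`).
#' @export
tracker_finish <- function(tr, origin = c(tr$um_per_px, -tr$um_per_px)) {
  traj <- do.call(rbind, tr$rows)
  traj$x_um <- origin[1] + (traj$col - 1) * tr$um_per_px
  traj$y_um <- origin[2] - (traj$row - 1) * tr$um_per_px
  derive_kinematics(traj, tr$config)
}

#' Track a frame sequence end to end
#'
#' @param frames a [frame_sequence()].
#' @param config a [tracker_config()].
#' @param origin world coordinates of pixel `[1, 1]`'s centre.
#' @return trajectory data.frame (see [derive_kinematics()]).
#' @export
track_frames <- function(frames, config = tracker_config(), origin = NULL) {
  stopifnot(inherits(frames, "wf_frames"))
  tr <- tracker_new(frames$um_per_px, config)
  for (i in seq_along(frames$frames))
    tracker_feed(tr, frames$frames[[i]], frames$times[i])
  if (is.null(origin)) origin <- c(frames$um_per_px, -frames$um_per_px)
  tracker_finish(tr, origin)
}
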