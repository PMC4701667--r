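#' Freehand tablet stroke stream
#'
#' An ordered stream of pen events from a drawing tablet. Tablet coordinates
#' are in tablet um; the drawing is shrunk by `scale_reduction` (default 50x,
#' the single end-to-end tablet-to-sample fold) before projection, and each
#' event reaches the sample plane `latency` seconds after the pen touch
#' (default 0.25 s).
#'
#' @param events data.frame with columns `x`, `y` (tablet um), `t` (s,
#'   non-decreasing), and optionally `pen` (logical pen-down; default TRUE).
#' @param brush_radius_tablet brush radius in tablet um.
#' @param scale_reduction dimensionless reduction fold.
#' @param latency touch-to-projection latency, s.
#' @return object of class `wf_strokes`.
#' @export
stroke_stream <- function(events, brush_radius_tablet = 2500,
                          scale_reduction = 50, latency = 0.25) {
  stopifnot(is.data.frame(events))
  if (nrow(events) > 0) {
    stopifnot(all(c("x", "y", "t") %in% names(events)))
    if (is.unsorted(events$t)) .wf_stop("event times must be non-decreasing")
  }
  if (scale_reduction <= 0) .wf_stop("scale_reduction must be > 0")
  if (is.null(events$pen)) events$pen <- rep(TRUE, nrow(events))
  structure(list(events = events, brush_radius_tablet = brush_radius_tablet,
                 scale_reduction = scale_reduction, latency = latency),
            class = "wf_strokes")
}

#' Compile a stroke stream into time-ordered mask increments
#'
#' Each pen-down event stamps a disc of radius `brush_radius_tablet /
#' scale_reduction` (um at the sample) at the scaled pen location, projected
#' at `t_event + latency`. Consecutive pen-down events further apart than one
#' brush radius are joined by a stamped line segment (tablets subsample fast
#' strokes). Events mapping outside the projected field are skipped with a
#' warning. Increments are cumulative-OR consistent: OR-ing the increments up
#' to any time gives the full projected drawing at that time.
#'
#' @param stream a [stroke_stream()].
#' @param transform a [projection_transform()].
#' @return list of `list(t_projected, mask)` in time order; `mask` is a
#'   `wf_mask` holding only that event's newly stamped pixels.
#' @export
stroke_to_mask_updates <- function(stream, transform) {
  ev <- stream$events
  ev <- ev[ev$pen, , drop = FALSE]
  if (nrow(ev) == 0) return(list())
  s <- transform$sample_um_per_dmd_px
  r_um <- stream$brush_radius_tablet / stream$scale_reduction
  r_px <- r_um / s
  fe <- field_extent(transform)
  nr <- transform$dmd_shape[1]; nc <- transform$dmd_shape[2]
  updates <- vector("list", nrow(ev))
  prev <- NULL
  prev_t <- -Inf
  acc <- matrix(0, nr, nc) # running OR of everything stamped so far
  nskip <- 0L
  for (i in seq_len(nrow(ev))) {
    wx <- ev$x[i] / stream$scale_reduction
    wy <- ev$y[i] / stream$scale_reduction
    if (wx < fe$xlim[1] || wx > fe$xlim[2] || wy < fe$ylim[1] || wy > fe$ylim[2]) {
      nskip <- nskip + 1L
      prev <- NULL
      prev_t <- -Inf
      next
    }
    px <- world_to_dmd(c(wx, wy), transform)
    pts <- px
    # join fast in-stroke subsampling gaps, but not separate taps: events
    # more than 0.2 s apart are distinct pen touches
    if (!is.null(prev) && (ev$t[i] - prev_t) <= 0.2 &&
        sqrt(sum((px - prev)^2)) > r_px) pts <- rbind(prev, px)
    stamped <- .stamp_tube(matrix(0, nr, nc), pts[, 1], pts[, 2], r_px, 1)
    inc <- stamped > 0 & acc == 0
    acc[inc] <- 1
    updates[[i]] <- list(t_projected = ev$t[i] + stream$latency,
                         mask = new_mask(inc, transform, exposure_time = NA))
    prev <- px
    prev_t <- ev$t[i]
  }
  if (nskip > 0)
    .wf_warn("%d stroke event(s) mapped outside the field and were skipped", nskip)
  updates[!vapply(updates, is.null, TRUE)]
}
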