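# Shared fixtures built in code (no binary files in the repository).

# small transform for fast rasterization tests: 2 um/px, 600 x 800 field
tf_small <- function(um_per_px = 2, shape = c(600L, 800L), objective = 5)
  projection_transform(objective, sample_um_per_dmd_px = um_per_px,
                       dmd_shape = shape)

# brute-force lattice-count oracle: pillar centres inside a w x h rectangle
# with the centre kept diameter/2 inside the region edge
oracle_pillar_count <- function(diameter, pitch, w, h) {
  r <- diameter / 2
  nx <- 0
  for (n in 1:10000) {
    if ((n - 1) * pitch + 2 * r <= w) nx <- n else break
  }
  ny <- 0
  for (n in 1:10000) {
    if ((n - 1) * pitch + 2 * r <= h) ny <- n else break
  }
  nx * ny
}

# deterministic random blob for moment tests
random_blob <- function(n = 60, nr = 40, nc = 40) {
  m <- matrix(FALSE, nr, nc)
  r <- sample.int(nr - 10, 1) + 5
  c <- sample.int(nc - 10, 1) + 5
  m[r, c] <- TRUE
  for (i in seq_len(n)) {
    px <- which(m, arr.ind = TRUE)
    k <- px[sample.int(nrow(px), 1), ]
    dr <- sample(c(-1, 0, 1), 1); dc <- sample(c(-1, 0, 1), 1)
    r2 <- min(max(k[1] + dr, 1), nr); c2 <- min(max(k[2] + dc, 1), nc)
    m[r2, c2] <- TRUE
  }
  m
}

# rectangle mask rotated by theta degrees from vertical (analytic moments
# oracle for orientation tests)
rotated_rect_mask <- function(theta_deg, len = 200, wid = 30, sz = 301) {
  th <- theta_deg * pi / 180
  ctr <- (sz + 1) / 2
  co <- matrix(seq_len(sz), sz, sz, byrow = TRUE) - ctr
  ro <- matrix(seq_len(sz), sz, sz) - ctr
  # axis along "vertical rotated clockwise by theta": u = along axis
  u <- -ro * cos(th) + co * sin(th)
  v <-  ro * sin(th) + co * cos(th)
  abs(u) <= len / 2 & abs(v) <= wid / 2
}

# hand-sized camera for fast rendering tests
cam_small <- function(...) camera_model(um_per_px = 10, frame_rate = 5, ...)
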