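test_that("world<->DMD transform round-trips and maps the centre", {
  tf <- projection_transform(5)
  expect_equal(unname(world_to_dmd(c(0, 0), tf)[1, ]),
               c(floor(768 / 2) + 1, floor(1024 / 2) + 1))
  set.seed(42)
  pts <- cbind(runif(1000, -2500, 2500), runif(1000, -1500, 1500))
  back <- dmd_to_world(world_to_dmd(pts, tf), tf)
  expect_lt(max(abs(back - pts)), 1e-6)
  # brute-force affine check: +x by 100 px worth of um moves col by +100
  s <- tf$sample_um_per_dmd_px
  px0 <- world_to_dmd(c(0, 0), tf)
  px1 <- world_to_dmd(c(100 * s, 0), tf)
  expect_equal(px1[1, "col"] - px0[1, "col"], 100)
  expect_equal(px1[1, "row"], px0[1, "row"])
  # out-of-field signal
  expect_warning(out <- world_to_dmd(c(1e6, 0), tf), "outside")
  expect_true(all(is.na(out)))
})

test_that("rasterization is deterministic, binary, pixel-centre sampled", {
  tf <- tf_small()
  spec <- pattern_frame(800, 600, 100)
  m1 <- rasterize(spec, tf)
  m2 <- rasterize(spec, tf)
  expect_identical(m1$pixels, m2$pixels)
  expect_true(all(m1$pixels %in% c(0L, 1L)))
  # empty polygon -> all-zero bitmap
  expect_equal(sum(rasterize(pattern_polygon(matrix(numeric(0), ncol = 2)),
                             tf)$pixels), 0)
  # a pattern reaching the field edge errors unless clipping is allowed
  big <- pattern_frame(2 * 800 * 2, 2 * 600 * 2, 100)
  expect_error(rasterize(big, tf), "field")
  expect_silent(rasterize(big, tf, allow_clip = TRUE))
})

test_that("pillar array geometry matches the printed 100/100 configuration", {
  # the paper's configuration: 100 um discs at 100 um centre-centre, i.e.
  # tangent pillars (they merge under connectivity, so measure by scanline)
  tf <- tf_small(um_per_px = 2)
  spec <- pattern_pillar_array(100, 100, region = c(1000, 600))
  m <- rasterize(spec, tf)
  # disc diameter 100 um +- 1 px: extent inside a one-pitch window centred
  # on a lattice point
  ctr_w <- wormfab:::.pillar_centers(spec)
  expect_equal(nrow(ctr_w), oracle_pillar_count(100, 100, 1000, 600))
  px0 <- world_to_dmd(ctr_w[1, , drop = FALSE], tf)
  win <- m$pixels[(px0[1] - 25):(px0[1] + 25), (px0[2] - 25):(px0[2] + 25)]
  rows_on <- range(which(rowSums(win) > 0))
  expect_lt(abs((rows_on[2] - rows_on[1] + 1) * 2 - 100), 2 + 1e-9)
  # neighbour spacing 100 um +- 1 px from the column-sum lattice profile
  cs <- colSums(m$pixels)
  pk <- which(cs == max(cs))
  pk <- pk[c(TRUE, diff(pk) > 10)] # one index per lattice column
  expect_gte(length(pk), 2)
  expect_lt(max(abs(diff(pk) * 2 - 100)), 2 + 1e-9)
  # separated lattice (pitch > diameter) matches the enumeration oracle as
  # connected components
  spec2 <- pattern_pillar_array(100, 200, region = c(1000, 600))
  m2 <- rasterize(spec2, tf)
  lab <- wormfab:::.cc_label(m2$pixels > 0)
  expect_equal(attr(lab, "n"), oracle_pillar_count(100, 200, 1000, 600))
})

test_that("rasterizing at half the pitch differs only on boundary pixels", {
  spec <- pattern_disk(c(0, 0), 300)
  tf1 <- tf_small(um_per_px = 4, shape = c(200L, 200L))
  tf2 <- tf_small(um_per_px = 2, shape = c(400L, 400L))
  a <- rasterize(spec, tf1)$pixels
  b <- rasterize(spec, tf2)$pixels
  # downsample fine raster by 2x2 majority
  ds <- (b[seq(1, 399, 2), seq(1, 399, 2)] + b[seq(2, 400, 2), seq(1, 399, 2)] +
         b[seq(1, 399, 2), seq(2, 400, 2)] + b[seq(2, 400, 2), seq(2, 400, 2)]) >= 2
  differ <- which(ds != (a > 0), arr.ind = TRUE)
  if (nrow(differ) > 0) {
    # every differing pixel must touch the boundary of the direct raster
    interior <- wormfab:::.erode_cross(a > 0)
    exterior <- wormfab:::.erode_cross(!(a > 0))
    on_boundary <- !(interior[differ] | exterior[differ])
    expect_true(all(on_boundary))
  } else succeed()
})

test_that("stitching is a commutative, associative, idempotent union", {
  tf <- tf_small(um_per_px = 4, shape = c(200L, 250L))
  f <- pattern_frame(800, 600, 100)
  m <- rasterize(f, tf)
  # single mask, zero offset: identical geometry
  s1 <- stitch(list(m))
  expect_equal(sum(s1$pixels), sum(m$pixels))
  # idempotent: same mask twice at the same offset
  s2 <- stitch(list(m, m), list(c(0, 0), c(0, 0)))
  expect_identical(s2$pixels, s1$pixels)
  # commutative on exposed sets
  off <- list(c(0, 0), c(300, 100))
  sa <- stitch(list(m, m), off)
  sb <- stitch(list(m, m), rev(off))
  expect_equal(sum(sa$pixels), sum(sb$pixels))
  # differing grids refuse to stitch without permission
  tfB <- tf_small(um_per_px = 5, shape = c(200L, 250L))
  expect_error(stitch(list(m, rasterize(f, tfB))), "grids")
})

test_that("two abutting frames stitch into a contiguous wall", {
  tf <- tf_small(um_per_px = 4, shape = c(250L, 250L))
  f <- pattern_frame(600, 600, 80)
  m <- rasterize(f, tf)
  # abut along x: second frame shifted by exactly the outer width
  st <- stitch(list(m, m), list(c(0, 0), c(600, 0)))
  # compare against direct rasterization of the doubled pattern
  direct <- rasterize_world(list(pattern_frame(600, 600, 80, center = c(0, 0)),
                                 pattern_frame(600, 600, 80, center = c(600, 0))),
                            range(occupancy_axes(st)$x) + c(-2, 2),
                            range(occupancy_axes(st)$y) + c(-2, 2), 4)
  # no gap at the seam: the shared wall column is solid in the stitched mask
  ax <- occupancy_axes(st)
  seam_cols <- which(abs(ax$x - 300) <= 40)
  wall_rows <- which(abs(ax$y) <= 260)
  expect_true(all(rowSums(st$pixels[wall_rows, seam_cols, drop = FALSE]) > 0))
  expect_lt(abs(sum(st$pixels) - sum(direct$pixels)) / sum(direct$pixels), 0.02)
})

test_that("T-maze raster has open lumen and disjoint terminals", {
  tm <- pattern_t_maze(1500, 1500, 200, 150, 300)
  occ <- rasterize_world(tm, c(-2100, 2100), c(-1800, 700), 10)
  ax <- occupancy_axes(occ)
  # lumen points are open: stem centre, junction, both terminals
  for (p in list(c(0, -750), c(0, 100), c(-1500, 100), c(1500, 100))) {
    r <- which.min(abs(ax$y - p[2])); c <- which.min(abs(ax$x - p[1]))
    expect_false(occ$pixels[r, c])
  }
  # wall between stem and outside is solid
  r <- which.min(abs(ax$y - (-750)))
  c <- which.min(abs(ax$x - (100 + 75)))
  expect_true(occ$pixels[r, c])
  tmn <- t_maze_terminals(tm)
  expect_lt(tmn$left["x"], tmn$right["x"])
})
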