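test_that("streamline length: 3-4-5 triangle, additivity, circle circumference", {
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0))
  expect_equal(streamline_length(a),
               streamline_length(a[1:2, ]) + streamline_length(a[2:3, ]))
  t <- seq(0, 2 * pi, length.out = 361)
  circ <- cbind(10 * cos(t), 10 * sin(t), 0)
  expect_equal(streamline_length(circ), 2 * pi * 10, tolerance = 1e-3)
  expect_error(streamline_length(rbind(c(0, 0, 0))), ">= 2 points")
})

test_that("Menger mean curvature: line, circle, helix, convergence", {
  line <- cbind(seq(0, 10, by = 0.7), 0, 0)
  expect_equal(streamline_mean_curvature(line), 0)
  t1 <- seq(0, 2 * pi, by = pi / 180)
  circ <- cbind(10 * cos(t1), 10 * sin(t1), 0)
  expect_equal(streamline_mean_curvature(circ), 0.1, tolerance = 1e-4)
  # helix r = 1, c = 1: kappa = r / (r^2 + c^2) = 0.5
  th <- seq(0, 4 * pi, by = 0.02)
  helix <- cbind(cos(th), sin(th), th)
  expect_equal(streamline_mean_curvature(helix), 0.5, tolerance = 0.01)
  # the Menger estimator is exact on a circle at any sampling (every
  # inscribed triple has circumradius R), so refinement cannot hurt ...
  err_at <- function(deg) {
    tt <- seq(0, 2 * pi, by = deg * pi / 180)
    abs(streamline_mean_curvature(cbind(10 * cos(tt), 10 * sin(tt), 0)) - 0.1)
  }
  expect_lte(err_at(0.5), err_at(5) + 1e-12)
  expect_lt(err_at(5), 1e-12)
  # ... and convergence under refinement is real where discretisation
  # bites, e.g. on the helix
  helix_err <- function(dt) {
    tt <- seq(0, 4 * pi, by = dt)
    abs(streamline_mean_curvature(cbind(cos(tt), sin(tt), tt)) - 0.5)
  }
  expect_lt(helix_err(0.02), helix_err(0.2))
  expect_error(streamline_mean_curvature(rbind(c(0, 0, 0), c(1, 0, 0))),
               ">= 3 points")
})

test_that("rasterization: axis-aligned crossings, re-entry uniqueness, outside grid", {
  g <- vox_grid(c(5, 3, 3), voxel_size = 1)
  # segment through the 5 voxel centres of row j=1, k=1
  s <- rbind(c(0, 1, 1), c(4, 1, 1))
  vox <- rasterize_streamline(s, g)
  expect_equal(sort_vox(vox), cbind(0:4, 1L, 1L))
  # a loop revisiting one voxel twice still reports it once
  loop <- rbind(c(1, 1, 1), c(1.2, 1.2, 1), c(1, 1.3, 1), c(0.9, 1, 1))
  expect_equal(nrow(rasterize_streamline(loop, g)), 1)
  # entirely outside the grid: empty set
  far <- rbind(c(100, 100, 100), c(101, 101, 101))
  expect_equal(nrow(rasterize_streamline(far, g)), 0)
})

test_that("exact rasterization equals the brute-force box-clipping oracle on random polylines", {
  set.seed(55)
  g <- vox_grid(c(10, 10, 10), voxel_size = 1)
  for (i in 1:30) {
    n_pts <- sample(2:6, 1)
    s <- matrix(runif(n_pts * 3, -1, 10), ncol = 3)
    got <- sort_vox(rasterize_streamline(s, g))
    want <- box_clip_oracle(s, g)
    expect_equal(got, want)
  }
})

test_that("dense supersampling membership is a subset of the exact raster set", {
  set.seed(56)
  g <- vox_grid(c(8, 8, 8), voxel_size = 1)
  for (i in 1:10) {
    s <- matrix(runif(12, 0, 7), ncol = 3)
    exact <- rasterize_streamline(s, g)
    dense <- supersample_oracle(s, g, step = 0.01)
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    expect_true(all(key(dense) %in% key(exact)))
  }
})

test_that("rasterization respects a non-trivial affine", {
  g <- vox_grid(c(6, 6, 2), voxel_size = 2, origin = c(-4, -4, 0))
  s <- rbind(c(-4, -4, 0), c(6, -4, 0))   # along x at voxel row j=0
  vox <- sort_vox(rasterize_streamline(s, g))
  expect_equal(vox, cbind(0:5, 0L, 0L))
})

test_that("track-weighted maps: homogeneous bundle, two-track mean, masking", {
  g <- vox_grid(c(9, 3, 3), voxel_size = 1)
  bundle <- replicate(4, rbind(c(0, 1, 1), c(8, 1, 1)), simplify = FALSE)
  maps <- track_weighted_maps(bundle, g)
  traversed <- maps$TDI$data > 0
  expect_equal(sum(traversed), 9)
  expect_true(all(maps$TDI$data[traversed] == 4))
  expect_true(all(maps$APM$data[traversed] == 8))
  expect_true(all(!maps$APM$valid[!traversed]))
  # two tracks of lengths 10 and 20 through one voxel: APM = 15
  g2 <- vox_grid(c(3, 25, 3), voxel_size = 1)
  t1 <- rbind(c(1, 1, 1), c(1, 11, 1))
  t2 <- rbind(c(1, 1, 1), c(1, 21, 1))
  maps2 <- track_weighted_maps(list(t1, t2), g2)
  expect_equal(maps2$APM$data[2, 2, 2], 15)
  expect_equal(maps2$TDI$data[2, 2, 2], 2)
  expect_error(track_weighted_maps(list(), g), "empty tractogram")
})

test_that("two-point streamlines feed TDI/APM but not the curvature map", {
  g <- vox_grid(c(5, 3, 3), voxel_size = 1)
  straight2 <- rbind(c(0, 1, 1), c(4, 1, 1))          # no curvature sample
  curved3 <- rbind(c(0, 1.2, 1), c(2, 1.4, 1), c(4, 1.2, 1))
  maps <- track_weighted_maps(list(straight2, curved3), g)
  v <- maps$TDI$data[3, 2, 2]
  expect_equal(v, 2)
  kap <- streamline_mean_curvature(curved3)
  expect_equal(maps$CURV$data[3, 2, 2], kap)   # mean over curvature-bearing tracks only
})

test_that("map accumulation is order independent", {
  set.seed(57)
  g <- vox_grid(c(8, 8, 8), voxel_size = 1)
  bundle <- lapply(1:6, function(i) matrix(runif(12, 0, 7), ncol = 3))
  m1 <- track_weighted_maps(bundle, g)
  m2 <- track_weighted_maps(rev(bundle), g)
  expect_equal(m1$TDI$data, m2$TDI$data)
  expect_equal(m1$APM$data, m2$APM$data)
  expect_equal(m1$CURV$data, m2$CURV$data)
})

test_that("every in-grid streamline contributes at least one TDI count", {
  b <- simulate_bundle(tract_sim_config(geometry = "circle", radius_mm = 10,
                                        n_streamlines = 25, jitter_sigma = 0.3,
                                        seed = 8))
  g <- vox_grid(c(26, 26, 3), voxel_size = 1, origin = c(-12.5, -12.5, -1))
  maps <- track_weighted_maps(b$tractogram, g)
  expect_gte(sum(maps$TDI$data), 25)
})
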