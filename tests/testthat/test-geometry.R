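test_that("distance fields reproduce simple exact distances", {
  m <- array(FALSE, c(16, 16, 16)); m[8, 8, 8] <- TRUE
  f <- distance_field(brain_mask(m))
  expect_equal(f$dist[9, 8, 8], 1)          # face neighbour at 1 mm
  expect_equal(f$dist[13, 8, 8], 5)         # 5 mm on-axis
  expect_equal(f$dist[8, 8, 8], 0)
  expect_error(distance_field(brain_mask(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("distance field matches the exhaustive nearest-source oracle", {
  set.seed(42)
  for (spacing in list(c(1, 1, 1), c(0.5, 1, 2))) {
    dm <- c(24, 20, 16)
    m <- array(stats::runif(prod(dm)) < 0.01, dm)
    m[5, 5, 5] <- TRUE
    bm <- brain_mask(m, diag(c(spacing, 1)))
    f <- distance_field(bm)
    # on-grid: exact agreement with brute force
    idx <- cbind(sample(0:(dm[1] - 1), 50, TRUE),
                 sample(0:(dm[2] - 1), 50, TRUE),
                 sample(0:(dm[3] - 1), 50, TRUE))
    pts <- sweep(idx, 2, spacing, "*")
    expect_equal(f$dist[idx + 1], bf_distance(bm, pts), tolerance = 1e-9)
    # off-grid: within one voxel diagonal of brute force
    pts_off <- pts + matrix(stats::runif(150, -0.5, 0.5), ncol = 3) *
      rep(spacing, each = 50)
    diag_len <- sqrt(sum(spacing^2))
    expect_lt(max(abs(sample_field(f, pts_off) - bf_distance(bm, pts_off))),
              diag_len)
  }
})

test_that("sampled nodes are equally spaced and endpoint-inclusive", {
  tr <- trajectory(c(0, 0, 0), c(100, 0, 0))
  expect_equal(sample_nodes(tr, 2), rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(sample_nodes(tr, 3)[2, ], c(50, 0, 0))
  tr2 <- trajectory(c(3, -2, 7), c(61, 40, -13))
  nd <- sample_nodes(tr2, 128)
  gaps <- sqrt(rowSums(diff(nd)^2))
  expect_lt(max(abs(gaps - tr2$length / 127)), 1e-9)
  expect_equal(nd[1, ], tr2$entry)
  expect_equal(nd[128, ], tr2$target)
  expect_error(sample_nodes(tr, 1), "2 nodes")
  expect_error(trajectory(c(1, 2, 3), c(1, 2, 3)), "degenerate")
})

test_that("skull normals recover planar and spherical surface orientations", {
  # flat axial slab
  m <- array(FALSE, c(24, 24, 24)); m[, , 10:12] <- TRUE
  slab <- brain_mask(m)
  n_top <- skull_normal(slab, c(12, 12, 12.4))
  expect_equal(sqrt(sum(n_top^2)), 1, tolerance = 1e-6)
  ang <- acos(abs(sum(n_top * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 2)
  expect_gt(n_top[3], 0)  # outward on the upper face

  # spherical shell: normal parallel to the radius vector
  dm <- c(40, 40, 40); ctr <- c(19.5, 19.5, 19.5)
  co <- as.matrix(expand.grid(i = 0:39, j = 0:39, k = 0:39))
  r <- sqrt(rowSums(sweep(co, 2, ctr)^2))
  shell <- brain_mask(array(r >= 14 & r <= 16, dm))
  sdist <- skull_signed_distance(shell)
  for (dir in list(c(1, 0, 0), c(0, 0, -1), c(1, 1, 1) / sqrt(3))) {
    p <- ctr + 15.5 * dir
    nrm <- skull_normal(sdist, p)
    expect_equal(sqrt(sum(nrm^2)), 1, tolerance = 1e-6)
    expect_lt(acos(min(1, abs(sum(nrm * dir)))) * 180 / pi, 2)
    expect_gt(sum(nrm * dir), 0)  # outward
  }
  expect_error(skull_normal(shell, ctr), "2 voxels")
})

test_that("drilling angle is the orientation-insensitive angle to the normal", {
  tr <- trajectory(c(0, 0, 0), c(0, 0, 10))
  expect_equal(drilling_angle(tr, c(0, 0, 1)), 0)
  expect_equal(drilling_angle(tr, c(0, 0, -1)), 0)   # sign-insensitive
  expect_equal(drilling_angle(tr, c(1, 0, 0)), 90)
  nrm <- c(sin(30 * pi / 180), 0, cos(30 * pi / 180))
  expect_equal(drilling_angle(tr, nrm), 30, tolerance = 1e-9)
  expect_equal(drilling_angle(tr, 2 * nrm), 30, tolerance = 1e-9)
})

test_that("segment intersection agrees with dense-sampling oracle on grazing paths", {
  bm <- ball_mask(dim = c(32, 32, 32), centre = c(16, 16, 16), radius = 6)
  far <- trajectory(c(1, 1, 1), c(2, 1, 1))
  expect_false(segment_intersects(bm, far))
  thru <- trajectory(c(1, 16, 16), c(31, 16, 16))
  expect_true(segment_intersects(bm, thru))
  set.seed(7)
  for (i in 1:25) {
    off <- stats::runif(1, 4.5, 8.5)   # graze near the ball surface
    z <- 16 + off * sin(stats::runif(1, 0, pi))
    y <- 16 + off * cos(stats::runif(1, 0, pi))
    tr <- trajectory(c(1, y, z), c(31, y + stats::runif(1, -1, 1), z))
    expect_identical(segment_intersects(bm, tr, step = 0.01),
                     bf_segment_intersects(bm$mask |> brain_mask(bm$affine),
                                           tr$entry, tr$target))
  }
})

test_that("exact traversal catches corner grazes that sampling can miss", {
  # single voxel at index (10,10,10): cube [9.5,10.5]^3 in world mm
  m <- array(FALSE, c(20, 20, 20)); m[11, 11, 11] <- TRUE
  bm <- brain_mask(m)
  # segment clipping only the cube corner at (9.5, 9.5): on the line
  # x + y = 19.04 the cube interior is crossed for x in [9.5, 9.54],
  # a chord of ~0.06 mm that a sampled test can step over
  graze <- trajectory(c(10.3, 8.74, 10), c(8.74, 10.3, 10))
  expect_true(segment_intersects_exact(bm, graze))
  expect_false(segment_intersects(bm, graze, step = 0.5))
  # x + y = 18.96 stays outside the cube entirely
  miss <- trajectory(c(10.3, 8.66, 10), c(8.66, 10.3, 10))
  expect_false(segment_intersects_exact(bm, miss))
  # agreement with the sampled test away from knife edges
  ball <- ball_mask(dim = c(32, 32, 32), centre = c(16, 16, 16), radius = 6)
  set.seed(5)
  for (i in 1:20) {
    tr <- trajectory(stats::runif(3, 0, 31), stats::runif(3, 0, 31))
    sampled <- segment_intersects(ball, tr, step = 0.01)
    exact <- segment_intersects_exact(ball, tr)
    # exact can only find more than a sampled test
    expect_true(exact >= sampled)
  }
})

test_that("min distance along a trajectory matches analytic placement", {
  m <- array(FALSE, c(32, 32, 32)); m[16, 16, 16] <- TRUE  # source at (15,15,15)
  f <- distance_field(brain_mask(m))
  # line at constant 7 mm offset in y, passing the source at closest approach
  tr <- trajectory(c(1, 22, 15), c(29, 22, 15))
  expect_equal(min_distance_along(tr, f, 128), 7, tolerance = 0.1)
  # 29 nodes over 28 mm puts one node exactly on the source voxel centre
  thru <- trajectory(c(1, 15, 15), c(29, 15, 15))
  expect_equal(min_distance_along(thru, f, 29), 0, tolerance = 1e-9)
})

test_that("geometry is invariant under joint rigid translation", {
  set.seed(11)
  dm <- c(24, 24, 24)
  m <- array(stats::runif(prod(dm)) < 0.02, dm); m[10, 10, 10] <- TRUE
  t_mm <- c(13.25, -8.5, 4.75)
  aff_t <- diag(4); aff_t[1:3, 4] <- t_mm
  f0 <- distance_field(brain_mask(m))
  f1 <- distance_field(brain_mask(m, aff_t))
  tr0 <- trajectory(c(2, 3, 4), c(20, 21, 18))
  tr1 <- trajectory(tr0$entry + t_mm, tr0$target + t_mm)
  expect_equal(min_distance_along(tr0, f0, 64),
               min_distance_along(tr1, f1, 64), tolerance = 1e-6)
  expect_equal(segment_intersects(brain_mask(m), tr0),
               segment_intersects(brain_mask(m, aff_t), tr1))
})

test_that("dilating the source never increases distances along a path", {
  bm <- ball_mask(dim = c(32, 32, 32), centre = c(16, 16, 16), radius = 4)
  big <- ball_mask(dim = c(32, 32, 32), centre = c(16, 16, 16), radius = 7)
  tr <- trajectory(c(1, 26, 16), c(31, 26, 16))
  expect_gte(min_distance_along(tr, distance_field(bm), 64),
             min_distance_along(tr, distance_field(big), 64))
})
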