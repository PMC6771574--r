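half_mm_grid <- function(extent = 40) {
  n <- round(extent / 0.5)
  label_volume(array(0L, c(n, n, n)), diag(c(0.5, 0.5, 0.5, 1)))
}

test_that("capsule voxelisation reproduces closed-form volumes within 2%", {
  grid <- half_mm_grid(40)
  r <- 7.5
  ctr <- c(20.1, 19.7, 20.3)       # generic, off voxel centres
  sph <- capsule_voxelize(ctr, r, grid)
  v_sphere <- 4 / 3 * pi * r^3     # 1767.15
  expect_lt(abs(volume_mm3(sph) - v_sphere) / v_sphere, 0.02)

  grid2 <- half_mm_grid(50)
  seg <- list(proximal = c(24.9, 25.2, 12.6), distal = c(24.9, 25.2, 32.6))
  cap <- capsule_voxelize(seg, r, grid2)
  v_capsule <- pi * r^2 * 20 + v_sphere   # 3534.29 + 1767.15
  expect_lt(abs(volume_mm3(cap) - v_capsule) / v_capsule, 0.02)
})

test_that("voxelisation error shrinks when the grid is refined", {
  r <- 7.5
  ctr <- c(20.1, 19.7, 20.3)
  v_true <- 4 / 3 * pi * r^3
  err <- sapply(c(1, 0.5, 0.25), function(h) {
    n <- round(40 / h)
    grid <- label_volume(array(0L, c(n, n, n)), diag(c(h, h, h, 1)))
    abs(volume_mm3(capsule_voxelize(ctr, r, grid)) - v_true)
  })
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
})

test_that("capsule membership equals the brute-force point-to-segment predicate", {
  set.seed(21)
  n <- 48
  grid <- label_volume(array(0L, c(n, n, n)), diag(c(0.75, 1, 1.25, 1)))
  for (i in 1:3) {
    a <- stats::runif(3, 10, 20); b <- stats::runif(3, 25, 40)
    r <- stats::runif(1, 3, 8)
    cap <- capsule_voxelize(list(proximal = a, distal = b), r, grid)
    all_mask <- brain_mask(array(TRUE, c(n, n, n)), grid$affine)
    expect_identical(sum(cap$mask),
                     bf_capsule_overlap_count(all_mask, a, b, r))
  }
})

test_that("ablation segment follows the capsule-touches-ROI rule", {
  # isolated sphere ROI of radius 5 centred on the trajectory
  roi <- ball_mask(dim = c(64, 64, 64), centre = c(32, 32, 32), radius = 5)
  tr <- trajectory(c(2, 32, 32), c(32, 32, 32))   # target at sphere centre
  seg <- ablation_segment(tr, roi, ablation_params(diameter = 15))
  # proximal point where distance to sphere surface = 7.5:
  # 12.5 mm before the centre (5 + 7.5)
  expect_equal(seg$ablation_length, 12.5, tolerance = 0.15)
  expect_equal(seg$distal, tr$target)

  # clipping plane at the target degenerates the segment to a point
  p_clip <- ablation_params(diameter = 15,
                            posterior_limit = list(point = c(32, 32, 32),
                                                   normal = c(1, 0, 0)))
  seg2 <- ablation_segment(tr, roi, p_clip)
  expect_equal(seg2$ablation_length, 0, tolerance = 1e-9)

  far <- trajectory(c(2, 5, 5), c(60, 5, 5))      # > 20 mm from the ROI
  expect_error(ablation_segment(far, roi, ablation_params()), "radius")
})

test_that("overlap percentages behave at the containment extremes", {
  n <- 64
  grid <- label_volume(array(0L, c(n, n, n)), diag(4))
  big <- ball_mask(dim = c(n, n, n), centre = c(32, 32, 32), radius = 20)
  small <- ball_mask(dim = c(n, n, n), centre = c(32, 32, 32), radius = 4)
  far <- ball_mask(dim = c(n, n, n), centre = c(10, 10, 10), radius = 4)
  capsule <- capsule_voxelize(c(32, 32, 32), 7.5, grid)
  est <- overlap_stats(capsule, list(big = big, small = small, far = far))
  ps <- est$per_structure
  # capsule strictly inside `big`: percent = V_capsule / V_big
  expect_equal(ps$percent[ps$structure == "big"],
               100 * volume_mm3(capsule) / volume_mm3(big))
  expect_equal(ps$percent[ps$structure == "small"], 100)
  expect_equal(ps$percent[ps$structure == "far"], 0)
  # disjoint structures cannot jointly absorb more than the cavity
  disjoint <- ps$structure %in% c("small", "far")
  expect_lte(sum(ps$overlap_mm3[disjoint]), est$total_volume)
  empty <- brain_mask(array(FALSE, c(n, n, n)), grid$affine)
  expect_error(overlap_stats(capsule, list(none = empty)), "zero volume")
})

test_that("overlaps are invariant under joint rigid translation", {
  ph <- cached_phantom(1)
  tr <- ph$truth$trajectories$centroid_T2
  est0 <- estimate_ablation(trajectory(tr$entry, tr$target), ph$scene)
  # translate the world: same labels, shifted affine, shifted trajectory
  t_mm <- c(5.25, -3.5, 8)
  aff <- ph$volume$affine
  aff[1:3, 4] <- aff[1:3, 4] + t_mm
  vol_t <- label_volume(ph$volume$labels, aff)
  roi_t <- extract_mask(vol_t, c("amygdala", "hippocampus",
                                 "entorhinal_cortex",
                                 "parahippocampal_gyrus"), ph$map)
  tr_t <- trajectory(tr$entry + t_mm, tr$target + t_mm)
  seg_t <- ablation_segment(tr_t, roi_t, ablation_params())
  cap_t <- capsule_voxelize(seg_t, 7.5, vol_t)
  st_t <- lapply(c(amygdala = "amygdala", hippocampus = "hippocampus"),
                 function(r) extract_mask(vol_t, r, ph$map))
  est_t <- overlap_stats(cap_t, st_t, seg_t)
  p0 <- est0$per_structure
  pt <- est_t$per_structure
  expect_equal(pt$percent[pt$structure == "amygdala"],
               p0$percent[p0$structure == "amygdala"], tolerance = 1e-9)
  expect_equal(pt$percent[pt$structure == "hippocampus"],
               p0$percent[p0$structure == "hippocampus"], tolerance = 1e-9)
  expect_equal(est_t$ablation_length, est0$ablation_length,
               tolerance = 1e-9)
})

test_that("cavity volume grows with diameter and segment length", {
  grid <- half_mm_grid(50)
  seg_short <- list(proximal = c(25, 25, 20), distal = c(25, 25, 30))
  seg_long <- list(proximal = c(25, 25, 12), distal = c(25, 25, 30))
  v <- function(seg, d) volume_mm3(capsule_voxelize(seg, d / 2, grid))
  expect_lt(v(seg_short, 10), v(seg_short, 15))
  expect_lt(v(seg_short, 15), v(seg_long, 15))
  expect_warning(ablation_params(diameter = 20), "5-15")
})
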