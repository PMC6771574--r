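# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (exhaustive enumeration / dense sampling) and never
# share code with the implementation paths they check.

# world centres of all TRUE voxels
mask_world_centres <- function(mask) {
  idx <- which(mask$mask, arr.ind = TRUE) - 1
  h <- cbind(idx, 1) %*% t(mask$affine)
  h[, 1:3, drop = FALSE]
}

# exhaustive nearest-source-voxel distance at query points (n x 3)
bf_distance <- function(mask, pts) {
  W <- mask_world_centres(mask)
  pts <- matrix(pts, ncol = 3)
  vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min((W[, 1] - pts[i, 1])^2 + (W[, 2] - pts[i, 2])^2 +
               (W[, 3] - pts[i, 3])^2))
  }, numeric(1))
}

# dense-sampling segment/mask intersection (nearest-voxel membership)
bf_segment_intersects <- function(mask, entry, target, step = 0.01) {
  len <- sqrt(sum((target - entry)^2))
  n <- max(2, ceiling(len / step) + 1)
  t <- seq(0, 1, length.out = n)
  pts <- cbind(entry[1] + t * (target[1] - entry[1]),
               entry[2] + t * (target[2] - entry[2]),
               entry[3] + t * (target[3] - entry[3]))
  v <- round(cbind(pts, 1) %*% t(solve(mask$affine)))[, 1:3, drop = FALSE]
  dm <- dim(mask$mask)
  keep <- v[, 1] >= 0 & v[, 1] < dm[1] & v[, 2] >= 0 & v[, 2] < dm[2] &
    v[, 3] >= 0 & v[, 3] < dm[3]
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0) return(FALSE)
  any(mask$mask[1 + v[, 1] + dm[1] * (v[, 2] + dm[2] * v[, 3])])
}

# independently coded risk score: explicit node loop over brute-force
# nearest-vessel distances
bf_risk_score <- function(entry, target, vessel_mask, n_nodes = 128,
                          d_safe = 3, d_max = 10) {
  risks <- numeric(n_nodes)
  for (i in seq_len(n_nodes)) {
    t <- (i - 1) / (n_nodes - 1)
    p <- entry + t * (target - entry)
    d <- bf_distance(vessel_mask, p)
    risks[i] <- (d_max - min(d, d_max)) / (d_max - d_safe)
  }
  mean(risks)
}

# brute-force capsule overlap: per-voxel point-to-segment distance test
bf_capsule_overlap_count <- function(struct_mask, a, b, radius) {
  W <- mask_world_centres(struct_mask)
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(W, 2, a)
  t <- if (len2 < 1e-24) rep(0, nrow(W)) else
    pmin(1, pmax(0, as.vector(rel %*% ab) / len2))
  dx <- rel - outer(t, ab)
  sum(sqrt(rowSums(dx^2)) <= radius)
}

# small solid-ball mask on an isotropic grid, for quick fixtures
ball_mask <- function(dim = c(32, 32, 32), centre = dim / 2, radius = 5,
                      spacing = c(1, 1, 1)) {
  co <- expand.grid(i = 0:(dim[1] - 1), j = 0:(dim[2] - 1),
                    k = 0:(dim[3] - 1))
  pts <- sweep(as.matrix(co), 2, spacing, "*")
  m <- array(rowSums(sweep(pts, 2, centre)^2) <= radius^2, dim)
  brain_mask(m, diag(c(spacing, 1)))
}
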