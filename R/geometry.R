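#' Straight stereotactic trajectory
#'
#' A directed segment from a scalp entry point to an intracranial target,
#' both in world millimetres.
#'
#' @param entry,target Length-3 numeric points (world mm).
#' @return Object of class `litt_trajectory` with unit `direction`
#'   (entry to target) and `length` (mm).
#' @export
trajectory <- function(entry, target) {
  entry <- as.numeric(entry); target <- as.numeric(target)
  if (length(entry) != 3L || length(target) != 3L)
    stop("entry and target must be length-3 points", call. = FALSE)
  d <- target - entry
  len <- sqrt(sum(d^2))
  if (len <= 0)
    stop("degenerate trajectory: entry and target coincide", call. = FALSE)
  structure(list(entry = entry, target = target,
                 direction = d / len, length = len),
            class = "litt_trajectory")
}

#' @export
print.litt_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> entry (%s) -> target (%s), length %.1f mm\n",
              paste(sprintf("%.1f", x$entry), collapse = ", "),
              paste(sprintf("%.1f", x$target), collapse = ", "),
              x$length))
  invisible(x)
}

#' Euclidean distance field of a mask
#'
#' Exact Euclidean distance transform in world millimetres, honouring
#' anisotropic voxel spacing: each grid value is the distance to the
#' nearest true voxel centre of the source mask. Off-grid queries use
#' trilinear interpolation; queries outside the grid clamp to the nearest
#' border voxel.
#'
#' @param mask A non-empty `brain_mask`.
#' @return Object of class `distance_field` with array `dist` plus the
#'   mask's `affine`/`spacing`.
#' @export
distance_field <- function(mask) {
  if (!any(mask$mask))
    stop("distance field of an empty mask is undefined", call. = FALSE)
  d <- edt3d_cpp(mask$mask, dim(mask$mask), mask$spacing)
  structure(list(dist = d, affine = mask$affine, spacing = mask$spacing),
            class = "distance_field")
}

#' Sample a gridded field at world points
#'
#' Trilinear interpolation; points outside the grid are clamped to the
#' border voxel layer.
#'
#' @param field A `distance_field` (or any list with `dist` array and
#'   `affine`).
#' @param pts n x 3 matrix (or length-3 vector) of world-mm points.
#' @return Numeric vector of n sampled values.
#' @export
sample_field <- function(field, pts) {
  pts <- matrix(pts, ncol = 3L)
  v <- world_to_voxel(field$affine, pts)
  dm <- dim(field$dist)
  interp_trilinear(field$dist, dm, v)
}

# trilinear interpolation at fractional 0-based voxel coords, clamped
interp_trilinear <- function(arr, dm, v) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  v1 <- clamp(v[, 1], 0, dm[1] - 1)
  v2 <- clamp(v[, 2], 0, dm[2] - 1)
  v3 <- clamp(v[, 3], 0, dm[3] - 1)
  i0 <- clamp(floor(v1), 0, dm[1] - 1); i1 <- clamp(i0 + 1, 0, dm[1] - 1)
  j0 <- clamp(floor(v2), 0, dm[2] - 1); j1 <- clamp(j0 + 1, 0, dm[2] - 1)
  k0 <- clamp(floor(v3), 0, dm[3] - 1); k1 <- clamp(k0 + 1, 0, dm[3] - 1)
  fx <- v1 - floor(v1); fy <- v2 - floor(v2); fz <- v3 - floor(v3)
  at <- function(i, j, k) arr[1L + i + dm[1] * (j + dm[2] * k)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(i0, j0, k0) + fx * at(i1, j0, k0)) +
                    fy  * ((1 - fx) * at(i0, j1, k0) + fx * at(i1, j1, k0))) +
        fz  * ((1 - fy) * ((1 - fx) * at(i0, j0, k1) + fx * at(i1, j0, k1)) +
                    fy  * ((1 - fx) * at(i0, j1, k1) + fx * at(i1, j1, k1)))
}

#' Equally spaced nodes along a trajectory
#'
#' `n` nodes including both endpoints, spacing `length/(n-1)`. The node
#' count is fixed by the caller, never by trajectory length.
#'
#' @param traj A [trajectory()].
#' @param n Node count, at least 2.
#' @return n x 3 matrix of world-mm points, entry first, target last.
#' @export
sample_nodes <- function(traj, n) {
  if (n < 2L)
    stop("at least 2 nodes are required", call. = FALSE)
  t <- seq(0, 1, length.out = n)
  sweep(outer(t, traj$target - traj$entry), 2, traj$entry, "+")
}

# separable Gaussian smoothing of a 3-D array, sigma in voxels
gauss_smooth3 <- function(arr, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  dm <- dim(arr)
  smooth_axis <- function(a, axis) {
    out <- array(0, dm)
    n <- dm[axis]
    for (o in seq(-r, r)) {
      src <- pmin(pmax(seq_len(n) + o, 1L), n)  # replicate border
      idx <- switch(axis,
                    list(src, TRUE, TRUE), list(TRUE, src, TRUE),
                    list(TRUE, TRUE, src))
      out <- out + k[o + r + 1] * do.call(`[`, c(list(a), idx))
    }
    out
  }
  arr <- smooth_axis(arr, 1L)
  arr <- smooth_axis(arr, 2L)
  smooth_axis(arr, 3L)
}

#' Smoothed signed distance of the skull for normal estimation
#'
#' Signed distance (mm) of the filled skull shell — negative inside the
#' head, positive outside, zero on the outer surface — smoothed with a
#' Gaussian of one voxel so its gradient is stable on a voxelised shell.
#'
#' @param skull A `brain_mask` of the skull/scalp shell.
#' @return A `distance_field`-like object usable with [sample_field()].
#' @export
skull_signed_distance <- function(skull, sigma = 1) {
  if (!any(skull$mask))
    stop("empty skull mask", call. = FALSE)
  dm <- dim(skull$mask)
  solid <- fill_holes_cpp(skull$mask, dm)
  d_out <- edt3d_cpp(solid, dm, skull$spacing)          # 0 inside head
  d_in <- edt3d_cpp(!solid, dm, skull$spacing)          # 0 outside head
  sd_raw <- array(d_out - d_in, dm)
  sd <- gauss_smooth3(sd_raw, sigma)
  # |signed distance| measures proximity to the head surface; used for
  # the "entry near the shell" precondition
  structure(list(dist = sd, affine = skull$affine, spacing = skull$spacing,
                 surf_dist = structure(
                   list(dist = abs(sd_raw), affine = skull$affine,
                        spacing = skull$spacing),
                   class = "distance_field")),
            class = c("skull_sdist", "distance_field"))
}

#' Outward skull-surface normal at an entry point
#'
#' Gradient of the smoothed signed skull distance, evaluated by central
#' differences at the entry point and normalised to unit length. The
#' entry must lie within two voxels of the shell surface.
#'
#' @param skull A `brain_mask` of the skull shell, or a precomputed
#'   [skull_signed_distance()] object (cheaper when evaluating many
#'   entries).
#' @param entry Length-3 world-mm point (or n x 3 matrix).
#' @return Unit outward normal (length-3, or n x 3 matrix).
#' @export
skull_normal <- function(skull, entry) {
  sdist <- if (inherits(skull, "skull_sdist")) skull
           else skull_signed_distance(skull)
  entry <- matrix(entry, ncol = 3L)
  surf_d <- sample_field(sdist$surf_dist, entry)
  tol <- 2 * max(sdist$spacing)
  if (any(surf_d > tol))
    stop("entry point lies more than 2 voxels from the skull surface",
         call. = FALSE)
  h <- 0.5 * min(sdist$spacing)
  g <- matrix(0, nrow(entry), 3L)
  for (ax in 1:3) {
    e <- matrix(0, 1, 3); e[ax] <- h
    g[, ax] <- (sample_field(sdist, sweep(entry, 2, e, "+")) -
                sample_field(sdist, sweep(entry, 2, e, "-"))) / (2 * h)
  }
  nrm <- sqrt(rowSums(g^2))
  if (any(nrm < 1e-12))
    stop("degenerate skull normal (flat signed distance)", call. = FALSE)
  g <- g / nrm
  if (nrow(g) == 1L) as.numeric(g) else g
}

#' Drilling angle between a trajectory and the skull normal
#'
#' Angle in degrees between the trajectory direction and the surface
#' normal line, orientation-insensitive: `acos(|direction . normal|)`.
#' 0 means drilling orthogonal to the bone surface; small angles prevent
#' skiving of the drill at the bone.
#'
#' @param traj A [trajectory()].
#' @param normal Unit normal at the entry (sign irrelevant).
#' @return Angle in `[0, 90]` degrees.
#' @export
drilling_angle <- function(traj, normal) {
  d <- abs(sum(traj$direction * normal / sqrt(sum(normal^2))))
  acos(min(1, d)) * 180 / pi
}

#' Does a segment pass through a mask?
#'
#' Samples the entry-target segment at spacing at most `step` (endpoints
#' included) and tests whether any sample's nearest voxel is true.
#'
#' @param mask A `brain_mask`.
#' @param traj A [trajectory()].
#' @param step Sampling step in mm (> 0).
#' @return Logical.
#' @export
segment_intersects <- function(mask, traj, step = 0.5) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  n <- max(2L, ceiling(traj$length / step) + 1L)
  pts <- sample_nodes(traj, n)
  v <- round(world_to_voxel(mask$affine, pts))
  dm <- dim(mask$mask)
  inside <- v[, 1] >= 0 & v[, 1] < dm[1] &
            v[, 2] >= 0 & v[, 2] < dm[2] &
            v[, 3] >= 0 & v[, 3] < dm[3]
  if (!any(inside)) return(FALSE)
  v <- v[inside, , drop = FALSE]
  any(mask$mask[1L + v[, 1] + dm[1] * (v[, 2] + dm[2] * v[, 3])])
}

#' Exact segment/mask intersection by voxel traversal
#'
#' Walks the voxel grid along the segment (3-D DDA) and reports whether
#' any traversed voxel is true. Unlike the sampled [segment_intersects()],
#' this catches arbitrarily short corner grazes, so it is what the
#' planner uses for no-entry zones.
#'
#' @param mask A `brain_mask`.
#' @param traj A [trajectory()].
#' @return Logical.
#' @export
segment_intersects_exact <- function(mask, traj) {
  v <- world_to_voxel(mask$affine, rbind(traj$entry, traj$target)) + 0.5
  segment_hits_mask_cpp(mask$mask, dim(mask$mask), v[1, ], v[2, ])
}

#' Minimum field value along a trajectory
#'
#' Minimum of a distance field sampled at [sample_nodes()] of the
#' trajectory.
#'
#' @param traj A [trajectory()].
#' @param field A `distance_field`.
#' @param n Node count (default 128).
#' @return Minimum sampled distance (mm).
#' @export
min_distance_along <- function(traj, field, n = 128L) {
  min(sample_field(field, sample_nodes(traj, n)))
}
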