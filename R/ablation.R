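#' Ablation-cavity parameters
#'
#' The thermal ablation cavity is modelled as a uniform-diameter capsule
#' (cylinder with hemispherical caps) along the distal trajectory.
#' Clinically reported cavity diameters span 5-15 mm; the default 15 mm
#' is the estimated maximal uniform cavity.
#'
#' @param diameter Cavity diameter in mm; a warning is issued outside
#'   `[5, 15]`.
#' @param posterior_limit Optional clipping plane, `list(point, normal)`
#'   in world mm (e.g. at the level of the tectum): the ablation segment
#'   is truncated to the target's side of this plane.
#' @return Object of class `ablation_params`.
#' @export
ablation_params <- function(diameter = 15, posterior_limit = NULL) {
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  if (diameter < 5 || diameter > 15)
    warning("ablation diameter outside the typical 5-15 mm range")
  if (!is.null(posterior_limit)) {
    if (!is.list(posterior_limit) ||
        length(posterior_limit$point) != 3L ||
        length(posterior_limit$normal) != 3L)
      stop("posterior_limit must be list(point=, normal=)", call. = FALSE)
  }
  structure(list(diameter = diameter, posterior_limit = posterior_limit),
            class = "ablation_params")
}

#' Ablated segment of a trajectory
#'
#' The cavity extends from the target (distal endpoint) proximally to
#' the most proximal trajectory point whose distance to the union of the
#' mesial ROIs (amygdala, hippocampus, entorhinal cortex, PHG) is at
#' most the capsule radius — i.e. the capsule is applied wherever it
#' touches the ROI complex — optionally clipped at a posterior limit
#' plane.
#'
#' @param traj A [trajectory()].
#' @param roi Either a `distance_field` of the ROI union or a
#'   `brain_mask` (converted internally).
#' @param params An [ablation_params()].
#' @param step Search step along the trajectory, mm.
#' @return List with `proximal`, `distal` (world mm) and
#'   `ablation_length` (mm).
#' @export
ablation_segment <- function(traj, roi, params = ablation_params(),
                             step = 0.25) {
  if (inherits(roi, "brain_mask")) roi <- distance_field(roi)
  radius <- params$diameter / 2
  n <- max(2L, ceiling(traj$length / step) + 1L)
  pts <- sample_nodes(traj, n)
  d <- sample_field(roi, pts)
  hit <- which(d <= radius)
  if (length(hit) == 0L)
    stop("trajectory never comes within the capsule radius of the ROI",
         call. = FALSE)
  t_prox <- (hit[1] - 1) / (n - 1)            # param of first touching point
  if (!is.null(params$posterior_limit)) {
    pl <- params$posterior_limit
    nrm <- pl$normal / sqrt(sum(pl$normal^2))
    # keep the target's side of the plane
    s_target <- sum((traj$target - pl$point) * nrm)
    keep_sign <- if (s_target >= 0) 1 else -1
    s_prox <- sum((pts[hit[1], ] - pl$point) * nrm) * keep_sign
    if (s_prox < 0) {
      # move proximal point up to the plane along the trajectory
      s_entry <- sum((traj$entry - pl$point) * nrm) * keep_sign
      s_tgt <- abs(s_target)
      denom <- s_tgt - s_entry
      t_plane <- if (abs(denom) < 1e-12) 1 else (0 - s_entry) / denom
      t_prox <- max(t_prox, min(1, t_plane))
    }
  }
  proximal <- traj$entry + t_prox * (traj$target - traj$entry)
  list(proximal = proximal, distal = traj$target,
       ablation_length = (1 - t_prox) * traj$length)
}

# minimum distance from points (n x 3) to segment [a, b]
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(pts, 2, a)
  t <- if (len2 < 1e-24) rep(0, nrow(pts)) else
    pmin(1, pmax(0, as.vector(rel %*% ab) / len2))
  dx <- rel - outer(t, ab)
  sqrt(rowSums(dx^2))
}

#' Voxelise a capsule around a segment
#'
#' A voxel is set iff its world centre lies within `radius` of the
#' segment (a cylinder with hemispherical caps; a sphere for a
#' zero-length segment).
#'
#' @param segment List with `proximal` and `distal` world-mm points (as
#'   from [ablation_segment()]), or a length-3 point for a sphere.
#' @param radius Capsule radius, mm (> 0).
#' @param grid A [label_volume()] or `brain_mask` supplying the grid
#'   geometry.
#' @return A `brain_mask` on the supplied grid.
#' @export
capsule_voxelize <- function(segment, radius, grid) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (is.numeric(segment) && length(segment) == 3L)
    segment <- list(proximal = segment, distal = segment)
  a <- as.numeric(segment$proximal); b <- as.numeric(segment$distal)
  dm <- if (inherits(grid, "label_volume")) dim(grid$labels)
        else dim(grid$mask)
  affine <- grid$affine
  out <- array(FALSE, dm)
  # bounding box in voxel space of the segment dilated by radius
  corners <- rbind(a, b)
  lo_w <- apply(corners, 2, min) - radius
  hi_w <- apply(corners, 2, max) + radius
  box <- world_to_voxel(affine, rbind(lo_w, hi_w,
                                      c(lo_w[1], hi_w[2], lo_w[3]),
                                      c(hi_w[1], lo_w[2], hi_w[3]),
                                      c(lo_w[1], lo_w[2], hi_w[3]),
                                      c(hi_w[1], hi_w[2], lo_w[3]),
                                      c(lo_w[1], hi_w[2], hi_w[3]),
                                      c(hi_w[1], lo_w[2], lo_w[3])))
  lo <- pmax(floor(apply(box, 2, min)) - 1, 0)
  hi <- pmin(ceiling(apply(box, 2, max)) + 1, dm - 1)
  if (any(hi < lo)) return(brain_mask(out, affine))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  ctrs <- voxel_to_world(affine, idx)
  inside <- point_segment_distance(ctrs, a, b) <= radius
  out[idx[inside, , drop = FALSE] + 1L] <- TRUE
  brain_mask(out, affine)
}

#' Per-structure ablation overlap statistics
#'
#' Intersects the voxelised cavity with each mesial structure and
#' reports overlap volume and percentage ablation (overlap normalised by
#' the structure's preoperative volume).
#'
#' @param capsule `brain_mask` of the ablation cavity.
#' @param structures Named list of `brain_mask`s on the same grid,
#'   typically the amygdala, hippocampus, entorhinal cortex and
#'   parahippocampal gyrus.
#' @param segment Optional segment (from [ablation_segment()]) recorded
#'   in the result.
#' @return Object of class `ablation_estimate` with `total_volume`
#'   (mm^3), `ablation_length` (mm, when a segment was given) and a
#'   per-structure data frame of `overlap_mm3` / `percent`.
#' @export
overlap_stats <- function(capsule, structures, segment = NULL) {
  vv <- prod(capsule$spacing)
  total <- sum(capsule$mask) * vv
  rows <- lapply(names(structures), function(nm) {
    s <- structures[[nm]]
    if (!identical(dim(s$mask), dim(capsule$mask)))
      stop("structure '", nm, "' is not on the capsule grid", call. = FALSE)
    vol <- volume_mm3(s)
    if (vol <= 0)
      stop("structure '", nm, "' has zero volume", call. = FALSE)
    ov <- sum(capsule$mask & s$mask) * vv
    data.frame(structure = nm, overlap_mm3 = ov,
               percent = 100 * ov / vol, structure_mm3 = vol)
  })
  structure(list(segment = segment,
                 ablation_length = if (!is.null(segment))
                   segment$ablation_length else NA_real_,
                 total_volume = total,
                 per_structure = do.call(rbind, rows)),
            class = "ablation_estimate")
}

#' @export
print.ablation_estimate <- function(x, ...) {
  cat(sprintf("<ablation_estimate> total %.0f mm^3", x$total_volume))
  if (!is.na(x$ablation_length))
    cat(sprintf(", length %.1f mm", x$ablation_length))
  cat("\n")
  for (i in seq_len(nrow(x$per_structure)))
    cat(sprintf("  %-22s %7.0f mm^3  (%5.1f%%)\n",
                x$per_structure$structure[i],
                x$per_structure$overlap_mm3[i],
                x$per_structure$percent[i]))
  invisible(x)
}

#' Full ablation estimate for a trajectory in a scene
#'
#' Convenience wrapper: derives the ablation segment from ROI proximity,
#' voxelises the capsule on the scene grid and computes overlap
#' statistics for the four mesial structures.
#'
#' @param traj A [trajectory()].
#' @param scene A [build_scene()] result.
#' @param params An [ablation_params()].
#' @return An `ablation_estimate`.
#' @export
estimate_ablation <- function(traj, scene, params = ablation_params()) {
  seg <- ablation_segment(traj, scene$fields$roi, params)
  capsule <- capsule_voxelize(seg, params$diameter / 2, scene$volume)
  est <- overlap_stats(capsule, scene$masks[ABLATION_ROLES], seg)
  est$capsule <- capsule
  est
}

#' Serialise an ablation estimate
#' @param x An `ablation_estimate`.
#' @param json_path,csv_path Optional output paths (JSON summary; one
#'   CSV row per structure).
#' @return The JSON string invisibly.
#' @export
ablation_estimate_json <- function(x, json_path = NULL, csv_path = NULL) {
  obj <- list(ablation_length = x$ablation_length,
              total_volume = x$total_volume,
              per_structure = x$per_structure)
  if (!is.null(json_path))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(x$per_structure, csv_path, row.names = FALSE)
  invisible(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}
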