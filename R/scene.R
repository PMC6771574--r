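#' Assemble a planning scene
#'
#' Resolves a role map against a labelled volume into the binary masks,
#' distance fields and derived geometry the planner needs: per-role
#' masks, Euclidean distance fields for vessels, sulci and brainstem, the
#' smoothed signed skull distance used for surface normals, the ROI-union
#' distance field used by the ablation model, and the mid-sagittal plane
#' position (x of the skull bounding-box midpoint) that defines "medial".
#'
#' @param vol A [label_volume()].
#' @param map A [role_map()]; validated against the volume.
#' @return Object of class `litt_scene`.
#' @export
build_scene <- function(vol, map) {
  validate_role_map(map, vol)
  masks <- lapply(ROLE_NAMES, function(r) extract_mask(vol, r, map))
  names(masks) <- ROLE_NAMES
  roi <- extract_mask(vol, ABLATION_ROLES, map)
  fields <- list(
    vessels = distance_field(masks$vessels),
    sulci = distance_field(masks$sulci),
    brainstem = distance_field(masks$brainstem),
    roi = distance_field(roi)
  )
  # the entry regions are labelled patches of the cranial shell; surface
  # geometry (normals, midline) uses the full shell
  shell_full <- brain_mask(masks$skull_shell$mask |
                             masks$entry_region_IOG$mask |
                             masks$entry_region_TOJ$mask, vol$affine)
  skull_sd <- skull_signed_distance(shell_full)
  idx <- mask_indices(shell_full$mask)
  w <- voxel_to_world(vol$affine, idx)
  midline_x <- (min(w[, 1]) + max(w[, 1])) / 2
  structure(list(volume = vol, map = map, side = map$side, masks = masks,
                 roi_union = roi, fields = fields, skull_sdist = skull_sd,
                 shell_full = shell_full, midline_x = midline_x),
            class = "litt_scene")
}

#' @export
print.litt_scene <- function(x, ...) {
  cat("<litt_scene> ", x$side, " hemisphere, grid ",
      paste(dim(x$volume$labels), collapse = " x "),
      ", midline x = ", signif(x$midline_x, 4), " mm\n", sep = "")
  vols <- vapply(x$masks[ABLATION_ROLES], volume_mm3, 1.0)
  for (r in ABLATION_ROLES)
    cat(sprintf("  %-22s %8.0f mm^3\n", r, vols[[r]]))
  invisible(x)
}
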