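#' @useDynLib littplan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Role names a StructureRoleMap must understand. Entry regions and the
# skull shell are planning scaffolding; the first four are ablation ROIs.
ROLE_NAMES <- c(
  "amygdala", "hippocampus", "parahippocampal_gyrus", "entorhinal_cortex",
  "lateral_ventricle", "brainstem", "sulci", "vessels",
  "entry_region_IOG", "entry_region_TOJ", "skull_shell"
)

ABLATION_ROLES <- c("amygdala", "hippocampus", "entorhinal_cortex",
                    "parahippocampal_gyrus")

#' Labelled brain volume
#'
#' A 3-D integer label grid with a voxel-to-world affine, the in-memory
#' form of a whole-brain parcellation. World space is RAS millimetres;
#' voxel indices are 0-based; a voxel occupies the closed cube centred on
#' the world image of its index.
#'
#' @param labels 3-D array of non-negative integers (label IDs).
#' @param affine 4x4 voxel-to-world transform (mm), 0-based voxel indices.
#' @return An object of class `label_volume` with fields `labels`, `affine`
#'   and `spacing` (per-axis voxel size in mm, column norms of the affine).
#' @export
label_volume <- function(labels, affine = diag(4)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3-D array", call. = FALSE)
  if (any(dim(labels) < 1L))
    stop("grid dimensions must all be >= 1", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE))
    stop("labels must be non-negative", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be 4x4", call. = FALSE)
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < 1e-12)
    stop("affine must be invertible", call. = FALSE)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0))
    stop("voxel spacing must be positive", call. = FALSE)
  structure(list(labels = labels, affine = affine, spacing = spacing),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", length(setdiff(unique(as.vector(x$labels)), 0L)),
      " labels\n", sep = "")
  invisible(x)
}

#' Read a labelled volume from NIfTI
#'
#' Data must be integer-valued (within 1e-6 of whole numbers). The affine
#' is taken from the image xform; spacing from its column norms.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  if (length(dim(dat)) > 3L) dat <- array(dat, dim = dim(dat)[1:3])
  rounded <- round(dat)
  if (max(abs(dat - rounded)) > 1e-6)
    stop("volume is not integer-labelled", call. = FALSE)
  affine <- structure(RNifti::xform(img), class = NULL)
  label_volume(array(as.integer(rounded), dim(rounded)),
               matrix(as.numeric(affine), 4, 4))
}

#' Write a labelled volume (or binary mask) to NIfTI
#'
#' @param vol A [label_volume()] or a mask from [extract_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  if (inherits(vol, "brain_mask"))
    vol <- label_volume(array(as.integer(vol$mask), dim(vol$mask)),
                        vol$affine)
  img <- RNifti::asNifti(vol$labels)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Structure role map
#'
#' Maps anatomical planning roles (amygdala, hippocampus, vessels, entry
#' regions, ...) to the label IDs that realise them in a given
#' parcellation, plus the hemisphere being planned. Label numbering is
#' parcellation-specific, so it is always supplied explicitly.
#'
#' @param roles Named list: role name -> integer vector of label IDs. All
#'   roles in `littplan:::ROLE_NAMES` must be present and non-empty.
#' @param side `"left"` or `"right"`.
#' @return An object of class `role_map`.
#' @export
role_map <- function(roles, side = c("left", "right")) {
  side <- match.arg(side)
  missing_roles <- setdiff(ROLE_NAMES, names(roles))
  if (length(missing_roles))
    stop("role map is missing roles: ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  roles <- lapply(roles[ROLE_NAMES], function(v) sort(unique(as.integer(v))))
  if (any(vapply(roles, length, 1L) == 0L))
    stop("every role must map to at least one label ID", call. = FALSE)
  # mesial ROIs must not share labels
  mtl <- roles[c("amygdala", "hippocampus", "parahippocampal_gyrus",
                 "entorhinal_cortex")]
  all_ids <- unlist(mtl)
  if (anyDuplicated(all_ids))
    stop("amygdala/hippocampus/PHG/entorhinal label sets must be disjoint",
         call. = FALSE)
  structure(list(roles = roles, side = side), class = "role_map")
}

#' Load a role map from YAML or JSON
#'
#' The document must hold a `side` field and a `roles` mapping from role
#' names to label-ID lists. When `volume` is given, every label ID is
#' checked to be present in the volume.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param volume Optional [label_volume()] to validate label IDs against.
#' @return A [role_map()].
#' @export
read_role_map <- function(path, volume = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(doc$roles) || is.null(doc$side))
    stop("role map document needs 'roles' and 'side' fields", call. = FALSE)
  map <- role_map(doc$roles, doc$side)
  if (!is.null(volume)) validate_role_map(map, volume)
  map
}

#' Write a role map to YAML
#' @param map A [role_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_role_map <- function(map, path) {
  yaml::write_yaml(list(side = map$side, roles = map$roles), path)
  invisible(path)
}

#' Check that every role's label IDs occur in a volume
#' @param map A [role_map()].
#' @param volume A [label_volume()].
#' @return `map`, invisibly; errors if a label ID is absent.
#' @export
validate_role_map <- function(map, volume) {
  present <- unique(as.vector(volume$labels))
  for (role in names(map$roles)) {
    absent <- setdiff(map$roles[[role]], present)
    if (length(absent))
      stop("role '", role, "' maps to label(s) absent from the volume: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  invisible(map)
}

#' Extract a binary mask for one or more roles
#'
#' @param vol A [label_volume()].
#' @param roles Character vector of role names (non-empty).
#' @param map A [role_map()].
#' @return An object of class `brain_mask`: logical array `mask` sharing
#'   the parent volume's `affine` and `spacing`.
#' @export
extract_mask <- function(vol, roles, map) {
  if (length(roles) == 0L)
    stop("at least one role must be requested", call. = FALSE)
  unknown <- setdiff(roles, names(map$roles))
  if (length(unknown))
    stop("unknown role(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  ids <- unlist(map$roles[roles], use.names = FALSE)
  brain_mask(array(vol$labels %in% ids, dim(vol$labels)), vol$affine)
}

#' Binary mask on a label grid
#' @param mask Logical 3-D array.
#' @param affine 4x4 voxel-to-world transform shared with the parent grid.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(mask, affine = diag(4)) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop("mask must be a 3-D array", call. = FALSE)
  storage.mode(mask) <- "logical"
  affine <- as.matrix(affine)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(mask = mask, affine = affine, spacing = spacing),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("<brain_mask> ", paste(dim(x$mask), collapse = " x "), " voxels, ",
      sum(x$mask), " set (", signif(volume_mm3(x), 6), " mm^3)\n", sep = "")
  invisible(x)
}

# world coordinates (n x 3, mm) of 0-based voxel indices (n x 3)
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  h <- cbind(ijk, 1)
  w <- h %*% t(affine)
  w[, 1:3, drop = FALSE]
}

# 0-based (fractional) voxel indices of world points (n x 3, mm)
world_to_voxel <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  h <- cbind(xyz, 1)
  v <- h %*% t(solve(affine))
  v[, 1:3, drop = FALSE]
}

# 0-based index triplets (n x 3) of TRUE voxels, in column-major order
mask_indices <- function(mask) {
  which(mask, arr.ind = TRUE) - 1L
}

#' Centroid of a mask in world millimetres
#'
#' Mean of the world coordinates of all true voxel centres.
#'
#' @param mask A `brain_mask`.
#' @return Numeric length-3 point (mm).
#' @export
centroid_mm <- function(mask) {
  idx <- mask_indices(mask$mask)
  if (nrow(idx) == 0L)
    stop("cannot take the centroid of an empty mask", call. = FALSE)
  colMeans(voxel_to_world(mask$affine, idx))
}

#' Volume of a mask in cubic millimetres
#'
#' Voxel count times voxel volume (product of spacings).
#'
#' @param mask A `brain_mask`.
#' @return Scalar volume (mm^3); 0 for an empty mask.
#' @export
volume_mm3 <- function(mask) {
  sum(mask$mask) * prod(mask$spacing)
}
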