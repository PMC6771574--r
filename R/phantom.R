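#' Phantom specification
#'
#' Parameters of the synthetic head scene used to exercise the planner
#' without patient data. Structure geometry is deterministic (so
#' ground-truth clearances are reproducible); the seed drives only the
#' stochastic vasculature and sulci. All positions are world mm relative
#' to the grid centre; the default grid is 128^3 at 1 mm isotropic.
#'
#' The anatomy is deliberately coarse but topologically faithful: an
#' ellipsoidal amygdala anterosuperior to a curved-tube hippocampus with
#' an anterior head bulge, a flattened parahippocampal sheet inferomedial
#' to it, a small entorhinal blob at its anterior end, a temporal-horn
#' ventricle superolateral to the hippocampus, a midline brainstem
#' cylinder, and a spherical skull shell carrying two labelled entry
#' patches (inferior occipital gyrus and temporo-occipital junction).
#' Vessels are seeded tortuous tubes concentrated in the two entry
#' approach cones, so that without the carved corridor almost no
#' trajectory is avascular.
#'
#' @param seed Integer seed for vessels and sulci.
#' @param dim Grid dimensions (default `c(128, 128, 128)`).
#' @param spacing Voxel size mm (default 1 mm isotropic).
#' @param side Hemisphere planned, `"left"` (default) or `"right"`.
#' @param corridor `"open"` (an avascular corridor of `corridor_radius`
#'   is carved from each entry patch centre to its target) or
#'   `"blocked"` (a vessel sheet seals both entry approaches).
#' @param corridor_radius Carve radius, mm (default 6).
#' @param n_vessels,vessel_radius,vessel_step,vessel_segments Vessel
#'   count, radius range (mm), random-walk step length (mm) and number
#'   of steps.
#' @param n_sulci Number of sulcal sheets.
#' @param entry_patch_radius Radius of each entry patch on the shell, mm.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, dim = c(128L, 128L, 128L),
                         spacing = c(1, 1, 1),
                         side = c("left", "right"),
                         corridor = c("open", "blocked"),
                         corridor_radius = 6,
                         n_vessels = 30L,
                         vessel_radius = c(1, 2),
                         vessel_step = 7, vessel_segments = 8L,
                         n_sulci = 8L,
                         entry_patch_radius = 10) {
  side <- match.arg(side)
  corridor <- match.arg(corridor)
  if (any(dim * spacing < 120))
    stop("grid must span at least 120 mm per axis to hold the head phantom",
         call. = FALSE)
  if (corridor_radius <= 0 || entry_patch_radius <= 0 ||
      any(vessel_radius <= 0))
    stop("radii must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), dim = as.integer(dim),
                 spacing = spacing, side = side, corridor = corridor,
                 corridor_radius = corridor_radius,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius = vessel_radius, vessel_step = vessel_step,
                 vessel_segments = as.integer(vessel_segments),
                 n_sulci = as.integer(n_sulci),
                 entry_patch_radius = entry_patch_radius),
            class = "phantom_spec")
}

# label numbering used by generated phantoms
PHANTOM_LABELS <- c(
  amygdala = 1L, hippocampus = 2L, parahippocampal_gyrus = 3L,
  entorhinal_cortex = 4L, lateral_ventricle = 5L, brainstem = 6L,
  sulci = 7L, vessels = 8L, skull_shell = 9L,
  entry_region_IOG = 10L, entry_region_TOJ = 11L
)

# deterministic structure geometry, as offsets (mm) from the grid centre;
# left-hemisphere convention, mirrored in x for the right
phantom_geometry <- function(spec) {
  C <- (spec$dim - 1) * spec$spacing / 2
  mirror <- if (spec$side == "right") -1 else 1
  off <- function(v) {
    m <- matrix(v, ncol = 3L, byrow = TRUE)
    m[, 1] <- m[, 1] * mirror
    sweep(m, 2, C, "+")
  }
  hippo_pts <- off(c(-17.5, 0.5, -10.5,
                     -20.5, -7.5, -13.5,
                     -23.5, -15.5, -16.5,
                     -26.5, -23.5, -18.5,
                     -28.5, -31.5, -20.5))
  shift <- function(pts, dv) sweep(pts, 2, c(mirror * dv[1], dv[2], dv[3]), "+")
  g <- list(
    centre = C,
    mirror = mirror,
    amygdala = list(centre = off(c(-21.5, 12.5, -3.5)),
                    semi = c(8, 7, 6.5)),
    hippo = list(pts = hippo_pts, head_radius = 6.5, tube_radius = 4.5),
    phg = list(pts = shift(hippo_pts[2:4, , drop = FALSE], c(5, 0, -9)),
               semi = c(5, 5, 3)),
    ec = list(centre = shift(hippo_pts[1, , drop = FALSE], c(5, 3, -10.5)),
              semi = c(6.5, 6, 4)),
    ventricle = list(pts = shift(hippo_pts[2:5, , drop = FALSE], c(-8, 0, 10)),
                     radius = 2.5),
    brainstem = list(xy = c(C[1], C[2] - 7.5),
                     radius = 8, z = C[3] + c(-45.5, 2.5)),
    skull = list(r_inner = 55.5, r_outer = 58.5, r_mid = 57),
    entry_dir = list(IOG = c(mirror * -0.05, -1, -0.45),
                     TOJ = c(mirror * -0.45, -1, -0.22))
  )
  g
}

# first intersection of ray p + t*d (t > 0) with sphere |x - c| = r
ray_sphere <- function(p, d, c, r) {
  d <- d / sqrt(sum(d^2))
  o <- p - c
  b <- sum(o * d)
  disc <- b^2 - (sum(o^2) - r^2)
  if (disc < 0) stop("ray misses sphere", call. = FALSE)
  t <- -b + sqrt(disc)
  p + t * d
}

# --- rasterization helpers (voxel centre tests over bounding boxes) ----

# world coords of voxel centres for an index range (0-based, inclusive)
box_grid <- function(lo, hi, spacing) {
  list(x = (lo[1]:hi[1]) * spacing[1],
       y = (lo[2]:hi[2]) * spacing[2],
       z = (lo[3]:hi[3]) * spacing[3],
       lo = lo, hi = hi)
}

world_box <- function(lo_w, hi_w, dim, spacing) {
  lo <- pmax(floor(lo_w / spacing), 0)
  hi <- pmin(ceiling(hi_w / spacing), dim - 1)
  if (any(hi < lo)) return(NULL)
  list(lo = lo, hi = hi)
}

# evaluate predicate(pts) on voxel centres in a world-mm bounding box and
# set labels[pred] <- label where labels currently satisfy `over`
paint <- function(labels, dim, spacing, lo_w, hi_w, predicate, label,
                  over = 0L) {
  bb <- world_box(lo_w, hi_w, dim, spacing)
  if (is.null(bb)) return(labels)
  ii <- bb$lo[1]:bb$hi[1]; jj <- bb$lo[2]:bb$hi[2]; kk <- bb$lo[3]:bb$hi[3]
  idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  pts <- sweep(idx, 2, spacing, "*")
  sel <- predicate(pts)
  if (!any(sel)) return(labels)
  sub <- idx[sel, , drop = FALSE] + 1L
  lin <- sub[, 1] + dim[1] * ((sub[, 2] - 1L) + dim[2] * (sub[, 3] - 1L))
  ok <- labels[lin] %in% over
  labels[lin[ok]] <- label
  labels
}

pred_ellipsoid <- function(centre, semi) {
  force(centre); force(semi)
  function(pts) {
    u <- sweep(pts, 2, as.numeric(centre))
    (u[, 1] / semi[1])^2 + (u[, 2] / semi[2])^2 + (u[, 3] / semi[3])^2 <= 1
  }
}

# min distance from points to a polyline (rows of P)
dist_polyline <- function(pts, P) {
  d <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(P) - 1L))
    d <- pmin(d, point_segment_distance(pts, P[s, ], P[s + 1L, ]))
  d
}

pred_tube <- function(P, radius, zscale = 1) {
  force(P); force(radius); force(zscale)
  Ps <- P; Ps[, 3] <- Ps[, 3] * zscale
  function(pts) {
    q <- pts; q[, 3] <- q[, 3] * zscale
    dist_polyline(q, Ps) <= radius
  }
}

pred_hippocampus <- function(g) {
  tube <- pred_tube(g$hippo$pts, g$hippo$tube_radius)
  head <- g$hippo$pts[1, ]
  r <- g$hippo$head_radius
  function(pts) {
    u <- sweep(pts, 2, head)
    tube(pts) | rowSums(u^2) <= r^2
  }
}

polyline_bbox <- function(P, pad) {
  list(lo = apply(P, 2, min) - pad, hi = apply(P, 2, max) + pad)
}

# numeric centroid/volume of a predicate by midpoint quadrature at `h` mm
quadrature_measure <- function(predicate, lo_w, hi_w, h = 0.5) {
  gx <- seq(lo_w[1], hi_w[1], by = h)
  gy <- seq(lo_w[2], hi_w[2], by = h)
  gz <- seq(lo_w[3], hi_w[3], by = h)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  sel <- predicate(pts)
  list(volume = sum(sel) * h^3, centroid = colMeans(pts[sel, , drop = FALSE]))
}

# --- generator ---------------------------------------------------------

#' Generate a synthetic head phantom
#'
#' Deterministic given the spec (same seed, byte-identical output).
#' Returns the labelled volume, its role map, an assembled planning
#' scene, and a ground-truth record holding the analytic structure
#' measurements (independent 0.5 mm quadrature of the generating
#' shapes), the target points, the corridor entry patches, and — for
#' open corridors — one pre-verified feasible trajectory per target
#' parameterisation.
#'
#' @param spec A [phantom_spec()].
#' @param verify For open corridors, check the ground-truth trajectories
#'   against the default constraints (default `TRUE`; errors if the
#'   construction fails its own guarantee).
#' @return Object of class `litt_phantom`: list with `volume`, `map`,
#'   `scene`, `truth`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(), verify = TRUE) {
  set.seed(spec$seed)
  g <- phantom_geometry(spec)
  dm <- spec$dim; sp <- spec$spacing
  C <- g$centre
  labels <- array(0L, dm)
  L <- PHANTOM_LABELS

  # mesial ROIs, ventricle, brainstem (priority order; no overwrites)
  am <- g$amygdala
  labels <- paint(labels, dm, sp, am$centre - am$semi, am$centre + am$semi,
                  pred_ellipsoid(am$centre, am$semi), L[["amygdala"]])
  hb <- polyline_bbox(g$hippo$pts, g$hippo$head_radius + 0.5)
  labels <- paint(labels, dm, sp, hb$lo, hb$hi, pred_hippocampus(g),
                  L[["hippocampus"]])
  ph <- g$phg
  phb <- polyline_bbox(ph$pts, max(ph$semi) + 0.5)
  labels <- paint(labels, dm, sp, phb$lo, phb$hi,
                  pred_tube(ph$pts, ph$semi[1], zscale = ph$semi[1] / ph$semi[3]),
                  L[["parahippocampal_gyrus"]])
  ec <- g$ec
  labels <- paint(labels, dm, sp, ec$centre - ec$semi, ec$centre + ec$semi,
                  pred_ellipsoid(ec$centre, ec$semi),
                  L[["entorhinal_cortex"]])
  vt <- g$ventricle
  vb <- polyline_bbox(vt$pts, vt$radius + 0.5)
  labels <- paint(labels, dm, sp, vb$lo, vb$hi, pred_tube(vt$pts, vt$radius),
                  L[["lateral_ventricle"]])
  bs <- g$brainstem
  pred_bs <- function(pts) {
    (pts[, 1] - bs$xy[1])^2 + (pts[, 2] - bs$xy[2])^2 <= bs$radius^2 &
      pts[, 3] >= bs$z[1] & pts[, 3] <= bs$z[2]
  }
  labels <- paint(labels, dm, sp,
                  c(bs$xy[1] - bs$radius, bs$xy[2] - bs$radius, bs$z[1]),
                  c(bs$xy[1] + bs$radius, bs$xy[2] + bs$radius, bs$z[2]),
                  pred_bs, L[["brainstem"]])

  # skull shell with entry patches
  sk <- g$skull
  pred_shell <- function(pts) {
    r <- sqrt(rowSums(sweep(pts, 2, C)^2))
    r >= sk$r_inner & r <= sk$r_outer
  }
  labels <- paint(labels, dm, sp, C - sk$r_outer - 1, C + sk$r_outer + 1,
                  pred_shell, L[["skull_shell"]])
  targets <- phantom_targets(g)
  e_iog <- ray_sphere(targets$centroid_T2, g$entry_dir$IOG, C, sk$r_mid)
  e_toj <- ray_sphere(targets$ml_T4, g$entry_dir$TOJ, C, sk$r_mid)
  patch <- function(centre) {
    force(centre)
    function(pts) rowSums(sweep(pts, 2, centre)^2) <= spec$entry_patch_radius^2
  }
  pr <- spec$entry_patch_radius + 1
  labels <- paint(labels, dm, sp, e_iog - pr, e_iog + pr, patch(e_iog),
                  L[["entry_region_IOG"]], over = L[["skull_shell"]])
  labels <- paint(labels, dm, sp, e_toj - pr, e_toj + pr, patch(e_toj),
                  L[["entry_region_TOJ"]], over = L[["skull_shell"]])

  # seeded sulcal sheets in the posterior cortex band
  for (s in seq_len(spec$n_sulci)) {
    dir <- c(stats::rnorm(1), -abs(stats::rnorm(1)), stats::rnorm(1))
    dir <- dir / sqrt(sum(dir^2))
    centre <- C + stats::runif(1, 42, 52) * dir
    rad <- dir
    t1 <- c(-rad[2], rad[1], 0); t1 <- t1 / sqrt(sum(t1^2))
    nrm <- t1  # sheet normal perpendicular to the radial direction
    ext <- 8; thick <- 1.2
    pred_sheet <- function(pts) {
      u <- sweep(pts, 2, centre)
      abs(u %*% nrm) <= thick & rowSums(u^2) <= ext^2
    }
    labels <- paint(labels, dm, sp, centre - ext, centre + ext,
                    pred_sheet, L[["sulci"]])
  }

  # seeded tortuous vessels concentrated in the two approach cones
  cone_dirs <- rbind(e_iog - C, e_toj - C)
  cone_dirs <- cone_dirs / sqrt(rowSums(cone_dirs^2))
  for (v in seq_len(spec$n_vessels)) {
    axis <- cone_dirs[1 + (v %% 2), ]
    # random direction within ~25 degrees of the cone axis
    repeat {
      d0 <- axis + 0.45 * stats::rnorm(3)
      d0 <- d0 / sqrt(sum(d0^2))
      if (sum(d0 * axis) > cos(25 * pi / 180)) break
    }
    start <- C + stats::runif(1, 30, 52) * d0
    rad <- stats::runif(1, spec$vessel_radius[1], spec$vessel_radius[2])
    step_dir <- stats::rnorm(3); step_dir <- step_dir / sqrt(sum(step_dir^2))
    P <- matrix(start, 1, 3)
    p <- start
    for (k in seq_len(spec$vessel_segments)) {
      step_dir <- 0.7 * step_dir + 0.6 * stats::rnorm(3)
      step_dir <- step_dir / sqrt(sum(step_dir^2))
      p2 <- p + spec$vessel_step * step_dir
      # stay inside the skull
      if (sqrt(sum((p2 - C)^2)) > sk$r_inner - 2)
        p2 <- C + (p2 - C) * (sk$r_inner - 2) / sqrt(sum((p2 - C)^2))
      P <- rbind(P, p2)
      p <- p2
    }
    vbb <- polyline_bbox(P, rad + 0.5)
    labels <- paint(labels, dm, sp, vbb$lo, vbb$hi, pred_tube(P, rad),
                    L[["vessels"]])
  }

  truth_traj <- list(
    centroid_T2 = list(entry = e_iog, target = targets$centroid_T2),
    expert_T3 = list(entry = e_iog, target = targets$expert_T3),
    ml_T4 = list(entry = e_toj, target = targets$ml_T4))

  if (spec$corridor == "open") {
    # carve the avascular corridors: strip vessels/sulci within
    # corridor_radius of each entry-centre -> target segment
    strip <- which(labels %in% c(L[["vessels"]], L[["sulci"]]))
    if (length(strip)) {
      idx <- arrayInd(strip, dm) - 1L
      pts <- sweep(idx, 2, sp, "*")
      near <- rep(FALSE, nrow(pts))
      for (tt in truth_traj)
        near <- near |
          point_segment_distance(pts, tt$entry, tt$target) <=
            spec$corridor_radius
      labels[strip[near]] <- 0L
    }
  } else {
    # seal both approaches with a vessel sheet just inside the skull
    pred_block <- function(pts) {
      u <- sweep(pts, 2, C)
      r <- sqrt(rowSums(u^2))
      ang_ok <- rep(FALSE, nrow(pts))
      for (i in 1:2)
        ang_ok <- ang_ok | (u %*% cone_dirs[i, ]) / pmax(r, 1e-9) >
          cos(22 * pi / 180)
      r >= sk$r_inner - 6 & r <= sk$r_inner - 3 & ang_ok
    }
    labels <- paint(labels, dm, sp, C - sk$r_inner, C + sk$r_inner,
                    pred_block, L[["vessels"]], over = c(0L, L[["sulci"]]))
  }

  affine <- diag(c(sp, 1))
  vol <- label_volume(labels, affine)
  map <- role_map(as.list(PHANTOM_LABELS), side = spec$side)
  scene <- build_scene(vol, map)

  # independent quadrature measurements of the generating shapes
  measures <- list(
    amygdala = c(quadrature_measure(pred_ellipsoid(am$centre, am$semi),
                                    am$centre - am$semi - 1,
                                    am$centre + am$semi + 1),
                 list(closed_form_volume = 4 / 3 * pi * prod(am$semi),
                      closed_form_centroid = as.numeric(am$centre))),
    hippocampus = quadrature_measure(pred_hippocampus(g),
                                     hb$lo - 0.5, hb$hi + 0.5),
    parahippocampal_gyrus = quadrature_measure(
      pred_tube(ph$pts, ph$semi[1], zscale = ph$semi[1] / ph$semi[3]),
      phb$lo - 0.5, phb$hi + 0.5),
    entorhinal_cortex = c(quadrature_measure(
      pred_ellipsoid(ec$centre, ec$semi),
      ec$centre - ec$semi - 1, ec$centre + ec$semi + 1),
      list(closed_form_volume = 4 / 3 * pi * prod(ec$semi))),
    brainstem = list(
      closed_form_volume = pi * bs$radius^2 * diff(bs$z),
      closed_form_centroid = c(bs$xy, mean(bs$z)))
  )

  # corridor mouth: scalp-facing entry voxels within the carve radius of
  # the corridor centre line
  entries_iog <- enumerate_entries(scene$masks$entry_region_IOG,
                                   scene$shell_full)
  entries_toj <- enumerate_entries(scene$masks$entry_region_TOJ,
                                   scene$shell_full)
  mouth <- function(entries, tt)
    entries[point_segment_distance(entries, tt$entry, tt$target) <=
              spec$corridor_radius, , drop = FALSE]
  corridor_patch <- list(
    centroid_T2 = mouth(entries_iog, truth_traj$centroid_T2),
    expert_T3 = mouth(entries_iog, truth_traj$expert_T3),
    ml_T4 = mouth(entries_toj, truth_traj$ml_T4))

  truth <- list(seed = spec$seed, side = spec$side,
                corridor = spec$corridor,
                targets = targets, entry_centres = list(IOG = e_iog,
                                                        TOJ = e_toj),
                corridor_radius = spec$corridor_radius,
                corridor_patch = corridor_patch,
                trajectories = truth_traj,
                structures = measures)

  if (verify && spec$corridor == "open") {
    for (nm in names(truth_traj)) {
      tt <- truth_traj[[nm]]
      viol <- check_feasibility(trajectory(tt$entry, tt$target), scene)
      if (nrow(viol) > 0L)
        stop("phantom construction failed its corridor guarantee (",
             nm, "): ", paste(viol$constraint, collapse = ", "),
             call. = FALSE)
    }
  }
  structure(list(volume = vol, map = map, scene = scene, truth = truth,
                 spec = spec),
            class = "litt_phantom")
}

#' @export
print.litt_phantom <- function(x, ...) {
  cat("<litt_phantom> seed ", x$spec$seed, ", ", x$spec$side,
      " hemisphere, corridor ", x$spec$corridor, "\n", sep = "")
  print(x$scene)
  invisible(x)
}

# target points implied by the deterministic geometry (world mm)
phantom_targets <- function(g) {
  ctr <- as.numeric(g$amygdala$centre)
  m <- g$mirror
  list(centroid_T2 = ctr,
       expert_T3 = ctr + c(m * 3, 3, -3),
       ml_T4 = ctr + c(m * 3, 3, 0))
}

#' Dilate the phantom's vessels
#'
#' Grows the vessel label into background by the given radius (other
#' labels are preserved), returning a regenerated phantom object with a
#' rebuilt scene. Supports monotonicity audits: dilation can only
#' decrease vessel distances, so any trajectory's risk score is
#' non-decreasing under it.
#'
#' @param phantom A `litt_phantom`.
#' @param dilation_mm Dilation radius, mm (>= 0).
#' @return A `litt_phantom` with dilated vessels.
#' @export
perturb_vessels <- function(phantom, dilation_mm) {
  if (dilation_mm < 0) stop("dilation must be >= 0", call. = FALSE)
  vol <- phantom$volume
  if (dilation_mm > 0) {
    vm <- phantom$scene$masks$vessels
    d <- edt3d_cpp(vm$mask, dim(vm$mask), vm$spacing)
    grow <- d <= dilation_mm & vol$labels == 0L
    labels <- vol$labels
    labels[grow] <- PHANTOM_LABELS[["vessels"]]
    vol <- label_volume(labels, vol$affine)
  }
  out <- phantom
  out$volume <- vol
  out$scene <- build_scene(vol, phantom$map)
  out
}

#' Write a phantom to disk
#'
#' NIfTI label volume, YAML role map and JSON ground truth.
#'
#' @param phantom A `litt_phantom`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named character vector of paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol_path <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  map_path <- file.path(dir, paste0(prefix, "_rolemap.yaml"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  write_label_volume(phantom$volume, vol_path)
  write_role_map(phantom$map, map_path)
  jsonlite::write_json(phantom$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(c(volume = vol_path, rolemap = map_path, truth = truth_path))
}
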