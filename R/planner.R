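#' Target parameterisation for an automated trajectory
#'
#' Three target definitions relative to the amygdala centroid:
#' `centroid_T2` targets the centroid itself; `expert_T3` (expert-derived
#' parameters) translates it 3 mm anterior, 3 mm medial and 3 mm
#' inferior; `ml_T4` (machine-learning-derived parameters) translates it
#' 3 mm anterior and 3 mm medial with no inferior component. Short
#' aliases `"centroid"`, `"expert"` and `"ml"` are accepted.
#'
#' @param method One of `"centroid_T2"`, `"expert_T3"`, `"ml_T4"`.
#' @return Object of class `target_spec` with the per-axis translation
#'   magnitudes (mm) in patient axes (anterior, medial, inferior).
#' @export
target_spec <- function(method = c("centroid_T2", "expert_T3", "ml_T4",
                                   "centroid", "expert", "ml")) {
  method <- match.arg(method)
  method <- switch(method, centroid = "centroid_T2", expert = "expert_T3",
                   ml = "ml_T4", method)
  shift <- switch(method,
    centroid_T2 = c(anterior = 0, medial = 0, inferior = 0),
    expert_T3 = c(anterior = 3, medial = 3, inferior = 3),
    ml_T4 = c(anterior = 3, medial = 3, inferior = 0))
  structure(list(method = method, shift_mm = shift), class = "target_spec")
}

# entry region role used by each target parameterisation
entry_role_for <- function(spec) {
  switch(spec$method,
         centroid_T2 = "entry_region_IOG",
         expert_T3 = "entry_region_IOG",
         ml_T4 = "entry_region_TOJ")
}

#' Compute the target point for a parameterisation
#'
#' Starts at the amygdala centroid and applies the spec's translation in
#' patient axes. In RAS world coordinates anterior is +y and inferior is
#' -z; medial is toward the mid-sagittal plane, so +x for the left
#' hemisphere and -x for the right.
#'
#' @param amygdala `brain_mask` of the amygdala.
#' @param spec A [target_spec()].
#' @param side `"left"` or `"right"`.
#' @return Length-3 target point (world mm).
#' @export
compute_target <- function(amygdala, spec, side = c("left", "right")) {
  side <- match.arg(side)
  ctr <- centroid_mm(amygdala)
  medial_sign <- if (side == "left") 1 else -1
  ctr + c(medial_sign * spec$shift_mm[["medial"]],
          spec$shift_mm[["anterior"]],
          -spec$shift_mm[["inferior"]])
}

#' Enumerate candidate entry points on an entry region's outer surface
#'
#' Returns world-mm centres of the entry region's scalp-facing surface
#' voxels: region voxels with at least one face neighbour outside the
#' filled head (skull shell plus region, cavities filled). Deterministic
#' lexicographic ordering by 0-based voxel index; `stride` keeps every
#' stride-th point.
#'
#' @param entry_mask `brain_mask` of the entry region (non-empty).
#' @param skull `brain_mask` of the skull shell (may be empty for
#'   free-standing test geometry).
#' @param stride Positive integer subsampling step (default 1).
#' @return n x 3 matrix of world-mm entry candidates.
#' @export
enumerate_entries <- function(entry_mask, skull, stride = 1L) {
  if (!any(entry_mask$mask))
    stop("entry region is empty", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  dm <- dim(entry_mask$mask)
  solid <- fill_holes_cpp(entry_mask$mask | skull$mask, dm)
  outside <- !solid
  pad <- function(a, shift, axis) {
    # neighbour lookup with out-of-grid treated as outside the head
    out <- array(TRUE, dm)
    n <- dm[axis]
    src <- seq_len(n) - shift
    ok <- src >= 1L & src <= n
    dst <- which(ok); src <- src[ok]
    idx_d <- switch(axis, list(dst, TRUE, TRUE), list(TRUE, dst, TRUE),
                    list(TRUE, TRUE, dst))
    idx_s <- switch(axis, list(src, TRUE, TRUE), list(TRUE, src, TRUE),
                    list(TRUE, TRUE, src))
    out <- do.call(`[<-`, c(list(out), idx_d,
                            list(do.call(`[`, c(list(a), idx_s)))))
    out
  }
  nb_outside <- pad(outside, 1L, 1L) | pad(outside, -1L, 1L) |
    pad(outside, 1L, 2L) | pad(outside, -1L, 2L) |
    pad(outside, 1L, 3L) | pad(outside, -1L, 3L)
  surf <- entry_mask$mask & nb_outside
  idx <- mask_indices(surf)
  if (nrow(idx) == 0L)
    stop("entry region has no scalp-facing surface voxels", call. = FALSE)
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  idx <- idx[seq(1L, nrow(idx), by = stride), , drop = FALSE]
  voxel_to_world(entry_mask$affine, idx)
}

#' Hard planning constraints
#'
#' Defaults follow standard LITT planning practice: maximum intracranial
#' length 120 mm (limits parenchymal transgression), drilling angle to
#' the skull normal at most 30 degrees (prevents skiving at the bone),
#' at least 3 mm clearance from critical structures (vessels and sulci),
#' at least 7 mm from the brainstem (limits heat transmission), and the
#' lateral ventricle as a strict no-entry zone. Comparisons are
#' inclusive at the bound.
#'
#' @param max_length Maximum trajectory length, mm.
#' @param max_drill_angle Maximum drilling angle, degrees, in (0, 90].
#' @param d_safe_critical Minimum clearance from vessels and sulci, mm.
#' @param d_min_brainstem Minimum clearance from the brainstem, mm.
#' @param no_entry_roles Roles whose masks the trajectory may not cross.
#' @param critical_roles Roles held at `d_safe_critical` clearance.
#' @param risk A [risk_params()].
#' @return Object of class `planning_constraints`.
#' @export
planning_constraints <- function(max_length = 120, max_drill_angle = 30,
                                 d_safe_critical = 3, d_min_brainstem = 7,
                                 no_entry_roles = "lateral_ventricle",
                                 critical_roles = c("vessels", "sulci",
                                                    "brainstem"),
                                 risk = risk_params()) {
  if (max_length <= 0 || d_safe_critical <= 0 || d_min_brainstem <= 0)
    stop("margins and lengths must be positive", call. = FALSE)
  if (!(max_drill_angle > 0 && max_drill_angle <= 90))
    stop("max_drill_angle must be in (0, 90]", call. = FALSE)
  structure(list(max_length = max_length,
                 max_drill_angle = max_drill_angle,
                 d_safe_critical = d_safe_critical,
                 d_min_brainstem = d_min_brainstem,
                 no_entry_roles = no_entry_roles,
                 critical_roles = critical_roles,
                 risk = risk),
            class = "planning_constraints")
}

#' Check a trajectory against all hard constraints
#'
#' Evaluates every constraint (not first-fail) and returns the full list
#' of violations: maximum length, drilling angle, no-entry intersection,
#' vessel clearance, sulcal clearance, brainstem clearance.
#'
#' @param traj A [trajectory()].
#' @param scene A [build_scene()] result.
#' @param constraints A [planning_constraints()].
#' @return Data frame with columns `constraint`, `value`, `limit`; zero
#'   rows when the trajectory is feasible.
#' @export
check_feasibility <- function(traj, scene, constraints = planning_constraints()) {
  needed <- c(constraints$no_entry_roles, "vessels", "sulci", "brainstem")
  missing_m <- setdiff(needed, names(scene$masks))
  if (length(missing_m))
    stop("scene lacks masks for: ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  v <- list()
  add <- function(name, value, limit)
    v[[length(v) + 1L]] <<- data.frame(constraint = name, value = value,
                                       limit = limit)
  if (traj$length > constraints$max_length)
    add("max_length", traj$length, constraints$max_length)
  # an entry too far off the scalp has no skull normal; that is itself a
  # violation (manual trajectories may supply such points)
  ang <- tryCatch(
    drilling_angle(traj, skull_normal(scene$skull_sdist, traj$entry)),
    error = function(e) NA_real_)
  if (is.na(ang))
    add("entry_off_scalp", NA_real_, 2 * max(scene$volume$spacing))
  else if (ang > constraints$max_drill_angle)
    add("max_drill_angle", ang, constraints$max_drill_angle)
  for (role in constraints$no_entry_roles)
    if (segment_intersects_exact(scene$masks[[role]], traj))
      add(paste0("no_entry:", role), 1, 0)
  n <- constraints$risk$n_nodes
  d_ves <- min_distance_along(traj, scene$fields$vessels, n)
  if (d_ves < constraints$d_safe_critical)
    add("d_min_vessels", d_ves, constraints$d_safe_critical)
  d_sul <- min_distance_along(traj, scene$fields$sulci, n)
  if (d_sul < constraints$d_safe_critical)
    add("d_min_sulci", d_sul, constraints$d_safe_critical)
  d_bs <- min_distance_along(traj, scene$fields$brainstem, n)
  if (d_bs < constraints$d_min_brainstem)
    add("d_min_brainstem", d_bs, constraints$d_min_brainstem)
  if (length(v)) do.call(rbind, v)
  else data.frame(constraint = character(), value = numeric(),
                  limit = numeric())
}

#' Plan automated trajectories for one target parameterisation
#'
#' Fixes the target point from the parameterisation, enumerates every
#' candidate entry on the matching entry region's outer surface, drops
#' candidates violating any hard constraint, and ranks the feasible rest
#' by ascending risk score, then descending combined amygdala +
#' hippocampus ablation percentage, then ascending length (final ties by
#' entry enumeration order). Deterministic: no randomness anywhere.
#'
#' @param scene A [build_scene()] result.
#' @param constraints A [planning_constraints()].
#' @param spec A [target_spec()].
#' @param k Number of top plans to return (default 1).
#' @param stride Entry-surface subsampling stride (default 1).
#' @param ablation A [ablation_params()] used for metric records.
#' @return Object of class `litt_plan`: list with the ranked `plans`
#'   (each holding trajectory, risk profile, metrics record, violations)
#'   and a `table` of per-candidate metrics. Zero plans (not an error)
#'   when nothing is feasible.
#' @export
plan_trajectories <- function(scene, constraints = planning_constraints(),
                              spec = target_spec("centroid_T2"), k = 1L,
                              stride = 1L, ablation = ablation_params()) {
  target <- compute_target(scene$masks$amygdala, spec, scene$side)
  entry_role <- entry_role_for(spec)
  entries <- enumerate_entries(scene$masks[[entry_role]],
                               scene$shell_full, stride)
  cand <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    traj <- trajectory(entries[i, ], target)
    viol <- check_feasibility(traj, scene, constraints)
    if (nrow(viol) > 0L) next
    rp <- risk_score(traj, scene$fields$vessels, constraints$risk)
    cand[[i]] <- list(index = i, trajectory = traj, risk = rp,
                      violations = viol)
  }
  cand <- Filter(Negate(is.null), cand)
  if (length(cand) == 0L) {
    return(structure(list(method = spec$method, target = target,
                          n_candidates = nrow(entries), plans = list(),
                          table = NULL),
                     class = "litt_plan"))
  }
  scores <- vapply(cand, function(p) p$risk$score, 1.0)
  ord <- order(scores)
  cand <- cand[ord]; scores <- scores[ord]
  # ablation metrics are needed only where risk ties could cross the
  # top-k boundary; compute for the top-k plus any candidates tied (to
  # 1e-12) with the k-th score
  k <- min(k, length(cand))
  cut <- scores[k]
  sel <- which(scores <= cut + 1e-12)
  for (i in sel) {
    p <- cand[[i]]
    cand[[i]]$metrics <- evaluate_trajectory(
      scene, p$trajectory$entry, p$trajectory$target,
      constraints = constraints, ablation = ablation,
      method = spec$method)
  }
  key_abl <- vapply(cand[sel], function(p)
    p$metrics$pct_amygdala + p$metrics$pct_hippocampus, 1.0)
  key_len <- vapply(cand[sel], function(p) p$trajectory$length, 1.0)
  key_idx <- vapply(cand[sel], function(p) p$index, 1L)
  ord2 <- order(scores[sel], -key_abl, key_len, key_idx)
  cand <- c(cand[sel][ord2], cand[setdiff(seq_along(cand), sel)])
  plans <- cand[seq_len(k)]
  tab <- do.call(rbind, lapply(plans, function(p) p$metrics))
  structure(list(method = spec$method, target = target,
                 n_candidates = nrow(entries), plans = plans, table = tab),
            class = "litt_plan")
}

#' @export
print.litt_plan <- function(x, ...) {
  cat("<litt_plan> method ", x$method, ": ", length(x$plans),
      " feasible plan(s) of ", x$n_candidates, " entry candidates\n",
      sep = "")
  if (length(x$plans)) {
    p <- x$plans[[1]]
    cat(sprintf(
      "  rank 1: length %.1f mm, angle %.1f deg, risk %.3f, amygdala %.1f%%, hippocampus %.1f%%\n",
      p$metrics$length_mm, p$metrics$angle_deg, p$metrics$risk_score,
      p$metrics$pct_amygdala, p$metrics$pct_hippocampus))
  }
  invisible(x)
}

#' Write a ranked plan to JSON and CSV
#'
#' @param x A `litt_plan`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default the method label).
#' @return Paths written, invisibly.
#' @export
write_plan <- function(x, dir, prefix = x$method) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(prefix, "_plans.json"))
  obj <- lapply(x$plans, function(p) list(
    entry = p$trajectory$entry, target = p$trajectory$target,
    length_mm = p$trajectory$length, risk_score = p$risk$score,
    violations = p$violations,
    metrics = as.list(p$metrics)))
  jsonlite::write_json(list(method = x$method, target = x$target,
                            plans = obj),
                       json_path, auto_unbox = TRUE, digits = NA)
  paths <- json_path
  if (!is.null(x$table)) {
    csv_path <- file.path(dir, paste0(prefix, "_metrics.csv"))
    utils::write.csv(x$table, csv_path, row.names = FALSE)
    paths <- c(paths, csv_path)
  }
  invisible(paths)
}
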