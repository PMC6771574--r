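#' Evaluate a trajectory into a full metrics record
#'
#' Computes the same per-trajectory metrics the planner stores for its
#' own candidates — length, drilling angle, risk score, brainstem
#' clearance, ablation length/volume and per-structure ablation
#' percentages — for an arbitrary entry/target pair, e.g. a manually
#' planned trajectory reconstructed from its entry and target points.
#' Constraint violations are reported in an attribute but are not fatal:
#' manual trajectories may violate them.
#'
#' @param scene A [build_scene()] result.
#' @param entry,target World-mm points; must lie within the scene grid.
#' @param constraints A [planning_constraints()].
#' @param ablation An [ablation_params()].
#' @param method Label recorded in the `method` column (e.g.
#'   `"manual_1"`).
#' @return One-row data frame (class `litt_metrics`) with columns
#'   `method`, `length_mm`, `angle_deg`, `risk_score`,
#'   `brainstem_mm`, `ablation_length_mm`, `ablation_mm3`,
#'   `pct_amygdala`, `pct_hippocampus`, `pct_entorhinal`, `pct_phg`,
#'   `n_violations`; the violation table is in
#'   `attr(, "violations")`.
#' @export
evaluate_trajectory <- function(scene, entry, target,
                                constraints = planning_constraints(),
                                ablation = ablation_params(),
                                method = "manual_1") {
  dm <- dim(scene$volume$labels)
  for (p in list(entry = entry, target = target)) {
    v <- world_to_voxel(scene$volume$affine, p)
    if (any(v < -0.5) || any(v > dm - 0.5))
      stop("point outside the scene grid: ",
           paste(signif(p, 4), collapse = ", "), call. = FALSE)
  }
  traj <- trajectory(entry, target)
  viol <- check_feasibility(traj, scene, constraints)
  rp <- risk_score(traj, scene$fields$vessels, constraints$risk)
  ang <- tryCatch(
    drilling_angle(traj, skull_normal(scene$skull_sdist, traj$entry)),
    error = function(e) NA_real_)   # off-scalp manual entry: no normal
  d_bs <- min_distance_along(traj, scene$fields$brainstem,
                             constraints$risk$n_nodes)
  est <- estimate_ablation(traj, scene, ablation)
  pct <- function(role) {
    i <- match(role, est$per_structure$structure)
    est$per_structure$percent[i]
  }
  rec <- data.frame(
    method = method,
    length_mm = traj$length,
    angle_deg = ang,
    risk_score = rp$score,
    brainstem_mm = d_bs,
    ablation_length_mm = est$ablation_length,
    ablation_mm3 = est$total_volume,
    pct_amygdala = pct("amygdala"),
    pct_hippocampus = pct("hippocampus"),
    pct_entorhinal = pct("entorhinal_cortex"),
    pct_phg = pct("parahippocampal_gyrus"),
    n_violations = nrow(viol),
    stringsAsFactors = FALSE)
  attr(rec, "violations") <- viol
  class(rec) <- c("litt_metrics", "data.frame")
  rec
}

#' Write / read metrics tables
#'
#' Plain CSV, one record per (case, method); a re-read table equals the
#' in-memory one.
#'
#' @param records Data frame of metrics records.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_metrics <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Compare trajectory-generation methods on one metric
#'
#' Convenience cohort summary: per-method mean and SD, one-way ANOVA F
#' and p, and all pairwise mean differences with Bonferroni-adjusted
#' equal-variance two-sample t-test p-values (`p_adj = min(1, m * p)`
#' over the m pairs).
#'
#' @param records Data frame with a `method` column and the metric
#'   column; at least two methods with at least two cases each.
#' @param metric Name of the metric column.
#' @return Object of class `litt_comparison`.
#' @export
compare_methods <- function(records, metric) {
  records <- as.data.frame(records)
  if (!metric %in% names(records))
    stop("no column '", metric, "' in records", call. = FALSE)
  grp <- factor(records$method)
  y <- records[[metric]]
  if (nlevels(grp) < 2L)
    stop("need at least 2 methods to compare", call. = FALSE)
  if (any(table(grp) < 2L))
    stop("need at least 2 cases per method", call. = FALSE)
  groups <- data.frame(
    method = levels(grp),
    n = as.integer(table(grp)),
    mean = as.numeric(tapply(y, grp, mean)),
    sd = as.numeric(tapply(y, grp, stats::sd)))
  fit <- stats::lm(y ~ grp)
  av <- stats::anova(fit)
  lev <- levels(grp)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  pw <- lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ya <- y[grp == a]; yb <- y[grp == b]
    p_raw <- if (stats::sd(c(ya - mean(ya), yb - mean(yb))) == 0) {
      if (mean(ya) == mean(yb)) 1 else 0
    } else stats::t.test(ya, yb, var.equal = TRUE)$p.value
    data.frame(group1 = a, group2 = b,
               mean_diff = mean(ya) - mean(yb),
               p = p_raw, p_adj = min(1, m * p_raw))
  })
  structure(list(metric = metric, groups = groups,
                 anova_F = av$`F value`[1], anova_p = av$`Pr(>F)`[1],
                 pairwise = do.call(rbind, pw)),
            class = "litt_comparison")
}

#' @export
print.litt_comparison <- function(x, ...) {
  cat("<litt_comparison> metric:", x$metric, "\n")
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %-14s n=%-3d mean %8.3f  sd %7.3f\n",
                x$groups$method[i], x$groups$n[i], x$groups$mean[i],
                x$groups$sd[i]))
  cat(sprintf("  one-way ANOVA: F = %.3f, p = %.4g\n", x$anova_F,
              x$anova_p))
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("  %s vs %s: diff %8.3f, p_adj %.4g\n",
                x$pairwise$group1[i], x$pairwise$group2[i],
                x$pairwise$mean_diff[i], x$pairwise$p_adj[i]))
  invisible(x)
}
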