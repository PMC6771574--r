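#' Risk-score parameters
#'
#' The avascular-corridor risk score samples the trajectory at a fixed
#' number of nodes and converts each node's distance to the nearest
#' vessel into a unitless risk. The per-node risk is normalised so that
#' it equals 1 exactly at the safety margin `d_safe` and exceeds 1
#' wherever the vessel distance falls below the margin; beyond `d_max`
#' a vessel contributes no risk.
#'
#' @param n_nodes Number of nodes sampled along the trajectory
#'   (default 128; independent of trajectory length, so longer paths do
#'   not accrue more risk).
#' @param d_safe Safety margin in mm (default 3).
#' @param d_max Outer risk-zone radius in mm (default 10): distance at
#'   which per-node risk reaches 0.
#' @param aggregate `"mean"` (default) or `"max"` across nodes.
#' @return Object of class `risk_params`.
#' @export
risk_params <- function(n_nodes = 128L, d_safe = 3, d_max = 10,
                        aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (n_nodes < 2L) stop("n_nodes must be >= 2", call. = FALSE)
  if (!(d_safe > 0 && d_safe < d_max))
    stop("need 0 < d_safe < d_max", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), d_safe = d_safe,
                 d_max = d_max, aggregate = aggregate),
            class = "risk_params")
}

#' Per-node risk of a vessel distance
#'
#' Linear in distance: `r(d) = (d_max - min(d, d_max)) / (d_max - d_safe)`,
#' so `r(d_max) = 0`, `r(d_safe) = 1`, and `r(0) = d_max / (d_max - d_safe)`;
#' continuous and non-increasing. Values above 1 flag nodes inside the
#' safety margin.
#'
#' @param d Vessel distance(s) in mm, non-negative.
#' @param params A [risk_params()].
#' @return Unitless risk value(s), same length as `d`.
#' @export
node_risk <- function(d, params = risk_params()) {
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  (params$d_max - pmin(d, params$d_max)) / (params$d_max - params$d_safe)
}

#' Avascular-corridor risk score of a trajectory
#'
#' Samples the vessel distance field at `n_nodes` equally spaced nodes
#' (entry and target inclusive), applies [node_risk()] at each node, and
#' aggregates (mean by default) into a single score. A score above 1
#' indicates that the corridor narrows below the safety margin.
#'
#' @param traj A [trajectory()].
#' @param vessels A `distance_field` of the vasculature mask.
#' @param params A [risk_params()].
#' @return Object of class `risk_profile` with `node_distances`,
#'   `node_risks`, `score` and the parameters used.
#' @export
risk_score <- function(traj, vessels, params = risk_params()) {
  nodes <- sample_nodes(traj, params$n_nodes)
  d <- sample_field(vessels, nodes)
  r <- node_risk(d, params)
  score <- if (params$aggregate == "mean") mean(r) else max(r)
  structure(list(node_distances = d, node_risks = r, score = score,
                 params = params),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf(
    "<risk_profile> score %.3f (%s of %d nodes); min vessel distance %.2f mm\n",
    x$score, x$params$aggregate, x$params$n_nodes, min(x$node_distances)))
  invisible(x)
}

#' Serialise a risk profile to JSON
#' @param x A `risk_profile`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
risk_profile_json <- function(x, path = NULL) {
  obj <- list(score = x$score,
              node_distances = x$node_distances,
              node_risks = x$node_risks,
              params = unclass(x$params))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
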