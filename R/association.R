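#' Univariable linear regression (closed form)
#'
#' Ordinary least squares fit of `y = a + b x` via the normal equations, with
#' the usual t test on the slope. Implemented in closed form so the
#' regression used throughout the backbone--behavior analysis has an exact,
#' dependency-free definition.
#'
#' @param x predictor values (a backbone metric), length >= 3, not constant.
#' @param y outcome values (deficit score or lesion volume), same length.
#' @return data.frame with slope, intercept, slope standard error, t,
#'   two-sided p, R-squared and n.
#' @export
univariable_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("regression needs at least 3 observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= .Machine$double.eps * max(1, mean(x)^2) * n) {
    stop("predictor is constant; slope is unidentifiable")
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- syy - slope * sxy
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  t <- slope / se
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  r2 <- if (syy > 0) 1 - rss / syy else NA_real_
  data.frame(slope = slope, intercept = intercept, se = se, t = t, p = p,
             r_squared = r2, n = n)
}

#' Screen backbone metrics against outcomes
#'
#' One univariable regression per (metric, scope) pair of the backbone metric
#' table against the deficit score, and per metric against lesion volume,
#' over stroke subjects only (outcome variables are undefined for controls).
#' Raw p-values are reported; optionally Benjamini-Hochberg adjusted p-values
#' are appended (off by default, mirroring a raw-p analysis).
#'
#' @param metric_table result of [backbone_metric_table()] (its `network`
#'   component is used), or that component directly.
#' @param records data.frame with subject, group, deficit_score,
#'   lesion_volume (see [make_deficit_scores()]).
#' @param scopes network scopes to screen.
#' @param adjust if TRUE, append BH-adjusted p-values per outcome.
#' @return data.frame of regression results with metric, scope and outcome
#'   columns.
#' @export
metric_outcome_screen <- function(metric_table, records,
                                  scopes = c("total", "sensorimotor"),
                                  adjust = FALSE) {
  tab <- if (is.data.frame(metric_table)) metric_table else metric_table$network
  stroke <- records[records$group == "stroke", ]
  if (nrow(stroke) < 3L) stop("need at least 3 stroke subjects")
  metrics <- c("n_leaf", "diameter", "mean_eccentricity", "kappa",
               "mean_betweenness", "mean_strength")
  out <- list()
  for (scope in scopes) {
    sub <- tab[tab$scope == scope & tab$subject %in% stroke$subject, ]
    ord <- match(sub$subject, stroke$subject)
    for (metric in metrics) {
      for (outcome in c("deficit_score", "lesion_volume")) {
        res <- univariable_regression(sub[[metric]], stroke[[outcome]][ord])
        out[[length(out) + 1L]] <-
          cbind(data.frame(metric = metric, scope = scope, outcome = outcome),
                res)
      }
    }
  }
  out <- do.call(rbind, out)
  if (adjust) {
    out$p_adjusted <- stats::ave(out$p, out$outcome,
                                 FUN = function(p) stats::p.adjust(p, "BH"))
  }
  out
}

#' Rank nodes by a backbone metric per group
#'
#' Per node and group, the mean and standard deviation of a nodal MST metric,
#' ordered by descending control-group mean (the standard presentation for
#' node strength / betweenness rankings), with sensorimotor nodes flagged.
#'
#' @param nodal_table the `nodal` component of [backbone_metric_table()].
#' @param metric "strength" or "betweenness".
#' @param scope network scope to rank within.
#' @param regions region table (for the sensorimotor flag).
#' @return data.frame: node, sensorimotor, control_mean, control_sd,
#'   stroke_mean, stroke_sd, control_rank, stroke_rank (rank 1 = highest
#'   group mean).
#' @export
rank_nodal_metric <- function(nodal_table, metric = c("strength",
                                                      "betweenness"),
                              scope = "total", regions = region_table()) {
  metric <- match.arg(metric)
  tab <- nodal_table[nodal_table$scope == scope, ]
  stopifnot(nrow(tab) > 0)
  agg <- function(group, fun) {
    sub <- tab[tab$group == group, ]
    out <- tapply(sub[[metric]], sub$node, fun)
    out[match(unique(tab$node), names(out))]
  }
  nodes <- unique(tab$node)
  res <- data.frame(
    node = nodes,
    sensorimotor = regions$sensorimotor[match(nodes, regions$name)],
    control_mean = as.numeric(agg("control", mean)),
    control_sd = as.numeric(agg("control", stats::sd)),
    stroke_mean = as.numeric(agg("stroke", mean)),
    stroke_sd = as.numeric(agg("stroke", stats::sd))
  )
  res$control_rank <- rank(-res$control_mean, ties.method = "average")
  res$stroke_rank <- rank(-res$stroke_mean, ties.method = "average")
  res[order(res$control_rank), ]
}
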