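# Weighting and aggregation of normalized endpoint groups into the single
# cumulative impact C = sum(W x R), with either fixed EPI weights
# (health 0.4, ecosystem 0.6) or data-driven entropy weights in which the
# group with more interannual dispersion receives the larger weight.

#' Endpoint group weights
#'
#' @param health,ecosystem weights in `[0, 1]`, summing to 1
#' @param method one of `"user"`, `"EPI"`, `"entropy"`
#' @return an `impact_weights` object (named numeric of length 2)
#' @export
impact_weights <- function(health, ecosystem, method = "user") {
  check_num(health, "health"); check_num(ecosystem, "ecosystem")
  if (health < 0 || health > 1 || ecosystem < 0 || ecosystem > 1)
    stop_validation("weights must lie in [0, 1]")
  if (abs(health + ecosystem - 1) > 1e-9)
    stop_validation("weights must sum to 1 (got %.6g)", health + ecosystem)
  structure(c(health = health, ecosystem = ecosystem),
            method = method, class = "impact_weights")
}

#' @export
print.impact_weights <- function(x, ...) {
  cat(sprintf("<impact_weights [%s]> health = %.3g, ecosystem = %.3g\n",
              attr(x, "method"), x[["health"]], x[["ecosystem"]]))
  invisible(x)
}

#' Fixed EPI weights (health 0.4, ecosystem 0.6)
#' @return an [impact_weights()] object
#' @export
epi_weights <- function() impact_weights(0.4, 0.6, method = "EPI")

#' Aggregate normalized endpoint groups into a cumulative impact
#'
#' `C = w_health * r_health + w_ecosystem * r_ecosystem`, the annual
#' environmental damage per person.
#'
#' @param r_health,r_ecosystem normalized endpoint group scores
#'   (dimensionless per person); vectorized
#' @param weights an [impact_weights()] object
#' @return cumulative impact C (same length as the inputs)
#' @export
aggregate_impact <- function(r_health, r_ecosystem, weights = epi_weights()) {
  if (!inherits(weights, "impact_weights"))
    weights <- impact_weights(weights[["health"]], weights[["ecosystem"]])
  check_num(r_health, "r_health"); check_num(r_ecosystem, "r_ecosystem")
  weights[["health"]] * r_health + weights[["ecosystem"]] * r_ecosystem
}

#' Entropy weights from per-year endpoint series
#'
#' Standard entropy-weight procedure on a years-by-groups matrix of
#' non-negative scores: each group's values are normalized to shares
#' `p_z = R_z / sum(R)`; the entropy `e = -(1/ln t) * sum(p_z ln p_z)`
#' (with `0 ln 0 := 0`) measures how evenly the series is spread over the
#' years; the divergence `d = 1 - e` rewards dispersion; weights are
#' `d / sum(d)`. A constant series has maximal entropy and receives zero
#' weight; when every group is constant the groups are indistinguishable
#' and equal weights are returned.
#'
#' @param series numeric matrix or data frame, rows = years (t >= 2),
#'   columns = endpoint groups; column names are preserved in the result.
#' @return named weights summing to 1, with attributes `entropy` and
#'   `divergence`; when the columns are named `health` and `ecosystem`
#'   the result is an [impact_weights()] object.
#' @export
entropy_weights <- function(series) {
  x <- as.matrix(series)
  t <- nrow(x)
  if (t < 2) stop_domain("entropy weighting needs at least 2 years (got %d)", t)
  if (any(x < 0)) stop_domain("entropy weighting needs non-negative values")
  cs <- colSums(x)
  if (any(cs == 0)) {
    nm <- colnames(x)[which(cs == 0)[1]] %||% as.character(which(cs == 0)[1])
    stop_domain("group '%s' is all zero: entropy weight undefined", nm)
  }
  p <- sweep(x, 2, cs, "/")
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -colSums(plogp) / log(t)
  # a constant series gives e = 1 exactly in theory; clamp the tiny
  # negative divergence floating-point summation can leave behind
  d <- pmax(0, 1 - e)
  w <- if (sum(d) > 0) d / sum(d) else rep(1 / ncol(x), ncol(x))
  names(w) <- colnames(x)
  out <- structure(w, entropy = e, divergence = d)
  if (setequal(names(w), c("health", "ecosystem"))) {
    iw <- impact_weights(w[["health"]], w[["ecosystem"]], method = "entropy")
    attr(iw, "entropy") <- e
    attr(iw, "divergence") <- d
    return(iw)
  }
  out
}

#' Literal entropy expression (diagnostic)
#'
#' Evaluates `-(1/ln t) * sum(R ln R)` on the raw (not share-normalized)
#' series of each group, with `0 ln 0 := 0`. This is the bare entropy
#' expression without the share normalization and divergence steps of the
#' full procedure in [entropy_weights()]; on its own it does not produce
#' weights that sum to 1 and is provided for comparison only.
#'
#' @inheritParams entropy_weights
#' @return named numeric, one value per group
#' @export
entropy_literal <- function(series) {
  x <- as.matrix(series)
  t <- nrow(x)
  if (t < 2) stop_domain("needs at least 2 years (got %d)", t)
  if (any(x < 0)) stop_domain("needs non-negative values")
  xlogx <- ifelse(x > 0, x * log(x), 0)
  -colSums(xlogx) / log(t)
}
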