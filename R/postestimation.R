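#' Marginal choice probabilities
#'
#' Converts utilities to the probability scale as the logit share over the
#' full item universe: \eqn{MP(i) = e^{\gamma(i)} / \sum_j e^{\gamma(j)}}
#' across all \eqn{v} items. This is the model-implied probability that item
#' \eqn{i} would be picked as most important were every item offered at once;
#' it preserves the utility ranking and is invariant to recentring the
#' utilities. When only \eqn{v - 1} utilities are supplied (the free
#' parameters of a sum-to-zero fit with the baseline dropped), the missing
#' baseline is reconstructed as minus their sum.
#'
#' @param utilities a fitted [maxdiff()] model or a numeric vector of
#'   utilities; a vector of length v, or of length v - 1 with
#'   `baseline` naming the omitted item.
#' @param baseline label for the reconstructed baseline item when
#'   `utilities` has one value fewer than the item universe.
#' @return Named probability vector summing to 1.
#' @examples
#' marginal_probabilities(c(a = 0.5, b = 0, c = -0.5))
#' @export
marginal_probabilities <- function(utilities, baseline = NULL) {
  if (inherits(utilities, "maxdiff")) utilities <- utilities$coefficients
  if (!is.numeric(utilities) || any(!is.finite(utilities))) {
    stop("'utilities' must be a finite numeric vector")
  }
  if (!is.null(baseline)) {
    utilities <- c(utilities, structure(-sum(utilities), names = baseline))
  }
  e <- exp(utilities - max(utilities))
  e / sum(e)
}

#' All pairwise utility-difference contrasts
#'
#' For every ordered pair of items computes the estimated utility difference
#' \eqn{DUE(i, j) = \gamma(i) - \gamma(j)}, its standard error from the
#' estimate covariance (\eqn{\sqrt{V_{ii} + V_{jj} - 2 V_{ij}}}), a two-sided
#' Wald p-value, and the 95% confidence interval. The table is antisymmetric:
#' `due(i, j) = -due(j, i)` and the diagonal is zero with SE 0 and p 1. No
#' multiplicity adjustment is applied.
#'
#' @param fit a fitted [maxdiff()] model.
#' @param level confidence level for the interval.
#' @return Data frame of class `"bws_contrasts"` with columns `item_a`,
#'   `item_b`, `due`, `se`, `z`, `p`, `ci_low`, `ci_high`, one row per
#'   ordered pair (including i = j for completeness of the square table).
#' @export
pairwise_contrasts <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "maxdiff"))
  V <- fit$vcov
  if (any(!is.finite(V))) stop("covariance unavailable; cannot form contrasts")
  g <- fit$coefficients
  v <- length(g)
  items <- names(g)
  idx <- expand.grid(j = seq_len(v), i = seq_len(v))[, c("i", "j")]
  due <- g[idx$i] - g[idx$j]
  se2 <- diag(V)[idx$i] + diag(V)[idx$j] - 2 * V[cbind(idx$i, idx$j)]
  se <- sqrt(pmax(se2, 0))
  z <- ifelse(se > 0, due / se, 0)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(
    item_a = items[idx$i],
    item_b = items[idx$j],
    due = unname(due),
    se = unname(se),
    z = unname(z),
    p = ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1),
    ci_low = unname(due - zq * se),
    ci_high = unname(due + zq * se),
    stringsAsFactors = FALSE)
  class(out) <- c("bws_contrasts", "data.frame")
  out
}

#' Greatest utility difference
#'
#' The spread of the utility scale: the maximum utility minus the minimum
#' utility across all items — the largest change in value a single swap of
#' influencing factor could achieve.
#'
#' @param utilities a fitted [maxdiff()] model or a numeric utility vector.
#' @return A single non-negative number.
#' @export
greatest_utility_difference <- function(utilities) {
  if (inherits(utilities, "maxdiff")) utilities <- utilities$coefficients
  if (length(utilities) < 2L) stop("need at least two utilities")
  max(utilities) - min(utilities)
}

#' Per-item significance at the 95% level
#'
#' An estimate is flagged significant when its 95% confidence interval
#' excludes zero (strictly: lower bound above zero or upper bound below
#' zero; an interval touching zero is not significant).
#'
#' @param fit a fitted [maxdiff()] model.
#' @return Named logical vector, one flag per item.
#' @export
significance_flags <- function(fit) {
  stopifnot(inherits(fit, "maxdiff"))
  fit$ci_low > 0 | fit$ci_high < 0
}

#' Best-minus-worst count scores
#'
#' The model-free importance metric: for each item, the number of times it
#' was picked best, picked worst, their difference (the B-W score), and the
#' score standardised by its maximum attainable value — the item's number of
#' appearances across all answered tasks — so it lies in [-1, 1]. Totals are
#' conserved: best counts and worst counts each sum to the number of tasks.
#'
#' @param data a [bws_data()] object.
#' @return Data frame of class `"bws_counts"` with columns `item`,
#'   `best_count`, `worst_count`, `bw_score`, `shown` (appearances) and
#'   `std_score`, sorted by `bw_score` descending.
#' @export
counting_scores <- function(data) {
  stopifnot(inherits(data, "bws_data"))
  design <- data$design
  agg <- .aggregate_choices(data)
  shown <- vapply(seq_len(design$v), function(i) {
    sum(agg$m_block[apply(design$blocks == i, 1L, any)])
  }, numeric(1))
  out <- data.frame(
    item = design$items,
    best_count = agg$best,
    worst_count = agg$worst,
    bw_score = agg$best - agg$worst,
    shown = as.integer(shown),
    std_score = ifelse(shown > 0, (agg$best - agg$worst) / shown, 0),
    stringsAsFactors = FALSE)
  out <- out[order(-out$bw_score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bws_counts", "data.frame")
  out
}
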