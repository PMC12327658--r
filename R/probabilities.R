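#' Choice probabilities under the maximum-difference model
#'
#' The model places one utility \eqn{\gamma(i)} per item on a common logit
#' scale. For a choice set \eqn{T}:
#' \describe{
#'   \item{best}{\eqn{Q_T(i) = e^{\gamma(i)} / \sum_{r \in T} e^{\gamma(r)}}}
#'   \item{worst}{\eqn{R_T(i) = e^{-\gamma(i)} / \sum_{r \in T} e^{-\gamma(r)}}
#'     — the worst scale is the negative of the best scale, so on any two-item
#'     set the probability of picking \eqn{a} as best equals the probability
#'     of picking \eqn{b} as worst}
#'   \item{pair}{\eqn{P(a, b) = e^{\gamma(a) - \gamma(b)} /
#'     \sum_{u \ne v \in T} e^{\gamma(u) - \gamma(v)}} over the
#'     \eqn{k (k - 1)} ordered (best, worst) pairs of distinct options}
#' }
#' All three maps are invariant to adding a constant to every utility, which
#' is why estimation fixes the scale by a sum-to-zero constraint.
#'
#' @param utilities named numeric vector of item utilities (logit scale).
#' @param block items forming the choice set: a character vector of names of
#'   `utilities`, or an index vector into it. Defaults to all items.
#' @return `best_prob()` and `worst_prob()` return a named probability vector
#'   over the block (sums to 1). `maxdiff_pair_prob()` returns a k x k matrix
#'   with rows indexing the best pick and columns the worst pick; the
#'   diagonal is `NA` and the off-diagonal entries sum to 1.
#' @examples
#' u <- c(a = 0.695, b = 0.107, c = -0.083)
#' best_prob(u)
#' worst_prob(u)
#' maxdiff_pair_prob(u)
#' @export
best_prob <- function(utilities, block = NULL) {
  g <- .block_utilities(utilities, block, min_size = 2L)
  e <- exp(g - max(g))
  e / sum(e)
}

#' @rdname best_prob
#' @export
worst_prob <- function(utilities, block = NULL) {
  g <- .block_utilities(utilities, block, min_size = 2L)
  e <- exp(-(g - min(g)))
  e / sum(e)
}

#' @rdname best_prob
#' @export
maxdiff_pair_prob <- function(utilities, block = NULL) {
  g <- .block_utilities(utilities, block, min_size = 3L)
  g <- g - mean(g)
  w <- outer(exp(g), exp(-g))
  diag(w) <- 0
  p <- w / sum(w)
  diag(p) <- NA_real_
  p
}

.block_utilities <- function(utilities, block, min_size) {
  if (!is.numeric(utilities) || any(!is.finite(utilities))) {
    stop("'utilities' must be a finite numeric vector")
  }
  g <- if (is.null(block)) utilities else {
    if (is.character(block)) {
      if (is.null(names(utilities))) stop("'utilities' must be named to index by label")
      miss <- setdiff(block, names(utilities))
      if (length(miss)) stop("unknown items in block: ", paste(miss, collapse = ", "))
    }
    utilities[block]
  }
  if (length(g) < min_size) {
    stop(sprintf("a choice set needs at least %d options", min_size))
  }
  if (anyDuplicated(names(g))) stop("duplicate items in block")
  g
}

#' Log-likelihood of best-worst responses
#'
#' Sum over observed tasks of the log probability that the recorded
#' (best, worst) pair is drawn from the ordered-pair distribution of its
#' choice set (see [maxdiff_pair_prob()]). At all-zero utilities every pair
#' in a set of size k is equally likely, so the value is
#' `-n_tasks * log(k * (k - 1))`.
#'
#' @param data a [bws_data()] object.
#' @param utilities numeric vector of utilities, one per design item (in
#'   design item order, or named by item label).
#' @return The log-likelihood (a single non-positive number).
#' @export
bws_loglik <- function(data, utilities) {
  stopifnot(inherits(data, "bws_data"))
  g <- .design_utilities(data$design, utilities)
  agg <- .aggregate_choices(data)
  .mdl_loglik(g, agg)
}

.design_utilities <- function(design, utilities) {
  if (length(utilities) != design$v) {
    stop(sprintf("'utilities' must have one value per item (%d)", design$v))
  }
  if (!is.null(names(utilities))) {
    miss <- setdiff(design$items, names(utilities))
    if (length(miss)) stop("utilities missing for: ", paste(miss, collapse = ", "))
    utilities <- utilities[design$items]
  }
  if (any(!is.finite(utilities))) stop("'utilities' must be finite")
  unname(utilities)
}

# Sufficient statistics: per-item best and worst counts, per-block task counts.
# The log-likelihood only depends on these because the pair-model denominator
# is shared by all tasks on the same block.
.aggregate_choices <- function(data) {
  design <- data$design
  ch <- data$choices
  list(
    design = design,
    best = tabulate(match(ch$best, design$items), nbins = design$v),
    worst = tabulate(match(ch$worst, design$items), nbins = design$v),
    m_block = tabulate(ch$block, nbins = design$b),
    n_tasks = nrow(ch))
}

# denominator of the pair model for one block: sum_{u != v} e^{g_u - g_v}
# = (sum e^{g})(sum e^{-g}) - k
.mdl_loglik <- function(g, agg) {
  design <- agg$design
  ll <- sum(g * (agg$best - agg$worst))
  for (b in seq_len(design$b)) {
    if (agg$m_block[b] == 0L) next
    gb <- g[design$blocks[b, ]]
    gb <- gb - mean(gb)
    D <- sum(exp(gb)) * sum(exp(-gb)) - design$k
    ll <- ll - agg$m_block[b] * log(D)
  }
  ll
}

# gradient of .mdl_loglik with respect to the v utilities
.mdl_grad <- function(g, agg) {
  design <- agg$design
  grad <- agg$best - agg$worst
  for (b in seq_len(design$b)) {
    if (agg$m_block[b] == 0L) next
    idx <- design$blocks[b, ]
    gb <- g[idx]
    gb <- gb - mean(gb)
    ep <- exp(gb); en <- exp(-gb)
    D <- sum(ep) * sum(en) - design$k
    grad[idx] <- grad[idx] - agg$m_block[b] * (ep * sum(en) - en * sum(ep)) / D
  }
  grad
}
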