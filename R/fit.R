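#' Fit the maximum-difference model to best-worst responses
#'
#' Maximum-likelihood estimation of item utilities from best/worst choices.
#' Each answered choice set contributes the log probability of its selected
#' ordered (best, worst) pair under the pair model of [maxdiff_pair_prob()].
#' The utilities are identified by effects (sum-to-zero) coding: the
#' \eqn{v - 1} free parameters are the first \eqn{v - 1} utilities and the
#' last equals minus their sum, so every reported estimate is a contrast
#' against the average item. The log-likelihood is concave in the utilities,
#' so optimisation starts at zero and uses BFGS followed by Newton polishing
#' until the gradient infinity-norm falls below `tol`.
#'
#' Standard errors come from the inverse observed information of the free
#' parameters, mapped to all \eqn{v} items through the sum-to-zero contrast;
#' 95% confidence intervals are Wald intervals. The likelihood-ratio
#' chi-square compares the fit against the null of all-equal utilities
#' (uniform pair probabilities) on \eqn{v - 1} degrees of freedom. AIC and
#' BIC use \eqn{-2 \ell + 2 p} and \eqn{-2 \ell + p \log n} with
#' \eqn{p = v - 1} and \eqn{n} the number of answered tasks; the
#' small-sample-corrected AICc is also reported.
#'
#' An item that is picked best every time its set is shown (or worst every
#' time) has no finite maximum-likelihood utility; such separation is
#' reported by a warning naming the item, and non-convergence is flagged in
#' the `converged` field rather than raised as an error.
#'
#' @param data a [bws_data()] object.
#' @param start optional numeric vector of starting utilities (length v,
#'   recentred to sum to zero); defaults to all zeros.
#' @param tol convergence tolerance on the gradient infinity-norm.
#' @param max_iter maximum number of Newton polishing steps.
#' @return An object of class `"maxdiff"` with components `coefficients`
#'   (named utilities for all v items, summing to zero), `se`, `ci_low`,
#'   `ci_high`, `zval`, `pval`, `vcov` (v x v), `vcov_free`, `logLik`,
#'   `null_loglik`, `lr_chisq`, `df`, `lr_pvalue`, `aic`, `aicc`, `bic`,
#'   `n_tasks`, `n_respondents`, `converged`, `grad_norm`, and the `data`.
#' @examples
#' fx <- study_fixture(seed = 1, n_respondents = 40)
#' fit <- maxdiff(fx$data)
#' fit
#' coef(fit)[1:3]
#' @seealso [summary.maxdiff()], [marginal_probabilities()],
#'   [pairwise_contrasts()], [counting_scores()], [simulate_bws()]
#' @export
maxdiff <- function(data, start = NULL, tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(data, "bws_data"))
  design <- data$design
  v <- design$v
  if (data$n_tasks < 1L) stop("no responses to fit")
  agg <- .aggregate_choices(data)
  .check_separation(agg)

  # free parameters: utilities 1..(v-1); the last is minus their sum
  expand <- function(th) c(th, -sum(th))
  nll <- function(th) -.mdl_loglik(expand(th), agg)
  ngr <- function(th) {
    gr <- .mdl_grad(expand(th), agg)
    -(gr[-v] - gr[v])
  }

  th <- if (is.null(start)) rep(0, v - 1L) else {
    s <- .design_utilities(design, start)
    s <- s - mean(s)
    s[-v]
  }
  opt <- stats::optim(th, nll, ngr, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  th <- opt$par
  # Newton polish: concave objective, quadratic convergence from here
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gr <- ngr(th)
    if (max(abs(gr)) <= tol) { converged <- TRUE; break }
    H <- stats::optimHess(th, nll, ngr)
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    th <- th - step
  }
  grad_norm <- max(abs(ngr(th)))
  if (grad_norm <= tol) converged <- TRUE
  if (!converged) {
    warning(sprintf("estimation did not converge (gradient norm %.2e)", grad_norm))
  }

  g <- expand(th)
  names(g) <- design$items
  H <- stats::optimHess(th, nll, ngr)
  vcov_free <- tryCatch(solve(H), error = function(e) {
    warning("observed information is singular; standard errors unavailable")
    matrix(NA_real_, v - 1L, v - 1L)
  })
  K <- rbind(diag(v - 1L), rep(-1, v - 1L))     # sum-to-zero contrast map
  vcov_full <- K %*% vcov_free %*% t(K)
  dimnames(vcov_full) <- list(design$items, design$items)
  se <- sqrt(pmax(diag(vcov_full), 0))

  z975 <- stats::qnorm(0.975)
  ll <- .mdl_loglik(g, agg)
  ll0 <- .mdl_loglik(rep(0, v), agg)
  p <- v - 1L
  n <- data$n_tasks
  fit <- structure(
    list(coefficients = g,
         se = se,
         ci_low = g - z975 * se,
         ci_high = g + z975 * se,
         zval = g / se,
         pval = 2 * stats::pnorm(-abs(g / se)),
         vcov = vcov_full,
         vcov_free = vcov_free,
         logLik = ll,
         null_loglik = ll0,
         lr_chisq = 2 * (ll - ll0),
         df = p,
         lr_pvalue = stats::pchisq(2 * (ll - ll0), df = p, lower.tail = FALSE),
         aic = -2 * ll + 2 * p,
         aicc = -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1),
         bic = -2 * ll + p * log(n),
         n_tasks = n,
         n_respondents = data$n_respondents,
         converged = converged,
         grad_norm = grad_norm,
         data = data,
         call = match.call()),
    class = "maxdiff")
  fit
}

# warn when an item is always best (or always worst) whenever shown: its MLE
# utility diverges to +/- Inf
.check_separation <- function(agg) {
  design <- agg$design
  shown <- vapply(seq_len(design$v), function(i) {
    sum(agg$m_block[apply(design$blocks == i, 1L, any)])
  }, numeric(1))
  always_best <- shown > 0 & agg$best == shown
  always_worst <- shown > 0 & agg$worst == shown
  if (any(always_best | always_worst)) {
    bad <- design$items[always_best | always_worst]
    warning("separation: item(s) always chosen best or always chosen worst: ",
            paste(bad, collapse = ", "),
            "; the corresponding utilities are unbounded", call. = FALSE)
  }
  never <- shown > 0 & agg$best == 0 & agg$worst == 0
  if (any(never)) {
    warning("item(s) never chosen best or worst: ",
            paste(design$items[never], collapse = ", "), call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.maxdiff <- function(x, digits = 4, ...) {
  cat("Maximum-difference (best-worst) model\n")
  cat(sprintf("%d items, %d tasks from %d respondents\n",
              length(x$coefficients), x$n_tasks, x$n_respondents))
  cat("\nUtility estimates (sum-to-zero):\n")
  print(round(sort(x$coefficients, decreasing = TRUE), digits))
  cat(sprintf("\nlogLik %.2f, LR chi-square %.2f on %d df (p %s)\n",
              x$logLik, x$lr_chisq, x$df, format.pval(x$lr_pvalue, digits = 3)))
  if (!x$converged) cat("WARNING: estimation did not converge\n")
  invisible(x)
}

#' Summarise a fitted maximum-difference model
#'
#' Produces the standard reporting table: one row per item with the utility
#' estimate, standard error, 95% Wald confidence limits, z and p value, the
#' model-implied marginal probability, and a significance flag (TRUE when the
#' 95% CI excludes zero). Model fit statistics are attached.
#'
#' @param object a fitted [maxdiff()] model.
#' @param ... unused.
#' @return An object of class `"summary.maxdiff"` with a `coefficients`
#'   data frame (sorted by estimate, descending) and the fit statistics.
#' @export
summary.maxdiff <- function(object, ...) {
  tab <- data.frame(
    item = names(object$coefficients),
    estimate = unname(object$coefficients),
    se = unname(object$se),
    ci_low = unname(object$ci_low),
    ci_high = unname(object$ci_high),
    z = unname(object$zval),
    p = unname(object$pval),
    mp = unname(marginal_probabilities(object$coefficients)),
    significant = unname(significance_flags(object)),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$estimate), , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(coefficients = tab,
         logLik = object$logLik, lr_chisq = object$lr_chisq, df = object$df,
         lr_pvalue = object$lr_pvalue,
         aic = object$aic, aicc = object$aicc, bic = object$bic,
         n_tasks = object$n_tasks, n_respondents = object$n_respondents,
         gud = greatest_utility_difference(object),
         converged = object$converged),
    class = "summary.maxdiff")
}

#' @export
print.summary.maxdiff <- function(x, digits = 4, ...) {
  cat("Maximum-difference model results\n\n")
  tab <- x$coefficients
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  cat(sprintf("\nL-R chi-square %.2f on %d df, p %s\n",
              x$lr_chisq, x$df, format.pval(x$lr_pvalue, digits = 3)))
  cat(sprintf("logLik %.2f | AIC %.2f | AICc %.2f | BIC %.2f\n",
              x$logLik, x$aic, x$aicc, x$bic))
  cat(sprintf("Greatest utility difference: %.4f\n", x$gud))
  cat(sprintf("n = %d tasks from %d respondents\n", x$n_tasks, x$n_respondents))
  if (!x$converged) cat("WARNING: estimation did not converge\n")
  invisible(x)
}

#' @export
coef.maxdiff <- function(object, ...) object$coefficients

#' @export
vcov.maxdiff <- function(object, free = FALSE, ...) {
  if (free) object$vcov_free else object$vcov
}

#' @export
logLik.maxdiff <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n_tasks,
            class = "logLik")
}

#' @export
confint.maxdiff <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predicted choice probabilities
#'
#' Evaluates the fitted model on a choice set: the probability each option is
#' picked best, picked worst, or — for `type = "pair"` — the full matrix of
#' ordered (best, worst) pair probabilities.
#'
#' @param object a fitted [maxdiff()] model.
#' @param block items forming the choice set (labels or indices); defaults to
#'   all items.
#' @param type `"best"`, `"worst"` or `"pair"`.
#' @param ... unused.
#' @export
predict.maxdiff <- function(object, block = NULL,
                            type = c("best", "worst", "pair"), ...) {
  type <- match.arg(type)
  switch(type,
         best = best_prob(object$coefficients, block),
         worst = worst_prob(object$coefficients, block),
         pair = maxdiff_pair_prob(object$coefficients, block))
}

#' @export
fitted.maxdiff <- function(object, ...) {
  data <- object$data
  design <- data$design
  g <- unname(object$coefficients)
  pb <- lapply(seq_len(design$b), function(b) {
    maxdiff_pair_prob(g, design$blocks[b, ])
  })
  ch <- data$choices
  vapply(seq_len(nrow(ch)), function(t) {
    idx <- design$blocks[ch$block[t], ]
    i <- match(match(ch$best[t], design$items), idx)
    j <- match(match(ch$worst[t], design$items), idx)
    pb[[ch$block[t]]][i, j]
  }, numeric(1))
}

#' Cell-level Pearson residuals
#'
#' Aggregates the responses into (block, best, worst) cells, compares the
#' observed counts with the fitted expected counts (tasks on the block times
#' the pair probability), and returns the Pearson residual for every cell.
#' Large absolute residuals point at choice sets the pair model fits poorly.
#'
#' @param object a fitted [maxdiff()] model.
#' @param ... unused.
#' @return Data frame with columns `block`, `best`, `worst`, `observed`,
#'   `expected`, `pearson`, one row per ordered pair of each answered block.
#' @export
residuals.maxdiff <- function(object, ...) {
  data <- object$data
  design <- data$design
  g <- unname(object$coefficients)
  ch <- data$choices
  out <- vector("list", design$b)
  for (b in seq_len(design$b)) {
    m <- sum(ch$block == b)
    if (m == 0L) next
    idx <- design$blocks[b, ]
    p <- maxdiff_pair_prob(g, idx)
    sub <- ch[ch$block == b, ]
    obs <- table(factor(match(match(sub$best, design$items), idx), levels = seq_len(design$k)),
                 factor(match(match(sub$worst, design$items), idx), levels = seq_len(design$k)))
    keep <- which(!is.na(p), arr.ind = TRUE)
    expd <- m * p[keep]
    o <- obs[keep]
    out[[b]] <- data.frame(
      block = b,
      best = design$items[idx[keep[, 1]]],
      worst = design$items[idx[keep[, 2]]],
      observed = as.integer(o),
      expected = expd,
      pearson = (as.numeric(o) - expd) / sqrt(expd * (1 - p[keep])),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dot plot of utility estimates with confidence intervals
#'
#' @param x a fitted [maxdiff()] model.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.maxdiff <- function(x, ...) {
  ord <- order(x$coefficients)
  est <- x$coefficients[ord]
  lo <- x$ci_low[ord]
  hi <- x$ci_high[ord]
  old <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(est, seq_along(est), xlim = range(lo, hi), yaxt = "n",
                 xlab = "utility (sum-to-zero logit scale)", ylab = "",
                 pch = 19, ...)
  graphics::segments(lo, seq_along(est), hi, seq_along(est))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_along(est),
                 labels = substr(names(est), 1, 40), las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Simulate new response datasets from a fitted model
#'
#' Draws `nsim` fresh datasets from the fitted utilities on the model's own
#' design, with the same number of respondents as the original data.
#'
#' @param object a fitted [maxdiff()] model.
#' @param nsim number of datasets.
#' @param seed integer seed (optional).
#' @param ... unused.
#' @return A list of `nsim` [bws_data()] objects.
#' @export
simulate.maxdiff <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    simulate_bws(object$data$design, object$coefficients,
                 n_respondents = object$n_respondents)
  })
}
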