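#' Simulate best-worst responses under a random-utility model
#'
#' Generates one record per (respondent, block) of a design. Under the
#' default `"maxdiff_pair"` rule the (best, worst) selection is one draw from
#' the \eqn{k (k - 1)}-category ordered-pair distribution of
#' [maxdiff_pair_prob()] — the same model family the estimator fits, so
#' recovery of the generating utilities is clean. The
#' `"sequential_best_worst"` rule instead draws the best item from the best
#' model and then the worst from the worst model restricted to the remaining
#' \eqn{k - 1} options; it exists to probe robustness to the response
#' process, and coincides in distribution with the pair rule when all
#' utilities are equal. Best and worst always differ.
#'
#' Draws are made respondent by respondent, block by block in design order,
#' one categorical draw per task under the pair rule (two under the
#' sequential rule), using R's default Mersenne-Twister stream; a fixed
#' `seed` therefore reproduces the dataset exactly.
#'
#' @param design a [bws_design()] object.
#' @param utilities true utilities, one per design item (named by label, or
#'   in design item order).
#' @param n_respondents number of simulated respondents; each answers every
#'   block of the design.
#' @param seed optional integer seed set before drawing.
#' @param rule response process, see Details.
#' @return A [bws_data()] object with `n_respondents * b` records;
#'   respondents are labelled `"r0001"`, `"r0002"`, ...
#' @examples
#' design <- cyclic_bws_design(letters[1:7], set_size = 3)
#' sim <- simulate_bws(design, utilities = rnorm(7, sd = 0.5),
#'                     n_respondents = 5, seed = 42)
#' sim
#' @export
simulate_bws <- function(design, utilities, n_respondents,
                         seed = NULL,
                         rule = c("maxdiff_pair", "sequential_best_worst")) {
  stopifnot(inherits(design, "bws_design"))
  rule <- match.arg(rule)
  n_respondents <- as.integer(n_respondents)
  if (n_respondents < 1L) stop("'n_respondents' must be at least 1")
  g <- .design_utilities(design, utilities)
  if (!is.null(seed)) set.seed(seed)

  b <- design$b; k <- design$k
  # per-block machinery precomputed once
  if (rule == "maxdiff_pair") {
    grid <- expand.grid(worst = seq_len(k), best = seq_len(k))
    grid <- grid[grid$best != grid$worst, c("best", "worst")]
    pair_prob <- lapply(seq_len(b), function(bl) {
      p <- maxdiff_pair_prob(g, design$blocks[bl, ])
      p[cbind(grid$best, grid$worst)]
    })
  } else {
    bp <- lapply(seq_len(b), function(bl) best_prob(g, design$blocks[bl, ]))
  }

  n <- n_respondents * b
  best <- integer(n); worst <- integer(n)
  row <- 0L
  for (r in seq_len(n_respondents)) {
    for (bl in seq_len(b)) {
      row <- row + 1L
      idx <- design$blocks[bl, ]
      if (rule == "maxdiff_pair") {
        pick <- sample.int(k * (k - 1L), 1L, prob = pair_prob[[bl]])
        best[row] <- idx[grid$best[pick]]
        worst[row] <- idx[grid$worst[pick]]
      } else {
        i <- sample.int(k, 1L, prob = bp[[bl]])
        rest <- idx[-i]
        j <- sample.int(k - 1L, 1L, prob = worst_prob(g, rest))
        best[row] <- idx[i]
        worst[row] <- rest[j]
      }
    }
  }
  out <- bws_data(design, data.frame(
    respondent = rep(sprintf("r%04d", seq_len(n_respondents)), each = b),
    block = rep(seq_len(b), times = n_respondents),
    best = design$items[best],
    worst = design$items[worst],
    stringsAsFactors = FALSE))
  out$simulation <- list(rule = rule, seed = seed, rng = RNGkind()[1L],
                         true_utilities = structure(g, names = design$items))
  out
}

#' The packaged self-medication worked example
#'
#' A desk-scale replica of a best-worst scaling study of the factors that
#' drive self-medication with antimicrobial drugs among health-science
#' students: 15 candidate factors arranged in 15 choice sets of 7 options
#' (every factor shown 7 times, every pair together 3 times), answered by
#' `n_respondents` simulated participants whose true utilities are the
#' published estimates returned by `self_medication_utilities()`.
#'
#' `self_medication_factors()` returns the 15 factor labels.
#' `self_medication_utilities()` returns the reported utility estimates on
#' the sum-to-zero logit scale: 14 published values plus the baseline factor
#' ("Use of leftover antimicrobial drugs") reconstructed as minus their sum
#' (-0.500).
#'
#' @param seed integer seed for the simulated responses.
#' @param n_respondents number of simulated respondents (study size 300).
#' @return `study_fixture()` returns a list with the `design`
#'   ([bws_design()]), the simulated `data` ([bws_data()]) and the
#'   generating `utilities`. The helper functions return a character vector
#'   of length 15 and a named numeric vector of length 15.
#' @examples
#' fx <- study_fixture(seed = 1, n_respondents = 30)
#' fx$data
#' @export
study_fixture <- function(seed = 1, n_respondents = 300) {
  u <- self_medication_utilities()
  design <- cyclic_bws_design(names(u), set_size = 7)
  data <- simulate_bws(design, u, n_respondents = n_respondents, seed = seed)
  list(design = design, data = data, utilities = u)
}

#' @rdname study_fixture
#' @export
self_medication_factors <- function() {
  names(self_medication_utilities())
}

#' @rdname study_fixture
#' @export
self_medication_utilities <- function() {
  u <- c(
    "Consider minor illness" = -0.083,
    "Dissatisfaction with hospital workers' attitudes" = -0.392,
    "Easy access to antimicrobial drugs over the counter/pharmacies" = 0.171,
    "Frustration with hospital protocols (long waiting times/queues to seek medical care)" = -0.358,
    "Good knowledge of antimicrobial drugs" = 0.695,
    "Idea of self-care" = 0.107,
    "Long-distance travel to health facilities" = -0.362,
    "Poor control of antimicrobial drug dispensation" = -0.269,
    "Poor quality of the provided care" = -0.374,
    "Previous experience with the same illness" = 0.488,
    "Previous knowledge of health condition" = 0.620,
    "Previous use of antimicrobial drugs" = 0.218,
    "Recommendation from a friend/relative" = 0.036,
    "Relatively lower cost of purchasing antimicrobials than that of seeking care from a medical doctor" = 0.003)
  c(u, "Use of leftover antimicrobial drugs" = -sum(u))
}
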