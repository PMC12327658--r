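fit_small <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      fx <- study_fixture(seed = 3, n_respondents = 60)
      memo <<- list(fx = fx, fit = maxdiff(fx$data))
    }
    memo
  }
})

test_that("the estimator satisfies its identification and convergence contract", {
  m <- fit_small()
  fit <- m$fit
  expect_true(fit$converged)
  expect_lte(fit$grad_norm, 1e-8)
  expect_equal(sum(coef(fit)), 0, tolerance = 1e-10)
  expect_equal(fit$df, 14)
  expect_true(all(fit$ci_low < fit$ci_high))
  # covariance symmetric positive semi-definite
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-10)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  # the maximised likelihood beats the null and nearby points
  expect_gt(fit$logLik, fit$null_loglik)
  expect_gt(fit$logLik, bws_loglik(m$fx$data, coef(fit) + c(0.01, rep(0, 14))))
  expect_equal(fit$lr_chisq, 2 * (fit$logLik - fit$null_loglik))
})

test_that("fit statistics follow the stated conventions", {
  fit <- fit_small()$fit
  p <- fit$df
  n <- fit$n_tasks
  expect_equal(fit$aic, -2 * fit$logLik + 2 * p)
  expect_equal(fit$bic, -2 * fit$logLik + p * log(n))
  expect_equal(fit$aicc, fit$aic + 2 * p * (p + 1) / (n - p - 1))
  # stats-generic accessors agree
  expect_equal(AIC(fit), fit$aic)
  expect_equal(BIC(fit), fit$bic)
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  ci <- confint(fit)
  expect_equal(unname(ci[, 1]), unname(fit$ci_low))
})

test_that("standard errors agree with the brute-force observed information", {
  d <- design7_3()
  sim <- simulate_bws(d, stats::rnorm(7, sd = 0.5), n_respondents = 25, seed = 5)
  fit <- maxdiff(sim)
  v <- d$v
  th <- unname(coef(fit))[-v]
  # numeric Hessian of the enumeration-oracle likelihood over the free params
  nll_free <- function(th) -oracle_loglik(sim, c(th, -sum(th)))
  H <- stats::optimHess(th, nll_free)
  V <- solve(H)
  K <- rbind(diag(v - 1), rep(-1, v - 1))
  se_oracle <- sqrt(diag(K %*% V %*% t(K)))
  expect_equal(unname(fit$se), se_oracle, tolerance = 1e-4)
})

test_that("estimation error shrinks as the sample grows", {
  u <- self_medication_utilities()
  d <- design15_7()
  mae <- vapply(c(50, 300, 1000), function(n) {
    sim <- simulate_bws(d, u, n_respondents = n, seed = 2024 + n)
    mean(abs(coef(maxdiff(sim)) - u))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
  expect_lt(mae[3], 0.05)
})

test_that("separation and never-chosen items are reported by name", {
  d <- design7_3()
  # respondent who always picks the block's lexicographically first item as
  # best: item "a" is first in every block that contains it
  ch <- do.call(rbind, lapply(1:7, function(b) {
    labs <- sort(d$items[d$blocks[b, ]])
    data.frame(respondent = "r1", block = b, best = labs[1], worst = labs[3])
  }))
  expect_warning(maxdiff(bws_data(d, ch)), "separation.*a")
})

test_that("prediction, fitted values and residuals are coherent", {
  m <- fit_small()
  fit <- m$fit
  pb <- predict(fit, block = 1:7, type = "best")
  expect_equal(sum(pb), 1, tolerance = 1e-12)
  pw <- predict(fit, block = 1:7, type = "worst")
  expect_equal(sum(pw), 1, tolerance = 1e-12)
  pp <- predict(fit, block = 1:7, type = "pair")
  expect_equal(sum(pp, na.rm = TRUE), 1, tolerance = 1e-12)

  f <- fitted(fit)
  expect_length(f, fit$n_tasks)
  expect_true(all(f > 0 & f < 1))
  expect_equal(sum(log(f)), fit$logLik, tolerance = 1e-8)

  r <- residuals(fit)
  expect_equal(nrow(r), 15 * 42)
  expect_equal(sum(r$observed), fit$n_tasks)
  expect_equal(sum(r$expected), fit$n_tasks, tolerance = 1e-8)
})

test_that("simulate() round-trips through the fitted model", {
  fit <- fit_small()$fit
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "bws_data")
  expect_equal(sims[[1]]$n_respondents, fit$n_respondents)
  expect_false(identical(sims[[1]]$choices, sims[[2]]$choices))
})
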