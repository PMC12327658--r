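# The published worked example: 14 reported utilities plus the baseline
# factor at minus their sum; marginal probabilities reported alongside them.
published_mp <- c(
  "Good knowledge of antimicrobial drugs" = 0.1243,
  "Previous knowledge of health condition" = 0.1153,
  "Previous experience with the same illness" = 0.1011,
  "Previous use of antimicrobial drugs" = 0.0772,
  "Easy access to antimicrobial drugs over the counter/pharmacies" = 0.0736,
  "Idea of self-care" = 0.0690,
  "Frustration with hospital protocols (long waiting times/queues to seek medical care)" = 0.0433,
  "Long-distance travel to health facilities" = 0.0432,
  "Poor quality of the provided care" = 0.0427,
  "Dissatisfaction with hospital workers' attitudes" = 0.0419)

test_that("marginal probabilities reproduce the published worked-example values", {
  mp <- marginal_probabilities(self_medication_utilities())
  expect_equal(sum(mp), 1, tolerance = 1e-12)
  for (item in names(published_mp)) {
    expect_equal(mp[[item]], published_mp[[item]], tolerance = 6e-3)
    expect_lt(abs(mp[[item]] - published_mp[[item]]), 5e-4)
  }
})

test_that("marginal probabilities normalise, recentre and rebuild the baseline", {
  expect_equal(unname(marginal_probabilities(rep(0, 15))), rep(1 / 15, 15))
  u <- self_medication_utilities()
  expect_equal(marginal_probabilities(u), marginal_probabilities(u + 2),
               tolerance = 1e-12)
  # supplying the 14 free estimates rebuilds the baseline at minus their sum
  mp14 <- marginal_probabilities(u[-15], baseline = names(u)[15])
  expect_equal(mp14, marginal_probabilities(u)[names(mp14)], tolerance = 1e-12)
  expect_error(marginal_probabilities(c(1, NA)), "finite")
})

test_that("pairwise contrasts match the published utility differences", {
  u <- self_medication_utilities()
  due_knowledge_baseline <- u[["Previous knowledge of health condition"]] -
    u[["Use of leftover antimicrobial drugs"]]
  expect_equal(due_knowledge_baseline, 1.120, tolerance = 1e-8)
  expect_lt(abs(due_knowledge_baseline - 1.122), 0.01)
  due_experience_knowledge <- u[["Previous experience with the same illness"]] -
    u[["Previous knowledge of health condition"]]
  expect_lt(abs(due_experience_knowledge - (-0.131)), 0.01)
})

test_that("the contrast table is antisymmetric with delta-method errors", {
  fit <- maxdiff(study_fixture(seed = 5, n_respondents = 40)$data)
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), 15 * 15)
  key <- function(a, b) which(ct$item_a == a & ct$item_b == b)
  items <- names(coef(fit))
  set.seed(8)
  for (r in 1:10) {
    ab <- sample(items, 3)
    ij <- key(ab[1], ab[2]); ji <- key(ab[2], ab[1])
    expect_equal(ct$due[ij], -ct$due[ji])
    expect_equal(ct$se[ij], ct$se[ji])
    # triangle identity
    expect_equal(ct$due[key(ab[1], ab[3])],
                 ct$due[key(ab[1], ab[2])] + ct$due[key(ab[2], ab[3])],
                 tolerance = 1e-12)
    # SE from the covariance directly
    cvec <- as.numeric(items == ab[1]) - as.numeric(items == ab[2])
    expect_equal(ct$se[ij], sqrt(drop(t(cvec) %*% vcov(fit) %*% cvec)),
                 tolerance = 1e-10)
  }
  diag_rows <- ct$item_a == ct$item_b
  expect_true(all(ct$due[diag_rows] == 0))
  expect_true(all(ct$se[diag_rows] == 0))
  expect_true(all(ct$p[diag_rows] == 1))
})

test_that("greatest utility difference spans the full item set", {
  expect_equal(greatest_utility_difference(self_medication_utilities()), 1.195,
               tolerance = 1e-8)
  expect_equal(greatest_utility_difference(rep(0.3, 5)), 0)
  expect_equal(greatest_utility_difference(c(1, -1)), 2)
  expect_error(greatest_utility_difference(1), "at least two")
})

test_that("significance uses strict exclusion of zero by the 95% interval", {
  fake <- structure(list(ci_low = c(a = 0.620, b = -0.041, c = -0.45, d = 0),
                         ci_high = c(a = 0.771, b = 0.113, c = -0.02, d = 0.2)),
                    class = "maxdiff")
  expect_equal(unname(significance_flags(fake)),
               c(TRUE, FALSE, TRUE, FALSE))  # interval touching zero: not significant
})

test_that("count scores conserve totals and track the generating utilities", {
  fx <- study_fixture(seed = 11, n_respondents = 300)
  cs <- counting_scores(fx$data)
  expect_equal(sum(cs$best_count), fx$data$n_tasks)
  expect_equal(sum(cs$worst_count), fx$data$n_tasks)
  expect_equal(sum(cs$bw_score), 0)
  expect_true(all(abs(cs$std_score) <= 1))
  expect_true(all(cs$shown == 7 * 300))

  # rank agreement with the generating utilities over repeated draws
  rho <- vapply(1:20, function(s) {
    sim <- study_fixture(seed = 100 + s, n_respondents = 300)
    cs <- counting_scores(sim$data)
    stats::cor(cs$bw_score, sim$utilities[cs$item], method = "spearman")
  }, numeric(1))
  expect_true(all(rho > 0.9))
})

test_that("a deliberate always-best respondent contributes r best picks", {
  d <- design7_3()
  target <- "a"
  rows <- which(apply(d$blocks == match(target, d$items), 1, any))
  ch <- do.call(rbind, lapply(rows, function(b) {
    others <- setdiff(d$items[d$blocks[b, ]], target)
    data.frame(respondent = "r1", block = b, best = target, worst = others[1])
  }))
  data <- bws_data(d, ch)
  cs <- counting_scores(data)
  expect_equal(cs$best_count[cs$item == target], 3)  # r = k = 3 for this design
  # an item never chosen best or worst scores zero
  untouched <- setdiff(d$items, c(target, ch$worst))
  if (length(untouched)) {
    expect_true(all(cs$bw_score[cs$item %in% untouched] == 0))
  }
})

test_that("importance rankings agree across MP, utilities and baseline contrasts", {
  fit <- maxdiff(study_fixture(seed = 21, n_respondents = 40)$data)
  u <- coef(fit)
  mp <- marginal_probabilities(fit)
  expect_identical(order(mp), order(u))
  ct <- pairwise_contrasts(fit)
  base <- names(u)[15]
  due_vs_base <- ct$due[ct$item_b == base][match(names(u), ct$item_a[ct$item_b == base])]
  expect_identical(order(due_vs_base), order(u))
})
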