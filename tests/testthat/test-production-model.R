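test_that("rates normalise against the reference construct", {
  expect_equal(normalize_rate(5, 5), 100)
  expect_equal(normalize_rate(12, 5), 240)
  expect_equal(normalize_rate(0, 5), 0)
  expect_error(normalize_rate(1, 0), "positive")
})

test_that("categorisation uses strict outer bounds and an inclusive middle", {
  expect_equal(categorize(c(0, 19.99, 20, 45, 70, 70.01, 240)),
               c(0L, 0L, 1L, 1L, 1L, 2L, 2L))
  expect_error(categorize(-1), "non-negative")
  expect_error(categorize(NaN), "finite")
  # monotone non-decreasing in the rate
  r <- sort(runif(200, 0, 250))
  expect_true(all(diff(categorize(r)) >= 0))
})

test_that("class probabilities follow the per-class sigmoid, not a softmax", {
  zero <- manual_model(rep(0, 3), matrix(0, 3, 2))
  expect_equal(as.numeric(class_probability(zero, c(1, 2))), rep(0.5, 3))
  expect_equal(predict(zero, c(1, 2)), 0L)  # all tied -> lowest class index

  # affine score 2 + 3 - 5 = 0 for class 0; huge intercept saturates to 1
  m <- manual_model(c(2, 50, -50), rbind(c(1, -1), c(0, 0), c(0, 0)))
  p <- class_probability(m, c(3, 5))
  expect_equal(as.numeric(p), c(0.5, 1, 0), tolerance = 1e-15)
  expect_false(isTRUE(all.equal(sum(p), 1)))  # one-vs-rest scores
  pn <- class_probability(m, c(3, 5), normalized = TRUE)
  expect_equal(sum(pn), 1)

  # brute-force oracle over random parameters and features
  set.seed(5)
  for (i in 1:25) {
    b0 <- rnorm(3); B <- matrix(rnorm(3 * 6), 3, 6); x <- rnorm(6)
    got <- class_probability(manual_model(b0, B), x)
    want <- vapply(1:3, function(k) {
      1 / (1 + exp(-(b0[k] + sum(B[k, ] * x))))
    }, numeric(1))
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
  }

  expect_error(class_probability(m, c(1, 2, 3)), "dimension")
})

test_that("prediction breaks score ties towards the lower class", {
  m <- manual_model(c(0, 0, -5), rbind(c(1, 0), c(1, 0), c(0, 0)))
  expect_equal(predict(m, c(2, 0)), 0L)
  m2 <- manual_model(c(-5, 0, 0), rbind(c(0, 0), c(1, 0), c(1, 0)))
  expect_equal(predict(m2, c(2, 0)), 1L)
})

test_that("the penalised fit matches glm at zero penalty and shrinks with it", {
  set.seed(21)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(0.3 + X %*% c(1, -0.5, 0)))

  ours <- aacap:::fit_penalized_logistic(X, y, lambda = 0)
  ref <- glm(y ~ X, family = binomial)
  expect_equal(ours$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(unname(ours$coef), unname(coef(ref)[-1]), tolerance = 1e-6)

  # ridge limit: coefficients vanish, objective trace never increases
  heavy <- aacap:::fit_penalized_logistic(X, y, lambda = 1e6)
  expect_lt(max(abs(heavy$coef)), 1e-3)
  for (fit in list(ours, heavy)) {
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
})

test_that("cross-validated fitting separates classes and collapses under lambda -> Inf", {
  ds <- generate_variants(generator_config(n_variants = 150, noise_sd = 0,
                                           seed = 4))
  m <- suppressWarnings(
    fit_production_model(ds$records, lambda_grid = 1e-6, folds = 5, seed = 4)
  )
  expect_equal(predict(m, ds$records), ds$records$label)  # separable limit

  # ridge limit with plain (unit) class weights: only the intercepts survive,
  # so every sample falls to the clearly most prevalent class
  skew <- generate_variants(generator_config(
    n_variants = 150, proportions = c(low = 0.6, medium = 0.25, high = 0.15),
    seed = 4))
  m_inf <- suppressWarnings(
    fit_production_model(skew$records, lambda_grid = 1e10, folds = 5,
                         seed = 4, class_weights = c(1, 1, 1))
  )
  expect_lt(max(abs(m_inf$coef)), 1e-4)
  top <- as.integer(names(which.max(table(skew$records$label))))
  expect_equal(unique(predict(m_inf, skew$records)), top)
})

test_that("support-weighted precision and F1 match their hand formulas", {
  y <- c(0, 0, 1, 1, 2, 2)
  expect_equal(weighted_precision(y, y), 1)
  expect_equal(weighted_f1(y, y), 1)
  expect_warning(
    expect_warning(wp <- weighted_precision(y, rep(0, 6)), "class 1"),
    "class 2"
  )
  expect_equal(wp, 1 / 9)
  expect_equal(weighted_precision(c(1, 1), c(1, 1)), 1)
  expect_equal(weighted_f1(c(0, 1), c(1, 0)), 0)

  y10 <- c(0, 0, 0, 1, 1, 1, 1, 2, 2, 2)
  p10 <- c(0, 1, 0, 1, 1, 2, 0, 2, 2, 1)
  expect_equal(suppressWarnings(weighted_f1(y10, p10)),
               oracle_weighted_f1(y10, p10))
  expect_error(weighted_precision(integer(0), integer(0)), "empty")
  expect_error(weighted_precision(1:3, 1:2), "differ")
})

test_that("pairwise AUC equals exhaustive pair enumeration", {
  y <- c(0, 0, 1, 1, 2, 2)
  perfect <- matrix(0, 6, 3, dimnames = list(NULL, 0:2))
  perfect[cbind(1:6, y + 1)] <- 1
  expect_equal(pairwise_auc(y, perfect), 1)

  constant <- matrix(1 / 3, 6, 3, dimnames = list(NULL, 0:2))
  expect_equal(pairwise_auc(y, constant), 0.5)

  set.seed(9)
  scores <- matrix(runif(18), 6, 3, dimnames = list(NULL, 0:2))
  expect_equal(pairwise_auc(y, scores), oracle_pairwise_auc(y, scores))
  expect_error(pairwise_auc(rep(0, 4), scores[1:4, ]), "2 classes")

  # the rank form also agrees with pROC on a binary slice
  if (requireNamespace("pROC", quietly = TRUE)) {
    s <- runif(30); lab <- rbinom(30, 1, 0.5)
    if (length(unique(lab)) == 2) {
      expect_equal(aacap:::binary_auc(s, lab == 1),
                   as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE,
                                                  direction = "<"))))
    }
  }
})

test_that("metric implementations agree with the oracles on random instances", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    y <- sample(0:2, n, replace = TRUE)
    while (length(unique(y)) < 2) y <- sample(0:2, n, replace = TRUE)
    p <- sample(0:2, n, replace = TRUE)
    s <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, 0:2))
    expect_equal(suppressWarnings(weighted_precision(y, p)),
                 oracle_weighted_precision(y, p), tolerance = 1e-10)
    expect_equal(suppressWarnings(weighted_f1(y, p)),
                 oracle_weighted_f1(y, p), tolerance = 1e-10)
    expect_equal(pairwise_auc(y, s), oracle_pairwise_auc(y, s),
                 tolerance = 1e-10)
  }
})

test_that("the split plan is exact at the reference size and scales otherwise", {
  plan <- split_plan(168, seed = 5)
  expect_equal(lengths(plan), c(M = 118, T_a = 30, T_b = 20))
  expect_equal(sort(unname(unlist(plan))), 1:168)  # disjoint and exhaustive
  expect_identical(plan, split_plan(168, seed = 5))
  expect_false(identical(plan, split_plan(168, seed = 6)))

  half <- split_plan(84, seed = 1)
  expect_equal(lengths(half), c(M = 59, T_a = 15, T_b = 10))
  expect_error(split_plan(2), "n >= 3")
})

test_that("the frequency baseline has prior scores and chance-level AUC", {
  recs <- data.frame(matrix(5L, 9, 20, dimnames = list(NULL, aa_alphabet())),
                     production_rate = rep(c(10, 40, 90), each = 3))
  d <- dummy_baseline(recs, seed = 2)
  expect_equal(as.numeric(d$priors), rep(1 / 3, 3))
  ev <- evaluate_model(d, recs)
  expect_equal(ev$pairwise_auc, 0.5)

  solo <- recs[1:3, ]
  d1 <- dummy_baseline(solo, seed = 2)
  expect_equal(predict(d1, 10), rep(0L, 10))
  dm <- dummy_baseline(recs, method = "most_frequent")
  expect_equal(predict(dm, 4), rep(0L, 4))
})

test_that("the triplicate protocol is reproducible bookkeeping", {
  ds <- generate_variants(generator_config(n_variants = 100, seed = 8))
  args <- list(ds$records, n_replicates = 3, base_seed = 8,
               lambda_grid = c(1e-3, 1), folds = 5)
  reps <- suppressWarnings(do.call(run_replicates, args))
  expect_length(reps, 3)
  for (r in reps) {
    expect_named(r$reports, c("T_a", "T_b"))
    expect_named(r$reports$T_a, c("model", "baseline"))
  }
  expect_equal(vapply(reps, `[[`, numeric(1), "seed"), c(8, 9, 10))

  again <- suppressWarnings(do.call(run_replicates, args))
  expect_identical(lapply(reps, `[[`, "reports"),
                   lapply(again, `[[`, "reports"))
})
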