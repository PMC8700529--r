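test_that("hurdle fits reproduce the observed zero count exactly", {
  for (seed in c(31, 32)) {
    d <- sim_hurdle(600, seed = seed)
    fit <- fit_hurdle_nb(d$y, d$x)
    expect_equal(expected_zeros_diff(fit), 0, tolerance = 1e-8)
  }
})

test_that("NB and Poisson miss the zero count on zero-heavy data, Poisson worse", {
  # on hurdle-generated data the NB consistently predicts fewer zeros
  # than observed (positive difference), and the Poisson misses by far
  # more; only the hurdle reproduces the zero count exactly
  d <- sim_hurdle(2000, gamma0 = -1, gamma1 = 0.5, seed = 33)
  fn <- suppressWarnings(fit_negbin(d$y, d$x))
  fp <- fit_poisson(d$y, d$x)
  dn <- expected_zeros_diff(fn)
  dp <- expected_zeros_diff(fp)
  expect_gt(dn, 0)
  expect_gte(abs(dp), abs(dn))
})

test_that("final count model drops missing-AIS documents and reports RR", {
  d <- sim_hurdle(500, seed = 34)
  ais <- d$x + 1.0
  ais[1:25] <- NA
  fit <- fit_final_count(ais, d$y)
  expect_identical(attr(fit, "n_dropped"), 25L)
  expect_identical(fit$n_obs, 475L)
  rr <- relative_risk(fit, "ais_mean")
  expect_true(is.finite(rr$weight))
  # constant AIS: slope inestimable
  flat <- suppressWarnings(fit_final_count(rep(2, 500), d$y))
  expect_false(flat$converged)
  expect_true(is.na(relative_risk(flat)$weight))
})

test_that("rootogram frequencies total n and expose model structure", {
  d <- sim_hurdle(800, seed = 35)
  fit <- fit_hurdle_nb(d$y, d$x)
  rg <- rootogram(fit, max_count = max(d$y))
  expect_equal(sum(rg$observed), length(d$y))
  expect_equal(rg$hang_bottom, rg$sqrt_expected - rg$sqrt_observed)
  # the hurdle zero bar hangs exactly to zero: expected zeros = observed
  expect_equal(rg$expected[1], rg$observed[1], tolerance = 1e-6)
  # a Poisson fit on overdispersed data misses the zero bin badly
  fp <- fit_poisson(d$y, d$x)
  rp <- rootogram(fp, max_count = max(d$y))
  expect_gt(abs(rp$expected[1] - rp$observed[1]),
            abs(rg$expected[1] - rg$observed[1]) + 10)
})

test_that("a perfectly calibrated rootogram hangs to zero everywhere", {
  # expected == observed implies every hanging bar bottom is exactly 0
  rg <- data.frame(observed = c(4, 9, 16), expected = c(4, 9, 16))
  expect_equal(sqrt(rg$expected) - sqrt(rg$observed), rep(0, 3))
})

test_that("Kruskal-Wallis matches the hand formula and is rank-invariant", {
  set.seed(36)
  scores <- c(rnorm(12, 0), rnorm(10, 1))
  groups <- rep(c(0, 1), c(12, 10))
  got <- kruskal_wallis(scores, groups)
  expect_equal(got$statistic, kw_stat_hand(scores, groups),
               tolerance = 1e-10)
  expect_equal(got$df, 1)
  # invariant under strictly increasing transforms
  got2 <- kruskal_wallis(exp(scores), groups)
  expect_equal(got$statistic, got2$statistic, tolerance = 1e-10)
  expect_equal(got$p_value, got2$p_value, tolerance = 1e-12)
  expect_error(kruskal_wallis(scores, rep(1, 22)), "non-empty")
})

test_that("Kruskal-Wallis chi-square p tracks the exact permutation p on a small fixture", {
  scores <- c(0.3, 1.1, 0.8, 2.0, 1.5, 0.6, 1.9, 2.4, 1.2, 2.8, 0.9, 2.2)
  groups <- rep(c(0, 1), each = 6)
  got <- kruskal_wallis(scores, groups)
  idx <- utils::combn(12, 6)
  perm_stats <- apply(idx, 2, function(i) {
    g <- rep(1, 12); g[i] <- 0
    kw_stat_hand(scores, g)
  })
  p_exact <- mean(perm_stats >= got$statistic - 1e-12)
  expect_lt(abs(got$p_value - p_exact), 0.06)
})

test_that("identical group distributions give p close to one", {
  scores <- rep(c(1, 2, 3, 4), times = 2)
  groups <- rep(c(0, 1), each = 4)
  got <- kruskal_wallis(scores, groups)
  expect_gt(got$p_value, 0.9)
})

test_that("AUC equals Mann-Whitney pair counting, with known special cases", {
  r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  # perfect separation
  rp <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_equal(rp$auc, 1)
  set.seed(37)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n, mean = 0.4 * labels), sample(1:2, 1)) # ties
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, mw_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("label flip and score inversion symmetries hold", {
  set.seed(38)
  labels <- rbinom(60, 1, 0.5)
  scores <- rnorm(60)             # continuous: no ties
  a1 <- roc_analysis(scores, labels)$auc
  a2 <- roc_analysis(scores, 1 - labels)$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
  pos_scores <- exp(scores)
  r_recip <- roc_analysis(1 / pos_scores, labels)
  r_lower <- roc_analysis(pos_scores, labels,
                          direction = "lower_is_positive")
  expect_equal(r_recip$auc, r_lower$auc, tolerance = 1e-12)
})

test_that("the Youden cutoff maximises sensitivity + specificity", {
  set.seed(39)
  labels <- rbinom(100, 1, 0.5)
  scores <- rnorm(100, mean = labels)
  r <- roc_analysis(scores, labels)
  j <- r$sensitivity + r$specificity - 1
  expect_equal(r$best_sens + r$best_spec - 1, max(j), tolerance = 1e-12)
  # constant scores: degenerate, AUC 0.5 by convention
  rc <- roc_analysis(rep(1, 40), rep(c(0, 1), 20))
  expect_true(rc$degenerate)
  expect_equal(rc$auc, 0.5)
})

test_that("auto direction reports an AUC of at least one half", {
  set.seed(40)
  labels <- rbinom(80, 1, 0.5)
  scores <- rnorm(80, mean = -labels)   # lower score = positive class
  r <- roc_analysis(scores, labels, direction = "auto")
  expect_gte(r$auc, 0.5)
  expect_identical(r$direction, "lower_is_positive")
})
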