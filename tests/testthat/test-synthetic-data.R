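test_that("a fixed seed reproduces the corpus byte-for-byte", {
  spec <- corpus_spec(n_docs = c(60, 60), seed = 41)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1, c2)
  c3 <- generate_corpus(corpus_spec(n_docs = c(60, 60), seed = 42))
  expect_false(identical(c1$text, c3$text))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_corpus(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the empirical zero fraction matches the hurdle spec", {
  spec <- corpus_spec(n_docs = c(2500, 2500), seed = 43)
  corp <- generate_corpus(spec)
  # model-implied zero probability per document from its planted eta
  freq <- vapply(strsplit(corp$text, " "),
                 function(tk) sum(tk == "child"), numeric(1))
  eta <- spec$beta0 + spec$planted_count_effects[["child"]] * freq
  p0 <- 1 - plogis(spec$gamma0 + spec$gamma1 * eta)
  expected <- mean(p0)
  se <- sqrt(sum(p0 * (1 - p0))) / nrow(corp)
  expect_lt(abs(mean(corp$outcome_count == 0) - expected), 3 * se)
})

test_that("labels, ids and planted terms respect the spec", {
  spec <- corpus_spec(n_docs = c(50, 70), seed = 44)
  corp <- generate_corpus(spec)
  expect_identical(nrow(corp), 120L)
  expect_identical(sum(corp$topic_label), 50L)
  expect_false(anyDuplicated(corp$doc_id) > 0)
  expect_true(all(corp$outcome_count >= 0))
  # a term with no planted effect never enters eta: outcome distribution
  # is exchangeable across its presence, so just check the plumbing --
  # the effect map only names terms actually in play
  expect_true(all(names(spec$planted_count_effects) %in%
                    unlist(lapply(spec$topic_term_sets, names))))
})

test_that("decorated text cleans back to the undecorated tokens", {
  base <- corpus_spec(n_docs = c(20, 20), seed = 45)
  deco <- corpus_spec(n_docs = c(20, 20), seed = 45, decorate = TRUE)
  c_base <- generate_corpus(base)
  c_deco <- generate_corpus(deco)
  expect_identical(clean_corpus(c_deco), clean_corpus(c_base))
  expect_true(all(grepl("^RT @someone", c_deco$text)))
})

test_that("invalid specifications are rejected", {
  expect_error(corpus_spec(n_docs = c(0, 10)))
  expect_error(corpus_spec(theta = -1))
  expect_error(corpus_spec(cross_leakage = 2))
  expect_error(corpus_spec(topic_term_sets = list(c(a = 1.5), c(b = 0.1))),
               "probabilities")
})

test_that("zero-truncated NB draws have the truncated distribution", {
  set.seed(46)
  mu <- 1.7; theta <- 2
  y <- aisglm:::rztnbinom(20000, rep(mu, 20000), theta)
  expect_gte(min(y), 1)
  p0 <- (theta / (theta + mu))^theta
  m_expect <- mu / (1 - p0)
  expect_lt(abs(mean(y) - m_expect), 0.05)
  # pmf of the smallest support point
  p1 <- exp(truncated_nb_logpmf(1, mu, theta))
  expect_lt(abs(mean(y == 1) - p1), 0.01)
})

test_that("AIS-sum degrades for classification when the control group has more, weaker terms", {
  # the sum ignores how many terms a document matched, so a control
  # vocabulary rich in sub-unit weights pushes control sums up and
  # erodes the sum's discrimination while mean/median stay informative
  spec <- corpus_spec(
    n_docs = c(1000, 1000),
    topic_term_sets = list(
      c(spectrum = 0.35, child = 0.35),
      setNames(rep(0.4, 10), paste0("ctrl", letters[1:10]))),
    cross_leakage = 0.3, background_skew_sd = 0.2, seed = 47)
  ais <- classify_pipeline(spec)
  auc <- vapply(c("ais_mean", "ais_median", "ais_sum"), function(v) {
    keep <- is.finite(ais[[v]])
    roc_analysis(ais[[v]][keep], ais$topic_label[keep])$auc
  }, numeric(1))
  expect_gt(auc[["ais_median"]], 0.8)
  expect_lt(auc[["ais_sum"]], auc[["ais_median"]] - 0.1)
})

test_that("the worked-example fixture is constant and complete", {
  fx <- worked_example_fixture()
  expect_identical(fx, worked_example_fixture())
  expect_identical(nrow(fx$weights), 3L)
  expect_setequal(fx$weights$term, c("take", "child", "see"))
  expect_identical(length(fx$doc$tokens), 11L)
})
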