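test_that("intercept-only Poisson recovers the closed form log-mean", {
  y <- rep(5L, 20)
  fit <- fit_poisson(y, rep(0, 20))   # constant x -> intercept-only
  expect_false(fit$converged)
  expect_true(is.na(fit$count_coefs[["slope"]]))
  expect_equal(unname(fit$count_coefs[["intercept"]]), log(5),
               tolerance = 1e-8)
})

test_that("Poisson loglik matches the direct formula and a grid oracle", {
  set.seed(2)
  x <- c(0, 0, 1, 1, 2, 0, 1, 3, 0, 2, 1, 0, 2, 1, 0, 1, 0, 2, 1, 3)
  y <- rpois(20, exp(0.2 + 0.4 * x))
  for (link in c("loglinear", "loglog")) {
    fit <- fit_poisson(y, x, link = link)
    xt <- if (link == "loglog") log1p(x) else x
    ll_fun <- function(p) sum(dpois(y, exp(p[1] + p[2] * xt), log = TRUE))
    expect_equal(ll_fun(unname(fit$count_coefs)), fit$loglik,
                 tolerance = 1e-8)
    expect_lte(grid_max_loglik(ll_fun, unname(fit$count_coefs)),
               fit$loglik + 1e-4)
    expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  }
  expect_error(fit_poisson(c(0.5, 1), c(0, 1)), "integer")
})

test_that("NB fit agrees with an independent alternating-estimation fit", {
  set.seed(3)
  x <- rbinom(500, 2, 0.4)
  y <- rnbinom(500, size = 1.5, mu = exp(0.5 + 0.7 * x))
  fit <- fit_negbin(y, x)
  ref <- MASS::glm.nb(y ~ x)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$count_coefs[["slope"]]),
               unname(coef(ref)[2]), tolerance = 1e-4)
  expect_equal(fit$theta, ref$theta, tolerance = 1e-3)
  expect_equal(fit$aic, 2 * 3 - 2 * fit$loglik)
})

test_that("NB recovers simulated parameters within 3 joint SEs", {
  set.seed(4)
  n <- 5000
  x <- rbinom(n, 2, 0.3)
  y <- rnbinom(n, size = 1.5, mu = exp(0.3 + 0.7 * x))
  fit <- fit_negbin(y, x)
  expect_true(fit$converged)
  expect_lt(abs(fit$count_coefs[["slope"]] - 0.7), 3 * fit$se_slope)
})

test_that("NB degenerates to Poisson for huge theta and caps without overdispersion", {
  set.seed(5)
  y <- rpois(300, 3)
  ll_nb <- sum(dnbinom(y, size = 1e8, mu = rep(3, 300), log = TRUE))
  ll_po <- sum(dpois(y, 3, log = TRUE))
  expect_equal(ll_nb, ll_po, tolerance = 1e-3)
  # underdispersed data push theta to the cap: flagged, warned, converged
  yu <- rep(c(2L, 3L), 150)
  x <- rbinom(300, 1, 0.5)
  expect_warning(fit <- fit_negbin(yu, x), "cap")
  expect_true(fit$converged)
  expect_true(fit$theta_capped)
  po <- fit_poisson(yu, x)
  expect_equal(fit$loglik, po$loglik, tolerance = 1e-3)
})

test_that("intercept-only NB loglik matches hand-written pmf summation", {
  y <- c(rep(0L, 19), 4L)
  fit <- suppressWarnings(fit_negbin(y, rep(1, 20)))
  cf <- fit$count_coefs[["intercept"]]
  expect_equal(sum(nb_logpmf_hand(y, exp(cf), fit$theta)), fit$loglik,
               tolerance = 1e-8)
})

test_that("truncated NB log-pmf normalises, matches the ratio, and has the Poisson limit", {
  mu <- 2; theta <- 1
  ys <- 1:400
  expect_equal(sum(exp(truncated_nb_logpmf(ys, mu, theta))), 1,
               tolerance = 1e-8)
  # direct ratio of hand-written pmf values
  direct <- nb_logpmf_hand(1:10, mu, theta) -
    log(1 - exp(nb_logpmf_hand(0, mu, theta)))
  expect_equal(truncated_nb_logpmf(1:10, mu, theta), direct,
               tolerance = 1e-10)
  # theta -> Inf: zero-truncated Poisson
  ztp <- dpois(1:10, mu, log = TRUE) - log(1 - exp(-mu))
  expect_equal(truncated_nb_logpmf(1:10, mu, 1e9), ztp, tolerance = 1e-6)
  expect_error(truncated_nb_logpmf(0, mu, theta), "y >= 1")
})

test_that("truncated pmf mass plus the zero mass is exactly one", {
  mu <- 1.3; theta <- 2.5
  p0 <- (theta / (theta + mu))^theta
  mass <- p0 + (1 - p0) * sum(exp(truncated_nb_logpmf(1:300, mu, theta)))
  expect_equal(mass, 1, tolerance = 1e-10)
})

test_that("hurdle likelihood separates into its two components", {
  d <- sim_hurdle(800, seed = 6)
  fit <- fit_hurdle_nb(d$y, d$x)
  lz <- fit_logistic(as.integer(d$y > 0), d$x)$loglik
  mu <- exp(fit$count_coefs[["intercept"]] +
              fit$count_coefs[["slope"]] * d$x[d$y > 0])
  lc <- sum(truncated_nb_logpmf(d$y[d$y > 0], mu, fit$theta))
  expect_equal(fit$loglik, lz + lc, tolerance = 1e-8)
  expect_equal(fit$loglik, fit$loglik_zero + fit$loglik_count,
               tolerance = 1e-12)
  expect_equal(fit$aic, 2 * 5 - 2 * fit$loglik)
})

test_that("hurdle fit recovers its simulation parameters within 3 SEs", {
  d <- sim_hurdle(5000, gamma0 = -0.5, gamma1 = 0.8, beta0 = 0.3,
                  beta1 = 0.6, theta = 2, seed = 7)
  fit <- fit_hurdle_nb(d$y, d$x)
  expect_true(fit$converged)
  expect_lt(abs(fit$count_coefs[["slope"]] - 0.6), 3 * fit$se_slope)
  expect_lt(abs(fit$zero_coefs[["slope"]] - 0.8), 3 * fit$se_zero_slope)
})

test_that("degenerate outcomes are rejected by the hurdle fit", {
  expect_error(fit_hurdle_nb(rep(0L, 10), rbinom(10, 1, 0.5)), "positive")
  expect_error(fit_hurdle_nb(rep(2L, 10), rbinom(10, 1, 0.5)), "zero")
})

test_that("relative risk is exp(slope) with absent weight on failure", {
  d <- sim_hurdle(400, seed = 8)
  fit <- fit_hurdle_nb(d$y, d$x)
  rr <- relative_risk(fit, term = "tm")
  expect_equal(rr$weight, exp(fit$count_coefs[["slope"]]))
  expect_identical(rr$term, "tm")
  bad <- suppressWarnings(fit_hurdle_nb(d$y, rep(1, length(d$y))))
  expect_true(is.na(relative_risk(bad)$weight))
})

test_that("term screening equals standalone fits and tolerates failures", {
  set.seed(9)
  docs <- lapply(1:60, function(i)
    sample(c("aa", "bb", "cc"), sample(1:4, 1), replace = TRUE))
  names(docs) <- paste0("d", 1:60)
  dtm <- build_dtm(docs)
  y <- rpois(60, 2) * rbinom(60, 1, 0.7)
  w <- suppressWarnings(screen_terms_count(dtm, y, "negbin"))
  expect_identical(w$term, dtm$terms)
  for (j in seq_along(dtm$terms)) {
    solo <- suppressWarnings(
      relative_risk(fit_negbin(y, as.numeric(dtm$counts[, j]))))
    expect_equal(w$weight[j], solo$weight, tolerance = 1e-8)
  }
  # a term absent from every document gives an absent weight
  dtm0 <- build_dtm(c(docs, list(extra = "zz")))
  dtm0$counts[, "zz"] <- 0
  dtm0 <- aisglm:::new_ais_dtm(dtm0$counts)
  w0 <- suppressWarnings(screen_terms_count(dtm0, c(y, 0L), "negbin"))
  expect_true(is.na(w0$weight[w0$term == "zz"]))
  expect_false(w0$converged[w0$term == "zz"])
  # permuting the vocabulary permutes the output identically
  perm <- rev(seq_along(dtm$terms))
  dtm_p <- aisglm:::new_ais_dtm(dtm$counts[, perm, drop = FALSE])
  w_p <- suppressWarnings(screen_terms_count(dtm_p, y, "negbin"))
  expect_equal(w_p$weight, w$weight[perm])
  expect_identical(w_p$term, w$term[perm])
})
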