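## Count-outcome models on a single predictor: Poisson (two link variants),
## negative-binomial (NB2), and the hurdle negative-binomial. The hurdle
## factorises into a logistic model for zero vs positive and a
## zero-truncated NB for the positives, maximised independently; its total
## log-likelihood is the sum of the two component log-likelihoods.

THETA_CAP <- 1e8

#' Fit a univariate count model
#'
#' Maximum-likelihood fit of a count outcome on a single predictor.
#' Available models:
#' \describe{
#'   \item{`poisson_loglinear`}{\eqn{\log E[y] = \beta_0 + \beta x}.}
#'   \item{`poisson_loglog`}{\eqn{\log E[y] = \beta_0 + \beta \log(x+1)};
#'     the log-transformed predictor tames the skew of term frequencies
#'     while keeping \eqn{x = 0} admissible.}
#'   \item{`negbin`}{NB2: \eqn{Var(y) = \mu + \mu^2/\theta}, joint ML over
#'     \eqn{(\beta_0, \beta, \theta)}.}
#'   \item{`hurdle_nb`}{a logistic model for \eqn{1\{y>0\}} (coefficients
#'     \eqn{\gamma}) plus a zero-truncated NB for \eqn{y \mid y>0}
#'     (coefficients \eqn{\beta}, dispersion \eqn{\theta}); both components
#'     use the same predictor and are maximised independently.}
#' }
#'
#' The exponentiated count-component slope is the relative risk (RR): the
#' multiplicative change in expected (positive-part) count per unit of the
#' predictor. Extract it with [relative_risk()].
#'
#' Dispersion is optimised on the log scale and capped at `1e8`; hitting
#' the cap (equidispersed data, where the NB degenerates to Poisson)
#' triggers a warning but the fit is still flagged converged. A constant
#' predictor makes the slope inestimable: the model is refit
#' intercept-only and `converged` is set to `FALSE`.
#'
#' @param y non-negative integer outcome vector.
#' @param x numeric predictor vector, same length.
#' @param kind one of `"hurdle_nb"` (default), `"negbin"`,
#'   `"poisson_loglinear"`, `"poisson_loglog"`.
#' @return an object of class `c("ais_count_fit", "ais_fit")` with
#'   components `model_kind`, `count_coefs` (intercept, slope),
#'   `zero_coefs` (hurdle only), `theta`, `loglik` (plus `loglik_zero`,
#'   `loglik_count` for hurdle fits), `df`, `aic`, `converged`, `se_slope`,
#'   `p_slope`, `n_obs`, and the data. Standard accessors `coef()`,
#'   `logLik()`, `AIC()`, `predict()`, `fitted()`, `residuals()`,
#'   `summary()` and `plot()` (rootogram) apply.
#' @examples
#' set.seed(1)
#' x <- rbinom(200, 2, 0.3)
#' y <- rnbinom(200, size = 2, mu = exp(0.5 + 0.7 * x)) *
#'   rbinom(200, 1, 0.6)
#' fit <- fit_count_model(y, x, "hurdle_nb")
#' relative_risk(fit)
#' @export
fit_count_model <- function(y, x,
                            kind = c("hurdle_nb", "negbin",
                                     "poisson_loglinear", "poisson_loglog")) {
  kind <- match.arg(kind)
  switch(kind,
         hurdle_nb = fit_hurdle_nb(y, x),
         negbin = fit_negbin(y, x),
         poisson_loglinear = fit_poisson(y, x, link = "loglinear"),
         poisson_loglog = fit_poisson(y, x, link = "loglog"))
}

check_count_inputs <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have the same length")
  if (length(y) < 2L) stop("need at least 2 observations")
  if (anyNA(y) || anyNA(x) || any(!is.finite(x)))
    stop("y and x must be finite and free of missing values")
  if (any(y < 0) || any(y != round(y)))
    stop("y must be a non-negative integer vector")
  invisible(TRUE)
}

## predictor transform per model kind (loglog uses log(x + 1))
transform_x <- function(x, kind) {
  if (identical(kind, "poisson_loglog")) log1p(x) else x
}

new_count_fit <- function(kind, y, x, count_coefs, zero_coefs = NULL,
                          theta = NA_real_, loglik, df, converged,
                          se_slope = NA_real_, loglik_zero = NA_real_,
                          loglik_count = NA_real_, se_zero_slope = NA_real_,
                          theta_capped = FALSE) {
  p_slope <- if (is.finite(se_slope) && se_slope > 0) {
    2 * stats::pnorm(-abs(count_coefs[["slope"]] / se_slope))
  } else NA_real_
  structure(
    list(model_kind = kind, count_coefs = count_coefs,
         zero_coefs = zero_coefs, theta = theta,
         loglik = loglik, loglik_zero = loglik_zero,
         loglik_count = loglik_count, df = df, aic = 2 * df - 2 * loglik,
         converged = converged, se_slope = se_slope,
         se_zero_slope = se_zero_slope, p_slope = p_slope,
         theta_capped = theta_capped, n_obs = length(y), y = y, x = x),
    class = c("ais_count_fit", "ais_fit"))
}

#' @rdname fit_count_model
#' @param link for `fit_poisson()`: `"loglinear"` or `"loglog"`.
#' @export
fit_poisson <- function(y, x, link = c("loglinear", "loglog")) {
  link <- match.arg(link)
  check_count_inputs(y, x)
  kind <- paste0("poisson_", link)
  xt <- transform_x(x, kind)
  if (stats::var(xt) == 0) {
    fit0 <- stats::glm(y ~ 1, family = stats::poisson())
    return(new_count_fit(kind, y, x,
                         c(intercept = unname(stats::coef(fit0)[1L]),
                           slope = NA_real_),
                         loglik = as.numeric(stats::logLik(fit0)), df = 1L,
                         converged = FALSE))
  }
  fit <- stats::glm(y ~ xt, family = stats::poisson())
  cf <- stats::coef(fit)
  new_count_fit(kind, y, x,
                c(intercept = unname(cf[1L]), slope = unname(cf[2L])),
                loglik = as.numeric(stats::logLik(fit)), df = 2L,
                converged = isTRUE(fit$converged),
                se_slope = sqrt(stats::vcov(fit)[2L, 2L]))
}

## safe objective wrapper: L-BFGS-B needs finite values
finite_or_big <- function(v) if (is.finite(v)) v else 1e12

negbin_negll <- function(par, y, x) {
  mu <- exp(par[1L] + par[2L] * x)
  finite_or_big(-sum(stats::dnbinom(y, size = exp(par[3L]), mu = mu,
                                    log = TRUE)))
}

moment_theta <- function(y) {
  m <- mean(y); v <- stats::var(y)
  th <- if (is.finite(v) && v > m && m > 0) m^2 / (v - m) else 10
  min(max(th, 0.05), 1e4)
}

#' @rdname fit_count_model
#' @export
fit_negbin <- function(y, x) {
  check_count_inputs(y, x)
  if (all(y == 0)) stop("all-zero outcome: negative-binomial inestimable")
  slope_ok <- stats::var(x) > 0
  x_use <- if (slope_ok) x else NULL
  nll <- if (slope_ok) {
    function(p) negbin_negll(p, y, x)
  } else {
    function(p) negbin_negll(c(p[1L], 0, p[2L]), y, x)
  }
  start_glm <- if (slope_ok) stats::glm(y ~ x, family = stats::poisson())
               else stats::glm(y ~ 1, family = stats::poisson())
  start <- c(stats::coef(start_glm), log(moment_theta(y)))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, length(start) - 1L), log(1e-4)),
                      upper = c(rep(Inf, length(start) - 1L), log(THETA_CAP)),
                      hessian = TRUE,
                      control = list(maxit = 500L, factr = 1e4))
  cap <- cap_flat_theta(opt, nll)
  opt <- cap$opt; theta <- cap$theta; capped <- cap$capped
  if (capped)
    warning("dispersion estimate at cap (", format(THETA_CAP),
            "): data look equidispersed, NB ~ Poisson")
  se_slope <- NA_real_
  if (slope_ok) {
    vc <- try(solve(opt$hessian), silent = TRUE)
    if (!inherits(vc, "try-error") && vc[2L, 2L] > 0)
      se_slope <- sqrt(vc[2L, 2L])
  }
  coefs <- if (slope_ok) c(intercept = unname(opt$par[1L]),
                           slope = unname(opt$par[2L]))
           else c(intercept = unname(opt$par[1L]), slope = NA_real_)
  new_count_fit("negbin", y, x, coefs, theta = theta,
                loglik = -opt$value, df = if (slope_ok) 3L else 2L,
                converged = slope_ok && (opt$convergence == 0L || capped),
                se_slope = se_slope, theta_capped = capped)
}

## Equidispersed data leave the likelihood flat in theta beyond some
## point, so the optimizer can halt anywhere on the plateau. If pushing
## theta to the cap costs (essentially) no likelihood, report the capped
## value so screening is stable across terms.
cap_flat_theta <- function(opt, nll) {
  j <- length(opt$par)
  theta <- exp(opt$par[[j]])
  capped <- theta >= THETA_CAP * (1 - 1e-6)
  if (!capped && theta >= 1e3) {
    par_cap <- opt$par
    par_cap[j] <- log(THETA_CAP)
    v <- nll(par_cap)
    if (v <= opt$value + 1e-3) {
      opt$par <- par_cap
      opt$value <- min(opt$value, v)
      theta <- THETA_CAP
      capped <- TRUE
    }
  }
  list(opt = opt, theta = theta, capped = capped)
}

#' Zero-truncated negative-binomial log-pmf
#'
#' \eqn{\log[f_{NB}(y; \mu, \theta) / (1 - f_{NB}(0; \mu, \theta))]} for
#' \eqn{y \ge 1}, computed via `log1p`/`expm1` so the renormalisation is
#' stable whether the zero mass is near 0 or near 1.
#'
#' @param y positive integer vector.
#' @param mu positive mean of the untruncated NB.
#' @param theta positive dispersion (NB2: `Var = mu + mu^2/theta`).
#' @return numeric vector of log-probabilities.
#' @export
truncated_nb_logpmf <- function(y, mu, theta) {
  if (any(y < 1) || any(y != round(y)))
    stop("truncated support is y >= 1")
  stopifnot(all(mu > 0), all(theta > 0))
  lp0 <- -theta * log1p(mu / theta)   # log P(Y = 0)
  stats::dnbinom(y, size = theta, mu = mu, log = TRUE) - log1mexp(-lp0)
}

## log(1 - exp(-a)) for a > 0, split at log 2 to avoid cancellation
log1mexp <- function(a) {
  ifelse(a < log(2), log(-expm1(-a)), log1p(-exp(-a)))
}

truncnb_negll <- function(par, y, x) {
  mu <- exp(par[1L] + par[2L] * x)
  finite_or_big(-sum(truncated_nb_logpmf(y, mu, exp(par[3L]))))
}

#' @rdname fit_count_model
#' @export
fit_hurdle_nb <- function(y, x) {
  check_count_inputs(y, x)
  pos <- y > 0
  if (!any(pos)) stop("no positive counts: hurdle count component inestimable")
  if (all(pos)) stop("no zero counts: hurdle zero component inestimable")
  z <- as.integer(pos)
  slope_ok <- stats::var(x) > 0 && stats::var(x[pos]) > 0

  ## zero component: logistic model for positive vs zero
  zero_sep <- FALSE
  zfit <- withCallingHandlers(
    if (slope_ok) stats::glm(z ~ x, family = stats::binomial())
    else stats::glm(z ~ 1, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        zero_sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  zcf <- stats::coef(zfit)
  zero_coefs <- c(intercept = unname(zcf[1L]),
                  slope = if (slope_ok) unname(zcf[2L]) else NA_real_)
  ll_zero <- as.numeric(stats::logLik(zfit))
  se_zero <- if (slope_ok) sqrt(stats::vcov(zfit)[2L, 2L]) else NA_real_

  ## count component: zero-truncated NB on the positives
  yp <- y[pos]; xp <- x[pos]
  nll <- if (slope_ok) {
    function(p) truncnb_negll(p, yp, xp)
  } else {
    function(p) truncnb_negll(c(p[1L], 0, p[2L]), yp, xp)
  }
  start_glm <- if (slope_ok) stats::glm(yp ~ xp, family = stats::poisson())
               else stats::glm(yp ~ 1, family = stats::poisson())
  start <- c(stats::coef(start_glm), log(moment_theta(yp)))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, length(start) - 1L), log(1e-4)),
                      upper = c(rep(Inf, length(start) - 1L), log(THETA_CAP)),
                      hessian = TRUE,
                      control = list(maxit = 500L, factr = 1e4))
  cap <- cap_flat_theta(opt, nll)
  opt <- cap$opt; theta <- cap$theta; capped <- cap$capped
  if (capped)
    warning("hurdle count dispersion at cap: positives look equidispersed")
  se_slope <- NA_real_
  if (slope_ok) {
    vc <- try(solve(opt$hessian), silent = TRUE)
    if (!inherits(vc, "try-error") && vc[2L, 2L] > 0)
      se_slope <- sqrt(vc[2L, 2L])
  }
  coefs <- if (slope_ok) c(intercept = unname(opt$par[1L]),
                           slope = unname(opt$par[2L]))
           else c(intercept = unname(opt$par[1L]), slope = NA_real_)
  ll_count <- -opt$value
  new_count_fit("hurdle_nb", y, x, coefs, zero_coefs = zero_coefs,
                theta = theta, loglik = ll_zero + ll_count,
                df = if (slope_ok) 5L else 3L,
                converged = slope_ok && (opt$convergence == 0L || capped) &&
                  zfit$converged && !zero_sep,
                se_slope = se_slope, loglik_zero = ll_zero,
                loglik_count = ll_count, se_zero_slope = se_zero,
                theta_capped = capped)
}

#' Relative risk of a fitted count model
#'
#' The exponentiated count-component slope, with its log-scale standard
#' error and Wald p-value, packaged as a one-row term-weight table. A
#' non-converged fit (e.g. constant predictor) yields an absent (`NA`)
#' weight.
#'
#' @param fit an `ais_count_fit`.
#' @param term label for the `term` column (default `"x"`).
#' @return one-row data frame with columns `term`, `weight`, `std_err`
#'   (standard error of the log-weight, i.e. of the slope), `p_value`
#'   (Wald), `converged`, `source`.
#' @export
relative_risk <- function(fit, term = "x") {
  stopifnot(inherits(fit, "ais_count_fit"))
  src <- switch(fit$model_kind,
                hurdle_nb = "hurdle_count", negbin = "negbin", "poisson")
  ok <- isTRUE(fit$converged) && is.finite(fit$count_coefs[["slope"]])
  data.frame(term = term,
             weight = if (ok) exp(fit$count_coefs[["slope"]]) else NA_real_,
             std_err = if (ok) fit$se_slope else NA_real_,
             p_value = if (ok) fit$p_slope else NA_real_,
             converged = ok, source = src, stringsAsFactors = FALSE)
}

#' Screen every DTM term with a univariate count model
#'
#' Fits one univariate model per vocabulary term (predictor = that term's
#' frequency column) against the count outcome and collects the
#' relative-risk weights. Per-term failures (constant column, optimizer
#' breakdown) are recorded as absent weights, never raised, so a screen
#' over hundreds of terms always completes.
#'
#' @param dtm a (typically sparse-filtered) `ais_dtm`.
#' @param y count outcome aligned with the DTM rows.
#' @param model_kind passed to [fit_count_model()]; default `"hurdle_nb"`.
#' @return data frame of term weights in vocabulary order (columns as
#'   [relative_risk()]).
#' @export
screen_terms_count <- function(dtm, y, model_kind = "hurdle_nb") {
  stopifnot(inherits(dtm, "ais_dtm"))
  if (length(y) != nrow(dtm$counts))
    stop("outcome length does not match DTM rows")
  rows <- lapply(seq_along(dtm$terms), function(j) {
    x <- as.numeric(dtm$counts[, j])
    res <- tryCatch(
      suppressWarnings(relative_risk(fit_count_model(y, x, model_kind),
                                     term = dtm$terms[j])),
      error = function(e) failed_weight(dtm$terms[j], model_kind))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

failed_weight <- function(term, model_kind) {
  src <- switch(model_kind,
                hurdle_nb = "hurdle_count", negbin = "negbin",
                logistic = "logistic", "poisson")
  data.frame(term = term, weight = NA_real_, std_err = NA_real_,
             p_value = NA_real_, converged = FALSE, source = src,
             stringsAsFactors = FALSE)
}

#' Write a term-weight table to CSV
#'
#' @param weights data frame from [screen_terms_count()] or
#'   [screen_terms_logistic()].
#' @param path output CSV path.
#' @export
write_weights_csv <- function(weights, path) {
  utils::write.csv(weights, path, row.names = FALSE)
  invisible(path)
}
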