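## S3 methods shared by the fitted-model classes.

## linear predictor on the count scale; a missing slope means the model
## was refit intercept-only
count_linpred <- function(fit, x) {
  b <- fit$count_coefs
  slope <- if (is.finite(b[["slope"]])) b[["slope"]] else 0
  b[["intercept"]] + slope * transform_x(x, fit$model_kind)
}

zero_linpred <- function(fit, x) {
  g <- fit$zero_coefs
  slope <- if (is.finite(g[["slope"]])) g[["slope"]] else 0
  g[["intercept"]] + slope * x
}

## P(y = c) for each observation (rows) and count value (columns)
prob_matrix <- function(fit, counts, x = fit$x) {
  stopifnot(inherits(fit, "ais_count_fit"))
  mu <- exp(count_linpred(fit, x))
  kind <- fit$model_kind
  if (kind == "hurdle_nb") {
    pi_pos <- stats::plogis(zero_linpred(fit, x))
    lp0 <- -fit$theta * log1p(mu / fit$theta)
    out <- vapply(counts, function(cc) {
      if (cc == 0) 1 - pi_pos
      else pi_pos * exp(stats::dnbinom(cc, size = fit$theta, mu = mu,
                                       log = TRUE) - log1mexp(-lp0))
    }, numeric(length(mu)))
  } else if (kind == "negbin") {
    out <- vapply(counts, function(cc)
      stats::dnbinom(cc, size = fit$theta, mu = mu), numeric(length(mu)))
  } else {
    out <- vapply(counts, function(cc) stats::dpois(cc, mu),
                  numeric(length(mu)))
  }
  matrix(out, nrow = length(mu), ncol = length(counts),
         dimnames = list(NULL, counts))
}

#' @export
coef.ais_count_fit <- function(object, ...) {
  out <- c(count_intercept = unname(object$count_coefs[["intercept"]]),
           count_slope = unname(object$count_coefs[["slope"]]))
  if (!is.null(object$zero_coefs))
    out <- c(out, zero_intercept = unname(object$zero_coefs[["intercept"]]),
             zero_slope = unname(object$zero_coefs[["slope"]]))
  if (is.finite(object$theta)) out <- c(out, theta = object$theta)
  out
}

#' @export
coef.ais_logit_fit <- function(object, ...) object$coefficients

#' @export
logLik.ais_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
print.ais_count_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Univariate %s count model (n = %d)\n", x$model_kind, x$n_obs))
  cat("  count component: intercept =",
      format(x$count_coefs[["intercept"]], digits = digits),
      " slope =", format(x$count_coefs[["slope"]], digits = digits), "\n")
  if (!is.null(x$zero_coefs))
    cat("  zero component:  intercept =",
        format(x$zero_coefs[["intercept"]], digits = digits),
        " slope =", format(x$zero_coefs[["slope"]], digits = digits), "\n")
  if (is.finite(x$theta))
    cat("  dispersion theta =", format(x$theta, digits = digits),
        if (isTRUE(x$theta_capped)) "(capped)" else "", "\n")
  cat(sprintf("  logLik = %.4f  AIC = %.4f  converged = %s\n",
              x$loglik, x$aic, x$converged))
  invisible(x)
}

#' @export
print.ais_logit_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Univariate logistic model (n = %d)\n", x$n_obs))
  cat("  intercept =", format(x$coefficients[["intercept"]], digits = digits),
      " slope =", format(x$coefficients[["slope"]], digits = digits), "\n")
  cat(sprintf("  logLik = %.4f  AIC = %.4f  converged = %s\n",
              x$loglik, x$aic, x$converged))
  invisible(x)
}

#' @export
summary.ais_fit <- function(object, ...) {
  slope <- if (inherits(object, "ais_count_fit"))
    object$count_coefs[["slope"]] else object$coefficients[["slope"]]
  structure(
    list(fit = object, slope = slope, se_slope = object$se_slope,
         p_slope = object$p_slope,
         ratio = if (is.finite(slope)) exp(slope) else NA_real_,
         ratio_label = if (inherits(object, "ais_count_fit")) "RR" else "OR"),
    class = "summary.ais_fit")
}

#' @export
print.summary.ais_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  slope = %s (SE %s), %s = %s, Wald p = %s\n",
              format(x$slope, digits = digits),
              format(x$se_slope, digits = digits),
              x$ratio_label, format(x$ratio, digits = digits),
              format(x$p_slope, digits = digits)))
  invisible(x)
}

#' Predictions from a fitted count model
#'
#' @param object an `ais_count_fit`.
#' @param newdata predictor values (defaults to the training predictor).
#' @param type `"response"` for the unconditional mean \eqn{E[y]} (for
#'   hurdle fits \eqn{P(y>0)} times the zero-truncated mean) or
#'   `"zero_prob"` for \eqn{P(y = 0)}.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.ais_count_fit <- function(object, newdata = NULL,
                                  type = c("response", "zero_prob"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x else newdata
  mu <- exp(count_linpred(object, x))
  if (object$model_kind == "hurdle_nb") {
    pi_pos <- stats::plogis(zero_linpred(object, x))
    if (type == "zero_prob") return(1 - pi_pos)
    p0 <- exp(-object$theta * log1p(mu / object$theta))
    return(pi_pos * mu / (1 - p0))
  }
  if (type == "zero_prob") {
    if (object$model_kind == "negbin")
      return(exp(-object$theta * log1p(mu / object$theta)))
    return(exp(-mu))
  }
  mu
}

#' @export
predict.ais_logit_fit <- function(object, newdata = NULL,
                                  type = "response", ...) {
  x <- if (is.null(newdata)) object$x else newdata
  b <- object$coefficients
  slope <- if (is.finite(b[["slope"]])) b[["slope"]] else 0
  stats::plogis(b[["intercept"]] + slope * x)
}

#' @export
fitted.ais_fit <- function(object, ...) predict(object)

#' @export
residuals.ais_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - predict(object)
  if (type == "response") return(r)
  mu <- predict(object)
  v <- switch(object$model_kind,
              negbin = mu + mu^2 / object$theta,
              logistic = mu * (1 - mu),
              mu)   # poisson variants and hurdle: mean-scale denominator
  r / sqrt(v)
}

#' Simulate responses from a fitted count model
#'
#' @param object an `ais_count_fit`.
#' @param nsim number of replicate response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame of `nsim` simulated response columns.
#' @export
simulate.ais_count_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  x <- object$x
  mu <- exp(count_linpred(object, x))
  one <- switch(object$model_kind,
    hurdle_nb = function() {
      pos <- stats::rbinom(length(x), 1, stats::plogis(zero_linpred(object, x)))
      y <- integer(length(x))
      if (any(pos == 1))
        y[pos == 1] <- rztnbinom(sum(pos == 1), mu[pos == 1], object$theta)
      y
    },
    negbin = function() stats::rnbinom(length(x), size = object$theta, mu = mu),
    function() stats::rpois(length(x), mu))
  out <- as.data.frame(replicate(nsim, one()))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.ais_count_fit <- function(x, max_count = max(x$y), ...) {
  plot(rootogram(x, max_count = max_count), ...)
}
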