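#' Fit a univariate logistic model
#'
#' Maximum-likelihood logistic regression of a binary outcome on a single
#' predictor: \eqn{\log(\pi / (1-\pi)) = \beta_0 + \beta_1 x}. The
#' exponentiated slope is the odds ratio (OR) used as a term's
#' classification weight.
#'
#' @param y 0/1 vector; both classes must be present.
#' @param x numeric predictor of the same length.
#' @return object of class `c("ais_logit_fit", "ais_fit")` with
#'   `coefficients` (intercept, slope), `loglik`, `df`, `aic`,
#'   `converged` (`FALSE` under complete separation or a constant
#'   predictor), `se_slope`, `p_slope`, `n_obs` and the data.
#' @export
fit_logistic <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have the same length")
  if (anyNA(y) || anyNA(x)) stop("missing values not allowed")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  slope_ok <- stats::var(x) > 0
  separated <- FALSE
  fit <- withCallingHandlers(
    if (slope_ok) stats::glm(y ~ x, family = stats::binomial())
    else stats::glm(y ~ 1, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
        warning("possible complete separation: slope estimate diverging",
                call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  coefs <- c(intercept = unname(cf[1L]),
             slope = if (slope_ok) unname(cf[2L]) else NA_real_)
  se <- if (slope_ok) sqrt(stats::vcov(fit)[2L, 2L]) else NA_real_
  ll <- as.numeric(stats::logLik(fit))
  df <- if (slope_ok) 2L else 1L
  p <- if (slope_ok && is.finite(se) && se > 0) {
    2 * stats::pnorm(-abs(coefs[["slope"]] / se))
  } else NA_real_
  structure(
    list(model_kind = "logistic", coefficients = coefs, loglik = ll,
         df = df, aic = 2 * df - 2 * ll,
         converged = slope_ok && fit$converged && !separated,
         se_slope = se, p_slope = p, n_obs = length(y), y = y, x = x),
    class = c("ais_logit_fit", "ais_fit"))
}

#' Odds ratio of a fitted logistic model
#'
#' Exponentiated slope with log-scale standard error and Wald p-value, as
#' a one-row term-weight table; absent (`NA`) when the fit did not
#' converge.
#'
#' @param fit an `ais_logit_fit`.
#' @param term label for the `term` column.
#' @return one-row data frame with columns `term`, `weight`, `std_err`,
#'   `p_value`, `converged`, `source`.
#' @export
odds_ratio <- function(fit, term = "x") {
  stopifnot(inherits(fit, "ais_logit_fit"))
  ok <- isTRUE(fit$converged) && is.finite(fit$coefficients[["slope"]])
  data.frame(term = term,
             weight = if (ok) exp(fit$coefficients[["slope"]]) else NA_real_,
             std_err = if (ok) fit$se_slope else NA_real_,
             p_value = if (ok) fit$p_slope else NA_real_,
             converged = ok, source = "logistic", stringsAsFactors = FALSE)
}

#' Screen DTM terms with univariate logistic models
#'
#' Fits one logistic model per term against a binary topic label and
#' collects the odds-ratio weights. The vocabulary is restricted to terms
#' present at least once in *each* class (`shared_only = TRUE`, the
#' default): terms exclusive to one class are degenerate for a merged
#' two-topic corpus and invite complete separation. Per-term failures are
#' recorded as absent weights.
#'
#' @param dtm an `ais_dtm` built from the merged two-class corpus (after
#'   sparse filtering).
#' @param labels 0/1 class labels aligned with DTM rows.
#' @param shared_only restrict to terms occurring in both classes.
#' @return data frame of term weights (columns as [odds_ratio()]) for the
#'   retained vocabulary, in vocabulary order.
#' @export
screen_terms_logistic <- function(dtm, labels, shared_only = TRUE) {
  stopifnot(inherits(dtm, "ais_dtm"))
  if (length(labels) != nrow(dtm$counts))
    stop("labels length does not match DTM rows")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  keep <- rep(TRUE, length(dtm$terms))
  if (shared_only && length(dtm$terms)) {
    in1 <- doc_frequencies(dtm$counts[labels == 1, , drop = FALSE]) > 0
    in0 <- doc_frequencies(dtm$counts[labels == 0, , drop = FALSE]) > 0
    keep <- in1 & in0
  }
  terms <- dtm$terms[keep]
  rows <- lapply(which(keep), function(j) {
    x <- as.numeric(dtm$counts[, j])
    tryCatch(
      suppressWarnings(odds_ratio(fit_logistic(labels, x),
                                  term = dtm$terms[j])),
      error = function(e) failed_weight(dtm$terms[j], "logistic"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- failed_weight(character(), "logistic")[0, ]
  rownames(out) <- NULL
  out
}
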