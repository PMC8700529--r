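## Final-model evaluation and diagnostics: count models on the AIS,
## expected-zeros difference, hanging rootograms, Kruskal-Wallis tests and
## ROC/AUC with a Youden-optimal cutoff.

#' Fit the final count model on the aggregated score
#'
#' Regresses the count outcome on a single AIS column, after dropping
#' documents with a missing score (documents that contained no weighted
#' term).
#'
#' @param ais numeric AIS vector (may contain `NA`).
#' @param y count outcome aligned with `ais`.
#' @param model_kind passed to [fit_count_model()].
#' @return an `ais_count_fit`; the number of dropped documents is attached
#'   as attribute `n_dropped`.
#' @export
fit_final_count <- function(ais, y, model_kind = "hurdle_nb") {
  if (length(ais) != length(y)) stop("ais and y must have the same length")
  keep <- is.finite(ais)
  fit <- fit_count_model(y[keep], ais[keep], model_kind)
  attr(fit, "n_dropped") <- sum(!keep)
  fit
}

#' Observed minus model-expected number of zeros
#'
#' \eqn{D = \#\{y_i = 0\} - \sum_i \hat P(y_i = 0)}. A hurdle fit returns
#' 0 up to numerical noise: its logistic zero component reproduces the
#' observed zero total by construction (the score equations of a logistic
#' model with an intercept force the fitted probabilities to sum to the
#' observed successes). Poisson and NB fits under-predict zeros on
#' zero-heavy data, giving negative `D`.
#'
#' @param fit an `ais_count_fit`.
#' @param y the outcome the model was fitted to (defaults to the stored
#'   one).
#' @return numeric scalar.
#' @export
expected_zeros_diff <- function(fit, y = fit$y) {
  stopifnot(inherits(fit, "ais_count_fit"))
  sum(y == 0) - sum(predict(fit, type = "zero_prob"))
}

#' Hanging rootogram data for a count-model fit
#'
#' For each count value `c` in `0..max_count` compares the observed
#' frequency with the model-expected frequency
#' \eqn{\sum_i \hat P(y_i = c)} on the square-root scale; in the hanging
#' style each observed bar is suspended from the expected curve, so bars
#' failing to reach zero expose mis-fit (excess zeros, heavy tails).
#'
#' @param fit an `ais_count_fit`.
#' @param y outcome vector (defaults to the one stored in the fit).
#' @param max_count largest count bin; defaults to `max(y)` capped at 50
#'   for display sanity.
#' @return data frame of class `ais_rootogram` with columns `count`,
#'   `observed`, `expected`, `sqrt_observed`, `sqrt_expected`,
#'   `hang_bottom` (`sqrt_expected - sqrt_observed`).
#' @export
rootogram <- function(fit, y = fit$y, max_count = min(max(y), 50L)) {
  stopifnot(inherits(fit, "ais_count_fit"), max_count >= 0)
  bins <- 0:max_count
  obs <- vapply(bins, function(cc) sum(y == cc), numeric(1))
  expd <- colSums(prob_matrix(fit, bins))
  out <- data.frame(count = bins, observed = obs, expected = expd,
                    sqrt_observed = sqrt(obs), sqrt_expected = sqrt(expd),
                    hang_bottom = sqrt(expd) - sqrt(obs))
  class(out) <- c("ais_rootogram", "data.frame")
  out
}

#' @export
plot.ais_rootogram <- function(x, main = "Hanging rootogram",
                               xlab = "count", ylab = "sqrt(frequency)",
                               ...) {
  ylim <- range(0, x$sqrt_expected, x$hang_bottom)
  graphics::plot(x$count, x$sqrt_expected, type = "l", lwd = 2, col = "red3",
                 ylim = ylim, main = main, xlab = xlab, ylab = ylab, ...)
  graphics::rect(x$count - 0.4, x$hang_bottom, x$count + 0.4,
                 x$sqrt_expected, col = "grey80")
  graphics::lines(x$count, x$sqrt_expected, lwd = 2, col = "red3")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Kruskal-Wallis rank-sum test between two score groups
#'
#' Tie-corrected rank-sum test of whether the AIS distribution differs
#' between the two classes (for two groups this is the chi-square form of
#' the Wilcoxon rank-sum test, 1 degree of freedom).
#'
#' @param scores numeric vector.
#' @param groups 0/1 group indicator.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(scores, groups) {
  if (length(scores) != length(groups))
    stop("scores and groups must have the same length")
  g <- factor(groups)
  if (nlevels(g) < 2L || any(table(g) == 0L))
    stop("both groups must be non-empty")
  kt <- stats::kruskal.test(scores, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' ROC analysis of a score against binary labels
#'
#' Empirical ROC over all distinct score thresholds with trapezoidal AUC
#' (equal to the Mann-Whitney probability with ties given half credit),
#' and the Youden-optimal cutoff (maximal sensitivity + specificity - 1,
#' ties broken toward the smaller cutoff). Computed with \pkg{pROC}.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 labels (1 = positive class); both classes required.
#' @param direction `"higher_is_positive"`, `"lower_is_positive"`, or
#'   `"auto"` (choose the direction giving AUC >= 0.5 and report it).
#' @return list of class `ais_roc`: `thresholds`, `sensitivity`,
#'   `specificity` (aligned vectors), `auc`, `best_cutoff`, `best_sens`,
#'   `best_spec`, `direction` (the direction used), `degenerate` (`TRUE`
#'   for constant scores, where AUC is 0.5 by convention).
#' @export
roc_analysis <- function(scores, labels,
                         direction = c("higher_is_positive",
                                       "lower_is_positive", "auto")) {
  direction <- match.arg(direction)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (anyNA(scores)) stop("scores must not contain NA")
  if (stats::var(scores) == 0) {
    return(structure(list(thresholds = numeric(), sensitivity = numeric(),
                          specificity = numeric(), auc = 0.5,
                          best_cutoff = NA_real_, best_sens = NA_real_,
                          best_spec = NA_real_, direction = direction,
                          degenerate = TRUE),
                     class = "ais_roc"))
  }
  dir_proc <- switch(direction, higher_is_positive = "<",
                     lower_is_positive = ">", auto = "auto")
  r <- pROC::roc(response = labels, predictor = scores,
                 direction = dir_proc, levels = c(0, 1), quiet = TRUE)
  co <- pROC::coords(r, "all", ret = c("threshold", "sensitivity",
                                       "specificity"), transpose = FALSE)
  ord <- order(co$threshold)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  if (nrow(best) > 1L) best <- best[which.min(best$threshold), , drop = FALSE]
  used_dir <- if (r$direction == "<") "higher_is_positive"
              else "lower_is_positive"
  structure(list(thresholds = co$threshold[ord],
                 sensitivity = co$sensitivity[ord],
                 specificity = co$specificity[ord],
                 auc = as.numeric(pROC::auc(r)),
                 best_cutoff = best$threshold[1L],
                 best_sens = best$sensitivity[1L],
                 best_spec = best$specificity[1L],
                 direction = used_dir, degenerate = FALSE),
            class = "ais_roc")
}

#' @export
print.ais_roc <- function(x, digits = 4, ...) {
  cat(sprintf("ROC analysis (%s%s)\n", x$direction,
              if (x$degenerate) ", degenerate: constant scores" else ""))
  cat(sprintf("  AUC = %.4f\n", x$auc))
  if (!x$degenerate)
    cat(sprintf("  Youden cutoff = %.4f (sens %.4f, spec %.4f)\n",
                x$best_cutoff, x$best_sens, x$best_spec))
  invisible(x)
}

#' @export
plot.ais_roc <- function(x, main = "ROC curve", ...) {
  o <- order(1 - x$specificity, x$sensitivity)
  graphics::plot(c(0, (1 - x$specificity)[o], 1),
                 c(0, x$sensitivity[o], 1), type = "l", lwd = 2,
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = main, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write a ROC table to CSV
#'
#' @param roc an `ais_roc`.
#' @param path output CSV path.
#' @export
write_roc_csv <- function(roc, path) {
  utils::write.csv(data.frame(threshold = roc$thresholds,
                              sensitivity = roc$sensitivity,
                              specificity = roc$specificity),
                   path, row.names = FALSE)
  invisible(path)
}
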