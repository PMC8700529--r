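## End-to-end pipelines for the two case studies: popularity modelling of
## a count outcome (case I) and two-topic classification (case II). All
## intermediate artifacts are plain CSV/JSON so the stages compose across
## processes; the thin command-line wrapper in inst/cli drives these
## functions.

#' Pipeline configuration
#'
#' @param input CSV path or a data frame in the [read_corpus_csv()]
#'   output schema.
#' @param text_col,count_col,label_col,id_col column names in the input
#'   (ignored when `input` is already standardised).
#' @param topic_words topic/query words stripped during cleaning.
#' @param drop_hashtags,stem passed to [clean_corpus()].
#' @param k sparse-term threshold for [filter_sparse()] (study default
#'   500; scale it to the corpus size).
#' @param model_kind count model for the popularity case (default
#'   `"hurdle_nb"`).
#' @param summaries which AIS variants to evaluate.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in the summary (the pipeline itself
#'   is deterministic given its input).
#' @param quiet suppress progress messages (stderr).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, text_col = "text", count_col = NULL,
                            label_col = NULL, id_col = NULL,
                            topic_words = character(), drop_hashtags = TRUE,
                            stem = c("none", "light"), k = 500,
                            model_kind = "hurdle_nb",
                            summaries = c("mean", "median", "sum"),
                            out_dir = tempfile("ais_run_"), seed = 1L,
                            quiet = FALSE) {
  stopifnot(k >= 0)
  model_kind <- match.arg(model_kind, c("hurdle_nb", "negbin",
                                        "poisson_loglinear", "poisson_loglog"))
  summaries <- match.arg(summaries, c("mean", "median", "sum"),
                         several.ok = TRUE)
  structure(list(input = input, text_col = text_col, count_col = count_col,
                 label_col = label_col, id_col = id_col,
                 topic_words = topic_words, drop_hashtags = drop_hashtags,
                 stem = match.arg(stem), k = k, model_kind = model_kind,
                 summaries = summaries, out_dir = out_dir,
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

say <- function(config, ...) {
  if (!config$quiet) message(...)
}

load_config_input <- function(config, need_count = FALSE,
                              need_label = FALSE) {
  raw <- if (is.data.frame(config$input)) {
    config$input
  } else {
    read_corpus_csv(config$input, text_col = config$text_col,
                    count_col = config$count_col,
                    label_col = config$label_col, id_col = config$id_col)
  }
  if (need_count && !"outcome_count" %in% names(raw))
    stop("pipeline needs a count outcome column (count_col)")
  if (need_label && !"topic_label" %in% names(raw))
    stop("pipeline needs a binary label column (label_col)")
  raw
}

prepare_dtm <- function(config, raw) {
  say(config, "documents: ", nrow(raw))
  docs <- clean_corpus(raw, topic_words = config$topic_words,
                       drop_hashtags = config$drop_hashtags,
                       stem = config$stem)
  dtm <- build_dtm(docs)
  say(config, "terms before filtering: ", length(dtm$terms))
  dtm <- filter_sparse(dtm, config$k)
  say(config, "terms after filtering (doc freq > ", config$k, "): ",
      length(dtm$terms))
  if (length(dtm$terms) == 0L)
    stop("empty vocabulary after sparse-term filtering; lower k")
  dtm
}

#' Run the popularity (count-outcome) case study
#'
#' Clean, build and filter the DTM, screen every term with a univariate
#' count model, aggregate the relative risks into AIS scores, refit the
#' count model with each AIS variant as the sole predictor, and write the
#' diagnostics (expected-zeros difference, rootogram data).
#'
#' Artifacts in `out_dir`: `term_weights.csv`, `ais.csv`,
#' `case_popularity_summary.json`, and per-variant
#' `rootogram_<variant>.csv`.
#'
#' @param config a [pipeline_config()] whose input has a count outcome.
#' @return invisibly, a list with the weights, AIS table, fits and the
#'   summary list.
#' @export
run_case_popularity <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  raw <- load_config_input(config, need_count = TRUE)
  dtm <- prepare_dtm(config, raw)
  y <- join_outcomes(dtm, raw)$outcome_count

  say(config, "screening ", length(dtm$terms), " terms with ",
      config$model_kind, " models")
  weights <- screen_terms_count(dtm, y, config$model_kind)
  write_weights_csv(weights, file.path(config$out_dir, "term_weights.csv"))

  ais <- score_corpus(dtm, weights)
  write_ais_csv(ais, file.path(config$out_dir, "ais.csv"))
  n_missing <- sum(!is.finite(ais$ais_mean))
  say(config, "documents without any weighted term (AIS missing): ",
      n_missing)

  fits <- list(); summary <- list()
  for (v in config$summaries) {
    s <- ais[[paste0("ais_", v)]]
    fit <- suppressWarnings(fit_final_count(s, y, config$model_kind))
    fits[[v]] <- fit
    rg <- rootogram(fit)
    utils::write.csv(as.data.frame(rg)[, c("count", "observed", "expected")],
                     file.path(config$out_dir,
                               paste0("rootogram_", v, ".csv")),
                     row.names = FALSE)
    rr <- relative_risk(fit, term = paste0("ais_", v))
    summary[[v]] <- list(model_kind = config$model_kind,
                         rr = rr$weight, se_log_rr = rr$std_err,
                         p_value = rr$p_value, aic = fit$aic,
                         loglik = fit$loglik,
                         expected_zeros_diff = expected_zeros_diff(fit),
                         n_used = fit$n_obs,
                         n_dropped = attr(fit, "n_dropped"))
  }
  out <- list(n_documents = nrow(raw), n_terms = length(dtm$terms),
              n_ais_missing = n_missing, k = config$k, seed = config$seed,
              models = summary)
  jsonlite::write_json(out,
                       file.path(config$out_dir,
                                 "case_popularity_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(weights = weights, ais = ais, fits = fits, summary = out))
}

#' Run the topic-classification case study
#'
#' Clean and filter the merged two-topic corpus, screen shared terms with
#' univariate logistic models, aggregate the odds ratios into AIS scores,
#' then evaluate each variant with a Kruskal-Wallis test and ROC analysis
#' (including the reciprocal of the AIS-sum, whose raw direction is
#' inverted when the control vocabulary carries more sub-unit weights).
#'
#' Artifacts in `out_dir`: `term_weights.csv`, `ais.csv`, per-variant
#' `roc_<variant>.csv` and `case_classification_summary.json`.
#'
#' @param config a [pipeline_config()] whose input has a 0/1 label.
#' @return invisibly, a list with the weights, AIS table, ROC objects and
#'   the summary list.
#' @export
run_case_classification <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  raw <- load_config_input(config, need_label = TRUE)
  dtm <- prepare_dtm(config, raw)
  labels <- join_outcomes(dtm, raw)$topic_label

  say(config, "screening shared terms with logistic models")
  weights <- screen_terms_logistic(dtm, labels)
  say(config, "shared terms screened: ", nrow(weights))
  write_weights_csv(weights, file.path(config$out_dir, "term_weights.csv"))

  ais <- score_corpus(dtm, weights)
  ais$topic_label <- labels
  write_ais_csv(ais, file.path(config$out_dir, "ais.csv"))

  rocs <- list(); summary <- list()
  variants <- c(config$summaries,
                if ("sum" %in% config$summaries) "reciprocal_sum")
  for (v in variants) {
    s <- if (v == "reciprocal_sum") 1 / ais$ais_sum
         else ais[[paste0("ais_", v)]]
    keep <- is.finite(s)
    kw <- kruskal_wallis(s[keep], labels[keep])
    roc <- roc_analysis(s[keep], labels[keep])
    rocs[[v]] <- roc
    write_roc_csv(roc, file.path(config$out_dir, paste0("roc_", v, ".csv")))
    summary[[v]] <- list(auc = roc$auc, cutoff = roc$best_cutoff,
                         sensitivity = roc$best_sens,
                         specificity = roc$best_spec,
                         direction = roc$direction,
                         kw_statistic = kw$statistic,
                         kw_p_value = kw$p_value,
                         n_used = sum(keep), n_dropped = sum(!keep))
  }
  out <- list(n_documents = nrow(raw), n_terms = length(dtm$terms),
              n_shared_terms = nrow(weights), k = config$k,
              seed = config$seed, scores = summary)
  jsonlite::write_json(out,
                       file.path(config$out_dir,
                                 "case_classification_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(weights = weights, ais = ais, rocs = rocs, summary = out))
}
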