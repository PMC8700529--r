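# aisglm

Aggregated influence scores (AIS) for short-text regression and
classification.

## The problem

Short documents — tweets, message snippets, free-text fields — yield
document-term matrices that are wide, sparse and hostile to ordinary
regression: hundreds of term columns, most of them zero almost
everywhere. `aisglm` implements a screening-and-aggregation approach
aimed at applied health/epidemiology analysts who are comfortable with
GLMs but not with heavy text-mining machinery:

1. **Screen.** Each retained term gets a *univariate* GLM against the
   outcome: a hurdle negative-binomial (or NB / Poisson) model for a
   count outcome such as retweets, or a logistic model for a binary topic
   label. The exponentiated slope is the term's weight — a relative risk
   (RR = e^β̂) or odds ratio (OR = e^β̂₁).
2. **Aggregate.** A document containing weighted terms *i* = 1..*k* with
   frequencies *nᵢ* and weights *wᵢ* is summarised by

   - AIS-mean = Σ nᵢwᵢ / Σ nᵢ
   - AIS-median = median of the multiset with *wᵢ* replicated *nᵢ* times
   - AIS-sum = Σ nᵢwᵢ

3. **Model.** The AIS becomes the sole predictor of a final count model
   (popularity) or logistic classifier (topic), with diagnostics: hanging
   rootograms, the expected-zeros difference *D* (exactly 0 for hurdle
   fits, structurally), Kruskal–Wallis tests and ROC/AUC with a
   Youden-optimal cutoff.

The package also ships a deterministic tweet-style text cleaner, a
sparse-term DTM builder (Matrix-backed, MTX import/export), a seeded
synthetic-corpus generator with planted term effects for end-to-end
validation, and two pipeline drivers with a thin command-line wrapper
(`inst/cli/ais-pipeline.R`).

## Worked example

The canonical single-tweet example: after cleaning, the tweet
*"Father takes his child with #Autism to see his favorite band
Coldplay"* becomes
`father take his child with to see his favorite band coldplay`;
three of its words survive the sparse-term filter, with hurdle-model
relative risks take = 3.6210, child = 4.3122, see = 4.529, each
occurring once.

```r
library(aisglm)
fx  <- worked_example_fixture()
dtm <- build_dtm(setNames(list(fx$doc$tokens), fx$doc$doc_id))
score_corpus(dtm, fx$weights)
#>         doc_id ais_mean ais_median ais_sum n_terms_used
#>  example_tweet 4.154067     4.3122 12.4622            3
```

AIS-mean 4.1541 (4 d.p.), AIS-median 4.3122 (the middle of the three
sorted weights), AIS-sum 12.4622: the document's terms multiply expected
retweets roughly four-fold each on average.

On a synthetic corpus with a planted term effect (log-RR 0.7 on the term
"child"), the univariate hurdle screen recovers it:

```r
corp <- generate_corpus(corpus_spec(seed = 1))   # 5000 documents
dtm  <- filter_sparse(build_dtm(clean_corpus(corp)), 25)
y    <- join_outcomes(dtm, corp)$outcome_count
fit  <- fit_hurdle_nb(y, as.numeric(dtm$counts[, "child"]))
summary(fit)
#> Univariate hurdle_nb count model (n = 5000)
#>   count component: intercept = 0.2342  slope = 0.7654
#>   zero component:  intercept = -0.2857  slope = 0.5677
#>   dispersion theta = 1.704
#>   logLik = -6931.4415  AIC = 13872.8829  converged = TRUE
#>   slope = 0.7654 (SE 0.05631), RR = 2.15, Wald p = 4.46e-42
expected_zeros_diff(fit)
#> [1] 4.547474e-13
```

The estimated slope 0.77 sits within 1.2 standard errors of the planted
0.7, and the hurdle fit reproduces the observed number of zeros exactly
(D ≈ 0), as its structure guarantees.

Full pipelines: `run_case_popularity()` (term RRs → AIS → final count
model + rootogram/D diagnostics) and `run_case_classification()` (shared
term ORs → AIS → Kruskal–Wallis + ROC per variant, including the
reciprocal of the AIS-sum). See the vignette
`vignettes/ais-methods.Rmd` for the models, assumptions and design
choices.

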