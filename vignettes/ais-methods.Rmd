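---
title: "Aggregated influence scores: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated influence scores: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aisglm)
```

## The problem

Short-text corpora — tweets about a health topic, free-text snippets from
records — produce document-term matrices (DTMs) that are wide and
extremely sparse. Regressing an outcome on hundreds of term columns at
once is neither stable nor interpretable for the applied analyst. The
aggregated influence score (AIS) sidesteps this: every retained term is
screened with a *univariate* generalized linear model against the outcome,
its exponentiated slope becomes the term's weight, and each document is
then summarised by the frequency-weighted mean, median and sum of the
weights of the terms it contains. The corpus collapses to a single
continuous predictor per document, which feeds an ordinary final model.

## Models

### Count outcome (popularity)

For a count outcome $y_i$ (e.g. retweets) on a single predictor $x_i$
(a term's frequency, later the AIS itself) the package fits, by maximum
likelihood:

* **Poisson, log-linear**: $\log E[y_i] = \beta_0 + \beta x_i$.
* **Poisson, log-log**: $\log E[y_i] = \beta_0 + \beta \log(x_i + 1)$.
  "Log-log" is understood here as a log link with a log-transformed
  predictor; the $+1$ keeps zero frequencies admissible. This is a
  deliberate interpretation of a link that has no single standard
  definition for counts; it keeps the mean positive and tames the skew of
  frequency predictors.
* **Negative binomial (NB2)**: $\mathrm{Var}(y) = \mu + \mu^2/\theta$,
  joint ML over $(\beta_0, \beta, \theta)$, for overdispersed outcomes.
* **Hurdle NB**: a logistic model for $1\{y_i > 0\}$ with coefficients
  $(\gamma_0, \gamma_1)$, and a zero-truncated NB for $y_i \mid y_i > 0$
  with coefficients $(\beta_0, \beta, \theta)$. The likelihood factorises,
  so the two parts are maximised independently and the total
  log-likelihood is their sum. Both parts share the same single predictor:
  although the general two-part formulation allows distinct covariates in
  the zero and count parts, the univariate screening design has only one
  predictor per model, so $z = x$.

The relative risk of a term is $RR = e^{\hat\beta}$ from the count
component: the multiplicative change in the (positive-part) expected
count per additional occurrence.

### Binary outcome (topic classification)

A univariate logistic model
$\log(\pi/(1-\pi)) = \beta_0 + \beta_1 x$ per term, giving the odds ratio
$OR = e^{\hat\beta_1}$ as the weight. The screening vocabulary is
restricted to terms present at least once in *both* classes: terms
exclusive to one class are an artefact of how a merged two-topic corpus
is assembled and invite complete separation.

### Aggregation

For a document containing weighted terms $i = 1,\dots,k$ with frequencies
$n_i$ and weights $w_i$:

$$\mathrm{AIS}_{mean} = \frac{\sum_i n_i w_i}{\sum_i n_i}, \qquad
  \mathrm{AIS}_{sum} = \sum_i n_i w_i,$$

and $\mathrm{AIS}_{median}$ is the median of the multiset in which $w_i$
is replicated $n_i$ times, sorted ascending, with the even-total case
averaging the two middle entries. This multiset construction follows the
prose definition ("place $n_i$ entries" of a weight); it reduces to the
simple order-statistic formula whenever all $n_i = 1$. Terms whose weight
is absent (non-converged or inestimable fits) are silently excluded;
a document with no weighted term has missing scores and is dropped from
final models, with the dropped count reported.

Mean and median are bounded by the weights they aggregate; the sum is
not, which is exactly why it can fail for classification (below).

## Numerical choices

* The NB and truncated-NB likelihoods are maximised with L-BFGS-B on
  $(\beta_0, \beta, \log\theta)$, started from a Poisson fit and a
  moment estimate of $\theta$ clipped to $[0.05, 10^4]$.
* $\theta$ is bounded above at $10^8$. Data without overdispersion leave
  the likelihood flat in $\theta$ beyond some point; if moving
  $\theta$ to the bound costs less than $10^{-3}$ log-likelihood units
  the capped value is reported, with a warning, and the fit is still
  flagged converged. This keeps screening stable across hundreds of
  terms. Equally important, a finite interior optimum of the
  $\theta$-profile (which genuinely occurs on equidispersed data) is
  *not* forced to the cap.
* The zero-truncated NB log-pmf is computed as
  $\log f(y) - \log(1 - f(0))$ with $\log f(0) = -\theta\log(1+\mu/\theta)$
  and a split `log1p`/`expm1` evaluation of $\log(1 - e^{x})$, so the
  renormalisation is stable whether the zero mass is near 0 or 1.
* Standard errors come from the inverse observed information (numerical
  Hessian at the optimum for the NB parts, the GLM information
  otherwise); p-values are Wald. No multiple-testing correction is
  applied to the per-term screens — the weights are descriptive inputs to
  the aggregation, not a hypothesis-testing procedure.
* A constant predictor makes the slope inestimable: the model is refit
  intercept-only, flagged non-converged, and the term's weight is absent.
  Complete separation in a logistic fit is likewise flagged.

## Diagnostics

* **Expected-zeros difference** $D = \#\{y_i = 0\} - \sum_i \hat P(y_i = 0)$.
  A hurdle fit returns $D = 0$ to numerical precision, structurally: the
  logistic zero component's score equations force the fitted zero
  probabilities to sum to the observed zero count. NB and Poisson fits
  on zero-heavy data miss the zero count — on the synthetic corpora used
  in the tests the NB consistently predicts *fewer* zeros than observed
  (positive $D$), and the Poisson misses by an order of magnitude more.
* **Hanging rootograms** (square-root scale): observed bars suspended
  from the model-expected curve; bars failing to reach zero expose
  excess zeros or heavy tails.
* **Kruskal–Wallis rank-sum test** (tie-corrected; for two groups this is
  the chi-square form of the Wilcoxon rank-sum test, 1 df) for whether
  the AIS distributions differ between classes.
* **ROC/AUC** with all distinct thresholds, trapezoidal AUC (equal to the
  Mann–Whitney probability with half credit for ties), and the cutoff
  maximising Youden's $J$ = sensitivity + specificity − 1, ties broken
  toward the smaller cutoff. Since no single cutoff rule is canonical,
  Youden maximisation was chosen as the standard single-point summary.
  The score direction is *not* silently flipped: an AIS-sum whose
  distribution is inverted between groups reports its sub-0.5 AUC as
  computed, plus a direction flag (`direction = "auto"` opts into
  choosing the orientation).

## Text cleaning

Cleaning is deterministic and ordered: topic/query words removed at token
boundaries (including hashtag forms, case-insensitively); URLs,
`@`-mentions and the retweet marker dropped as whole tokens; characters
other than letters, digits, `#` and whitespace removed; lowercasing;
hashtag tokens dropped (or kept with the `#` stripped); digits removed
from tokens (standalone numbers vanish); whitespace tokenization. Stop
words are *not* removed — function words carry weight estimates like any
other term and the aggregation is robust to their near-unit weights.
An optional conservative stemmer (strip a final `s` from tokens longer
than three characters not ending in `ss`) is off by default: inflected
and base forms are distinct vocabulary entries unless the analyst opts
in. Tokens never retain uppercase, `@`, `/`, digits or whitespace, and
cleaning is idempotent.

The sparse-term filter keeps terms whose *document frequency* (number of
documents containing the term, not total occurrences) exceeds `k`;
default `k = 500`, appropriate for corpora of tens of thousands of
documents and meant to be scaled down for smaller ones (the tests use
`k` of 5–25 on corpora of hundreds to thousands).

## The synthetic corpus generator

`generate_corpus()` emulates the statistical skeleton the method assumes,
so every stage is testable without any external data:

* two groups of documents (default 2 500 each, totalling 5 000) over a
  shared background vocabulary (default 40 letter-only terms, so tokens
  survive cleaning unchanged), document lengths uniform on 3–8;
* per-term background usage mildly group-skewed (log-normal skew,
  sd 0.4 by default) — mirroring that in real language almost every
  word's frequency differs somewhat between topics, which is what makes
  aggregation of many weak signals work;
* group-specific topic terms included per document by Bernoulli draws
  (probabilities 0.20–0.35 by default), leaking into the other group at
  a tenth of their rate so that topic terms remain *shared* vocabulary;
* a count outcome from the hurdle process: linear predictor
  $\eta = \beta_0 + \sum_t (\text{planted log-RR}_t)\times\text{freq}_t$
  (default a single planted term with log-RR 0.7), positive indicator
  $\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\gamma_0 + \gamma_1\eta))$
  with $\gamma_0 = -0.5$, $\gamma_1 = 0.8$, $\beta_0 = 0.3$, and
  positive counts zero-truncated NB with mean $e^\eta$ and $\theta = 2$.
  These defaults give roughly 55 % zeros and variance about 2.6 times
  the mean — the excess-zero, overdispersed regime the hurdle model is
  built for.

All randomness flows from the single spec seed, and the generator
restores the caller's RNG state. What the generator does **not** emulate:
natural-language syntax, Zipfian vocabulary growth, term co-occurrence
structure (terms are sampled independently, matching the univariate
screen's working assumption), hashtag/URL patterns beyond an optional
decoration used to exercise cleaning, and corpus-scale document counts.
Passing tests therefore demonstrate correctness of the *method's
machinery* under its own assumptions, not performance on real social
media text.

## Test design and problem sizes

Exact identities (likelihood separability, $D = 0$ for hurdle fits,
AUC = pair counting, the algebraic AIS identities) are tested at
tolerances of $10^{-8}$ or tighter. Optimum log-likelihoods are compared
against two-stage grid-search oracles and hand-written pmf formulas on
20-point fixtures at $10^{-4}$. Parameter recovery uses corpora of 5 000
documents across ten seeds, requiring the planted log-RR of 0.7 to fall
within three standard errors in at least nine; the hurdle < NB < Poisson
AIC ordering is likewise required in at least nine of ten seeds on
2 500-document corpora. End-to-end classification uses a well-separated
design (topic-term probabilities 0.40–0.55, leakage 0.05, short
documents), where the AIS-median must exceed AUC 0.9; a contrasting
design with a control vocabulary of many weaker terms reproduces the
qualitative failure of the AIS-sum (its AUC drops well below the
median's) — the sum is the one summary not bounded by its inputs, so it
rewards merely matching *more* terms.

## Known limitations

* Univariate screening ignores term co-occurrence; weights of correlated
  terms are each marginal, not adjusted.
* The log-log Poisson variant is an interpretation (log link,
  $\log(x+1)$ predictor); other readings of that name exist.
* Weight standard errors are reported on the log scale (the slope's SE);
  downstream AIS uncertainty is not propagated — scores are treated as
  fixed predictors in the final models, as in the original procedure.
* In-sample evaluation only: no cross-validation, no AUC confidence
  intervals.
* Two-class classification only; a multinomial extension would follow
  the same screening/aggregation pattern but is not implemented.
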