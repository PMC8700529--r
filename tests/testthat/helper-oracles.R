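# Independent oracles and small simulation helpers, deliberately written
# from first principles so they never share code with the implementation
# paths they check.

# Mann-Whitney AUC by exhaustive pair counting (ties get half credit)
mw_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# NB2 log-pmf from the gamma-function definition (independent of dnbinom)
nb_logpmf_hand <- function(y, mu, theta) {
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * (log(theta) - log(theta + mu)) +
    y * (log(mu) - log(theta + mu))
}

# Kruskal-Wallis statistic from the rank-sum definition with tie correction
kw_stat_hand <- function(scores, groups) {
  n <- length(scores)
  r <- rank(scores)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) -
    3 * (n + 1)
  ties <- table(scores)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# two-stage grid maximisation of a log-likelihood around a centre point;
# returns the best loglik found on the lattice
grid_max_loglik <- function(ll_fun, centre, half_width = 0.5, n = 31L,
                            stages = 3L) {
  best <- ll_fun(centre)
  for (s in seq_len(stages)) {
    grids <- lapply(centre, function(ci)
      seq(ci - half_width, ci + half_width, length.out = n))
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1L, ll_fun)
    i <- which.max(vals)
    if (vals[i] > best) best <- vals[i]
    centre <- pts[i, ]
    half_width <- half_width * 2 / (n - 1)   # zoom in around the best node
  }
  best
}

# hurdle data simulated straight from the two-part definition
sim_hurdle <- function(n, gamma0 = -0.5, gamma1 = 0.8, beta0 = 0.3,
                       beta1 = 0.6, theta = 2, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 2, 0.3)
  z <- rbinom(n, 1, plogis(gamma0 + gamma1 * x))
  mu <- exp(beta0 + beta1 * x)
  y <- integer(n)
  if (any(z == 1)) {
    idx <- which(z == 1)
    p0 <- (theta / (theta + mu[idx]))^theta
    u <- runif(length(idx), p0, 1)
    y[idx] <- pmax(qnbinom(u, size = theta, mu = mu[idx]), 1L)
  }
  list(y = y, x = x)
}

# well-separated two-topic corpus specification used by the
# classification end-to-end checks
separated_spec <- function(seed, n_per_group = 1000L) {
  corpus_spec(
    n_docs = c(n_per_group, n_per_group),
    doc_length = c(2L, 5L),
    topic_term_sets = list(
      c(spectrum = 0.55, awareness = 0.50, child = 0.50,
        support = 0.45, world = 0.40),
      c(outbreak = 0.55, vaccine = 0.50, campaign = 0.50,
        safety = 0.45, violence = 0.40)),
    cross_leakage = 0.05,
    seed = seed)
}

# run the classification front half: corpus -> filtered DTM -> OR screen
# -> AIS table (returns scores plus aligned labels)
classify_pipeline <- function(spec, k = 10) {
  corp <- generate_corpus(spec)
  dtm <- filter_sparse(build_dtm(clean_corpus(corp)), k)
  labels <- join_outcomes(dtm, corp)$topic_label
  weights <- screen_terms_logistic(dtm, labels)
  ais <- score_corpus(dtm, weights)
  ais$topic_label <- labels
  ais
}
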