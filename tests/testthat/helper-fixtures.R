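# Fixture builders shared across the suite. Everything is generated in
# code; no stored data.

# four untied units with equal weights: ranks 1/8, 3/8, 5/8, 7/8
quartet_ranking <- function() fractional_rank(c(1, 2, 3, 4), weights = rep(1, 4))

# exact finite population with the outcome held entirely by the top
# category of share p (cells weighted by their population shares)
perfect_concentration <- function(p, n_categories = 2) {
  shares <- c(rep((1 - p) / (n_categories - 1), n_categories - 1), p)
  rs <- fractional_rank(seq_len(n_categories), weights = shares)
  list(h = c(rep(0, n_categories - 1), 1), rs = rs)
}

# random survey-like fixture: 3-level stratifier, random positive weights,
# outcome prevalence tied loosely to the stratifier, optional clusters
random_fixture <- function(seed, n = NULL) {
  set.seed(seed)
  n <- n %||% sample(30:500, 1)
  cat <- sample(c("low", "medium", "high"), n, replace = TRUE,
                prob = as.vector(stats::rmultinom(1, 30, rep(1 / 3, 3)) + 1) / 33)
  w <- stats::rlnorm(n, sdlog = 0.5)
  p <- c(low = 0.2, medium = 0.4, high = 0.6)[cat]
  h <- stats::rbinom(n, 1, p)
  if (sum(h) == 0) h[sample.int(n, 2)] <- 1      # keep the index defined
  if (sum(h) == n) h[sample.int(n, 2)] <- 0
  cluster <- sample(sprintf("c%02d", 1:12), n, replace = TRUE)
  list(cat = cat, w = w, h = h, cluster = cluster,
       rs = fractional_rank(cat, weights = w, levels = c("low", "medium", "high")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small generator configuration for fast end-to-end tests
small_synth_config <- function(..., seed = 11) {
  synth_config(n_surveys = 2, survey_years = c(2011, 2016),
               strata_per_survey = 5, clusters_per_stratum = 4,
               women_per_cluster = 15, seed = seed, ...)
}

# weighted covariance computed with plain arithmetic (test-side oracle)
oracle_cov <- function(x, y, w) {
  wn <- w / sum(w)
  sum(wn * (x - sum(wn * x)) * (y - sum(wn * y)))
}
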