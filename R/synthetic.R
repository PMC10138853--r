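# Synthetic DHS-like pooled survey generator. Emulates the structure of a
# two-stage stratified cluster sample: region-like strata, clusters drawn
# within strata, unequal lognormal sampling weights, categorical
# covariates and ordinal empowerment domains tied together by a shared
# latent socioeconomic factor (a one-factor Gaussian copula), and binary
# outcomes drawn from a logit model with known coefficients. Because the
# latent factor has a N(0,1) marginal regardless of how its variance is
# split across stratum / cluster / woman levels, the implied
# superpopulation is enumerable and the true Erreygers index of every
# outcome-by-domain pair can be computed to high precision.

#' Configuration for the synthetic pooled-survey generator
#'
#' @param n_surveys number of survey rounds to generate and pool.
#' @param survey_years labels for the rounds (length `n_surveys`).
#' @param strata_per_survey,clusters_per_stratum,women_per_cluster sample
#'   layout counts (all >= 1). Total rows =
#'   `n_surveys * strata_per_survey * clusters_per_stratum *
#'   women_per_cluster`.
#' @param weight_dispersion sdlog of the lognormal cluster-level sampling
#'   weights (centred so weights average 1); must be > 0.
#' @param covariate_spec named list of covariates. Each element is a list
#'   with `labels` (category labels, ascending in the latent ordering),
#'   `probs` (population shares, summing to 1) and `latent_cor`
#'   (correlation of the covariate's latent with the shared socioeconomic
#'   factor, in \[-1, 1\]).
#' @param empowerment_spec named list of empowerment domains, same shape as
#'   `covariate_spec` (labels default low/medium/high); an element may add
#'   `omit_first_survey = TRUE` to mirror a domain unavailable in the
#'   earliest round.
#' @param outcome_coefficients named list of outcomes; each outcome is a
#'   list with `intercept` (log-odds) and, per covariate / domain /
#'   `survey_year`, a named vector of log-odds for the non-reference
#'   categories (reference = first label, first year).
#' @param variance_shares length-3 vector (stratum, cluster, woman) of the
#'   latent factor's variance decomposition; must sum to 1. Nonzero
#'   stratum/cluster shares induce realistic intra-cluster correlation
#'   without changing the N(0,1) marginal.
#' @param missing_rate probability in \[0, 1) that an eligible covariate
#'   cell is replaced by the `"dont_know"` sentinel.
#' @param seed integer master seed; per-survey streams are derived from it
#'   deterministically.
#' @return A validated object of class `synth_config`.
#' @export
synth_config <- function(n_surveys = 4,
                         survey_years = c(2000, 2005, 2011, 2016)[seq_len(n_surveys)],
                         strata_per_survey = 22,
                         clusters_per_stratum = 10,
                         women_per_cluster = 25,
                         weight_dispersion = 0.3,
                         covariate_spec = default_covariate_spec(),
                         empowerment_spec = default_empowerment_spec(),
                         outcome_coefficients = default_outcome_coefficients(),
                         variance_shares = c(stratum = 0.05, cluster = 0.15, woman = 0.80),
                         missing_rate = 0,
                         seed = 1L) {
  counts <- c(n_surveys = n_surveys, strata_per_survey = strata_per_survey,
              clusters_per_stratum = clusters_per_stratum,
              women_per_cluster = women_per_cluster)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all layout counts must be integers >= 1", call. = FALSE)
  }
  if (length(survey_years) != n_surveys) {
    stop("`survey_years` must have length `n_surveys`", call. = FALSE)
  }
  if (anyDuplicated(survey_years)) stop("survey year labels must be distinct", call. = FALSE)
  if (!is.numeric(weight_dispersion) || weight_dispersion <= 0) {
    stop("`weight_dispersion` must be > 0", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  if (length(variance_shares) != 3L || any(variance_shares < 0) ||
      abs(sum(variance_shares) - 1) > 1e-10) {
    stop("`variance_shares` must be 3 non-negative values summing to 1", call. = FALSE)
  }
  check_cat_spec <- function(spec, what) {
    if (is.null(names(spec)) || any(names(spec) == "")) {
      stop("`", what, "` must be a named list", call. = FALSE)
    }
    for (nm in names(spec)) {
      el <- spec[[nm]]
      if (is.null(el$labels) || is.null(el$probs) ||
          length(el$labels) != length(el$probs) || length(el$labels) < 2L) {
        stop(what, " `", nm, "`: need matching `labels` and `probs` (>= 2 categories)",
             call. = FALSE)
      }
      if (any(el$probs < 0) || any(el$probs > 1) || abs(sum(el$probs) - 1) > 1e-8) {
        stop(what, " `", nm, "`: probabilities must lie in [0,1] and sum to 1",
             call. = FALSE)
      }
      a <- el$latent_cor %||% 0
      if (abs(a) > 1) stop(what, " `", nm, "`: |latent_cor| must be <= 1", call. = FALSE)
      spec[[nm]]$latent_cor <- a
    }
    spec
  }
  covariate_spec <- check_cat_spec(covariate_spec, "covariate")
  empowerment_spec <- check_cat_spec(empowerment_spec, "empowerment domain")

  valid_terms <- c("intercept", names(covariate_spec), names(empowerment_spec),
                   "survey_year")
  if (is.null(names(outcome_coefficients))) {
    stop("`outcome_coefficients` must be a named list of outcomes", call. = FALSE)
  }
  for (out in names(outcome_coefficients)) {
    co <- outcome_coefficients[[out]]
    if (is.null(co$intercept)) stop("outcome `", out, "` lacks an intercept", call. = FALSE)
    bad <- setdiff(names(co), valid_terms)
    if (length(bad)) stop("outcome `", out, "` references unknown terms: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }

  structure(list(
    n_surveys = as.integer(n_surveys), survey_years = survey_years,
    strata_per_survey = as.integer(strata_per_survey),
    clusters_per_stratum = as.integer(clusters_per_stratum),
    women_per_cluster = as.integer(women_per_cluster),
    weight_dispersion = weight_dispersion,
    covariate_spec = covariate_spec, empowerment_spec = empowerment_spec,
    outcome_coefficients = outcome_coefficients,
    variance_shares = unname(variance_shares),
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Default covariate specification
#'
#' Five categorical covariates with category shares and latent correlations
#' chosen to resemble a rural-majority DHS population: residence, wealth
#' quintile, maternal education, maternal age group and occupation. Labels
#' are ordered from least- to most-advantaged so positive `latent_cor`
#' concentrates the advantaged categories among high-SES women.
#' @return Named list usable as `covariate_spec`.
#' @export
default_covariate_spec <- function() {
  list(
    residence = list(labels = c("rural", "urban"), probs = c(0.79, 0.21),
                     latent_cor = 0.60),
    wealth = list(labels = c("poorest", "poorer", "middle", "richer", "richest"),
                  probs = rep(0.2, 5), latent_cor = 0.75),
    education = list(labels = c("none", "primary", "secondary", "higher"),
                     probs = c(0.55, 0.30, 0.10, 0.05), latent_cor = 0.65),
    age_group = list(labels = c("under20", "20plus"), probs = c(0.15, 0.85),
                     latent_cor = 0.10),
    occupation = list(labels = c("none", "working"), probs = c(0.50, 0.50),
                      latent_cor = 0.15)
  )
}

#' Default empowerment-domain specification
#'
#' Three ordinal low/medium/high domains whose latent scores correlate with
#' the shared socioeconomic factor (so covariates have nonzero
#' concentration indices against the empowerment ranking, as a
#' decomposition requires); the decision-making domain is flagged as
#' unavailable in the earliest survey round.
#' @return Named list usable as `empowerment_spec`.
#' @export
default_empowerment_spec <- function() {
  tert <- c(1, 1, 1) / 3
  list(
    attitude_to_violence = list(labels = c("low", "medium", "high"), probs = tert,
                                latent_cor = 0.50),
    social_independence = list(labels = c("low", "medium", "high"), probs = tert,
                               latent_cor = 0.45),
    decision_making = list(labels = c("low", "medium", "high"), probs = tert,
                           latent_cor = 0.35, omit_first_survey = TRUE)
  )
}

#' Default outcome coefficient sets
#'
#' Log-odds of magnitudes comparable to a maternal-health-services model:
#' moderate urban, wealth, education and empowerment gradients plus a
#' secular improvement across survey rounds; intercepts placed so the four
#' outcomes span plausible prevalences (roughly 0.15-0.45).
#' @return Named list usable as `outcome_coefficients`.
#' @export
default_outcome_coefficients <- function() {
  shared <- list(
    residence = c(urban = 0.70),
    wealth = c(poorer = 0.10, middle = 0.20, richer = 0.35, richest = 0.80),
    education = c(primary = 0.30, secondary = 0.70, higher = 1.00),
    age_group = c("20plus" = 0.10),
    occupation = c(working = 0.10),
    attitude_to_violence = c(medium = 0.20, high = 0.40),
    survey_year = c("2005" = 0.20, "2011" = 0.50, "2016" = 0.90)
  )
  list(
    quality_anc = c(list(intercept = -1.9), shared),
    early_anc = c(list(intercept = -2.7), shared),
    anc4plus = c(list(intercept = -2.4), shared),
    pnc2days = c(list(intercept = -3.0), shared)
  )
}

# thresholds putting the requested shares on a N(0,1) latent
cat_thresholds <- function(probs) stats::qnorm(cumsum(probs)[-length(probs)])

# draw category labels from latent = a*z + sqrt(1-a^2)*eps
draw_categories <- function(z, spec) {
  a <- spec$latent_cor
  latent <- a * z + sqrt(1 - a^2) * stats::rnorm(length(z))
  th <- cat_thresholds(spec$probs)
  spec$labels[findInterval(latent, th) + 1L]
}

# linear predictor for one outcome's coefficient list over a data frame
linear_predictor <- function(co, data) {
  eta <- rep(co$intercept, nrow(data))
  for (term in setdiff(names(co), "intercept")) {
    v <- co[[term]]
    vals <- as.character(data[[term]])
    add <- unname(v[vals])
    add[is.na(add)] <- 0          # reference category, first year, or omitted domain
    eta <- eta + add
  }
  eta
}

#' Generate a pooled synthetic survey with known ground truth
#'
#' Draws the full pooled table (one row per woman) under the layout and
#' model in `config`, and—unless `truth = FALSE`—enumerates the true
#' population Erreygers index of every outcome-by-domain pair via
#' [enumerate_truth()].
#'
#' @param config a [synth_config()].
#' @param truth logical: attach the enumerated [SyntheticTruth] object?
#' @param truth_method,truth_n_super passed to [enumerate_truth()].
#' @return An object of class `synthetic_survey`: list with `data` (the
#'   pooled woman table), `truth` (generating coefficients, true
#'   prevalences and true ECIs, or `NULL`), and `config`. The data carry
#'   attributes `covariate_columns`, `domain_columns`, `outcome_columns`.
#' @details Identical configs (including the seed) yield identical tables.
#'   Weights are cluster-level lognormal draws centred at 1 and normalized
#'   to mean 1 within each survey; they are independent of all model
#'   variables (noninformative sampling), so design-weighted estimators
#'   target the enumerated superpopulation quantities.
#' @export
generate_pooled_survey <- function(config, truth = TRUE,
                                   truth_method = c("montecarlo", "quadrature"),
                                   truth_n_super = 1e5) {
  stopifnot(inherits(config, "synth_config"))
  truth_method <- match.arg(truth_method)
  vs <- sqrt(config$variance_shares)

  surveys <- vector("list", config$n_surveys)
  for (s in seq_len(config$n_surveys)) {
    set.seed(derive_seed(config$seed, s))
    n_str <- config$strata_per_survey
    n_cl <- config$clusters_per_stratum
    n_w <- config$women_per_cluster
    n <- n_str * n_cl * n_w

    yr <- config$survey_years[s]
    stratum <- rep(sprintf("%s_S%03d", yr, seq_len(n_str)), each = n_cl * n_w)
    cluster <- rep(sprintf("%s_C%05d", yr, seq_len(n_str * n_cl)), each = n_w)

    stratum_eff <- rep(stats::rnorm(n_str), each = n_cl * n_w)
    cluster_eff <- rep(stats::rnorm(n_str * n_cl), each = n_w)
    z <- vs[1] * stratum_eff + vs[2] * cluster_eff + vs[3] * stats::rnorm(n)

    disp <- config$weight_dispersion
    wcl <- stats::rlnorm(n_str * n_cl, meanlog = -disp^2 / 2, sdlog = disp)
    weight <- rep(wcl, each = n_w)
    weight <- weight / mean(weight)

    df <- data.frame(survey_year = config$survey_years[s],
                     stratum = stratum, cluster = cluster, weight = weight,
                     stringsAsFactors = FALSE)
    for (nm in names(config$covariate_spec)) {
      df[[nm]] <- draw_categories(z, config$covariate_spec[[nm]])
    }
    for (nm in names(config$empowerment_spec)) {
      spec <- config$empowerment_spec[[nm]]
      vals <- draw_categories(z, spec)
      if (isTRUE(spec$omit_first_survey) && s == 1L) vals <- rep(NA_character_, n)
      df[[nm]] <- vals
    }
    for (out in names(config$outcome_coefficients)) {
      p <- stats::plogis(linear_predictor(config$outcome_coefficients[[out]], df))
      df[[out]] <- stats::rbinom(n, 1L, p)
    }
    surveys[[s]] <- df
  }
  data <- do.call(rbind, c(surveys, list(make.row.names = FALSE)))
  data$woman_id <- seq_len(nrow(data))

  if (config$missing_rate > 0) {
    data <- inject_missingness(data, config$missing_rate,
                               seed = derive_seed(config$seed, 10007L),
                               columns = names(config$covariate_spec))
  }
  attr(data, "covariate_columns") <- names(config$covariate_spec)
  attr(data, "domain_columns") <- names(config$empowerment_spec)
  attr(data, "outcome_columns") <- names(config$outcome_coefficients)

  tr <- NULL
  if (truth) {
    tr <- enumerate_truth(config, method = truth_method, n_super = truth_n_super)
  }
  structure(list(data = data, truth = tr, config = config),
            class = "synthetic_survey")
}

#' Enumerate the true population concentration indices of a configuration
#'
#' Computes, for every outcome-by-domain pair implied by `config`, the true
#' prevalence and the true population Erreygers index
#' \eqn{8\,\mathrm{cov}(E[h\mid \cdot], r)} of the generating
#' superpopulation, where ranks are tie-aware fractional midranks over the
#' domain categories.
#'
#' Two routes are provided. `"montecarlo"` draws `n_super` independent
#' women from the marginal model (the latent factor is N(0,1) marginally,
#' so no cluster structure is needed) and uses the expected outcome
#' probability per woman rather than a Bernoulli draw, which removes all
#' outcome-level noise from the enumeration. `"quadrature"` integrates the
#' one-dimensional latent factor on a fine grid and enumerates the exact
#' discrete cell distribution (years x covariates x domain), which is
#' deterministic and accurate to integration error; it requires the cell
#' space to be modest (< 2e6 cells per domain).
#'
#' @param config a [synth_config()].
#' @param method `"montecarlo"` or `"quadrature"`.
#' @param n_super superpopulation size for the Monte-Carlo route.
#' @param seed seed for the Monte-Carlo route (default derived from the
#'   config seed, so truth is reproducible per configuration).
#' @return A list of class `synthetic_truth` with elements `coefficients`
#'   (the generating log-odds), `table` (data frame: outcome, domain,
#'   true_prevalence, true_eci), `method`, `n_super`.
#' @export
enumerate_truth <- function(config, method = c("montecarlo", "quadrature"),
                            n_super = 1e5, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  method <- match.arg(method)
  outcomes <- names(config$outcome_coefficients)
  domains <- names(config$empowerment_spec)
  rows <- list()

  if (method == "montecarlo") {
    set.seed(seed %||% derive_seed(config$seed, 777L))
    years <- sample(config$survey_years, n_super, replace = TRUE)
    z <- stats::rnorm(n_super)
    df <- data.frame(survey_year = years, stringsAsFactors = FALSE)
    for (nm in names(config$covariate_spec)) {
      df[[nm]] <- draw_categories(z, config$covariate_spec[[nm]])
    }
    for (nm in domains) df[[nm]] <- draw_categories(z, config$empowerment_spec[[nm]])

    for (out in outcomes) {
      p_all <- stats::plogis(linear_predictor(config$outcome_coefficients[[out]], df))
      for (dom in domains) {
        keep <- rep(TRUE, n_super)
        if (isTRUE(config$empowerment_spec[[dom]]$omit_first_survey)) {
          keep <- df$survey_year != config$survey_years[1]
        }
        spec <- config$empowerment_spec[[dom]]
        rs <- fractional_rank(df[[dom]][keep], weights = rep(1, sum(keep)),
                              levels = spec$labels)
        p <- p_all[keep]
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = out, domain = dom,
          true_prevalence = mean(p),
          true_eci = 8 * wtd_cov(p, rs$rank, rs$weight))
      }
    }
  } else {
    zgrid <- seq(-8.5, 8.5, length.out = 1701L)
    qw <- stats::dnorm(zgrid)
    qw <- qw / sum(qw)
    # per-variable conditional category probabilities at each grid node
    cond_prob <- function(spec) {
      a <- spec$latent_cor
      s <- sqrt(1 - a^2)
      th <- cat_thresholds(spec$probs)
      if (s == 0) {
        idx <- findInterval(a * zgrid, th) + 1L
        out <- matrix(0, length(zgrid), length(spec$probs))
        out[cbind(seq_along(zgrid), idx)] <- 1
        return(out)
      }
      cum <- vapply(th, function(t) stats::pnorm((t - a * zgrid) / s),
                    numeric(length(zgrid)))
      cbind(cum, 1)[, seq_along(spec$probs), drop = FALSE] -
        cbind(0, cum)[, seq_along(spec$probs), drop = FALSE]
    }
    cov_probs <- lapply(config$covariate_spec, cond_prob)
    dom_probs <- lapply(config$empowerment_spec, cond_prob)

    # domains the outcome models reference must live in the cell space
    # alongside the ranked domain; all are conditionally independent given z
    referenced <- unique(unlist(lapply(config$outcome_coefficients,
                                       function(co) intersect(names(co), domains))))
    for (dom in domains) {
      spec <- config$empowerment_spec[[dom]]
      yrs <- config$survey_years
      if (isTRUE(spec$omit_first_survey)) yrs <- yrs[-1]
      dims <- c(names(config$covariate_spec), union(referenced, dom))
      dim_probs <- c(cov_probs, dom_probs)[dims]
      dim_labels <- lapply(dims, function(nm) {
        (config$covariate_spec[[nm]] %||% config$empowerment_spec[[nm]])$labels
      })
      names(dim_labels) <- dims
      cells <- expand.grid(c(list(.year = seq_along(yrs)),
                             lapply(dim_labels, seq_along)),
                           KEEP.OUT.ATTRS = FALSE)
      if (nrow(cells) > 2e6) stop("cell space too large for quadrature; use montecarlo",
                                  call. = FALSE)
      # integrate P(cell) = (1/|years|) * Int phi(z) prod_k P_k(cat_k | z) dz
      pcell <- rep(0, nrow(cells))
      for (t in seq_along(zgrid)) {
        pt <- rep(qw[t] / length(yrs), nrow(cells))
        for (nm in dims) pt <- pt * dim_probs[[nm]][t, cells[[nm]]]
        pcell <- pcell + pt
      }
      cell_df <- data.frame(survey_year = yrs[cells$.year], stringsAsFactors = FALSE)
      for (nm in dims) cell_df[[nm]] <- dim_labels[[nm]][cells[[nm]]]

      share <- vapply(split(pcell, cells[[dom]]), sum, numeric(1))
      share <- share / sum(share)
      midrank <- cumsum(c(0, share[-length(share)])) + share / 2
      r <- midrank[cells[[dom]]]
      wn <- pcell / sum(pcell)
      for (out in outcomes) {
        co <- config$outcome_coefficients[[out]]
        p <- stats::plogis(linear_predictor(co, cell_df))
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = out, domain = dom,
          true_prevalence = sum(wn * p),
          true_eci = 8 * sum(wn * (p - sum(wn * p)) * (r - sum(wn * r))))
      }
    }
  }
  structure(list(coefficients = config$outcome_coefficients,
                 table = do.call(rbind, rows),
                 method = method,
                 n_super = if (method == "montecarlo") n_super else NA_real_),
            class = "synthetic_truth")
}

#' Inject "don't know" responses into covariate cells
#'
#' Independently replaces each eligible covariate cell with the
#' `"dont_know"` sentinel with probability `missing_rate`. Outcome and
#' design variables are never made missing.
#'
#' @param data a data frame.
#' @param missing_rate probability in \[0, 1).
#' @param seed integer seed (reproducible injection).
#' @param columns eligible covariate columns; defaults to the
#'   `covariate_columns` attribute set by [generate_pooled_survey()].
#' @return The data frame with sentinels injected.
#' @export
inject_missingness <- function(data, missing_rate, seed = 1L, columns = NULL) {
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  columns <- columns %||% attr(data, "covariate_columns")
  if (is.null(columns)) stop("specify eligible `columns`", call. = FALSE)
  protected <- c("weight", "rescaled_weight", "stratum", "cluster",
                 "unique_stratum", "unique_cluster", "survey_year")
  if (any(columns %in% protected)) {
    stop("design variables are never made missing", call. = FALSE)
  }
  if (missing_rate == 0) return(data)
  set.seed(seed)
  for (col in columns) {
    hit <- stats::runif(nrow(data)) < missing_rate
    v <- as.character(data[[col]])
    v[hit] <- "dont_know"
    data[[col]] <- v
  }
  data
}

#' Write a synthetic survey to disk
#'
#' Writes `data.csv` (the woman table), `truth.json` (generating
#' coefficients and enumerated truth) and `config.json` into `dir`.
#'
#' @param x a `synthetic_survey`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(data = file.path(dir, "data.csv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.json"))
  utils::write.csv(x$data, paths["data"], row.names = FALSE)
  jsonlite::write_json(list(coefficients = x$truth$coefficients,
                            table = x$truth$table,
                            method = x$truth$method,
                            n_super = x$truth$n_super),
                       paths["truth"], auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(unclass(x$config), paths["config"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
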