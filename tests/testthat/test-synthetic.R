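test_that("the generator is deterministic and has the requested layout", {
  cfg <- small_synth_config()
  g1 <- generate_pooled_survey(cfg, truth = FALSE)
  g2 <- generate_pooled_survey(cfg, truth = FALSE)
  expect_identical(g1$data, g2$data)

  n_expected <- 2 * 5 * 4 * 15
  expect_equal(nrow(g1$data), n_expected)
  expect_true(all(g1$data$weight > 0))
  # stratum and cluster IDs are unique across surveys
  per_survey_strata <- tapply(g1$data$stratum, g1$data$survey_year,
                              function(z) unique(z))
  expect_length(intersect(per_survey_strata[[1]], per_survey_strata[[2]]), 0)
  expect_equal(length(unique(g1$data$cluster)), 2 * 5 * 4)
  # a different seed changes the draw
  g3 <- generate_pooled_survey(small_synth_config(seed = 12), truth = FALSE)
  expect_false(identical(g1$data$quality_anc, g3$data$quality_anc))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(strata_per_survey = 0), ">= 1")
  expect_error(synth_config(weight_dispersion = 0), "> 0")
  expect_error(synth_config(missing_rate = 1), "\\[0, 1\\)")
  expect_error(
    synth_config(covariate_spec = list(x = list(labels = c("a", "b"),
                                                probs = c(0.7, 0.7)))),
    "sum to 1")
  expect_error(
    synth_config(outcome_coefficients = list(y = list(intercept = 0,
                                                      nonexistent = c(a = 1)))),
    "unknown terms")
})

test_that("a domain flagged unavailable is absent from the earliest survey only", {
  g <- generate_pooled_survey(small_synth_config(), truth = FALSE)
  first <- g$data$survey_year == 2011
  expect_true(all(is.na(g$data$decision_making[first])))
  expect_false(anyNA(g$data$decision_making[!first]))
})

test_that("missingness injection hits the expected cells and nothing else", {
  cfg <- small_synth_config()
  g <- generate_pooled_survey(cfg, truth = FALSE)

  # rate 0: unchanged
  expect_identical(inject_missingness(g$data, 0, seed = 1,
                                      columns = c("wealth", "education")),
                   g$data)

  # rate 0.1 over 2 columns: the sentinel count must land in the central
  # 99.9% binomial range for the number of eligible cells
  inj <- inject_missingness(g$data, 0.1, seed = 7,
                            columns = c("wealth", "education"))
  n_sent <- sum(inj$wealth == "dont_know") + sum(inj$education == "dont_know")
  bounds <- qbinom(c(0.0005, 0.9995), 2 * nrow(g$data), 0.1)
  expect_gte(n_sent, bounds[1])
  expect_lte(n_sent, bounds[2])

  # reproducible under the same seed
  inj2 <- inject_missingness(g$data, 0.1, seed = 7,
                             columns = c("wealth", "education"))
  expect_identical(inj, inj2)

  # design variables are never eligible
  expect_error(inject_missingness(g$data, 0.1, seed = 1,
                                  columns = c("weight")), "never")
  expect_false(any(inj$weight == "dont_know"))
  expect_false(any(inj$stratum == "dont_know"))
  expect_error(inject_missingness(g$data, 1.2, seed = 1, columns = "wealth"),
               "\\[0, 1\\)")
})

test_that("the two truth-enumeration routes agree", {
  cfg <- small_synth_config()
  tq <- enumerate_truth(cfg, method = "quadrature")
  tm <- enumerate_truth(cfg, method = "montecarlo", n_super = 2e5)
  m <- merge(tq$table, tm$table, by = c("outcome", "domain"))
  # Monte-Carlo error at n_super = 2e5 is a few 1e-3 at most
  expect_lt(max(abs(m$true_eci.x - m$true_eci.y)), 0.01)
  expect_lt(max(abs(m$true_prevalence.x - m$true_prevalence.y)), 0.01)
  # bound |ECI| <= 4 p (1 - p) holds for the enumerated truth
  expect_true(all(abs(tq$table$true_eci) <=
                    4 * tq$table$true_prevalence * (1 - tq$table$true_prevalence)))
})

test_that("an outcome held entirely by the top tertile has true ECI 8/9", {
  cfg <- synth_config(
    n_surveys = 1, survey_years = 2016, strata_per_survey = 2,
    clusters_per_stratum = 2, women_per_cluster = 5,
    covariate_spec = list(residence = list(labels = c("rural", "urban"),
                                           probs = c(0.8, 0.2), latent_cor = 0)),
    empowerment_spec = list(emp = list(labels = c("low", "medium", "high"),
                                       probs = rep(1 / 3, 3), latent_cor = 0.5)),
    outcome_coefficients = list(y = list(intercept = -40,
                                         emp = c(medium = 0, high = 80))),
    seed = 2)
  tr <- enumerate_truth(cfg, method = "quadrature")
  expect_lt(abs(tr$table$true_eci[1] - 8 / 9), 1e-9)
  expect_lt(abs(tr$table$true_prevalence[1] - 1 / 3), 1e-9)
})

test_that("truth is internally consistent with the covariance identity", {
  cfg <- small_synth_config()
  set.seed(99)
  # re-derive the Monte-Carlo truth by hand on the same enumeration draw
  tm1 <- enumerate_truth(cfg, method = "montecarlo", n_super = 5e4, seed = 123)
  tm2 <- enumerate_truth(cfg, method = "montecarlo", n_super = 5e4, seed = 123)
  expect_equal(tm1$table, tm2$table, tolerance = 1e-9)
})

test_that("with a null outcome model the estimated ECI is statistically zero", {
  null_co <- list(y = list(intercept = -0.5))
  cfg <- synth_config(n_surveys = 2, survey_years = c(2011, 2016),
                      strata_per_survey = 8, clusters_per_stratum = 6,
                      women_per_cluster = 20,
                      outcome_coefficients = null_co, seed = 31)
  g <- generate_pooled_survey(cfg, truth = FALSE)
  pooled <- pool_and_rescale(g$data)
  rs <- fractional_rank(pooled$attitude_to_violence, pooled$rescaled_weight,
                        levels = c("low", "medium", "high"))
  res <- erreygers_index(pooled$y, rs,
                         design = list(cluster = pooled$unique_cluster,
                                       strata = pooled$unique_stratum))
  expect_lt(abs(res$eci), 3.5 * res$se)
})

test_that("synthetic output round-trips through disk", {
  g <- generate_pooled_survey(small_synth_config(), truth = TRUE,
                              truth_method = "quadrature")
  dir <- tempfile("synth")
  paths <- write_synthetic(g, dir)
  expect_true(all(file.exists(paths)))
  back <- read_woman_table(paths["data"])
  expect_equal(nrow(back), nrow(g$data))
  tr <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(tr$table$true_eci, g$truth$table$true_eci, tolerance = 1e-12)
})
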