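# exact finite "population" laid out as weighted cells: a 3-level
# stratifier with given shares, cell outcome probabilities, expanded into
# h = 0/1 cells with joint probability weights. Fitting on this table is a
# deterministic population computation, no sampling noise.
cell_population <- function(shares, p_by_cat) {
  k <- length(shares)
  data.frame(
    emp = rep(c("low", "medium", "high")[seq_len(k)], each = 2),
    h = rep(c(1, 0), k),
    w = as.vector(rbind(shares * p_by_cat, shares * (1 - p_by_cat)))
  )
}

test_that("the logit fit recovers known log-odds from an exact population", {
  # single binary covariate, log-odds 0 vs 2
  pop <- data.frame(x = rep(c("a", "b"), each = 2), h = c(1, 0, 1, 0))
  px <- stats::plogis(c(0, 2))
  pop$w <- c(0.6 * px[1], 0.6 * (1 - px[1]), 0.4 * px[2], 0.4 * (1 - px[2]))
  fit <- fit_outcome_model(pop, "h", "x", weights = pop$w)
  expect_lt(abs(unname(fit$coefficients["(Intercept)"]) - 0), 1e-6)
  expect_lt(abs(unname(fit$coefficients["xb"]) - 2), 1e-6)
  expect_equal(unname(fit$xbar["xb"]), 0.4, tolerance = 1e-12)
})

test_that("fits are invariant to rescaling the weights", {
  fx <- random_fixture(41, n = 300)
  df <- data.frame(h = fx$h, cat = fx$cat)
  f1 <- fit_outcome_model(df, "h", "cat", weights = fx$w)
  f2 <- fit_outcome_model(df, "h", "cat", weights = fx$w * 2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$me, f2$me, tolerance = 1e-10)
})

test_that("reference categories are honoured and aliased dummies reported", {
  fx <- random_fixture(42, n = 200)
  df <- data.frame(h = fx$h, cat = fx$cat, dup = fx$cat)
  f <- fit_outcome_model(df, "h", "cat", weights = fx$w,
                         reference = list(cat = "high"))
  expect_false("cathigh" %in% names(f$coefficients))
  expect_warning(
    fit_outcome_model(df, "h", c("cat", "dup"), weights = fx$w),
    "aliased")
})

test_that("a null generator yields near-zero marginal effects and elasticities", {
  cfg <- synth_config(n_surveys = 1, survey_years = 2016,
                      strata_per_survey = 10, clusters_per_stratum = 10,
                      women_per_cluster = 25,
                      outcome_coefficients = list(y = list(intercept = -0.4)),
                      seed = 44)
  d <- generate_pooled_survey(cfg, truth = FALSE)$data
  f <- fit_outcome_model(d, "y", c("residence", "wealth", "education"),
                         weights = d$weight)
  expect_true(all(abs(f$me) < 0.06))
  rs <- fractional_rank(d$attitude_to_violence, d$weight,
                        levels = c("low", "medium", "high"))
  conc <- erreygers_index(d$y, rs, se_method = "none")
  if (abs(conc$ci_standard) > 1e-8) {
    dec <- decompose_inequality(f, rs, conc)
    expect_true(all(abs(dec$rows$elasticity) < 0.1))
  }
})

test_that("contributions plus the residual always total 100 percent", {
  for (seed in c(51, 52, 53)) {
    fx <- random_fixture(seed, n = 400)
    df <- data.frame(h = fx$h, cat = fx$cat,
                     extra = sample(c("u", "v"), 400, TRUE))
    f <- fit_outcome_model(df, "h", c("cat", "extra"), weights = fx$w)
    conc <- erreygers_index(fx$h, fx$rs, se_method = "none")
    dec <- decompose_inequality(f, fx$rs, conc)
    expect_lt(abs(sum(dec$rows$contribution_pct) + dec$residual_pct - 100), 1e-6)
  }
})

test_that("a covariate uncorrelated with rank contributes nothing", {
  # exact population: stratifier drives the outcome; a balanced covariate
  # is independent of the stratifier, so its CI_k and contribution are 0
  shares <- rep(1 / 3, 3)
  p_cat <- stats::plogis(c(-0.45, -0.15, 0.15))
  pop <- cell_population(shares, p_cat)
  pop <- rbind(transform(pop, z = "m", w = w / 2), transform(pop, z = "f", w = w / 2))
  rs <- fractional_rank(pop$emp, pop$w, levels = c("low", "medium", "high"))
  f <- fit_outcome_model(pop, "h", c("emp", "z"), weights = pop$w,
                         reference = list(emp = "low"))
  conc <- erreygers_index(pop$h, rs, se_method = "none")
  dec <- decompose_inequality(f, rs, conc)
  zrow <- dec$rows[dec$rows$covariate == "z", ]
  expect_lt(abs(zrow$conc_index), 1e-10)
  expect_lt(abs(zrow$contribution_pct), 1e-7)
})

test_that("a stratifier that is the sole driver receives nearly all attribution", {
  # weak-effect regime, where the derivative-ME linearization is accurate:
  # the stratifier's combined contribution approaches 100%
  shares <- rep(1 / 3, 3)
  p_cat <- stats::plogis(c(-0.45, -0.15, 0.15))
  pop <- cell_population(shares, p_cat)
  rs <- fractional_rank(pop$emp, pop$w, levels = c("low", "medium", "high"))
  f <- fit_outcome_model(pop, "h", "emp", weights = pop$w,
                         reference = list(emp = "low"))
  conc <- erreygers_index(pop$h, rs, se_method = "none")
  dec <- decompose_inequality(f, rs, conc)
  total <- sum(dec$rows$contribution_pct)
  expect_gt(total, 97)
  expect_lt(total, 103)
  expect_lt(abs(dec$residual_pct), 3)
})

test_that("zero outcome inequality makes percent contributions undefined", {
  pop <- data.frame(emp = c("low", "medium", "high"), h = c(1, 0, 1),
                    w = c(0.25, 0.5, 0.25))
  rs <- fractional_rank(pop$emp, pop$w, levels = c("low", "medium", "high"))
  conc <- erreygers_index(pop$h, rs, se_method = "none")
  expect_lt(abs(conc$eci), 1e-12)
  f <- fit_outcome_model(pop, "h", "emp", weights = pop$w)
  expect_error(decompose_inequality(f, rs, conc), "absolute contributions")
})

test_that("sign annotations follow the contribution and elasticity signs", {
  fx <- random_fixture(61, n = 300)
  df <- data.frame(h = fx$h, cat = fx$cat)
  f <- fit_outcome_model(df, "h", "cat", weights = fx$w)
  conc <- erreygers_index(fx$h, fx$rs, se_method = "none")
  dec <- interpret_signs(decompose_inequality(f, fx$rs, conc))
  rows <- dec$rows
  expect_true(all(rows$inequality_effect[rows$contribution_pct > 0] == "widening"))
  expect_true(all(rows$inequality_effect[rows$contribution_pct < 0] == "narrowing"))
  expect_true(all(rows$elasticity_direction[rows$elasticity > 0] == "increases"))
  # serialized table carries the residual row
  path <- tempfile(fileext = ".csv")
  out <- write_decomposition(dec, path)
  expect_true(file.exists(path))
  expect_equal(out$covariate[nrow(out)], "(residual)")
})
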