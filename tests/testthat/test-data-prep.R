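outcome_mapping <- function() {
  list(anc_skilled = "anc_skilled", anc_timing_months = "anc_timing",
       anc_visits = "anc_visits", bp_check = "bp", blood_test = "blood",
       urine_test = "urine", pnc_skilled = "pnc_skilled",
       pnc_timing_days = "pnc_days")
}

component_frame <- function(...) {
  base <- data.frame(anc_skilled = 1, anc_timing = 2, anc_visits = 4,
                     bp = 1, blood = 1, urine = 1, pnc_skilled = 1, pnc_days = 1)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("quality ANC requires all three component services", {
  df <- build_outcomes(component_frame(), outcome_mapping())
  expect_equal(df$quality_anc, 1)
  expect_equal(build_outcomes(component_frame(urine = 0), outcome_mapping())$quality_anc, 0)
  expect_equal(build_outcomes(component_frame(blood = 0), outcome_mapping())$quality_anc, 0)
  expect_equal(build_outcomes(component_frame(bp = 0), outcome_mapping())$quality_anc, 0)
})

test_that("visit-count and timing thresholds are honoured", {
  expect_equal(build_outcomes(component_frame(anc_visits = 4), outcome_mapping())$anc4plus, 1)
  expect_equal(build_outcomes(component_frame(anc_visits = 3), outcome_mapping())$anc4plus, 0)
  # early ANC: skilled first visit in months 1-3
  expect_equal(build_outcomes(component_frame(anc_timing = 3), outcome_mapping())$early_anc, 1)
  expect_equal(build_outcomes(component_frame(anc_timing = 4), outcome_mapping())$early_anc, 0)
  expect_equal(build_outcomes(component_frame(anc_skilled = 0), outcome_mapping())$early_anc, 0)
  # PNC within two days, skilled
  expect_equal(build_outcomes(component_frame(pnc_days = 2), outcome_mapping())$pnc2days, 1)
  expect_equal(build_outcomes(component_frame(pnc_days = 3), outcome_mapping())$pnc2days, 0)
  # not-applicable components yield NA outcomes, keeping per-outcome Ns distinct
  df <- build_outcomes(component_frame(pnc_skilled = NA, pnc_days = NA), outcome_mapping())
  expect_true(is.na(df$pnc2days))
  expect_equal(df$quality_anc, 1)
  # validation
  expect_error(build_outcomes(component_frame(anc_visits = -1), outcome_mapping()),
               "negative")
  expect_error(build_outcomes(component_frame(pnc_days = -2), outcome_mapping()),
               "negative")
})

test_that("recoding replaces sentinels with the least-advantaged category", {
  df <- data.frame(
    occupation = c("working", "dont_know", "working", "none", "dont_know",
                   "working", "none"),
    education = c("none", "primary", NA, "secondary", "primary", "none", "primary"),
    weight = rexp(7) + 0.1, stringsAsFactors = FALSE)
  out <- recode_missing(df, list(occupation = "none", education = "none"))
  expect_equal(nrow(out), 7)                       # never drops rows
  expect_equal(attr(out, "n_recoded"), 3L)         # exactly the 3 sentinel cells
  expect_equal(out$occupation[c(2, 5)], c("none", "none"))
  expect_equal(out$education[3], "none")
  expect_false(any(out$occupation == "dont_know"))

  # a table with no sentinels passes through unchanged
  clean <- data.frame(occupation = c("working", "none"), stringsAsFactors = FALSE)
  out2 <- recode_missing(clean, list(occupation = "none"))
  expect_equal(out2$occupation, clean$occupation)
  expect_equal(attr(out2, "n_recoded"), 0L)

  # configuration errors
  expect_error(recode_missing(df, list(ethnicity = "other")), "not in data")
  expect_error(recode_missing(df, list(occupation = NA_character_)), "designated")
})

test_that("pooled rescaling equalizes survey weight totals and splits design IDs", {
  s1 <- data.frame(weight = c(2, 3, 5), stratum = "1", cluster = c("a", "a", "b"))
  s2 <- data.frame(weight = c(10, 20), stratum = "1", cluster = c("a", "b"))
  pooled <- pool_and_rescale(list(`2000` = s1, `2005` = s2), target_total = 1)
  tot <- tapply(pooled$rescaled_weight, pooled$survey_year, sum)
  expect_equal(as.vector(tot), c(1, 1), tolerance = 1e-15)
  # survey totals 10 and 30 -> per-survey factors 0.1 and 1/30
  expect_equal(pooled$rescaled_weight[1:3], c(2, 3, 5) / 10)
  expect_equal(pooled$rescaled_weight[4:5], c(10, 20) / 30)
  # identical stratum label "1" in both surveys -> two distinct design strata
  expect_equal(length(unique(pooled$unique_stratum)), 2L)
  # distinct pooled clusters = sum of per-survey distinct clusters
  expect_equal(length(unique(pooled$unique_cluster)), 4L)
  expect_error(pool_and_rescale(list(data.frame(weight = c(1, -1), stratum = 1,
                                                cluster = 1)), target_total = 1),
               "positive")
})

test_that("single-survey rescaling leaves ranks and indices unchanged", {
  fx <- random_fixture(31, n = 120)
  df <- data.frame(cat = fx$cat, h = fx$h, weight = fx$w,
                   stratum = "s", cluster = fx$cluster, survey_year = 2016)
  pooled <- pool_and_rescale(df, target_total = 5)
  rs0 <- fractional_rank(df$cat, df$weight, levels = c("low", "medium", "high"))
  rs1 <- fractional_rank(pooled$cat, pooled$rescaled_weight,
                         levels = c("low", "medium", "high"))
  expect_equal(rs1$rank, rs0$rank, tolerance = 1e-12)
  expect_equal(erreygers_index(pooled$h, rs1, se_method = "none")$eci,
               erreygers_index(df$h, rs0, se_method = "none")$eci,
               tolerance = 1e-12)
})
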