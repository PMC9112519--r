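test_that("base-year fixture loads with converted units and full coverage", {
  strata <- fixture_strata()
  expect_s3_class(strata, "cohort_inputs")
  expect_equal(nrow(strata), 42L)
  expect_equal(sum(strata$n), 15560018)

  m45 <- strata[strata$sex == "male" & strata$age_group == "45-49", ]
  expect_equal(m45$n, 499837)
  expect_equal(m45$exposure_prev, 0.0749)
  expect_equal(m45$acmr, 237e-5)
  expect_equal(m45$inc_ihd, 177e-5)
  expect_equal(m45$cfr_ihd, 0.024)
  expect_equal(m45$yld_prop, 0.134)

  # SBP absent (not zero) below 15, present with positive sd elsewhere
  young <- strata$age_lo < 15
  expect_true(all(is.na(strata$sbp_mean[young])))
  expect_true(all(strata$sbp_sd[!young] > 0))

  # per-100k file values x 1e-5 equal loaded rates to machine precision
  raw <- read.csv(cold_housing_fixture("table2_2016.csv"))
  raw <- raw[order(match(raw$sex, c("male", "female")),
                   coldpmslt:::age_band_lower(raw$age_group)), ]
  expect_identical(strata$inc_isch_stroke, raw$isch_stroke_ir_per_100k * 1e-5)
  expect_identical(strata$acmr, raw$mortality_per_100k * 1e-5)
})

test_that("loader rejects malformed tables with named row/column errors", {
  empty <- tempfile(fileext = ".csv")
  writeLines(paste(coldpmslt:::required_input_cols(), collapse = ","), empty)
  expect_error(load_cohort_inputs(empty), "no strata")

  expect_error(
    load_cohort_inputs(edited_fixture_csv(function(r) {
      r$mortality_per_100k[5] <- -1; r
    })), "mortality_per_100k.*row 5")
  expect_error(
    load_cohort_inputs(edited_fixture_csv(function(r) {
      r$prevalence_pct[2] <- 120; r
    })), "prevalence_pct")
  expect_error(
    load_cohort_inputs(edited_fixture_csv(function(r) rbind(r, r[1, ]))),
    "duplicate stratum")
  expect_error(
    load_cohort_inputs(edited_fixture_csv(function(r) r[-3, ])),
    "missing stratum")
  expect_error(
    load_cohort_inputs(edited_fixture_csv(function(r) {
      r$sbp_mean[r$sex == "male" & r$age_group == "50-54"] <- NA; r
    })), "blood pressure")
  expect_error(load_cohort_inputs(cold_housing_fixture("table2_2016.csv"),
                                  schema_version = "2"), "schema_version")
})

test_that("write then read round-trips a strata collection exactly", {
  strata <- fixture_strata()
  path <- tempfile(fileext = ".csv")
  write_cohort_inputs(strata, path)
  back <- load_cohort_inputs(path)
  expect_equal(back, strata)

  # also for a synthetic table with non-integer per-100k rates
  syn <- generate_inputs(synthetic_spec(jitter = 0.05, seed = 7))
  write_cohort_inputs(syn, path)
  expect_equal(load_cohort_inputs(path), syn, tolerance = 1e-12)
})

test_that("risk functions load with log-linear slopes and validation", {
  risks <- fixture_risks()
  expect_s3_class(risks, "risk_functions")
  r <- risks[risks$disease == "ihd" & risks$age_group == "55-59", ]
  expect_equal(r$rr_per_10mmhg, 1.60)
  expect_equal(r$beta, log(1.60) / 10)

  tmp <- tempfile(fileext = ".csv")
  raw <- read.csv(cold_housing_fixture("synthetic_sbp_rr_by_age.csv"))
  write.csv(rbind(raw, raw[1, ]), tmp, row.names = FALSE)
  expect_error(load_risk_functions(tmp), "duplicate")

  bad <- raw; bad$rr_per_10mmhg[3] <- 0
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_risk_functions(tmp), "> 0")

  write.csv(raw[raw$disease != "ihd", ], tmp, row.names = FALSE)
  expect_error(load_risk_functions(tmp), "missing disease: ihd")

  # incomplete age coverage: error by default, nearest-older inheritance on
  # request
  gap <- raw[!(raw$disease == "ihd" & raw$age_group == "15-19"), ]
  write.csv(gap, tmp, row.names = FALSE)
  expect_error(load_risk_functions(tmp), "incomplete age coverage")
  inh <- load_risk_functions(tmp, inherit_older = TRUE)
  expect_equal(inh$rr_per_10mmhg[inh$disease == "ihd" &
                                   inh$age_group == "15-19"],
               raw$rr_per_10mmhg[raw$disease == "ihd" &
                                   raw$age_group == "20-24"])
})

test_that("coherence report flags impossibilities and never mutates", {
  strata <- fixture_strata()
  # zero incidence with positive case fatality implies zero prevalence: no flag
  z <- strata
  z$inc_ihd[] <- 0
  zf <- check_epi_coherence(z)
  expect_false(any(zf$disease == "ihd" &
                     zf$check == "disease_mortality_exceeds_acmr"))

  # force cfr x implied prevalence above all-cause mortality
  bad <- strata
  bad$inc_ihd[1] <- 0.5; bad$cfr_ihd[1] <- 0.5; bad$acmr[1] <- 1e-4
  flags <- check_epi_coherence(bad)
  expect_true(any(flags$check == "disease_mortality_exceeds_acmr" &
                    flags$disease == "ihd"))

  # regression: the packaged table yields exactly the three known marginal
  # flags (male 45-59, summed disease mortality vs ACMR) and the run completes
  before <- strata
  fl <- check_epi_coherence(strata)
  expect_identical(strata, before)
  expect_equal(nrow(fl), 3L)
  expect_true(all(fl$check == "summed_disease_mortality_exceeds_acmr"))
  expect_equal(fl$age_group, c("45-49", "50-54", "55-59"))

  # observed-prevalence ratio check
  op <- strata
  op$prev_ihd <- pmax(10 * op$inc_ihd / pmax(op$inc_ihd + op$cfr_ihd, 1e-12),
                      1e-6) * 20
  expect_true(any(check_epi_coherence(op, factor = 10)$check ==
                    "prevalence_inconsistent_with_steady_state"))
})
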