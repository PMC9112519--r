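# helper: a file-convention table with one flat schedule everywhere and the
# population mass in a single stratum, loaded through the public reader
flat_strata_csv <- function(m, i, f, dr, yld, pi, sex = "male",
                            age_group = "60-64", n = 1000) {
  bands <- sprintf("%d-%d", seq(0, 100, 5), seq(4, 104, 5))
  one <- function(s) data.frame(
    sex = s, age_group = bands, n = 0, prevalence_pct = 100 * pi,
    mortality_per_100k = 1e5 * m, morbidity_prop = yld,
    sbp_mean = ifelse(seq(0, 100, 5) >= 15, 120, NA),
    sbp_sd = ifelse(seq(0, 100, 5) >= 15, 15, NA),
    ihd_ir_per_100k = 1e5 * i, ihd_cfr = f, ihd_dr_per_100k = 1e5 * dr,
    isch_stroke_ir_per_100k = 0, isch_stroke_cfr = 0,
    isch_stroke_dr_per_100k = 0, haem_stroke_ir_per_100k = 0,
    haem_stroke_cfr = 0, haem_stroke_dr_per_100k = 0)
  raw <- rbind(one("male"), one("female"))
  raw$n[raw$sex == sex & raw$age_group == age_group] <- n
  path <- tempfile(fileext = ".csv")
  write.csv(raw, path, row.names = FALSE, na = "")
  path
}

test_that("zero-effect intervention reproduces BAU to machine precision", {
  strata <- fixture_strata()
  risks <- fixture_risks()
  res <- run_scenario(strata, risks, scenario_config(sbp_effect = 0))
  expect_identical(res$haly_int, res$haly_bau)
  expect_identical(res$l_int, res$l_bau)
  expect_equal(horizon_aggregate(res, "lifetime", 0)$gain_total, 0)
})

test_that("three-cycle run matches a straight-line hand recomputation", {
  # m=0.01, i=0.02, f=0.1, pi=0.5, exposed RR 2 (beta*delta = ln 2), dr=0.1,
  # yld=0.1: configuration chosen so every per-cycle number is spreadsheet
  # arithmetic
  path <- flat_strata_csv(m = 0.01, i = 0.02, f = 0.1, dr = 0.1, yld = 0.1,
                          pi = 0.5, n = 1000)
  strata <- load_cohort_inputs(path)
  risks <- flat_risk_functions(rr10 = 2)
  cfg <- scenario_config(t_cold = 0, t_target = 20, sbp_effect = 10,
                         effect_contrast = 10, exposure_time_fraction = 0.5)
  expect_equal(annual_sbp_shift(cfg), 10)
  res <- run_scenario(strata, risks, cfg)

  pif <- 0.5 * (2 - 1) / (0.5 * 2 + 0.5)      # = 1/3
  i <- 0.02; f <- 0.1; m <- 0.01; dr <- 0.1; yld <- 0.1
  C0 <- i / (i + f)
  step3 <- function(S, C, i., f.) {
    c(S * exp(-i.), C * exp(-f.) + i. * S * (exp(-i.) - exp(-f.)) / (f. - i.))
  }
  Sb <- Si <- 1 - C0; Cb <- Ci <- C0; lb <- li <- 1
  gain <- bau <- 0
  for (t in 0:2) {
    pb <- Cb / (Sb + Cb); p2 <- Ci / (Si + Ci)
    lb2 <- lb * exp(-m)
    li2 <- li * exp(-(m + f * (p2 - pb)))
    bau <- bau + (lb + lb2) / 2 * (1 - yld)
    gain <- gain + (li + li2) / 2 * (1 - (yld + dr * (p2 - pb))) -
      (lb + lb2) / 2 * (1 - yld)
    sb <- step3(Sb, Cb, i, f); Sb <- sb[1]; Cb <- sb[2]
    si <- step3(Si, Ci, i * (1 - pif), f); Si <- si[1]; Ci <- si[2]
    lb <- lb2; li <- li2
  }
  agg <- horizon_aggregate(res, 3, 0)
  expect_equal(agg$gain_total, 1000 * gain, tolerance = 1e-9)
  expect_equal(agg$bau_total, 1000 * bau, tolerance = 1e-9)
})

test_that("BAU arm ignores risks and intervention temperature settings", {
  strata <- fixture_strata()
  risks <- fixture_risks()
  a <- run_scenario(strata, NULL, scenario_config(), mode = "bau")
  b <- run_scenario(strata, risks,
                    scenario_config(t_cold = 10, t_target = 30,
                                    sbp_effect = 20))
  expect_identical(a$haly_bau, b$haly_bau)
  expect_identical(a$deaths_bau, b$deaths_bau)
  expect_error(run_scenario(strata, NULL, scenario_config()), "requires risk")
})

test_that("gains are non-negative cohort-by-cohort and additive over cohorts", {
  strata <- fixture_strata()
  risks <- fixture_risks()
  res <- run_scenario(strata, risks, scenario_config())
  expect_true(all(res$haly_int - res$haly_bau >= -1e-15))

  half1 <- strata; half1$n[1:21] <- 0
  half2 <- strata; half2$n[22:42] <- 0
  g <- function(s) horizon_aggregate(run_scenario(s, risks, scenario_config()),
                                     "lifetime", 0)$gain_total
  expect_equal(g(half1) + g(half2), g(strata), tolerance = 1e-12)

  doubled <- strata; doubled$n <- 2 * strata$n
  a1 <- horizon_aggregate(run_scenario(doubled, risks, scenario_config()),
                          "lifetime", 0.03)
  a0 <- horizon_aggregate(res, "lifetime", 0.03)
  expect_equal(a1$gain_total, 2 * a0$gain_total, tolerance = 1e-12)
  expect_equal(a1$per_1000_gain, a0$per_1000_gain, tolerance = 1e-12)
})

test_that("horizon windows are half-open and discounting anchors at base year", {
  strata <- fixture_strata()
  risks <- fixture_risks()
  res <- run_scenario(strata, risks, scenario_config())
  n <- res$cohorts$n
  d <- (res$haly_int - res$haly_bau) %*% n

  a10 <- horizon_aggregate(res, 10, 0)
  expect_equal(a10$gain_total, sum(d[1:10]))       # year index 10 excluded
  a20 <- horizon_aggregate(res, 20, 0)
  expect_equal(a20$gain_total, sum(d[1:20]))
  alt <- horizon_aggregate(res, "lifetime", 0)
  expect_equal(alt$gain_total, sum(d))
  expect_lt(horizon_aggregate(res, "lifetime", 0.03)$gain_total,
            alt$gain_total)
  w <- 1.03^-(0:9)
  expect_equal(horizon_aggregate(res, 10, 0.03)$gain_total, sum(w * d[1:10]),
               tolerance = 1e-12)
  expect_equal(alt$per_1000_gain, alt$gain_total / (sum(n) / 1000))
  expect_error(horizon_aggregate(res, -1), "unknown horizon")
})

test_that("league table ranks the model against comparators", {
  empty <- league_table_report(0.447, 0.064, 1.34)
  expect_equal(nrow(empty), 1L)
  expect_equal(empty$rank, 1L)

  tab <- league_table_report(0.447, 0.064, 1.34,
                             cold_housing_fixture("league_table_cvd.csv"))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$intervention[1], "Eradication of cold housing")
  expect_equal(tab$rank, 1:4)
  expect_equal(sort(tab$halys_per_1000, decreasing = TRUE),
               tab$halys_per_1000)

  # ties broken by name order
  ties <- data.frame(intervention = c("b plan", "a plan"),
                     halys_per_1000 = c(0.1, 0.1), ui_lo = NA, ui_hi = NA)
  tt <- league_table_report(0.1, comparators = ties, label = "m plan")
  expect_equal(tt$intervention, c("a plan", "b plan", "m plan"))

  bad <- data.frame(intervention = "x", halys_per_1000 = "oops",
                    ui_lo = NA, ui_hi = NA)
  expect_error(league_table_report(0.1, comparators = bad), "malformed")
})
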