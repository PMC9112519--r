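test_that("a cycle with zero rates leaves the state unchanged", {
  st <- list(S = 0.8, C = 0.15, D = 0.05)
  expect_identical(step_disease(st, 0, 0), st)
  expect_error(step_disease(st, -0.1, 0), ">= 0")
})

test_that("closed-form cycle matches an independent integrator across rates", {
  # includes the f = i removable singularity and rates up to 1
  cases <- expand.grid(i = c(0.001, 0.02, 0.1, 0.5, 1),
                       f = c(0, 0.02, 0.1, 0.5, 1))
  cases <- rbind(cases, data.frame(i = c(0.05, 0.3), f = c(0.05, 0.3)),
                 data.frame(i = 0.1, f = 0.1 + 5e-10))
  st <- list(S = 0.7, C = 0.25, D = 0.05)
  for (k in seq_len(nrow(cases))) {
    got <- step_disease(st, cases$i[k], cases$f[k])
    want <- ode_disease_oracle(st$S, st$C, st$D, cases$i[k], cases$f[k])
    expect_equal(got$S, want$S, tolerance = 1e-6)
    expect_equal(got$C, want$C, tolerance = 1e-6)
    expect_equal(got$D, want$D, tolerance = 1e-6)
  }
})

test_that("mass is conserved to 1e-12 per cycle and D never decreases", {
  set.seed(11)
  st <- list(S = 0.6, C = 0.3, D = 0.1)
  for (k in 1:200) {
    nxt <- step_disease(st, runif(1, 0, 1), runif(1, 0, 1))
    expect_lt(abs((nxt$S + nxt$C + nxt$D) - (st$S + st$C + st$D)), 1e-12)
    expect_gte(nxt$D, st$D)
    expect_true(all(c(nxt$S, nxt$C, nxt$D) >= 0))
    st <- nxt
  }
})

test_that("extreme case fatality kills new cases within the cycle", {
  got <- step_disease(list(S = 1, C = 0, D = 0), i = 0.02, f = 1e6)
  expect_equal(got$S, exp(-0.02))
  expect_lt(got$C, 1e-7)
  expect_equal(got$D, 1 - got$S - got$C)
})

test_that("cohort trajectory honours PIF limits and band switching", {
  strata <- fixture_strata()
  bau <- run_disease_trajectory(strata, "male", "60-64", "ihd",
                                pif_series = 0, horizon = 20)
  # null intervention identical to BAU
  expect_identical(
    run_disease_trajectory(strata, "male", "60-64", "ihd",
                           pif_series = rep(0, 20), horizon = 20), bau)

  # complete prevention: no new cases, prevalent pool decays as C e^{-f}
  full <- run_disease_trajectory(strata, "male", "60-64", "ihd",
                                 pif_series = 1 - 1e-12, horizon = 20)
  C <- full$C[1]
  for (y in 2:20) {
    f_y <- full$mortality[y - 1] / full$prevalence[y - 1]
    C <- C * exp(-f_y)
    expect_equal(full$C[y], C, tolerance = 1e-9)
  }

  # monotonicity: larger PIF series never raises prevalence or mortality
  half <- run_disease_trajectory(strata, "male", "60-64", "ihd",
                                 pif_series = 0.5, horizon = 20)
  expect_true(all(half$prevalence <= bau$prevalence + 1e-15))
  expect_true(all(half$mortality <= bau$mortality + 1e-15))
})

test_that("trajectory matches the integrator oracle over five cycles", {
  strata <- fixture_strata()
  traj <- run_disease_trajectory(strata, "male", "60-64", "ihd",
                                 pif_series = 0, horizon = 5)
  sub <- strata[strata$sex == "male", ]
  i0 <- sub$inc_ihd[sub$age_group == "60-64"]
  f0 <- sub$cfr_ihd[sub$age_group == "60-64"]
  expect_equal(i0, 721e-5)
  expect_equal(f0, 0.017)
  st <- list(S = 1 - i0 / (i0 + f0), C = i0 / (i0 + f0), D = 0)
  for (y in 1:5) {
    age <- 62 + y - 1
    band <- sub[age %/% 5 + 1, ]             # ages 62-64 use 60-64, 65+ next
    expect_equal(traj$prevalence[y], st$C / (st$S + st$C), tolerance = 1e-6)
    st <- ode_disease_oracle(st$S, st$C, st$D, band$inc_ihd, band$cfr_ihd)
  }
})

test_that("annual trends rescale rates multiplicatively from the base year", {
  strata <- fixture_strata()
  tr <- run_disease_trajectory(strata, "female", "70-74", "isch_stroke",
                               trend = c(incidence = -0.02,
                                         case_fatality = -0.01),
                               horizon = 10)
  bau <- run_disease_trajectory(strata, "female", "70-74", "isch_stroke",
                                horizon = 10)
  # year 0 rates identical; mortality rate ratio in year y reflects the trend
  expect_equal(tr$mortality[1], bau$mortality[1])
  expect_error(run_disease_trajectory(strata, "female", "70-74",
                                      "isch_stroke", horizon = 0),
               "horizon")
})
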