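# Shared fixtures and independent oracles for the test suite.

fixture_strata <- function() {
  load_cohort_inputs(cold_housing_fixture("table2_2016.csv"))
}

fixture_risks <- function() {
  load_risk_functions(cold_housing_fixture("synthetic_sbp_rr_by_age.csv"))
}

# Independent integrator oracle for the three-state disease system
#   dS/dt = -iS, dC/dt = iS - fC, dD/dt = fC
# over one annual cycle, via deSolve's stiff solver at tight tolerance.
ode_disease_oracle <- function(S, C, D, i, f) {
  rhs <- function(t, y, parms) {
    list(c(-i * y[1], i * y[1] - f * y[2], f * y[2]))
  }
  y0 <- c(S = unname(S), C = unname(C), D = unname(D))
  out <- deSolve::lsoda(y0, c(0, 1), rhs, NULL, rtol = 1e-11, atol = 1e-13)
  list(S = unname(out[2, "S"]), C = unname(out[2, "C"]),
       D = unname(out[2, "D"]))
}

# Write a cohort-input CSV after applying an in-place edit to the raw table;
# returns the temp path. Used to exercise loader validation.
edited_fixture_csv <- function(edit) {
  raw <- read.csv(cold_housing_fixture("table2_2016.csv"),
                  stringsAsFactors = FALSE)
  raw <- edit(raw)
  path <- tempfile(fileext = ".csv")
  write.csv(raw, path, row.names = FALSE, na = "")
  path
}
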