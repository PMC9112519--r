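# Synthetic input tables with known ground truth. The generator emulates the
# statistical structure of GBD-style age/sex schedules -- Gompertz all-cause
# mortality, log-linear-in-age CVD incidence, rising case fatality and
# disability, normal SBP distributions drifting up with age, and a
# cold-housing exposure prevalence that declines with age -- so every stage
# of the pipeline is testable without the packaged base-year table, and so
# closed-form checks (Gompertz life expectancy, single-cohort recursions)
# stay available.

#' Build a synthetic-input specification
#'
#' @param pop Population per stratum (persons).
#' @param gompertz `c(level, slope)`: all-cause hazard `level * exp(slope *
#'   age)`; band values are the exact band-average hazard so discrete band
#'   survival matches the continuous Gompertz curve at band edges.
#' @param sex_mortality_ratio Female/male all-cause hazard ratio.
#' @param incidence,cfr,disability Per-disease `c(level, slope)` pairs:
#'   rate at age 60 and exponential age slope (per year).
#' @param morbidity `c(level, slope, cap)`: all-cause YLD proportion
#'   `min(level * exp(slope * age), cap)`.
#' @param sbp `c(mean15, slope, sd, cap)`: mean SBP `min(mean15 + slope *
#'   (age - 15), cap)` mmHg from age 15, constant sd.
#' @param exposure `c(young, old, midpoint, width)`: logistic age decline of
#'   cold-housing prevalence from `young` to `old`.
#' @param disease_scale,morbidity_scale Global multipliers (0 switches the
#'   disease pathway / morbidity off).
#' @param jitter sdlog of multiplicative lognormal noise on rates (0 = fully
#'   smooth schedules).
#' @param seed RNG seed making the generated table deterministic.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(pop = 5e5,
                           gompertz = c(level = 5e-5, slope = 0.09),
                           sex_mortality_ratio = 0.85,
                           incidence = list(ihd = c(level = 0.006, slope = 0.075),
                                            isch_stroke = c(level = 0.0018, slope = 0.08),
                                            haem_stroke = c(level = 6e-4, slope = 0.075)),
                           cfr = list(ihd = c(level = 0.017, slope = 0.04),
                                      isch_stroke = c(level = 0.010, slope = 0.05),
                                      haem_stroke = c(level = 0.035, slope = 0.06)),
                           disability = list(ihd = c(level = 0.0015, slope = 0.05),
                                             isch_stroke = c(level = 0.028, slope = 0.055),
                                             haem_stroke = c(level = 2e-4, slope = 0.09)),
                           morbidity = c(level = 0.03, slope = 0.024, cap = 0.45),
                           sbp = c(mean15 = 112, slope = 0.35, sd = 17, cap = 145),
                           exposure = c(young = 0.09, old = 0.034,
                                        midpoint = 55, width = 8),
                           disease_scale = 1, morbidity_scale = 1,
                           jitter = 0, seed = 1) {
  stopifnot(pop >= 0, gompertz[["level"]] > 0, gompertz[["slope"]] > 0,
            sex_mortality_ratio > 0, jitter >= 0,
            disease_scale >= 0, morbidity_scale >= 0)
  structure(list(pop = pop, gompertz = gompertz,
                 sex_mortality_ratio = sex_mortality_ratio,
                 incidence = incidence, cfr = cfr, disability = disability,
                 morbidity = morbidity, sbp = sbp, exposure = exposure,
                 disease_scale = disease_scale,
                 morbidity_scale = morbidity_scale,
                 jitter = jitter, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic cohort-input table
#'
#' Schema-identical to the packaged base-year table (both sexes, all 21
#' bands); passes [load_cohort_inputs()] validation and round-trips through
#' [write_cohort_inputs()]. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `cohort_inputs` data frame.
#' @export
generate_inputs <- function(spec) {
  bands <- age_band_labels()
  lo <- age_band_lower(bands)
  mid <- lo + 2
  a <- spec$gompertz[["level"]]; b <- spec$gompertz[["slope"]]
  # exact band-average Gompertz hazard over [lo, lo+5)
  m_male <- (a / b) * (exp(b * (lo + 5)) - exp(b * lo)) / 5

  age_rate <- function(par) {
    pmin(spec$disease_scale * par[["level"]] *
           exp(par[["slope"]] * (mid - 60)), 0.99)
  }
  morb <- pmin(spec$morbidity[["level"]] *
                 exp(spec$morbidity[["slope"]] * mid),
               spec$morbidity[["cap"]]) * spec$morbidity_scale
  sbp_mean <- ifelse(lo >= 15,
                     pmin(spec$sbp[["mean15"]] +
                            spec$sbp[["slope"]] * (mid - 15),
                          spec$sbp[["cap"]]), NA_real_)
  sbp_sd <- ifelse(lo >= 15, spec$sbp[["sd"]], NA_real_)
  expo <- spec$exposure[["old"]] +
    (spec$exposure[["young"]] - spec$exposure[["old"]]) /
    (1 + exp((mid - spec$exposure[["midpoint"]]) / spec$exposure[["width"]]))

  set.seed(spec$seed)
  jit <- function(x) {
    if (spec$jitter == 0) return(x)
    x * rlnorm(length(x), meanlog = -spec$jitter^2 / 2, sdlog = spec$jitter)
  }

  one_sex <- function(sex, mort_mult) {
    raw <- data.frame(
      sex = sex, age_group = bands, n = round(spec$pop),
      prevalence_pct = 100 * expo,
      mortality_per_100k = 1e5 * jit(pmin(m_male * mort_mult, 0.99)),
      morbidity_prop = pmin(jit(morb), 1),
      sbp_mean = sbp_mean, sbp_sd = sbp_sd, stringsAsFactors = FALSE)
    for (d in CVD_DISEASES) {
      raw[[paste0(d, "_ir_per_100k")]] <- 1e5 * jit(age_rate(spec$incidence[[d]]))
      raw[[paste0(d, "_cfr")]] <- jit(age_rate(spec$cfr[[d]]))
      raw[[paste0(d, "_dr_per_100k")]] <- 1e5 * jit(age_rate(spec$disability[[d]]))
    }
    raw
  }
  # male and female share disease schedules (drawn once per table via the
  # common seed); only all-cause mortality differs
  raw <- rbind(one_sex("male", 1), one_sex("female", spec$sex_mortality_ratio))
  convert_raw_inputs(raw)
}

#' Generate a flat constant-rate risk-function table
#'
#' One relative risk for every covered age band and disease; used in
#' known-truth experiments where the PIF must be a single analytic constant.
#'
#' @param rr10 Relative risk per 10 mmHg applied everywhere.
#' @return A `risk_functions` data frame.
#' @export
flat_risk_functions <- function(rr10 = 2) {
  bands <- age_band_labels()
  bands <- bands[age_band_lower(bands) >= 15]
  out <- expand.grid(disease = CVD_DISEASES, age_group = bands,
                     stringsAsFactors = FALSE)
  out$rr_per_10mmhg <- rr10
  out$beta <- log(rr10) / 10
  class(out) <- c("risk_functions", "data.frame")
  out
}

#' Single-cohort known-truth experiment
#'
#' Builds a degenerate model -- constant rates across all ages, one disease,
#' population mass in a single stratum -- where the population impact
#' fraction is a single analytic constant and the whole two-arm lifetable
#' reduces to a short scalar recursion, recomputes that recursion
#' independently of the engine (plain per-cycle closed forms, trapezoidal
#' person-years, explicit discounting), and compares the engine's lifetime
#' HALY gains against it.
#'
#' @param cfg A [scenario_config()].
#' @param m All-cause mortality rate.
#' @param i,f,dr Disease incidence, case-fatality and disability rates.
#' @param yld All-cause morbidity proportion.
#' @param pi Exposure prevalence.
#' @param rr10 Relative risk per 10 mmHg.
#' @param sex,age_group Stratum carrying the population.
#' @param n Cohort size.
#' @param tol Relative-error pass threshold.
#' @return A list: `engine` and `oracle` (each `c(undiscounted, discounted)`
#'   total HALY gains), `rel_err`, `pass`.
#' @export
known_truth_experiment <- function(cfg = scenario_config(), m = 0.01,
                                   i = 0.02, f = 0.1, dr = 0.001, yld = 0.1,
                                   pi = 0.5, rr10 = 2, sex = "male",
                                   age_group = "60-64", n = 1000,
                                   tol = 1e-6) {
  bands <- age_band_labels()
  flat <- function(s) data.frame(
    sex = s, age_group = bands, n = 0,
    prevalence_pct = 100 * pi, mortality_per_100k = 1e5 * m,
    morbidity_prop = yld,
    sbp_mean = ifelse(age_band_lower(bands) >= 15, 120, NA_real_),
    sbp_sd = ifelse(age_band_lower(bands) >= 15, 15, NA_real_),
    ihd_ir_per_100k = 1e5 * i, ihd_cfr = f, ihd_dr_per_100k = 1e5 * dr,
    isch_stroke_ir_per_100k = 0, isch_stroke_cfr = 0,
    isch_stroke_dr_per_100k = 0,
    haem_stroke_ir_per_100k = 0, haem_stroke_cfr = 0,
    haem_stroke_dr_per_100k = 0, stringsAsFactors = FALSE)
  raw <- rbind(flat("male"), flat("female"))
  raw$n[raw$sex == sex & raw$age_group == age_group] <- n
  strata <- convert_raw_inputs(raw)
  risks <- flat_risk_functions(rr10)

  res <- run_scenario(strata, risks, cfg)
  engine <- c(horizon_aggregate(res, "lifetime", 0)$gain_total,
              horizon_aggregate(res, "lifetime", cfg$discount_rate)$gain_total)

  # independent scalar recursion
  start_age <- age_band_lower(age_group) + 2
  delta <- cfg$exposure_time_fraction * (cfg$t_target - cfg$t_cold) *
    cfg$sbp_effect / cfg$effect_contrast
  r <- exp(log(rr10) / 10 * delta)
  pif <- pi * (r - 1) / (pi * r + 1 - pi)
  cycle3 <- function(S, C, i., f.) {
    S2 <- S * exp(-i.)
    C2 <- if (abs(f. - i.) <= 1e-9) C * exp(-f.) + i. * S * exp(-i.)
          else C * exp(-f.) + i. * S * (exp(-i.) - exp(-f.)) / (f. - i.)
    c(S2, C2)
  }
  C0 <- if (i + f > 0) i / (i + f) else 0
  Sb <- Si <- 1 - C0; Cb <- Ci <- C0
  lb <- li <- 1
  g0 <- g3 <- 0
  for (t in 0:(cfg$max_age - 1 - start_age)) {
    pb <- if (Sb + Cb > 0) Cb / (Sb + Cb) else 0
    pi_ <- if (Si + Ci > 0) Ci / (Si + Ci) else 0
    dm <- f * (pi_ - pb); dy <- dr * (pi_ - pb)
    lb2 <- lb * exp(-m); li2 <- li * exp(-(m + dm))
    hb <- (lb + lb2) / 2 * (1 - yld)
    hi <- (li + li2) / 2 * (1 - (yld + dy))
    g0 <- g0 + (hi - hb)
    g3 <- g3 + (hi - hb) / (1 + cfg$discount_rate)^t
    sb <- cycle3(Sb, Cb, i, f); Sb <- sb[1]; Cb <- sb[2]
    si <- cycle3(Si, Ci, i * (1 - pif), f); Si <- si[1]; Ci <- si[2]
    lb <- lb2; li <- li2
  }
  oracle <- n * c(g0, g3)
  rel_err <- max(abs(engine - oracle) / pmax(abs(oracle), 1e-300))
  list(engine = engine, oracle = oracle, rel_err = rel_err,
       pass = rel_err <= tol)
}
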