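# Three-state disease lifetables: healthy (S), prevalent diseased (C),
# dead-from-disease (D), advanced in annual cycles with the exact
# constant-rate matrix-exponential solution of
#   dS/dt = -i S;  dC/dt = i S - f C;  dD/dt = f C
# (remission fixed at zero for chronic cardiovascular disease).

#' Initialise a disease lifetable state
#'
#' Seeds prevalence at the steady state implied by the base-year incidence
#' and case-fatality rates, `C0 = i/(i+f)` of the alive mass (0 where both
#' rates are 0), unless an observed prevalence proportion is given.
#'
#' @param i,f Base-year incidence and case-fatality rates (per person-year).
#' @param prevalence Optional observed prevalence proportion overriding the
#'   steady-state seed.
#' @return A list with components `S`, `C`, `D` (vectorised over inputs).
#' @export
disease_state_init <- function(i, f, prevalence = NULL) {
  stopifnot(all(i >= 0), all(f >= 0))
  C <- if (is.null(prevalence)) ifelse(i + f > 0, i / (i + f), 0)
       else prevalence
  stopifnot(all(C >= 0 & C <= 1))
  list(S = 1 - C, C = C, D = 0 * C)
}

#' Advance a disease lifetable by one annual cycle
#'
#' Exact solution of the constant-rate three-state system over one cycle:
#' `S' = S e^{-i}`; `C' = C e^{-f} + i S (e^{-i} - e^{-f}) / (f - i)` when
#' `f != i` (with the limit `C' = C e^{-f} + i S e^{-i}` when `|f - i|` is
#' below 1e-9); `D' = D + (S + C - S' - C')`, so mass is conserved by
#' construction. Vectorised over states and rates.
#'
#' @param state A list with components `S`, `C`, `D` as from
#'   [disease_state_init()].
#' @param i Incidence rate this cycle (per person-year, >= 0).
#' @param f Case-fatality rate this cycle (per prevalent case-year, >= 0).
#' @return The state after one cycle (same shape).
#' @export
step_disease <- function(state, i, f) {
  if (any(i < 0) || any(f < 0)) stop("rates must be >= 0")
  S <- state$S; C <- state$C; D <- state$D
  ei <- exp(-i); ef <- exp(-f)
  near <- abs(f - i) <= 1e-9
  flow <- ifelse(near, i * S * ei,
                 i * S * (ei - ef) / ifelse(near, 1, f - i))
  S2 <- S * ei
  C2 <- C * ef + flow
  D2 <- D + ((S - S2) + (C - C2))
  list(S = S2, C = C2, D = D2)
}

prevalence_among_alive <- function(S, C) {
  alive <- S + C
  ifelse(alive > 0, C / pmax(alive, .Machine$double.xmin), 0)
}

#' Run one cohort's disease lifetable trajectory
#'
#' Simulates a single disease for one age/sex cohort under a per-year series
#' of population impact fractions applied to incidence, with multiplicative
#' annual trends on incidence and case fatality, switching rate bands as the
#' cohort ages across 5-year boundaries (half-open bands; the last band's
#' rates carry forward past its upper edge).
#'
#' @param strata A `cohort_inputs` data frame (supplies the age-banded rate
#'   schedule for the cohort's sex).
#' @param sex,age_group Identify the cohort's base-year stratum.
#' @param disease One of [CVD_DISEASES].
#' @param pif_series Per-year proportions in \[0, 1\] applied as
#'   `i_y = i_base (1 - PIF_y)`; recycled to the horizon if length 1.
#' @param trend `c(incidence =, case_fatality =)` annual fractional changes
#'   applied as `(1 + apc)^y` from the base year.
#' @param horizon Number of annual cycles (> 0); default runs to age 110
#'   from the cohort's mid-band starting age.
#' @param max_age Extinction age.
#' @return A data frame with one row per cycle: `year` (index from 0),
#'   `age`, `S`, `C`, `D` (start-of-cycle state), `prevalence` among alive,
#'   `mortality` (disease mortality rate this cycle, case fatality times
#'   prevalence) and `yld` (prevalence times the band disability rate).
#' @export
run_disease_trajectory <- function(strata, sex, age_group, disease,
                                   pif_series = 0,
                                   trend = c(incidence = 0, case_fatality = 0),
                                   horizon = NULL, max_age = 110) {
  stopifnot(disease %in% CVD_DISEASES)
  sub <- strata[strata$sex == sex, , drop = FALSE]
  sub <- sub[order(sub$age_lo), , drop = FALSE]
  k <- which(sub$age_group == age_group)
  if (length(k) != 1L) stop("no stratum ", sex, " ", age_group)
  start_age <- sub$age_lo[k] + 2L
  if (is.null(horizon)) horizon <- max_age - start_age
  if (horizon <= 0) stop("horizon must be > 0")
  if (length(pif_series) == 1L) pif_series <- rep(pif_series, horizon)
  if (length(pif_series) < horizon)
    stop("pif_series shorter than horizon")
  stopifnot(all(pif_series >= 0), all(pif_series < 1))
  if (any(trend <= -1)) stop("trend must be > -1")

  inc <- sub[[paste0("inc_", disease)]]
  cfr <- sub[[paste0("cfr_", disease)]]
  dr <- sub[[paste0("dr_", disease)]]
  band_of <- function(age) pmin(age %/% 5L + 1L, nrow(sub))

  b0 <- band_of(start_age)
  prev0 <- NULL
  pc <- paste0("prev_", disease)
  if (pc %in% names(sub)) prev0 <- sub[[pc]][k]
  st <- disease_state_init(inc[b0], cfr[b0], prev0)

  out <- vector("list", horizon)
  for (y in seq_len(horizon)) {
    age <- start_age + y - 1L
    b <- band_of(age)
    i_y <- inc[b] * (1 + trend[["incidence"]])^(y - 1) * (1 - pif_series[y])
    f_y <- cfr[b] * (1 + trend[["case_fatality"]])^(y - 1)
    p <- prevalence_among_alive(st$S, st$C)
    out[[y]] <- data.frame(year = y - 1L, age = age, S = st$S, C = st$C,
                           D = st$D, prevalence = p, mortality = f_y * p,
                           yld = dr[b] * p)
    st <- step_disease(st, i_y, f_y)
  }
  do.call(rbind, out)
}
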