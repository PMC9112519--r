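# Orchestration: run the 42 base-year strata as closed cohorts through the
# coupled main/disease lifetables under BAU and intervention, and aggregate
# into the reporting quantities (HALYs gained, per-1000 values, horizons,
# discounting).

#' Run the proportional multistate lifetable
#'
#' Simulates every base-year stratum as a closed cohort (mid-band starting
#' age) in annual cycles from the base year until the cohort reaches
#' `cfg$max_age`. Each cycle, every disease advances one three-state cycle
#' in both arms; intervention incidence is scaled by `1 - PIF`, where the
#' PIF comes from the cohort's exposure prevalence, the annualised SBP
#' shift, and the risk-function slope of the band containing the cohort's
#' current age (ages below 15, or bands without a risk entry, get PIF 0).
#' The main lifetable absorbs the between-arm differences in disease
#' mortality (as a hazard increment) and disease YLD rates (as a morbidity
#' increment). Deterministic: central parameter values, no sampling.
#'
#' @param strata A `cohort_inputs` data frame (canonical 42 strata).
#' @param risks A `risk_functions` data frame; required unless
#'   `mode = "bau"`.
#' @param cfg A [scenario_config()].
#' @param mode `"both"` (default) runs BAU and intervention; `"bau"` runs
#'   only BAU (intervention columns equal BAU); `"intervention"` is a
#'   synonym of `"both"` since the intervention arm is defined by its
#'   differences from BAU.
#' @return A `pmslt_result` list: `years` (calendar), `cohorts` (stratum
#'   table with starting ages), per-capita cycle matrices (years x cohorts)
#'   `l_bau`, `l_int`, `ly_bau`, `ly_int`, `haly_bau`, `haly_int`,
#'   `deaths_bau`, `deaths_int`, plus `cfg`, `delta` (mmHg) and
#'   `weighted_exposure_prev`.
#' @export
run_scenario <- function(strata, risks = NULL, cfg = scenario_config(),
                         mode = c("both", "bau", "intervention")) {
  mode <- match.arg(mode)
  if (mode != "bau" && is.null(risks))
    stop("mode '", mode, "' requires risk functions")
  strata <- canonical_order(strata)
  delta <- if (mode == "bau") 0 else annual_sbp_shift(cfg)
  res <- pmslt_core(strata, risks, cfg, delta)
  res$mode <- mode
  res
}

# beta slope lookup: bands x diseases matrix of per-mmHg log-RR; 0 where no
# risk entry (those ages carry no SBP pathway).
beta_matrix <- function(risks, n_bands) {
  B <- matrix(0, nrow = n_bands, ncol = length(CVD_DISEASES),
              dimnames = list(NULL, CVD_DISEASES))
  if (is.null(risks)) return(B)
  bands <- age_band_labels()[seq_len(n_bands)]
  for (d in CVD_DISEASES) {
    sub <- risks[risks$disease == d, , drop = FALSE]
    idx <- match(sub$age_group, bands)
    B[idx[!is.na(idx)], d] <- sub$beta[!is.na(idx)]
  }
  B
}

pmslt_core <- function(strata, risks, cfg, delta) {
  n_bands <- nrow(strata) / 2L
  stopifnot(n_bands == as.integer(n_bands))
  nc <- nrow(strata)
  offset <- ifelse(strata$sex == "female", n_bands, 0L)
  start_age <- strata$age_lo + 2L
  pi_exp <- strata$exposure_prev
  B <- beta_matrix(risks, n_bands)

  inc <- lapply(CVD_DISEASES, function(d) strata[[paste0("inc_", d)]])
  cfr <- lapply(CVD_DISEASES, function(d) strata[[paste0("cfr_", d)]])
  dr <- lapply(CVD_DISEASES, function(d) strata[[paste0("dr_", d)]])
  apc_i <- vapply(cfg$apc, `[[`, 0, "incidence")
  apc_f <- vapply(cfg$apc, `[[`, 0, "case_fatality")

  last_age <- cfg$max_age - 1L           # last cycle starts here
  T_max <- max(last_age - start_age + 1L)
  band_of <- function(age) pmin(age %/% 5L + 1L, n_bands)

  # seed disease states at base-year band rates (optional observed
  # prevalence column overrides the steady state)
  b0 <- offset + band_of(start_age)
  Sb <- Cb <- Db <- Si <- Ci <- Di <- matrix(0, nc, 3)
  for (d in 1:3) {
    prev0 <- NULL
    pc <- paste0("prev_", CVD_DISEASES[d])
    if (pc %in% names(strata)) prev0 <- strata[[pc]]
    st <- disease_state_init(inc[[d]][b0], cfr[[d]][b0], prev0)
    Sb[, d] <- Si[, d] <- st$S
    Cb[, d] <- Ci[, d] <- st$C
  }

  lb <- li <- rep(1, nc)
  z <- matrix(0, T_max, nc)
  out <- list(l_bau = z, l_int = z, ly_bau = z, ly_int = z,
              haly_bau = z, haly_int = z, deaths_bau = z, deaths_int = z)
  clamped <- FALSE

  for (t in 0:(T_max - 1L)) {
    attained <- start_age + t
    act <- attained <= last_age
    band <- band_of(attained)
    row <- offset + band
    dm <- dy <- 0   # intervention-minus-BAU accumulators
    for (d in 1:3) {
      i_b <- inc[[d]][row] * (1 + apc_i[d])^t
      f <- cfr[[d]][row] * (1 + apc_f[d])^t
      pif <- ifelse(attained >= 15 & delta > 0,
                    pif_shift(pi_exp, delta, B[band, d]), 0)
      p_b <- prevalence_among_alive(Sb[, d], Cb[, d])
      p_i <- prevalence_among_alive(Si[, d], Ci[, d])
      dm <- dm + f * (p_i - p_b)
      dy <- dy + dr[[d]][row] * (p_i - p_b)
      sb <- step_disease(list(S = Sb[, d], C = Cb[, d], D = Db[, d]), i_b, f)
      si <- step_disease(list(S = Si[, d], C = Ci[, d], D = Di[, d]),
                         i_b * (1 - pif), f)
      Sb[act, d] <- sb$S[act]; Cb[act, d] <- sb$C[act]; Db[act, d] <- sb$D[act]
      Si[act, d] <- si$S[act]; Ci[act, d] <- si$C[act]; Di[act, d] <- si$D[act]
    }
    m <- strata$acmr[row] * (1 + cfg$acmr_trend)^t
    stb <- step_main(lb, m)
    sti <- step_main(li, m, dm)
    yld <- strata$yld_prop[row]
    yld_i <- yld + dy
    if (any(yld_i[act] < 0) || any(yld_i[act] > 1)) clamped <- TRUE
    yld_i <- pmin(pmax(yld_i, 0), 1)

    k <- t + 1L
    out$l_bau[k, act] <- lb[act]
    out$l_int[k, act] <- li[act]
    out$ly_bau[k, act] <- stb$L[act]
    out$ly_int[k, act] <- sti$L[act]
    out$haly_bau[k, act] <- (stb$L * (1 - yld))[act]
    out$haly_int[k, act] <- (sti$L * (1 - yld_i))[act]
    out$deaths_bau[k, act] <- stb$deaths[act]
    out$deaths_int[k, act] <- sti$deaths[act]
    lb[act] <- stb$l_next[act]
    li[act] <- sti$l_next[act]
  }
  if (clamped) warning("morbidity proportion clamped to [0, 1] in some cells")

  cohorts <- data.frame(sex = strata$sex, age_group = strata$age_group,
                        start_age = start_age, n = strata$n,
                        exposure_prev = pi_exp, stringsAsFactors = FALSE)
  structure(c(out, list(
    years = cfg$base_year + 0:(T_max - 1L),
    cohorts = cohorts, cfg = cfg, delta = delta,
    weighted_exposure_prev = weighted_exposure_prev(strata)
  )), class = "pmslt_result")
}

#' Aggregate a run over a reporting horizon and discount rate
#'
#' Sums population-scaled HALYs over calendar years
#' `[base_year, base_year + horizon)` (half-open; `"lifetime"` keeps all
#' years), discounting each year's contribution back to the base year.
#'
#' @param result A `pmslt_result` from [run_scenario()].
#' @param horizon `"lifetime"` or a number of years (e.g. 10, 20).
#' @param rate Annual discount rate.
#' @return A list: `horizon`, `rate`, `bau_total` (HALYs under BAU),
#'   `gain_total` (intervention minus BAU), `per_1000_bau`,
#'   `per_1000_gain`, `ly_gain_total` (undadjusted life years gained).
#' @export
horizon_aggregate <- function(result, horizon = "lifetime", rate = 0) {
  T_max <- length(result$years)
  if (identical(horizon, "lifetime")) {
    idx <- seq_len(T_max)
  } else if (is.numeric(horizon) && length(horizon) == 1L && horizon > 0) {
    idx <- seq_len(min(as.integer(horizon), T_max))
  } else stop("unknown horizon: ", deparse(horizon))
  w <- (1 + rate)^-(idx - 1)
  n <- result$cohorts$n
  tot <- function(mat) drop(crossprod(w, mat[idx, , drop = FALSE] %*% n))
  bau <- tot(result$haly_bau)
  gain <- tot(result$haly_int - result$haly_bau)
  ly_gain <- tot(result$ly_int - result$ly_bau)
  per1000 <- 1000 / sum(n)
  list(horizon = horizon, rate = rate,
       bau_total = bau, gain_total = gain, ly_gain_total = ly_gain,
       per_1000_bau = bau * per1000, per_1000_gain = gain * per1000)
}

#' Summary table across horizons and discount rates
#'
#' @param result A `pmslt_result`.
#' @param horizons Reporting horizons; default lifetime plus the scenario's
#'   configured windows.
#' @param rates Discount rates; default 0 and the configured rate.
#' @return A data frame with one row per horizon x rate.
#' @export
pmslt_summary_table <- function(result,
                                horizons = c(list("lifetime"),
                                             as.list(result$cfg$horizons)),
                                rates = c(0, result$cfg$discount_rate)) {
  rows <- list()
  for (h in horizons) for (r in unique(rates)) {
    a <- horizon_aggregate(result, h, r)
    rows[[length(rows) + 1L]] <- data.frame(
      horizon = as.character(a$horizon), discount_rate = r,
      bau_halys = a$bau_total, halys_gained = a$gain_total,
      bau_per_1000 = a$per_1000_bau, gain_per_1000 = a$per_1000_gain)
  }
  do.call(rbind, rows)
}

#' @export
print.pmslt_result <- function(x, ...) {
  cat("pMSLT run:", length(x$years), "annual cycles from", x$years[1],
      "|", nrow(x$cohorts), "cohorts | SBP shift", format(x$delta, digits = 4),
      "mmHg\n")
  tab <- pmslt_summary_table(x)
  tab[, 3:6] <- signif(tab[, 3:6], 6)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Per-cohort-year lifetable export
#'
#' @param x A `pmslt_result`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (unused).
#' @return Long data frame: year, sex, age_group, alive and person-years and
#'   HALYs per capita under both arms.
#' @export
as.data.frame.pmslt_result <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  nc <- nrow(x$cohorts)
  T_max <- length(x$years)
  data.frame(
    year = rep(x$years, nc),
    sex = rep(x$cohorts$sex, each = T_max),
    age_group = rep(x$cohorts$age_group, each = T_max),
    l_bau = as.vector(x$l_bau), l_int = as.vector(x$l_int),
    ly_bau = as.vector(x$ly_bau), ly_int = as.vector(x$ly_int),
    haly_bau = as.vector(x$haly_bau), haly_int = as.vector(x$haly_int),
    stringsAsFactors = FALSE)
}

#' Per-cohort, per-disease, per-year population impact fractions
#'
#' Tabulates the PIF the engine applies in each cell: the cohort's exposure
#' prevalence and the scenario's annualised SBP shift, through the risk
#' slope of the band containing the cohort's attained age (0 below age 15
#' or where no risk entry exists).
#'
#' @inheritParams run_scenario
#' @param years How many annual cycles to tabulate (default: all).
#' @return Data frame: `sex`, `age_group`, `disease`, `year` (calendar),
#'   `age`, `pif`.
#' @export
pif_table <- function(strata, risks, cfg = scenario_config(), years = NULL) {
  strata <- canonical_order(strata)
  n_bands <- nrow(strata) / 2L
  B <- beta_matrix(risks, n_bands)
  delta <- annual_sbp_shift(cfg)
  start_age <- strata$age_lo + 2L
  out <- list()
  for (c in seq_len(nrow(strata))) {
    T_c <- cfg$max_age - start_age[c]
    if (!is.null(years)) T_c <- min(T_c, years)
    t <- seq_len(T_c) - 1L
    age <- start_age[c] + t
    band <- pmin(age %/% 5L + 1L, n_bands)
    for (d in CVD_DISEASES) {
      pif <- ifelse(age >= 15,
                    pif_shift(strata$exposure_prev[c], delta, B[band, d]), 0)
      out[[length(out) + 1L]] <- data.frame(
        sex = strata$sex[c], age_group = strata$age_group[c], disease = d,
        year = cfg$base_year + t, age = age, pif = pif,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Rank the modelled gain against published comparator interventions
#'
#' Merges this model's discounted HALYs-per-1000 estimate into a
#' user-supplied comparator table and rank-orders by point estimate
#' (descending), breaking ties by intervention name.
#'
#' @param estimate Model point estimate (HALYs per 1000).
#' @param ui_lo,ui_hi Optional uncertainty interval bounds.
#' @param comparators Data frame with columns `intervention`,
#'   `halys_per_1000`, `ui_lo`, `ui_hi` (may have 0 rows), or a CSV path.
#'   The packaged comparator set is
#'   `cold_housing_fixture("league_table_cvd.csv")`.
#' @param label Row label for the model estimate.
#' @return Ranked data frame with a `rank` column.
#' @export
league_table_report <- function(estimate, ui_lo = NA_real_, ui_hi = NA_real_,
                                comparators = NULL,
                                label = "Eradication of cold housing") {
  if (is.character(comparators))
    comparators <- read.csv(comparators, stringsAsFactors = FALSE)
  if (is.null(comparators))
    comparators <- data.frame(intervention = character(),
                              halys_per_1000 = numeric(),
                              ui_lo = numeric(), ui_hi = numeric())
  need <- c("intervention", "halys_per_1000", "ui_lo", "ui_hi")
  if (!all(need %in% names(comparators)))
    stop("comparator table needs columns: ", paste(need, collapse = ", "))
  if (nrow(comparators) &&
      (!is.numeric(comparators$halys_per_1000) ||
       any(is.na(comparators$halys_per_1000))))
    stop("malformed comparator table: non-numeric halys_per_1000")
  tab <- rbind(
    data.frame(intervention = label, halys_per_1000 = estimate,
               ui_lo = ui_lo, ui_hi = ui_hi, stringsAsFactors = FALSE),
    comparators[, need])
  tab <- tab[order(-tab$halys_per_1000, tab$intervention), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[, c("rank", need)]
}
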