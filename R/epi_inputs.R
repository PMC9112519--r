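# Reading, validating and writing the age/sex-stratified epidemiological
# input tables. File convention: IR/DR/mortality per 100,000 persons, CFR per
# prevalent case-year, exposure prevalence in percent. In memory everything
# is a per-person annual rate or a proportion.

per_100k_cols <- function() {
  c("mortality_per_100k",
    paste0(rep(CVD_DISEASES, each = 2), rep(c("_ir_per_100k", "_dr_per_100k"), 3)))
}

required_input_cols <- function() {
  c("sex", "age_group", "n", "prevalence_pct", "morbidity_prop",
    "sbp_mean", "sbp_sd", per_100k_cols(),
    paste0(CVD_DISEASES, "_cfr"))
}

#' Load age/sex-stratified cohort inputs
#'
#' Reads a base-year epidemiology CSV (one row per sex by 5-year age band),
#' validates it, and converts file units to per-person annual rates:
#' per-100,000 incidence, disability and mortality rates are multiplied by
#' 1e-5 and exposure prevalence in percent is divided by 100. Case-fatality
#' rates are already per prevalent case-year. Systolic blood pressure is
#' absent (NA) below age 15; those ages carry no modelled SBP pathway.
#'
#' @param path CSV file path (UTF-8, comma separated, header row). The
#'   packaged base-year table is at `cold_housing_fixture("table2_2016.csv")`.
#' @param schema_version Input schema identifier; only `"1"` exists.
#' @return A `cohort_inputs` data frame in canonical order (males then
#'   females, ascending age) with columns `sex`, `age_group`, `age_lo`,
#'   `age_hi`, `n`, `exposure_prev`, `acmr`, `yld_prop`, `sbp_mean`,
#'   `sbp_sd`, and per disease `inc_*`, `cfr_*`, `dr_*`.
#' @export
load_cohort_inputs <- function(path, schema_version = "1") {
  if (!identical(as.character(schema_version), "1"))
    stop("unknown schema_version: ", schema_version)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no strata in ", path)
  missing_cols <- setdiff(required_input_cols(), names(raw))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  convert_raw_inputs(raw)
}

# shared by load_cohort_inputs() and generate_inputs(): validate a raw
# file-convention table and convert to per-person units
convert_raw_inputs <- function(raw) {
  validate_raw_inputs(raw)
  out <- data.frame(
    sex = raw$sex,
    age_group = raw$age_group,
    age_lo = age_band_lower(raw$age_group),
    n = raw$n,
    exposure_prev = raw$prevalence_pct / 100,
    acmr = raw$mortality_per_100k * 1e-5,
    yld_prop = raw$morbidity_prop,
    sbp_mean = raw$sbp_mean,
    sbp_sd = raw$sbp_sd,
    stringsAsFactors = FALSE
  )
  out$age_hi <- out$age_lo + 4L
  for (d in CVD_DISEASES) {
    out[[paste0("inc_", d)]] <- raw[[paste0(d, "_ir_per_100k")]] * 1e-5
    out[[paste0("cfr_", d)]] <- raw[[paste0(d, "_cfr")]]
    out[[paste0("dr_", d)]] <- raw[[paste0(d, "_dr_per_100k")]] * 1e-5
  }
  # optional observed disease prevalence proportions (override steady-state
  # seeding in the disease lifetables)
  for (d in CVD_DISEASES) {
    pc <- paste0("prev_", d)
    if (pc %in% names(raw)) out[[pc]] <- raw[[pc]]
  }
  out <- canonical_order(out)
  class(out) <- c("cohort_inputs", "data.frame")
  out
}

validate_raw_inputs <- function(raw) {
  bands <- age_band_labels()
  key <- paste(raw$sex, raw$age_group)
  dup <- key[duplicated(key)]
  if (length(dup)) stop("duplicate stratum: ", dup[1])
  if (!all(raw$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female' (row ",
         which(!raw$sex %in% c("male", "female"))[1], ")")
  want <- as.vector(outer(bands, c("male", "female"),
                          function(b, s) paste(s, b)))
  absent <- setdiff(want, key)
  if (length(absent)) stop("missing stratum: ", absent[1])
  if (!all(raw$age_group %in% bands))
    stop("unknown age band: ", setdiff(raw$age_group, bands)[1])

  check_range <- function(col, lo = 0, hi = Inf, allow_na = FALSE) {
    v <- raw[[col]]
    bad <- if (allow_na) which(!is.na(v) & (v < lo | v > hi))
           else which(is.na(v) | v < lo | v > hi)
    if (length(bad))
      stop(sprintf("invalid value in column '%s', row %d (%s %s): %s",
                   col, bad[1], raw$sex[bad[1]], raw$age_group[bad[1]],
                   v[bad[1]]))
  }
  check_range("n", 0)
  check_range("prevalence_pct", 0, 100)
  check_range("morbidity_prop", 0, 1)
  for (col in c(per_100k_cols(), paste0(CVD_DISEASES, "_cfr")))
    check_range(col, 0)
  # SBP present iff age >= 15, and positive sd where present
  lo <- age_band_lower(raw$age_group)
  needs_sbp <- lo >= 15
  if (any(needs_sbp & (is.na(raw$sbp_mean) | is.na(raw$sbp_sd))))
    stop("missing systolic blood pressure at ages 15+ (row ",
         which(needs_sbp & is.na(raw$sbp_mean))[1], ")")
  check_range("sbp_sd", lo = 1e-12, allow_na = TRUE)
  invisible(TRUE)
}

canonical_order <- function(strata) {
  ord <- order(match(strata$sex, c("male", "female")), strata$age_lo)
  strata <- strata[ord, , drop = FALSE]
  rownames(strata) <- NULL
  strata
}

#' Write cohort inputs back to the file convention
#'
#' Inverse of [load_cohort_inputs()]: converts per-person rates back to
#' per-100,000 and proportions back to percent, so that a write/read
#' round-trip is the identity.
#'
#' @param strata A `cohort_inputs` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_inputs <- function(strata, path) {
  raw <- data.frame(
    sex = strata$sex,
    age_group = strata$age_group,
    n = strata$n,
    prevalence_pct = strata$exposure_prev * 100,
    mortality_per_100k = strata$acmr * 1e5,
    morbidity_prop = strata$yld_prop,
    sbp_mean = strata$sbp_mean,
    sbp_sd = strata$sbp_sd,
    stringsAsFactors = FALSE
  )
  for (d in CVD_DISEASES) {
    raw[[paste0(d, "_ir_per_100k")]] <- strata[[paste0("inc_", d)]] * 1e5
    raw[[paste0(d, "_cfr")]] <- strata[[paste0("cfr_", d)]]
    raw[[paste0(d, "_dr_per_100k")]] <- strata[[paste0("dr_", d)]] * 1e5
  }
  for (d in CVD_DISEASES) {
    pc <- paste0("prev_", d)
    if (pc %in% names(strata)) raw[[pc]] <- strata[[pc]]
  }
  write.csv(raw, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Load systolic-blood-pressure risk functions
#'
#' Reads a CSV of per-disease, per-age-band relative risks of CVD incidence
#' per 10 mmHg systolic blood pressure and derives the per-mmHg log-linear
#' slope `beta = ln(rr)/10`. Optional `rr_lo`/`rr_hi` columns carry a 95% CI
#' used by the uncertainty module.
#'
#' @param path CSV path with columns `disease`, `age_group`,
#'   `rr_per_10mmhg` (and optionally `rr_lo`, `rr_hi`, `source`).
#' @param inherit_older If `TRUE`, age bands (15+) missing from the file
#'   inherit the nearest older band's relative risk; if `FALSE` (default)
#'   incomplete coverage is an error. Bands below 15 never need coverage
#'   (no modelled SBP pathway).
#' @return A `risk_functions` data frame with one row per (disease, band).
#' @export
load_risk_functions <- function(path, inherit_older = FALSE) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("disease", "age_group", "rr_per_10mmhg")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(raw$disease %in% CVD_DISEASES))
    stop("unknown disease: ", setdiff(raw$disease, CVD_DISEASES)[1])
  absent <- setdiff(CVD_DISEASES, raw$disease)
  if (length(absent)) stop("missing disease: ", absent[1])
  bad <- which(is.na(raw$rr_per_10mmhg) | raw$rr_per_10mmhg <= 0)
  if (length(bad))
    stop("rr_per_10mmhg must be > 0 (row ", bad[1], ")")
  key <- paste(raw$disease, raw$age_group)
  if (anyDuplicated(key))
    stop("duplicate (disease, age band): ", key[duplicated(key)][1])

  bands <- age_band_labels()
  if (!all(raw$age_group %in% bands))
    stop("unknown age band: ", setdiff(raw$age_group, bands)[1])
  covered_bands <- bands[age_band_lower(bands) >= 15]
  rows <- list()
  for (d in CVD_DISEASES) {
    sub <- raw[raw$disease == d, , drop = FALSE]
    miss <- setdiff(covered_bands, sub$age_group)
    if (length(miss)) {
      if (!inherit_older)
        stop("incomplete age coverage for ", d, ": missing ", miss[1],
             " (set inherit_older = TRUE to fill from the nearest older band)")
      for (band in miss) {
        lo <- age_band_lower(band)
        older <- sub[age_band_lower(sub$age_group) > lo, , drop = FALSE]
        if (nrow(older) == 0L)
          stop("no older band to inherit for ", d, " ", band)
        donor <- older[which.min(age_band_lower(older$age_group)), ]
        donor$age_group <- band
        sub <- rbind(sub, donor)
      }
    }
    rows[[d]] <- sub
  }
  out <- do.call(rbind, rows)
  out$beta <- log(out$rr_per_10mmhg) / 10
  out <- out[order(match(out$disease, CVD_DISEASES),
                   age_band_lower(out$age_group)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("risk_functions", "data.frame")
  out
}

#' Internal consistency report for epidemiological inputs
#'
#' Flags strata whose disease inputs are mutually impossible, in the spirit
#' of the coherence checking usually delegated to incidence-prevalence-
#' mortality tools: (a) disease-specific mortality implied by the inputs
#' (case fatality times implied prevalence) exceeding the all-cause
#' mortality rate, and (b) where an observed prevalence column is supplied,
#' an implied steady-state prevalence `i/(i+f)` differing from it by more
#' than `factor`-fold. Report only; never mutates the data.
#'
#' @param strata A `cohort_inputs` data frame.
#' @param factor Flag threshold for the observed/implied prevalence ratio.
#' @return A data frame of flags (possibly 0 rows) with columns `sex`,
#'   `age_group`, `disease`, `check`, `detail`.
#' @export
check_epi_coherence <- function(strata, factor = 10) {
  flags <- list()
  total_excess <- numeric(nrow(strata))
  for (d in CVD_DISEASES) {
    i <- strata[[paste0("inc_", d)]]
    f <- strata[[paste0("cfr_", d)]]
    p_implied <- ifelse(i + f > 0, i / (i + f), 0)
    excess <- f * p_implied
    total_excess <- total_excess + excess
    over <- which(excess > strata$acmr)
    for (k in over) {
      flags[[length(flags) + 1L]] <- data.frame(
        sex = strata$sex[k], age_group = strata$age_group[k], disease = d,
        check = "disease_mortality_exceeds_acmr",
        detail = sprintf("cfr x implied prevalence = %.5f > acmr = %.5f",
                         excess[k], strata$acmr[k]),
        stringsAsFactors = FALSE)
    }
    pc <- paste0("prev_", d)
    if (pc %in% names(strata)) {
      obs <- strata[[pc]]
      ratio <- pmax(obs, 1e-12) / pmax(p_implied, 1e-12)
      bad <- which(!is.na(obs) & (ratio > factor | ratio < 1 / factor))
      for (k in bad) {
        flags[[length(flags) + 1L]] <- data.frame(
          sex = strata$sex[k], age_group = strata$age_group[k], disease = d,
          check = "prevalence_inconsistent_with_steady_state",
          detail = sprintf("observed %.5f vs implied %.5f", obs[k],
                           p_implied[k]),
          stringsAsFactors = FALSE)
      }
    }
  }
  over_all <- which(total_excess > strata$acmr)
  for (k in over_all) {
    flags[[length(flags) + 1L]] <- data.frame(
      sex = strata$sex[k], age_group = strata$age_group[k], disease = "all",
      check = "summed_disease_mortality_exceeds_acmr",
      detail = sprintf("sum cfr x implied prevalence = %.5f > acmr = %.5f",
                       total_excess[k], strata$acmr[k]),
      stringsAsFactors = FALSE)
  }
  if (length(flags)) do.call(rbind, flags)
  else data.frame(sex = character(), age_group = character(),
                  disease = character(), check = character(),
                  detail = character(), stringsAsFactors = FALSE)
}

#' Population-weighted cold-housing exposure prevalence
#'
#' @param strata A `cohort_inputs` data frame.
#' @return Scalar: sum(n * exposure_prev) / sum(n).
#' @export
weighted_exposure_prev <- function(strata) {
  sum(strata$n * strata$exposure_prev) / sum(strata$n)
}
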