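# Main all-cause lifetable: rates are treated as hazards with exponential
# within-cycle survival and mid-cycle person-years (standard lifetable
# practice). Disease-specific mortality and morbidity *differences* from the
# parallel disease lifetables are absorbed here each cycle.

#' Advance the main lifetable one annual cycle
#'
#' Survival over one cycle at total hazard `m + dm`:
#' `l_next = l exp(-(m + dm))`, person-years by the mid-cycle approximation
#' `L = (l + l_next)/2`, deaths `l - l_next`. `dm` is the summed
#' disease-mortality difference relative to BAU and may be negative under
#' intervention; a negative total hazard signals inconsistent inputs and is
#' an error.
#'
#' @param l Alive proportion at cycle start.
#' @param m All-cause mortality rate (per person-year, >= 0).
#' @param dm Summed disease mortality rate difference (may be negative).
#' @return A list with `l_next`, `L` (person-years), `deaths`. Vectorised.
#' @export
step_main <- function(l, m, dm = 0) {
  if (any(m < 0)) stop("mortality rate must be >= 0")
  h <- m + dm
  if (any(h < 0))
    stop("total mortality hazard negative: disease inputs inconsistent")
  l_next <- l * exp(-h)
  list(l_next = l_next, L = (l + l_next) / 2, deaths = l - l_next)
}

#' Convert person-years to health-adjusted life years
#'
#' `HALY = L (1 - (yld_prop + dyld))`, where `yld_prop` is the all-cause
#' morbidity proportion and `dyld` the summed disease YLD-rate difference
#' relative to BAU (non-positive under an intervention that removes
#' disease). The total morbidity proportion is clamped to \[0, 1\] with a
#' warning when outside.
#'
#' @param L Person-years lived this cycle.
#' @param yld_prop All-cause morbidity as proportion of a life year lost.
#' @param dyld Summed disease YLD-rate difference.
#' @return Health-adjusted person-years. Vectorised.
#' @export
health_adjust <- function(L, yld_prop, dyld = 0) {
  tot <- yld_prop + dyld
  if (any(tot < 0) || any(tot > 1)) {
    warning("morbidity proportion outside [0, 1]; clamped")
    tot <- pmin(pmax(tot, 0), 1)
  }
  L * (1 - tot)
}

#' Discount a value back to the base year
#'
#' `value / (1 + rate)^(year - base_year)`; the base year itself is
#' undiscounted.
#'
#' @param value Quantity accrued in `year` (e.g. HALYs).
#' @param year Calendar year of accrual (>= `base_year`).
#' @param base_year Anchor year.
#' @param rate Annual discount rate (>= 0).
#' @return Discounted value. Vectorised.
#' @export
discount <- function(value, year, base_year = 2016, rate = 0.03) {
  if (rate < 0) stop("rate must be >= 0")
  if (any(year < base_year)) stop("year before base_year")
  value / (1 + rate)^(year - base_year)
}
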