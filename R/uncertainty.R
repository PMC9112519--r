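# Monte Carlo propagation of parameter uncertainty. Correlated deviates are
# induced rank-preservingly through shared standard-normal factors (a
# Gaussian copula): the exposure-prevalence deviates share a common factor
# giving an exchangeable cross-age correlation, and disease-input
# multipliers are drawn once per disease so male and female schedules move
# together (between-sex correlation 1.0).

#' Build an uncertainty specification
#'
#' Distributions follow the model's input-uncertainty statement:
#' exposure-time fraction ~ Beta(10.5, 22); trial SBP effect ~ Normal(5.8,
#' sd from its 95% CI (-9.3, -2.4), i.e. 6.9/(2 x 1.96) mmHg); age-specific
#' exposure prevalence ~ Normal with sd twice the survey standard error and
#' exchangeable cross-age correlation 0.1574; incidence ~ lognormal
#' multiplier with 5% sd; disability rates ~ normal multiplier with 10% sd;
#' relative risks ~ lognormal within their published CIs. Between-sex
#' correlation is 1.0 for all disease inputs (multipliers shared across
#' sexes).
#'
#' @param exposure_time `c(alpha1, alpha2)` of the Beta exposure-time
#'   distribution.
#' @param sbp_effect `c(mean, sd)` of the trial effect (mmHg).
#' @param prevalence List: `se_scale` (multiplier on the survey SE),
#'   `n_eff` (effective survey sample size per age band used to form
#'   binomial SEs), `correlation` (common pairwise cross-age correlation).
#' @param incidence List: `sd` of the lognormal incidence multiplier.
#' @param disability List: `sd` of the normal disability-rate multiplier.
#' @param rr List: `use_ci = TRUE` samples relative risks lognormally within
#'   their `rr_lo`/`rr_hi` columns (one deviate per disease, shared across
#'   ages).
#' @param iterations Default Monte Carlo iteration count.
#' @return An `uncertainty_spec` list.
#' @export
uncertainty_spec <- function(exposure_time = c(alpha1 = 10.5, alpha2 = 22),
                             sbp_effect = c(mean = 5.8,
                                            sd = (9.3 - 2.4) / (2 * qnorm(0.975))),
                             prevalence = list(se_scale = 2,
                                               n_eff = 4500 / 21,
                                               correlation = 0.1574),
                             incidence = list(sd = 0.05),
                             disability = list(sd = 0.10),
                             rr = list(use_ci = TRUE),
                             iterations = 2000) {
  stopifnot(all(exposure_time > 0), sbp_effect[["sd"]] >= 0,
            prevalence$correlation >= 0, prevalence$correlation <= 1,
            incidence$sd >= 0, disability$sd >= 0, iterations >= 0)
  structure(list(exposure_time = exposure_time, sbp_effect = sbp_effect,
                 prevalence = prevalence, incidence = incidence,
                 disability = disability, rr = rr,
                 iterations = iterations),
            class = "uncertainty_spec")
}

draw_positive <- function(n, rfun, max_tries = 100L) {
  rejections <- 0L
  for (k in seq_len(max_tries)) {
    x <- rfun(n)
    if (all(x >= 0)) return(list(x = x, rejections = rejections))
    rejections <- rejections + 1L
  }
  stop("could not draw a non-negative value in ", max_tries, " attempts")
}

#' Draw one coherent joint perturbation of the model inputs
#'
#' Uses the current RNG state; deterministic given it. Exposure prevalences
#' are clipped to \[0, 1\]; other invalid draws (negative effect sizes or
#' multipliers) are rejected and redrawn so their distributions keep shape
#' away from the boundary.
#'
#' @param spec An [uncertainty_spec()].
#' @param strata,risks,cfg Central inputs to perturb.
#' @return A list with perturbed `strata`, `risks`, `cfg`, plus `rejections`
#'   (redraw count) and `clipped` (number of prevalence cells clipped).
#' @export
sample_draw <- function(spec, strata, risks, cfg) {
  rejections <- 0L

  tf <- rbeta(1, spec$exposure_time[["alpha1"]], spec$exposure_time[["alpha2"]])
  eff <- draw_positive(1, function(n)
    rnorm(n, spec$sbp_effect[["mean"]], spec$sbp_effect[["sd"]]))
  rejections <- rejections + eff$rejections
  cfg$exposure_time_fraction <- tf
  cfg$sbp_effect <- eff$x

  # exchangeable cross-age correlation via a shared factor; one deviate per
  # age band applied to both sexes (prevalence is measured per person, not
  # per sex, in the source survey)
  strata <- canonical_order(strata)
  n_bands <- nrow(strata) / 2L
  rho <- spec$prevalence$correlation
  z <- sqrt(rho) * rnorm(1) + sqrt(1 - rho) * rnorm(n_bands)
  p0 <- strata$exposure_prev[seq_len(n_bands)]
  se <- spec$prevalence$se_scale * sqrt(p0 * (1 - p0) / spec$prevalence$n_eff)
  p_new <- p0 + se * z
  clipped <- sum(p_new < 0 | p_new > 1)
  p_new <- pmin(pmax(p_new, 0), 1)
  strata$exposure_prev <- rep(p_new, 2L)

  # per-disease multipliers, shared across sexes and ages
  for (d in CVD_DISEASES) {
    sdlog <- sqrt(log(1 + spec$incidence$sd^2))
    g_inc <- rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    strata[[paste0("inc_", d)]] <- strata[[paste0("inc_", d)]] * g_inc
    g_dr <- draw_positive(1, function(n) rnorm(n, 1, spec$disability$sd))
    rejections <- rejections + g_dr$rejections
    strata[[paste0("dr_", d)]] <- strata[[paste0("dr_", d)]] * g_dr$x
  }

  if (isTRUE(spec$rr$use_ci) && !is.null(risks) &&
      all(c("rr_lo", "rr_hi") %in% names(risks))) {
    for (d in CVD_DISEASES) {
      sel <- risks$disease == d
      se_log <- (log(risks$rr_hi[sel]) - log(risks$rr_lo[sel])) /
        (2 * qnorm(0.975))
      zd <- rnorm(1)
      rr_new <- exp(log(risks$rr_per_10mmhg[sel]) + se_log * zd)
      risks$rr_per_10mmhg[sel] <- rr_new
      risks$beta[sel] <- log(rr_new) / 10
    }
  }
  list(strata = strata, risks = risks, cfg = cfg,
       rejections = rejections, clipped = clipped)
}

#' Monte Carlo uncertainty propagation
#'
#' Runs the full two-arm model once at central values, then `iterations`
#' times under joint input draws, and summarises each reporting cell
#' (per-1000 HALY gain by horizon and discount rate) by its central-run
#' value, draw mean, and empirical 2.5th/97.5th percentiles. Reproducible
#' by seed; draws are independent across iterations.
#'
#' @param strata,risks,cfg Central inputs (see [run_scenario()]).
#' @param spec An [uncertainty_spec()].
#' @param iterations Number of draws (>= 2); default from `spec`.
#' @param seed Integer seed; default `cfg$seed`.
#' @return A `pmslt_mc` list: `cells` (data frame with `cell`, `central`,
#'   `mean`, `ui_lo`, `ui_hi`), `draws` (iterations x cells matrix),
#'   `iterations`, `seed`, `rejections`, `clipped`.
#' @export
run_monte_carlo <- function(strata, risks, cfg = scenario_config(),
                            spec = uncertainty_spec(),
                            iterations = spec$iterations, seed = cfg$seed) {
  if (iterations < 2) stop("iterations must be >= 2")
  if (!is.null(seed)) set.seed(seed)

  cells <- expand.grid(horizon = c("lifetime", cfg$horizons),
                       rate = unique(c(0, cfg$discount_rate)),
                       stringsAsFactors = FALSE)
  cell_names <- sprintf("gain_per_1000_%s_disc%g", cells$horizon,
                        100 * cells$rate)
  agg <- function(res) {
    vapply(seq_len(nrow(cells)), function(k) {
      h <- cells$horizon[k]
      if (h != "lifetime") h <- as.numeric(h)
      horizon_aggregate(res, h, cells$rate[k])$per_1000_gain
    }, 0)
  }

  central <- agg(run_scenario(strata, risks, cfg))
  draws <- matrix(NA_real_, iterations, nrow(cells),
                  dimnames = list(NULL, cell_names))
  rejections <- clipped <- 0L
  for (it in seq_len(iterations)) {
    dr <- sample_draw(spec, strata, risks, cfg)
    rejections <- rejections + dr$rejections
    clipped <- clipped + dr$clipped
    draws[it, ] <- agg(run_scenario(dr$strata, dr$risks, dr$cfg))
  }
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(cell = cell_names, horizon = cells$horizon,
                    rate = cells$rate, central = central,
                    mean = colMeans(draws), ui_lo = qs[1, ], ui_hi = qs[2, ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(cells = out, draws = draws, iterations = iterations,
                 seed = seed, rejections = rejections, clipped = clipped),
            class = "pmslt_mc")
}

#' @export
print.pmslt_mc <- function(x, ...) {
  cat("Monte Carlo:", x$iterations, "iterations, seed",
      if (is.null(x$seed)) "none" else x$seed, "|", x$rejections,
      "redraws,", x$clipped, "prevalence cells clipped\n")
  tab <- x$cells
  tab[, c("central", "mean", "ui_lo", "ui_hi")] <-
    signif(tab[, c("central", "mean", "ui_lo", "ui_hi")], 4)
  print(tab[, c("cell", "central", "mean", "ui_lo", "ui_hi")],
        row.names = FALSE)
  invisible(x)
}
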