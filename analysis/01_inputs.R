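#!/usr/bin/env Rscript
# Load and inspect the base-year (2016) epidemiological inputs for the
# three-state population (NSW, Victoria, South Australia), check their
# internal coherence, and summarise the cold-housing exposure.

suppressPackageStartupMessages(library(coldpmslt))
dir.create("results", showWarnings = FALSE)

strata <- load_cohort_inputs(cold_housing_fixture("table2_2016.csv"))
cat(sprintf("Loaded %d strata; total 2016 population %s persons\n",
            nrow(strata), format(sum(strata$n), big.mark = ",")))

wp <- weighted_exposure_prev(strata)
cat(sprintf("Population-weighted cold-housing prevalence: %.2f%%\n", 100 * wp))
cat("  (the published analysis quotes an exposed share of 5.74%;\n",
    "  the per-band table weights to the value above — both are reported)\n")

flags <- check_epi_coherence(strata)
cat(sprintf("Coherence check: %d flag(s)\n", nrow(flags)))
if (nrow(flags)) print(flags)
write.csv(flags, "results/coherence_flags.csv", row.names = FALSE)

risks <- load_risk_functions(cold_housing_fixture("synthetic_sbp_rr_by_age.csv"))
cat(sprintf("Risk functions: %d (disease, age band) entries; IHD RR per 10 mmHg at 55-59 = %.2f\n",
            nrow(risks), risks$rr_per_10mmhg[risks$disease == "ihd" &
                                               risks$age_group == "55-59"]))
cat("NOTE: the packaged risk schedule is a constructed, GBD-style stand-in\n",
    "(see the package vignette); substitute the original supplementary table\n",
    "via load_risk_functions() for a faithful reproduction.\n")

summ <- data.frame(total_population = sum(strata$n),
                   weighted_exposure_prev = wp,
                   coherence_flags = nrow(flags))
write.csv(summ, "results/input_summary.csv", row.names = FALSE)
cat("Wrote results/coherence_flags.csv and results/input_summary.csv\n")
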