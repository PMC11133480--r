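#!/usr/bin/env Rscript
# Survival and safety summaries: Kaplan-Meier with 6-month PFS landmark,
# EG12-high vs -low log-rank and Cox HR per cohort, Mann-Whitney comparison
# of biomarker distributions between cohorts, AE tabulation and PK
# steady-state summary. Writes results/survival_stats.json.

suppressPackageStartupMessages(library(cxtrial))

biomarker <- utils::read.csv("results/biomarker.csv")
out <- list()

for (arm_dir in c("aptamer", "soc")) {
  surv <- utils::read.csv(sprintf("results/survival_derived_%s.csv", arm_dir))
  arm <- if (arm_dir == "aptamer") "APTAMER" else "SOC"
  b <- biomarker[biomarker$cohort == arm, ]
  sv <- merge(surv, b[, c("patient_id", "EG12_class")], by = "patient_id")
  sv$group <- sv$EG12_class
  pfs <- sv[sv$endpoint == "PFS", ]
  os <- sv[sv$endpoint == "OS", ]

  km_pfs <- km_estimate(pfs, query_day = 183)
  km_hi <- km_estimate(pfs[pfs$group == "high", ])
  km_lo <- km_estimate(pfs[pfs$group == "low", ])
  cox <- tryCatch(suppressWarnings(cox_hr(pfs, level_of_interest = "high")),
                  error = function(e) NULL)
  lr <- suppressWarnings(logrank_test(pfs[pfs$group == "high", ],
                                      pfs[pfs$group == "low", ]))

  out[[arm]] <- list(
    km = list(median_pfs = km_pfs$median, pfs_6mo_pct = 100 * km_pfs$surv_at_query,
              median_os = km_estimate(os)$median,
              median_pfs_high = km_hi$median, median_pfs_low = km_lo$median),
    logrank = lr,
    cox = if (!is.null(cox)) unclass(cox))
  cat(sprintf("%s: median PFS %s d, 6-month PFS %.1f%%; EG12 high vs low median %s vs %s d, log-rank p = %.3f\n",
              arm, format(km_pfs$median), 100 * km_pfs$surv_at_query,
              format(km_hi$median), format(km_lo$median), lr$p))
}

mw <- mann_whitney(biomarker$EG12[biomarker$cohort == "APTAMER"],
                   biomarker$EG12[biomarker$cohort == "SOC"])
out$eg12_between_cohorts_mann_whitney <- mw
cat(sprintf("EG12 between cohorts: Mann-Whitney U = %.1f, p = %.3f (%s)\n",
            mw$U, mw$p, mw$method))

ae <- ae_summary(utils::read.csv("results/cohorts/aptamer/ae.csv"))
pk <- pk_summary(utils::read.csv("results/cohorts/aptamer/pk.csv"))
out$ae <- unclass(ae)
out$pk <- pk
cat(sprintf("AEs: %d total, grade-1 share %.1f%%\n", ae$total,
            ae$by_grade$pct[1]))
cat(sprintf("PK: steady state by day %g, plateau %.2f uM (> 1.5 uM: %s, drug over target: %s)\n",
            pk$steady_state_day, pk$plateau_uM, pk$exceeds_threshold,
            pk$drug_over_target))

esc <- escalation_decision(3, 0, dose_level = 3)
out$escalation <- esc
cat(sprintf("dose escalation: top level tolerated -> %s (RP2D %g mg/week)\n",
            esc$decision, esc$rp2d_mg_per_week))

jsonlite::write_json(out, "results/survival_stats.json", auto_unbox = TRUE,
                     digits = NA, force = TRUE)
cat("wrote results/survival_stats.json\n")
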