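#!/usr/bin/env Rscript
# Build the composite EG12 biomarker from the gated frequency profiles,
# dichotomize each cohort at its median, and correlate biomarker values with
# progression-free survival (event patients only).
# Writes results/biomarker.csv and results/biomarker_stats.json.

suppressPackageStartupMessages(library(cxtrial))

profiles <- utils::read.csv("results/frequency_profiles.csv")
surv <- rbind(utils::read.csv("results/cohorts/aptamer/survival.csv"),
              utils::read.csv("results/cohorts/soc/survival.csv"))

biomarker <- eg12_scores(profiles)
biomarker$EG12_class <- unsplit(
  lapply(split(biomarker$EG12, biomarker$cohort), median_split),
  biomarker$cohort)
utils::write.csv(biomarker, "results/biomarker.csv", row.names = FALSE)

stats <- list()
for (arm in unique(biomarker$cohort)) {
  b <- biomarker[biomarker$cohort == arm, ]
  ids <- b$patient_id
  s <- surv[surv$patient_id %in% ids, ]
  res <- lapply(c(EG12 = "EG12", E12 = "E12", P12 = "P12", M12 = "M12",
                  G12 = "G12"),
                function(v) {
                  r <- correlate_with_pfs(b, s, v)
                  list(r_s = r$r_s, p = r$p, n = r$n)
                })
  stats[[arm]] <- res
  cat(sprintf("%s: EG12 vs PFS r_s = %.3f (p = %.3f, n = %d)\n",
              arm, res$EG12$r_s, res$EG12$p, res$EG12$n))
}
cat("the aptamer cohort shows the positive EG12-PFS correlation built into\n",
    "the generator; the SOC cohort sits near the null\n")
jsonlite::write_json(stats, "results/biomarker_stats.json",
                     auto_unbox = TRUE, digits = NA)
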