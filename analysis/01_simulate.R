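#!/usr/bin/env Rscript
# Simulate the study cohorts: a 10-patient aptamer-arm cohort (one per dose
# level configuration) and a 22-patient standard-of-care comparison cohort,
# written as plain-text bundles under results/cohorts/.
#
# The aptamer cohort carries the built-in EG12 -> PFS hazard link
# (eg12_beta = -1.5 per SD of latent EG12); the SOC cohort draws survival
# independently of EG12. Cell tables use 5,000 segmented cells per sample.

suppressPackageStartupMessages(library(cxtrial))

seed <- 20260926L
out <- "results/cohorts"

apt <- synth_config(seed = seed, n_patients = 10, arm = "APTAMER",
                    id_prefix = "A")
soc <- synth_config(seed = seed + 1L, n_patients = 22, arm = "SOC",
                    id_prefix = "S")

co_apt <- generate_cohort(apt)
co_soc <- generate_cohort(soc)

write_cohort(co_apt, file.path(out, "aptamer"))
write_cohort(co_soc, file.path(out, "soc"))

cat("aptamer cohort: ", nrow(co_apt$truth), "patients,",
    sum(vapply(co_apt$cells, nrow, 1L)), "cells,",
    nrow(co_apt$lesions), "lesion measurements\n")
cat("soc cohort:     ", nrow(co_soc$truth), "patients\n")
cat("PFS events (aptamer):",
    sum(co_apt$survival$event[co_apt$survival$endpoint == "PFS"]), "of 10\n")
cat("bundles written under", out, "\n")
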