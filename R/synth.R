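# Synthetic cohort generator. Emulates the statistical structure the
# downstream analyses assume: cell-type mixtures with CXCL12+ rates ordered
# endothelial > pericyte > macrophage/microglia > glioma, an arm-dependent
# EG12 -> PFS hazard link (present under the aptamer, absent under SOC),
# scripted piecewise-exponential lesion courses on a q8w scan grid, and
# dose-proportional PK accumulation to a steady state above 1.5 uM.

#' Synthetic cohort configuration
#'
#' All tunables of the generator with defaults matching the emulated study
#' conditions: 10 patients per aptamer-arm cohort, an 8-week scan interval,
#' dose levels 200/400/600 mg per week with dose-proportional steady-state
#' plasma levels above 1.5 uM reached in about a week, a baseline PFS hazard
#' giving a median near 174 days, roughly one PFS censoring per 10 patients,
#' and a per-SD log-hazard coefficient for the latent EG12 score that acts in
#' the APTAMER arm only.
#'
#' @param seed integer RNG seed; all randomness streams from it via stable
#'   per-patient sub-seeds, so adding patients never perturbs existing ones.
#' @param n_patients patients in the cohort.
#' @param arm "APTAMER" or "SOC".
#' @param cell_type_mix named fractions over endothelial, pericyte,
#'   mphi_microglia, glioma, other; must sum to 1. Default keeps endothelial
#'   cells roughly an order of magnitude rarer than glioma cells.
#' @param cxcl12_rate named per-type CXCL12+ probabilities; the default is
#'   ordered endothelial > pericyte > mphi_microglia > glioma.
#' @param n_cells segmented cells per sample.
#' @param eg12_beta log hazard per SD of latent EG12 (APTAMER arm only).
#' @param baseline_hazard PFS events per day at EG12 = cohort mean.
#' @param post_progression_hazard hazard of the exponential post-progression
#'   survival increment (OS = PFS + increment).
#' @param censor_rate probability a patient is PFS-censored at a new-therapy
#'   start before progression.
#' @param visit_interval_days scan interval (default 56 = 8 weeks).
#' @param max_visits scans after baseline before follow-up stops.
#' @param followup_days administrative OS censoring horizon.
#' @param pk_dose_mg_per_week one of 200, 400, 600.
#' @param pk_k accumulation rate constant per day (default ln(2)/1.75 puts
#'   the curve at >90% of steady state after one week).
#' @param pk_css_per_mg steady-state uM per mg of weekly dose (default 0.01:
#'   2.0 uM at 200 mg, dose-proportional above it).
#' @param cxcl12_plateau_uM plateau of the mobilized-target series, below the
#'   drug level.
#' @param lesion_noise_sd multiplicative log-normal measurement noise on
#'   lesion diameters (default 5%).
#' @param rate_jitter_sd between-patient SD of per-type CXCL12+ rates on the
#'   logit scale.
#' @param id_prefix prefix for generated patient ids (use distinct prefixes
#'   when cohorts will be pooled).
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_patients = 10L,
                         arm = c("APTAMER", "SOC"),
                         cell_type_mix = c(endothelial = 0.03,
                                           pericyte = 0.03,
                                           mphi_microglia = 0.20,
                                           glioma = 0.36, other = 0.38),
                         cxcl12_rate = c(endothelial = 0.45, pericyte = 0.30,
                                         mphi_microglia = 0.15, glioma = 0.05,
                                         other = 0.05),
                         n_cells = 5000L, eg12_beta = -1.5,
                         baseline_hazard = log(2) / 174,
                         post_progression_hazard = log(2) / 215,
                         censor_rate = 0.1, visit_interval_days = 56L,
                         max_visits = 6L, followup_days = 730,
                         pk_dose_mg_per_week = 200,
                         pk_k = log(2) / 1.75, pk_css_per_mg = 0.01,
                         cxcl12_plateau_uM = 0.4,
                         lesion_noise_sd = 0.05, rate_jitter_sd = 0.5,
                         id_prefix = "P") {
  arm <- match.arg(arm)
  types <- c("endothelial", "pericyte", "mphi_microglia", "glioma", "other")
  if (!setequal(names(cell_type_mix), types) ||
      abs(sum(cell_type_mix) - 1) > 1e-9)
    stop("configuration error: cell_type_mix must cover the five types and ",
         "sum to 1")
  if (!setequal(names(cxcl12_rate), types) ||
      any(cxcl12_rate < 0 | cxcl12_rate > 1))
    stop("configuration error: cxcl12_rate must be probabilities in [0, 1] ",
         "for the five types")
  if (!censor_rate >= 0 || censor_rate > 1)
    stop("configuration error: censor_rate must lie in [0, 1]")
  if (visit_interval_days <= 0)
    stop("configuration error: visit_interval_days must be positive")
  if (!pk_dose_mg_per_week %in% c(200, 400, 600))
    stop("configuration error: pk_dose_mg_per_week must be 200, 400 or 600")
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 arm = arm, cell_type_mix = cell_type_mix[types],
                 cxcl12_rate = cxcl12_rate[types],
                 n_cells = as.integer(n_cells), eg12_beta = eg12_beta,
                 baseline_hazard = baseline_hazard,
                 post_progression_hazard = post_progression_hazard,
                 censor_rate = censor_rate,
                 visit_interval_days = as.integer(visit_interval_days),
                 max_visits = as.integer(max_visits),
                 followup_days = followup_days,
                 pk_dose_mg_per_week = pk_dose_mg_per_week, pk_k = pk_k,
                 pk_css_per_mg = pk_css_per_mg,
                 cxcl12_plateau_uM = cxcl12_plateau_uM,
                 lesion_noise_sd = lesion_noise_sd,
                 rate_jitter_sd = rate_jitter_sd,
                 id_prefix = as.character(id_prefix)),
            class = "synth_config")
}

# Stable sub-seed stream: a short LCG walk over the 31-bit ring keyed by
# (seed, patient index, stream id). Exact in double arithmetic.
.sub_seed <- function(seed, i, stream = 0L) {
  x <- as.double(seed) %% 2147483647
  for (k in c(i, stream, 12345L)) {
    x <- (x * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(x)
}

#' Generate a synthetic cohort
#'
#' Draws patient-level ground truth (per-type CXCL12+ rates jittered around
#' the configured means, PFS from an exponential proportional-hazards model
#' whose log hazard includes `eg12_beta` times the standardized latent EG12
#' in the APTAMER arm only, OS as PFS plus an exponential post-progression
#' increment, occasional new-therapy censoring) and, on request, the full
#' per-patient tables: segmented cell tables, scripted lesion series on the
#' scan grid, clinical events, and a PK series for the configured dose.
#' Deterministic given the seed.
#'
#' @param config a [synth_config()].
#' @param tables "all" for the full bundle or "truth" for ground truth plus
#'   survival records only (fast path for calibration studies).
#' @return list of class `synth_cohort`: `config`, `truth` (per-patient
#'   data.frame), `survival` (records as from [derive_pfs_os()]), and with
#'   `tables = "all"` also `cells` (named list of cell tables), `lesions`,
#'   `clinical_events`, `pk`, `ae`.
#' @export
generate_cohort <- function(config, tables = c("all", "truth")) {
  stopifnot(inherits(config, "synth_config"))
  tables <- match.arg(tables)
  n <- config$n_patients
  ids <- sprintf("%s%03d", config$id_prefix, seq_len(n))

  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    set.seed(.sub_seed(config$seed, i, 1L))
    lo <- stats::qlogis(pmin(pmax(config$cxcl12_rate, 1e-4), 1 - 1e-4))
    rates <- stats::plogis(lo + stats::rnorm(5, 0, config$rate_jitter_sd))
    data.frame(patient_id = ids[i], arm = config$arm,
               rate_endothelial = rates[1], rate_pericyte = rates[2],
               rate_mphi = rates[3], rate_glioma = rates[4],
               rate_other = rates[5], row.names = NULL)
  }))

  # latent EG12: mean of the latent E and G rates (percent scale),
  # standardized against a configuration-derived reference distribution so a
  # patient's hazard depends only on their own draws -- adding patients to a
  # cohort then never perturbs existing ones
  e <- 100 * truth$rate_endothelial
  g <- 100 * truth$rate_glioma
  set.seed(.sub_seed(config$seed, 0L, 7L))
  lo <- stats::qlogis(pmin(pmax(config$cxcl12_rate, 1e-4), 1 - 1e-4))
  ref <- replicate(2000, {
    r <- stats::plogis(lo + stats::rnorm(5, 0, config$rate_jitter_sd))
    100 * (r[[1]] + r[[4]]) / 2
  })
  latent <- (e + g) / 2 - mean(ref)
  z <- if (stats::sd(ref) > 0) latent / stats::sd(ref) else rep(0, n)
  truth$latent_eg12 <- latent
  truth$latent_eg12_z <- z

  beta <- if (config$arm == "APTAMER") config$eg12_beta else 0
  for (i in seq_len(n)) {
    set.seed(.sub_seed(config$seed, i, 2L))
    h <- config$baseline_hazard * exp(beta * z[i])
    pfs <- stats::rexp(1, h)
    os <- pfs + stats::rexp(1, config$post_progression_hazard)
    censored <- stats::runif(1) < config$censor_rate
    newtx <- if (censored) max(1, floor(stats::runif(1, 0.3, 0.9) * pfs))
             else NA_real_
    truth$pfs_days[i] <- max(1, round(pfs))
    truth$os_days[i] <- max(truth$pfs_days[i] + 1, round(os))
    truth$new_therapy_day[i] <- newtx
  }

  surv <- do.call(rbind, lapply(seq_len(n), function(i) {
    pfs <- truth$pfs_days[i]; os <- truth$os_days[i]
    newtx <- truth$new_therapy_day[i]
    os_event <- os <= config$followup_days
    os_time <- min(os, config$followup_days)
    if (!is.na(newtx) && newtx < pfs && newtx < config$followup_days) {
      pfs_time <- newtx; pfs_event <- FALSE; reason <- "censor_new_therapy"
    } else if (pfs <= config$followup_days) {
      pfs_time <- pfs; pfs_event <- TRUE; reason <- "confirmed_PD"
    } else {
      pfs_time <- config$followup_days; pfs_event <- FALSE
      reason <- "censor_eot_followup"
    }
    data.frame(patient_id = truth$patient_id[i], endpoint = c("PFS", "OS"),
               time_days = c(pfs_time, os_time),
               event = c(pfs_event, os_event),
               reason = c(reason, if (os_event) "death" else "censor_alive"),
               row.names = NULL)
  }))

  out <- list(config = config, truth = truth, survival = surv)
  class(out) <- "synth_cohort"
  if (tables == "truth") return(out)

  schedule <- seq(0, by = config$visit_interval_days,
                  length.out = config$max_visits + 1L)
  out$cells <- stats::setNames(lapply(seq_len(n), function(i) {
    generate_cell_table(truth[i, ], config)
  }), ids)
  out$lesions <- do.call(rbind, lapply(seq_len(n), function(i) {
    # scans stop after the confirming scan that follows the progression scan,
    # and always before death
    prog_scan <- schedule[which(schedule >= truth$pfs_days[i])[1]]
    stop_day <- min(if (is.na(prog_scan)) Inf
                    else prog_scan + config$visit_interval_days,
                    truth$os_days[i] - 1)
    sched_i <- schedule[schedule <= stop_day]
    generate_lesion_series(truth[i, ], sched_i, config)
  }))
  last_contact <- pmin(truth$os_days, config$followup_days)
  out$clinical_events <- data.frame(
    patient_id = ids,
    death_day = ifelse(truth$os_days <= config$followup_days,
                       truth$os_days, NA_real_),
    new_therapy_day = ifelse(!is.na(truth$new_therapy_day) &
                               truth$new_therapy_day < last_contact,
                             truth$new_therapy_day, NA_real_),
    clinical_pd_day = NA_real_,
    last_contact_day = last_contact,
    treatment_stop_reason = NA_character_, row.names = NULL)
  set.seed(.sub_seed(config$seed, 0L, 3L))
  out$pk <- generate_pk_series(config, days = seq(0, 28, by = 0.5))
  out$ae <- generate_ae_listing(config)
  out
}

#' Generate a segmented cell table for one patient
#'
#' Cell types are drawn from the configured mixture; marker completeness
#' fractions from Beta distributions with a high mode for a cell's own
#' lineage markers (Beta(10, 2.5)) and a low mode otherwise (Beta(1, 20)),
#' which keeps values in \[0,1\] and passes each true type through its gate
#' with probability >= 0.95 at the default thresholds. CXCL12 completeness
#' exceeds its threshold with the patient's per-type rate. Nuclear areas are
#' log-normal around 50 um^2, almost entirely inside the 12-1000 um^2 window.
#'
#' @param truth one row of a cohort `truth` table (needs `patient_id` and the
#'   `rate_*` columns).
#' @param config a [synth_config()].
#' @return cell table data.frame in the schema consumed by [filter_cells()].
#' @export
generate_cell_table <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_cells
  if (n < 1) stop("configuration error: n_cells must be >= 1")
  idx <- suppressWarnings(as.integer(gsub("\\D", "", truth$patient_id)))
  if (is.na(idx)) idx <- 1L
  set.seed(.sub_seed(config$seed, idx, 4L))

  types <- names(config$cell_type_mix)
  type <- sample(types, n, replace = TRUE, prob = config$cell_type_mix)
  rates <- c(endothelial = truth$rate_endothelial,
             pericyte = truth$rate_pericyte,
             mphi_microglia = truth$rate_mphi, glioma = truth$rate_glioma,
             other = truth$rate_other)

  hi <- function(k) stats::rbeta(k, 10, 2.5)
  lo <- function(k) stats::rbeta(k, 1, 20)
  own <- function(marker_type) ifelse(type == marker_type, hi(n), lo(n))
  cxcl12_pos <- stats::rbinom(n, 1, rates[type]) == 1

  data.frame(
    patient_id = truth$patient_id,
    cell_id = seq_len(n),
    nuclear_area_um2 = stats::rlnorm(n, log(50), 0.4),
    dapi_nuc = hi(n),
    cxcl12_nc = ifelse(cxcl12_pos, hi(n), lo(n)),
    cd31_nc = own("endothelial"),
    asma_nc = own("pericyte"),
    cd68_nc = own("mphi_microglia"),
    gfap_nc = own("glioma"),
    ki67_nuc = ifelse(stats::rbinom(n, 1, 0.2) == 1, hi(n), lo(n)),
    true_type = type, row.names = NULL)
}

#' Generate a scripted lesion series for one patient
#'
#' Each patient carries 1-3 lesions with baseline diameters of 8-40 mm. The
#' diameter course is piecewise exponential: shrinkage until a nadir at 60%
#' of the progression scan day, then regrowth calibrated so the SPD exceeds
#' the nadir by >= 25% (hence preliminary PD) at the first scheduled scan on
#' or after the true PFS day, maintained thereafter so the PD confirms.
#' Multiplicative log-normal noise (config `lesion_noise_sd`) is applied to
#' measured diameters.
#'
#' @param truth one truth row (needs `patient_id`, `pfs_days`).
#' @param schedule strictly increasing visit days starting at 0 (baseline).
#' @param config a [synth_config()].
#' @param script optional explicit course: a list with `d0` (matrix of
#'   baseline diameter pairs, one row per lesion), `segments` (data.frame
#'   `from_day`, `rate` of log-diameter slopes per day; an empty data.frame
#'   means a flat course) and optionally `disappear_day` (per-lesion day from
#'   which the lesion is recorded absent with zero diameters). When absent,
#'   the course is derived from the patient's true PFS day as documented
#'   above.
#' @return lesion visit data.frame in the schema of [classify_lesions()].
#' @export
generate_lesion_series <- function(truth, schedule, config, script = NULL) {
  if (is.unsorted(schedule, strictly = TRUE) || schedule[1] != 0)
    stop("input error: schedule must be strictly increasing and start at ",
         "day 0")
  idx <- suppressWarnings(as.integer(gsub("\\D", "", truth$patient_id)))
  if (is.na(idx)) idx <- 1L
  set.seed(.sub_seed(config$seed, idx, 5L))

  if (is.null(script)) {
    n_lesions <- sample(1:3, 1)
    d0 <- matrix(stats::runif(2 * n_lesions, 8, 40), ncol = 2)
    prog_day <- schedule[which(schedule >= truth$pfs_days)[1]]
    if (is.na(prog_day)) prog_day <- Inf  # progression beyond follow-up
    t_nadir <- if (is.finite(prog_day)) 0.6 * prog_day else max(schedule)
    shrink <- stats::runif(1, 0.1, 0.6)  # fractional diameter loss at nadir
    r_down <- if (t_nadir > 0) log(1 - shrink) / t_nadir else 0
    # regrow so SPD (proportional to d^2) sits well above the +25% PD bound
    # at prog_day even against the scan-grid nadir and measurement noise
    r_up <- if (is.finite(prog_day) && prog_day > t_nadir)
      log(1.6) / (2 * (prog_day - t_nadir)) else 0
    segments <- data.frame(from_day = c(0, t_nadir), rate = c(r_down, r_up))
    disappear_day <- rep(NA_real_, n_lesions)
  } else {
    d0 <- script$d0
    n_lesions <- nrow(d0)
    segments <- script$segments
    if (is.null(segments) || nrow(segments) == 0)
      segments <- data.frame(from_day = 0, rate = 0)
    disappear_day <- if (!is.null(script$disappear_day)) script$disappear_day
                     else rep(NA_real_, n_lesions)
  }

  log_growth_at <- function(t) {
    # integral of the piecewise-constant log-diameter slope up to day t
    brk <- c(segments$from_day, Inf)
    sum(segments$rate * pmax(0, pmin(t, brk[-1]) - brk[-length(brk)]))
  }
  do.call(rbind, lapply(schedule, function(day) {
    d <- d0 * exp(log_growth_at(day))
    if (config$lesion_noise_sd > 0 && day > 0)
      d <- d * exp(matrix(stats::rnorm(length(d), 0, config$lesion_noise_sd),
                          ncol = 2))
    gone <- !is.na(disappear_day) & day >= disappear_day
    d[gone, ] <- 0
    data.frame(patient_id = truth$patient_id, visit_day = day,
               lesion_id = sprintf("%s_L%d", truth$patient_id,
                                   seq_len(n_lesions)),
               diam1_mm = d[, 1], diam2_mm = d[, 2], present = !gone,
               new_lesion = FALSE, row.names = NULL)
  }))
}

#' Generate a plasma PK series
#'
#' Monotone saturating accumulation to a dose-proportional steady state,
#' C(t) = C_ss (1 - exp(-k t)) with C_ss = `pk_css_per_mg` x weekly dose, so
#' the 200 mg level plateaus above 1.5 uM and 600 vs 200 mg plateaus stand in
#' ratio 3. The mobilized CXCL12 series rises with the same kinetics to a
#' plateau below the drug level.
#'
#' @param config a [synth_config()].
#' @param days numeric grid of non-negative days.
#' @return data.frame: `day`, `conc_uM`, `cxcl12_uM`, `dose_mg_per_week`.
#' @export
generate_pk_series <- function(config, days = seq(0, 28, by = 0.5)) {
  if (any(days < 0)) stop("input error: days must be non-negative")
  css <- config$pk_css_per_mg * config$pk_dose_mg_per_week
  acc <- 1 - exp(-config$pk_k * days)
  data.frame(day = days, conc_uM = css * acc,
             cxcl12_uM = config$cxcl12_plateau_uM * acc,
             dose_mg_per_week = config$pk_dose_mg_per_week, row.names = NULL)
}

#' Generate a synthetic adverse-event listing
#'
#' Per patient, a Poisson number of AEs (mean 17, matching an early-phase
#' trial's density of low-grade events) with CTCAE grades and relationship
#' categories drawn from the marginal distribution typical of a
#' radiotherapy-plus-systemic-agent safety table.
#'
#' @param config a [synth_config()].
#' @return data.frame: `patient_id`, `term`, `grade`, `relationship`.
#' @export
generate_ae_listing <- function(config) {
  set.seed(.sub_seed(config$seed, 0L, 6L))
  grades <- 1:5
  gp <- c(0.51, 0.345, 0.135, 0.009, 0.001)
  rels <- c("none", "gbm", "rt", "rt_gbm", "nox_a12", "nox_a12_gbm",
            "nox_a12_rt", "nox_a12_rt_gbm")
  rp <- c(0.474, 0.251, 0.117, 0.035, 0.076, 0.023, 0.012, 0.012)
  terms <- c("headache", "fatigue", "nausea", "alt_increase", "leukocytosis",
             "constipation", "seizure", "edema")
  do.call(rbind, lapply(seq_len(config$n_patients), function(i) {
    k <- stats::rpois(1, 17)
    if (k == 0) return(NULL)
    data.frame(patient_id = sprintf("%s%03d", config$id_prefix, i),
               term = sample(terms, k, replace = TRUE),
               grade = sample(grades, k, replace = TRUE, prob = gp),
               relationship = sample(rels, k, replace = TRUE, prob = rp),
               row.names = NULL)
  }))
}

#' Write / read a cohort bundle as plain-text CSV + JSON
#'
#' Writes the per-patient cell tables, lesion series, clinical events, PK
#' series, AE listing and survival records as UTF-8 CSV files under `dir`,
#' plus the configuration and ground truth as a JSON sidecar. `read_cohort`
#' restores the bundle.
#'
#' @param cohort a `synth_cohort` with full tables.
#' @param dir output directory (created if needed).
#' @return `write_cohort`: `dir`, invisibly. `read_cohort`: the restored
#'   bundle (a plain list with the same table elements).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"), !is.null(cohort$cells))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(do.call(rbind, cohort$cells),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(cohort$lesions, file.path(dir, "lesions.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$clinical_events,
                   file.path(dir, "clinical_events.csv"), row.names = FALSE)
  utils::write.csv(cohort$pk, file.path(dir, "pk.csv"), row.names = FALSE)
  utils::write.csv(cohort$ae, file.path(dir, "ae.csv"), row.names = FALSE)
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(config = unclass(cohort$config),
                            truth = cohort$truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  cells_all <- rd("cells.csv")
  list(cells = split(cells_all, cells_all$patient_id),
       lesions = rd("lesions.csv"),
       clinical_events = rd("clinical_events.csv"),
       pk = rd("pk.csv"), ae = rd("ae.csv"), survival = rd("survival.csv"),
       truth_json = jsonlite::read_json(file.path(dir, "truth.json"),
                                        simplifyVector = TRUE))
}
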