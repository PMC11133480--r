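# Modified RANO (mRANO) lesion response engine: lesion classification, SPD,
# timepoint response with confirmation, and PFS/OS event derivation.
#
# Conventions: days are integers relative to the first treatment day (day 0);
# the baseline scan is the earliest visit. PR/CR are referenced to baseline
# SPD, PD to the nadir SPD (minimum of baseline and all prior on-treatment
# SPDs). Thresholds: PR at <= -50% vs baseline, PD at >= +25% vs nadir.

.MRANO_PR_PCT <- -50
.MRANO_PD_PCT <- 25
.CONFIRM_MIN_GAP_DAYS <- 42  # "successive scan after 8 weeks", with jitter

.validate_lesions <- function(lesions) {
  need <- c("patient_id", "visit_day", "lesion_id", "diam1_mm", "diam2_mm",
            "present")
  miss <- setdiff(need, names(lesions))
  if (length(miss))
    stop("lesion table is missing columns: ", paste(miss, collapse = ", "))
  if (!"new_lesion" %in% names(lesions)) lesions$new_lesion <- FALSE
  d <- c(lesions$diam1_mm, lesions$diam2_mm)
  if (any(!is.na(d) & d < 0)) stop("lesion diameters must be >= 0")
  ab <- !lesions$present
  if (any(ab & (lesions$diam1_mm != 0 | lesions$diam2_mm != 0)))
    stop("absent lesions must carry zero diameters")
  lesions
}

#' Classify lesions as target or non-target at baseline
#'
#' A lesion is bidimensionally measurable when both perpendicular diameters
#' are at least 10 mm at baseline (boundary inclusive); measurable lesions
#' become target lesions (TL), the rest non-target (NTL). Lesions first seen
#' after baseline are new lesions, flagged measurable by the same rule.
#'
#' @param lesions lesion visit table with columns `patient_id`, `visit_day`,
#'   `lesion_id`, `diam1_mm`, `diam2_mm`, `present` (logical), optionally
#'   `new_lesion`.
#' @return data.frame: `lesion_id`, `role` ("TL"/"NTL"/"NEW"), `measurable`.
#' @export
classify_lesions <- function(lesions) {
  lesions <- .validate_lesions(lesions)
  if (nrow(lesions) == 0L) stop("no baseline scan present")
  base_day <- min(lesions$visit_day)
  base <- lesions[lesions$visit_day == base_day, , drop = FALSE]
  if (nrow(base) == 0L) stop("no baseline scan present")
  ids <- unique(lesions$lesion_id)
  at_base <- ids %in% base$lesion_id
  meas_base <- with(base, diam1_mm >= 10 & diam2_mm >= 10 & present)
  roles <- data.frame(lesion_id = ids,
                      role = ifelse(at_base, NA_character_, "NEW"),
                      measurable = NA)
  for (i in seq_along(ids)) {
    if (at_base[i]) {
      m <- meas_base[match(ids[i], base$lesion_id)]
      roles$role[i] <- if (isTRUE(m)) "TL" else "NTL"
      roles$measurable[i] <- isTRUE(m)
    } else {
      first <- lesions[lesions$lesion_id == ids[i] & lesions$present, ,
                       drop = FALSE]
      first <- first[which.min(first$visit_day), , drop = FALSE]
      roles$measurable[i] <- nrow(first) == 1L &&
        first$diam1_mm >= 10 && first$diam2_mm >= 10
    }
  }
  roles
}

#' Sum of products of perpendicular diameters (SPD)
#'
#' SPD over a set of lesion measurements at one timepoint: the sum of
#' `diam1 * diam2` in mm^2. A lesion flagged absent contributes 0; a missing
#' measurement without the absent flag is an error.
#'
#' @param visits data.frame rows for one timepoint with `diam1_mm`,
#'   `diam2_mm`, `present`.
#' @return SPD in mm^2.
#' @examples
#' spd(data.frame(diam1_mm = c(20, 15), diam2_mm = c(10, 12),
#'                present = TRUE))  # 380
#' @export
spd <- function(visits) {
  if (nrow(visits) == 0L) return(0)
  if (any(visits$present & (is.na(visits$diam1_mm) | is.na(visits$diam2_mm))))
    stop("lesion measured as present but a diameter is missing")
  sum(ifelse(visits$present, visits$diam1_mm * visits$diam2_mm, 0))
}

#' Preliminary timepoint response
#'
#' Applies the mRANO rule table for one scan. PD if the SPD change versus the
#' nadir is >= +25% or a new measurable lesion has appeared; CR if all target
#' lesions and enhancing non-target lesions are absent (a new non-measurable
#' lesion constitutes progression only in that complete-response situation);
#' PR if the SPD change versus baseline is <= -50%; SD otherwise. For patients
#' without target lesions the same rules run on the non-target SPD, except
#' that PR is not assigned (non-measurable disease supports CR, SD or PD
#' only).
#'
#' @param baseline_spd,nadir_spd,current_spd SPD values in mm^2.
#' @param tl_all_absent,ntl_all_absent logical lesion-status summaries.
#' @param new_measurable,new_nonmeasurable new-lesion flags at this scan.
#' @param has_target_lesions whether the patient had TLs at baseline.
#' @return one of "CR", "PR", "SD", "PD".
#' @export
timepoint_response <- function(baseline_spd, nadir_spd, current_spd,
                               tl_all_absent = FALSE, ntl_all_absent = TRUE,
                               new_measurable = FALSE,
                               new_nonmeasurable = FALSE,
                               has_target_lesions = TRUE) {
  if (has_target_lesions && baseline_spd <= 0)
    stop("baseline SPD must be positive when target lesions exist")
  if (nadir_spd > baseline_spd + 1e-9)
    stop("internal invariant violation: nadir SPD exceeds baseline SPD")
  pd_growth <- nadir_spd > 0 &&
    100 * (current_spd - nadir_spd) / nadir_spd >= .MRANO_PD_PCT
  if (new_measurable || pd_growth) return("PD")
  all_absent <- if (has_target_lesions) tl_all_absent && ntl_all_absent
                else ntl_all_absent
  if (all_absent) return(if (new_nonmeasurable) "PD" else "CR")
  if (has_target_lesions &&
      100 * (current_spd - baseline_spd) / baseline_spd <= .MRANO_PR_PCT)
    return("PR")
  "SD"
}

#' Assess a patient's full scan series
#'
#' Computes per-scan SPD, percent changes versus baseline and nadir, the
#' preliminary response, and confirmation status. A preliminary PR or PD is
#' confirmed when the first scan at least 6 weeks later maintains the state
#' (CR maintains a PR; a repeat PD call maintains a PD); with no such scan the
#' confirmation is pending (`NA`). A histopathologically confirmed
#' pseudo-progression voids the PD call at the affected scan (recorded in the
#' `pseudo_pd` column, response reverted to SD). The best response is the
#' extreme percent change of SPD versus baseline over all on-treatment scans.
#'
#' @param lesions lesion visit table for one patient (see
#'   [classify_lesions()]), all scheduled visits included.
#' @param pseudo_progression_days integer vector of scan days whose PD calls
#'   are voided by histopathology.
#' @return list of class `mrano_assessment`: `assessments` (one row per
#'   post-baseline scan: visit_day, spd, pct_change_baseline,
#'   pct_change_nadir, preliminary, confirmed, pseudo_pd), `roles`,
#'   `baseline_spd`, `best_response_pct`, `best_overall_response`.
#' @export
assess_series <- function(lesions, pseudo_progression_days = integer()) {
  lesions <- .validate_lesions(lesions)
  if (!"new_lesion" %in% names(lesions)) lesions$new_lesion <- FALSE
  days <- sort(unique(lesions$visit_day))
  roles <- classify_lesions(lesions)
  has_tl <- any(roles$role == "TL")
  spd_role <- if (has_tl) "TL" else "NTL"
  spd_ids <- roles$lesion_id[roles$role == spd_role]

  day_spd <- vapply(days, function(d) {
    rows <- lesions[lesions$visit_day == d & lesions$lesion_id %in% spd_ids, ,
                    drop = FALSE]
    if (!all(spd_ids %in% rows$lesion_id))
      stop("visit day ", d, " is missing measurements for lesion(s): ",
           paste(setdiff(spd_ids, rows$lesion_id), collapse = ", "))
    spd(rows)
  }, numeric(1))
  baseline_spd <- day_spd[1]

  n_post <- length(days) - 1L
  out <- data.frame(visit_day = days[-1], spd = day_spd[-1],
                    pct_change_baseline = rep(NA_real_, n_post),
                    pct_change_nadir = rep(NA_real_, n_post),
                    preliminary = rep(NA_character_, n_post),
                    confirmed = rep(NA, n_post),
                    pseudo_pd = rep(FALSE, n_post))
  for (i in seq_len(n_post)) {
    d <- days[i + 1L]
    cur <- day_spd[i + 1L]
    nadir <- min(day_spd[seq_len(i)])
    rows <- lesions[lesions$visit_day == d, , drop = FALSE]
    rows <- merge(rows, roles, by = "lesion_id")
    tl_rows <- rows[rows$role == "TL", , drop = FALSE]
    ntl_rows <- rows[rows$role == "NTL", , drop = FALSE]
    new_rows <- rows[rows$role == "NEW" & rows$present, , drop = FALSE]
    resp <- timepoint_response(
      baseline_spd = baseline_spd, nadir_spd = nadir, current_spd = cur,
      tl_all_absent = nrow(tl_rows) == 0L || !any(tl_rows$present),
      ntl_all_absent = nrow(ntl_rows) == 0L || !any(ntl_rows$present),
      new_measurable = any(new_rows$measurable),
      new_nonmeasurable = any(!new_rows$measurable),
      has_target_lesions = has_tl)
    if (resp == "PD" && d %in% pseudo_progression_days) {
      out$pseudo_pd[i] <- TRUE
      resp <- "SD"
    }
    out$preliminary[i] <- resp
    out$pct_change_baseline[i] <-
      if (baseline_spd > 0) 100 * (cur - baseline_spd) / baseline_spd
      else NA_real_
    out$pct_change_nadir[i] <-
      if (nadir > 0) 100 * (cur - nadir) / nadir else NA_real_
  }

  for (i in seq_len(n_post)) {
    state <- out$preliminary[i]
    if (!state %in% c("PR", "PD")) next
    later <- which(out$visit_day >= out$visit_day[i] + .CONFIRM_MIN_GAP_DAYS)
    if (!length(later)) { out$confirmed[i] <- NA; next }
    nxt <- out$preliminary[later[1]]
    out$confirmed[i] <- if (state == "PR") nxt %in% c("PR", "CR")
                        else nxt == "PD"
  }

  best_pct <- if (baseline_spd > 0 && n_post > 0)
    min(out$pct_change_baseline) else NA_real_
  prelim <- out$preliminary
  bor <- if (n_post == 0L) NA_character_
  else if (any(prelim == "CR")) "CR"
  else if (any(prelim == "PR" & (is.na(out$confirmed) | out$confirmed))) "PR"
  else if (any(prelim == "SD")) "SD"
  else "PD"
  structure(list(assessments = out, roles = roles,
                 baseline_spd = unname(baseline_spd),
                 best_response_pct = best_pct,
                 best_overall_response = bor),
            class = "mrano_assessment")
}

#' @export
print.mrano_assessment <- function(x, ...) {
  cat(sprintf("mRANO series: baseline SPD %.0f mm^2, best change %.1f%%, best response %s\n",
              x$baseline_spd,
              ifelse(is.na(x$best_response_pct), NaN, x$best_response_pct),
              x$best_overall_response))
  print(x$assessments, row.names = FALSE)
  invisible(x)
}

#' Derive PFS and OS survival records from assessments and clinical events
#'
#' Applies the trial's event algebra. The PFS event day is the earliest of:
#' the day of the first preliminary-PD scan that was sequentially confirmed;
#' the day of a scan with simultaneous clinical progression (irrespective of
#' the scan's own outcome); the death day if the patient died before clinical
#' or radiographic progression; and the day of an unconfirmed preliminary PD
#' that still qualifies as an event because no later scan showed SD/PR/CR and
#' the patient stopped treatment for clinical progression, had no further
#' assessments, or died. When a new anticancer therapy starts before any such
#' progression day, PFS is censored at the new-therapy day. Otherwise PFS is
#' censored at the last contact. OS is the death day (event) or last contact
#' (censored). Days count from the first treatment day.
#'
#' @param assessment an `mrano_assessment` (or its `assessments` data.frame).
#' @param events list with elements (each a scalar day or `NA`):
#'   `clinical_pd_day` (clinical progression coinciding with a scan),
#'   `death_day`, `new_therapy_day`, `last_contact_day` (required),
#'   `treatment_stop_reason` (one of "eot", "clinical_progression",
#'   "other", `NA`).
#' @param patient_id identifier carried into the output.
#' @return data.frame with columns `patient_id`, `endpoint` ("PFS"/"OS"),
#'   `time_days`, `event` (logical), `reason`.
#' @export
derive_pfs_os <- function(assessment, events, patient_id = NA_character_) {
  a <- if (inherits(assessment, "mrano_assessment")) assessment$assessments
       else assessment
  ev <- utils::modifyList(list(clinical_pd_day = NA, death_day = NA,
                               new_therapy_day = NA, last_contact_day = NA,
                               treatment_stop_reason = NA), as.list(events))
  if (is.na(ev$last_contact_day)) stop("last_contact_day is required")
  death <- ev$death_day
  if (!is.na(death)) {
    others <- c(a$visit_day, ev$clinical_pd_day, ev$new_therapy_day)
    if (any(!is.na(others) & others > death))
      stop("inconsistent dates for patient ", patient_id,
           ": events recorded after death")
  }

  pd_idx <- which(a$preliminary == "PD")
  conf_day <- {
    i <- pd_idx[which(isTRUE_vec(a$confirmed[pd_idx]))]
    if (length(i)) a$visit_day[min(i)] else NA_real_
  }
  clin_day <- if (!is.na(ev$clinical_pd_day) &&
                  ev$clinical_pd_day %in% a$visit_day)
    ev$clinical_pd_day else NA_real_

  qual_day <- NA_real_
  for (i in pd_idx) {
    if (isTRUE(a$confirmed[i])) next
    later <- a$preliminary[a$visit_day > a$visit_day[i]]
    if (any(later %in% c("SD", "PR", "CR"))) next
    qualifies <- identical(ev$treatment_stop_reason, "clinical_progression") ||
      length(later) == 0L || !is.na(death)
    if (qualifies) { qual_day <- a$visit_day[i]; break }
  }

  prog_day <- suppressWarnings(min(c(conf_day, clin_day, qual_day),
                                   na.rm = TRUE))
  if (!is.finite(prog_day)) prog_day <- NA_real_

  newtx <- ev$new_therapy_day
  if (!is.na(newtx) && (is.na(prog_day) || newtx < prog_day) &&
      (is.na(death) || newtx < death)) {
    pfs_time <- newtx; pfs_event <- FALSE; pfs_reason <- "censor_new_therapy"
  } else if (!is.na(prog_day) && (is.na(death) || prog_day <= death)) {
    pfs_time <- prog_day; pfs_event <- TRUE
    pfs_reason <- if (!is.na(conf_day) && prog_day == conf_day) "confirmed_PD"
      else if (!is.na(clin_day) && prog_day == clin_day) "clinical_PD"
      else "unconfirmed_PD_qualified"
  } else if (!is.na(death)) {
    pfs_time <- death; pfs_event <- TRUE; pfs_reason <- "death"
  } else {
    pfs_time <- ev$last_contact_day; pfs_event <- FALSE
    pfs_reason <- if (identical(ev$treatment_stop_reason, "eot"))
      "censor_eot_followup" else "censor_alive"
  }

  if (!is.na(death)) {
    os_time <- death; os_event <- TRUE; os_reason <- "death"
  } else {
    os_time <- ev$last_contact_day; os_event <- FALSE
    os_reason <- "censor_alive"
  }
  if (pfs_time > os_time)
    stop("validation error for patient ", patient_id, ": PFS time ", pfs_time,
         " exceeds OS time ", os_time)
  if (pfs_time <= 0 || os_time <= 0)
    stop("validation error for patient ", patient_id, ": non-positive time")
  data.frame(patient_id = patient_id, endpoint = c("PFS", "OS"),
             time_days = c(pfs_time, os_time), event = c(pfs_event, os_event),
             reason = c(pfs_reason, os_reason), row.names = NULL)
}

# TRUE positions of a logical vector, treating NA as FALSE
isTRUE_vec <- function(x) !is.na(x) & x
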