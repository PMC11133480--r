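# Independent oracles used across the suite. Each re-derives the expected
# behaviour from first principles (literal predicate scans, rule-table
# enumeration), deliberately avoiding the package's own code paths.

# --- gating -----------------------------------------------------------------

# literal per-cell predicate scan of the filter + gates + frequencies
oracle_profile <- function(cells) {
  thr <- c(dapi = 0.15, cxcl12 = 0.35, cd68 = 0.20, cd31 = 0.30,
           ki67 = 0.30, asma = 0.35, gfap = 0.30)
  keep <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    keep[i] <- cells$dapi_nuc[i] >= thr["dapi"] &&
      cells$nuclear_area_um2[i] >= 12 && cells$nuclear_area_um2[i] <= 1000
  }
  k <- cells[keep, , drop = FALSE]
  out <- list(endothelial = c(0, 0), pericyte = c(0, 0),
              mphi_microglia = c(0, 0), glioma = c(0, 0))
  tot_cx <- 0
  for (i in seq_len(nrow(k))) {
    cd31 <- k$cd31_nc[i] >= thr["cd31"]; asma <- k$asma_nc[i] >= thr["asma"]
    cd68 <- k$cd68_nc[i] >= thr["cd68"]; gfap <- k$gfap_nc[i] >= thr["gfap"]
    cx <- k$cxcl12_nc[i] >= thr["cxcl12"]
    if (cx) tot_cx <- tot_cx + 1
    bump <- function(nm) out[[nm]] <<- out[[nm]] + c(1, as.integer(cx))
    if (cd31) bump("endothelial")
    if (asma && !cd31) bump("pericyte")
    if (cd68) bump("mphi_microglia")
    if (gfap && !cd68 && !cd31 && !asma) bump("glioma")
  }
  list(kept = which(keep), n_kept = nrow(k), total_cx = tot_cx,
       counts = out,
       pct = lapply(out, function(v) if (v[1] > 0) 100 * v[2] / v[1]
                    else NA_real_))
}

# --- mRANO ------------------------------------------------------------------

# literal timepoint rule table (target-lesion case, all lesions present)
oracle_timepoint <- function(baseline, nadir, current) {
  if (nadir > 0 && (current - nadir) / nadir >= 0.25) return("PD")
  if ((current - baseline) / baseline <= -0.5) return("PR")
  "SD"
}

# independent PFS/OS derivation from an SPD series plus clinical events,
# re-reading the trial's written rule list
oracle_derive <- function(spds, days, events) {
  base <- spds[1]
  n <- length(spds) - 1
  prelim <- character(n)
  for (i in seq_len(n)) {
    nadir <- min(spds[1:i])
    prelim[i] <- oracle_timepoint(base, nadir, spds[i + 1])
  }
  pdays <- days[-1]

  conf_day <- NA
  for (i in seq_len(n)) {
    if (prelim[i] != "PD") next
    j <- which(pdays >= pdays[i] + 42)
    if (length(j) && prelim[j[1]] == "PD") { conf_day <- pdays[i]; break }
  }
  clin_day <- if (!is.na(events$clinical_pd_day) &&
                  events$clinical_pd_day %in% pdays)
    events$clinical_pd_day else NA
  qual_day <- NA
  for (i in seq_len(n)) {
    if (prelim[i] != "PD") next
    j <- which(pdays >= pdays[i] + 42)
    if (length(j) && prelim[j[1]] == "PD") next  # confirmed, not this rule
    later <- prelim[pdays > pdays[i]]
    if (any(later %in% c("SD", "PR", "CR"))) next
    if (identical(events$treatment_stop_reason, "clinical_progression") ||
        length(later) == 0 || !is.na(events$death_day)) {
      qual_day <- pdays[i]; break
    }
  }
  cand <- c(conf_day, clin_day, qual_day)
  prog <- if (all(is.na(cand))) NA else min(cand, na.rm = TRUE)
  death <- events$death_day
  newtx <- events$new_therapy_day

  if (!is.na(newtx) && (is.na(prog) || newtx < prog) &&
      (is.na(death) || newtx < death)) {
    pfs <- c(newtx, FALSE)
  } else if (!is.na(prog) && (is.na(death) || prog <= death)) {
    pfs <- c(prog, TRUE)
  } else if (!is.na(death)) {
    pfs <- c(death, TRUE)
  } else {
    pfs <- c(events$last_contact_day, FALSE)
  }
  os <- if (!is.na(death)) c(death, TRUE) else c(events$last_contact_day, FALSE)
  list(pfs_time = pfs[1], pfs_event = as.logical(pfs[2]),
       os_time = os[1], os_event = as.logical(os[2]))
}

# SPD series realizing a preliminary response sequence over {SD, PR, PD}
# at baseline 400 (see test-mrano.R for the construction argument)
spds_for_sequence <- function(states, baseline = 400) {
  spds <- baseline
  for (s in states) {
    nadir <- min(spds)
    v <- switch(s,
                PD = 1.30 * nadir,
                PR = 0.45 * baseline,
                SD = max(0.95 * nadir, 0.55 * baseline))
    spds <- c(spds, v)
  }
  spds
}

# single-lesion visit table realizing an SPD series exactly
lesions_from_spds <- function(spds, days, patient_id = "PX") {
  data.frame(patient_id = patient_id, visit_day = days, lesion_id = "L1",
             diam1_mm = sqrt(spds), diam2_mm = sqrt(spds),
             present = TRUE, new_lesion = FALSE)
}

# --- dose escalation --------------------------------------------------------

# literal re-reading of the modified 3+3 protocol rules
oracle_escalation <- function(n, dlt, level, n_levels = 3) {
  if (dlt >= 2) return("stop_declare_MTD")
  if (n == 3 && dlt == 0) return(if (level >= n_levels) "declare_RP2D"
                                 else "escalate")
  if (n == 6 && dlt <= 1) return(if (level >= n_levels) "declare_RP2D"
                                 else "escalate")
  "expand_same_level"  # cohort incomplete (n < 3 or expansion under way)
}

# --- small statistics oracles ----------------------------------------------

# hand risk-table log-rank chi-square (no ties across groups assumed)
oracle_logrank_chisq <- function(ta, tb) {
  times <- sort(unique(c(ta, tb)))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    n1 <- sum(ta >= t); n2 <- sum(tb >= t); n <- n1 + n2
    d1 <- sum(ta == t); d2 <- sum(tb == t); d <- d1 + d2
    if (n < 2) next
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# brute-force Spearman r_s via the rank-and-Pearson route
oracle_spearman_r <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
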