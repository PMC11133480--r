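# Survival estimation and trial summary statistics: Kaplan-Meier, log-rank,
# Cox PH, Mann-Whitney U, adverse-event tabulation, PK steady-state summaries
# and modified 3+3 dose-escalation decisions.

.as_surv_df <- function(records, endpoint = NULL) {
  stopifnot(all(c("time_days", "event") %in% names(records)))
  if (!is.null(endpoint) && "endpoint" %in% names(records))
    records <- records[records$endpoint == endpoint, , drop = FALSE]
  if (any(records$time_days <= 0)) stop("survival times must be positive")
  records
}

#' Kaplan-Meier estimate
#'
#' Product-limit survival estimate with the median survival time (first time
#' at which the estimate drops to 0.5 or below) and the survival probability
#' at a query day (e.g. day 183 for 6-month PFS). Backed by
#' [survival::survfit()].
#'
#' @param records data.frame with `time_days` and logical `event`; if an
#'   `endpoint` column is present it can be filtered with `endpoint=`.
#' @param query_day optional day at which to report S(t).
#' @param endpoint optional endpoint filter ("PFS"/"OS").
#' @return list of class `km_curve`: `fit` (the survfit object), `median`
#'   (`NA` if never reached, with `median_defined = FALSE`), `surv_at_query`,
#'   `query_day`, `n`, `n_events`.
#' @export
km_estimate <- function(records, query_day = NULL, endpoint = NULL) {
  d <- .as_surv_df(records, endpoint)
  if (nrow(d) == 0L) stop("no survival records")
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = d)
  med <- unname(summary(fit)$table["median"])
  sq <- if (!is.null(query_day)) {
    s <- summary(fit, times = query_day, extend = TRUE)
    unname(s$surv)
  } else NA_real_
  structure(list(fit = fit, median = med, median_defined = !is.na(med),
                 surv_at_query = sq, query_day = query_day,
                 n = nrow(d), n_events = sum(d$event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: n = %d, events = %d, median = %s\n", x$n,
              x$n_events, if (x$median_defined) format(x$median) else "not reached"))
  if (!is.null(x$query_day))
    cat(sprintf("  S(%g) = %.3f\n", x$query_day, x$surv_at_query))
  invisible(x)
}

#' Log-rank test between two groups
#'
#' Two-sided log-rank test; p-value from the chi-square distribution with one
#' degree of freedom. Backed by [survival::survdiff()]. A group with zero
#' events triggers a warning but the statistic is still returned.
#'
#' @param a,b survival data.frames (`time_days`, `event`).
#' @param endpoint optional endpoint filter.
#' @return list: `chisq`, `p`, `n` (per group), `events` (per group).
#' @export
logrank_test <- function(a, b, endpoint = NULL) {
  a <- .as_surv_df(a, endpoint); b <- .as_surv_df(b, endpoint)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both groups must be non-empty")
  if (sum(a$event) == 0L || sum(b$event) == 0L)
    warning("a group has zero events; log-rank statistic may be degenerate")
  d <- rbind(data.frame(time_days = a$time_days, event = a$event, g = "A"),
             data.frame(time_days = b$time_days, event = b$event, g = "B"))
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ g, data = d)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = unname(sd$n), events = unname(sd$obs))
}

#' Cox proportional-hazards hazard ratio for a binary grouping
#'
#' Univariable Cox regression with Efron tie handling; reports the hazard
#' ratio for `group == level_of_interest` versus the reference, its Wald 95%
#' confidence interval and p-value, plus the log-rank p for the same
#' grouping. Monotone-likelihood / separation situations (common at n = 10)
#' are surfaced as a `separation` flag with the coxph warning retained.
#'
#' @param records data.frame with `time_days`, `event` and a `group` column
#'   with exactly two levels.
#' @param level_of_interest group level whose hazard is in the numerator;
#'   defaults to the second sorted level.
#' @param endpoint optional endpoint filter.
#' @return list of class `cox_result`: `hr`, `ci_low`, `ci_high`, `p_wald`,
#'   `p_logrank`, `n`, `n_events`, `separation`.
#' @export
cox_hr <- function(records, level_of_interest = NULL, endpoint = NULL) {
  d <- .as_surv_df(records, endpoint)
  stopifnot("group" %in% names(d))
  lev <- sort(unique(as.character(d$group)))
  if (length(lev) != 2) stop("group must have exactly two levels")
  if (sum(d$event) == 0L) stop("need at least one event")
  if (is.null(level_of_interest)) level_of_interest <- lev[2]
  d$g <- factor(as.character(d$group),
                levels = c(setdiff(lev, level_of_interest), level_of_interest))
  sep <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time_days, event) ~ g, data = d,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  lr <- logrank_test(d[d$g == levels(d$g)[1], , drop = FALSE],
                     d[d$g == levels(d$g)[2], , drop = FALSE])
  structure(list(hr = exp(beta), ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 p_wald = 2 * stats::pnorm(-abs(beta / se)),
                 p_logrank = lr$p, n = nrow(d), n_events = sum(d$event),
                 separation = sep),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH: HR = %.3f (95%% CI %.3f-%.3f), Wald p = %.4g, log-rank p = %.4g%s\n",
              x$hr, x$ci_low, x$ci_high, x$p_wald, x$p_logrank,
              if (x$separation) " [monotone likelihood warning]" else ""))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Unpaired two-tailed rank-sum comparison. For combined sample sizes up to
#' 12 the p-value is computed by exact enumeration of all assignments of the
#' pooled observations to the two groups (ties handled by mid-ranks), with
#' two-tailed p = min(1, 2 * min(P(U <= u), P(U >= u))); larger samples use
#' the tie-corrected normal approximation with continuity correction.
#'
#' @param x,y numeric samples.
#' @return list: `U` (statistic for `x`), `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n + m <= 12) {
    sel <- utils::combn(n + m, n)
    u_all <- apply(sel, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
    p <- 2 * min(mean(u_all <= U + 1e-9), mean(u_all >= U - 1e-9))
    list(U = U, p = min(1, p), method = "exact")
  } else {
    mu <- n * m / 2
    tie_tab <- table(r)
    N <- n + m
    sigma2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal_tie_corrected")
  }
}

# round half away from zero, matching clinical-table percentage style
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Adverse-event summary by CTCAE grade and relationship
#'
#' Tabulates an AE listing by CTCAE grade (1-5) and by relationship category,
#' with percentages of total events to one decimal (rounding half away from
#' zero, the style of clinical safety tables). Also reports the grade >= 2
#' subset and, within it, the count and share of events related to the study
#' drug (solely or in combination).
#'
#' @param events data.frame with integer `grade` in 1..5 and `relationship`
#'   in: "none", "gbm", "rt", "rt_gbm", "nox_a12", "nox_a12_gbm",
#'   "nox_a12_rt", "nox_a12_rt_gbm".
#' @return list of class `ae_summary`: `total`, `by_grade` (count + pct),
#'   `by_relationship`, `grade2plus` (total, drug-related count and pct).
#' @export
ae_summary <- function(events) {
  rel_levels <- c("none", "gbm", "rt", "rt_gbm", "nox_a12", "nox_a12_gbm",
                  "nox_a12_rt", "nox_a12_rt_gbm")
  if (nrow(events) > 0) {
    if (!all(events$grade %in% 1:5))
      stop("validation error: AE grade outside 1..5")
    bad <- setdiff(unique(events$relationship), rel_levels)
    if (length(bad))
      stop("validation error: unknown relationship category: ",
           paste(bad, collapse = ", "))
  }
  total <- nrow(events)
  gr <- table(factor(events$grade, levels = 1:5))
  rl <- table(factor(events$relationship, levels = rel_levels))
  pct <- function(k) if (total > 0) round_half_away(100 * k / total, 1)
                     else NA_real_
  g2 <- events[events$grade >= 2, , drop = FALSE]
  g2_drug <- sum(grepl("nox_a12", g2$relationship))
  structure(list(
    total = total,
    by_grade = data.frame(grade = 1:5, n = as.integer(gr),
                          pct = pct(as.integer(gr))),
    by_relationship = data.frame(relationship = rel_levels,
                                 n = as.integer(rl),
                                 pct = pct(as.integer(rl))),
    grade2plus = list(total = nrow(g2), drug_related = g2_drug,
                      drug_related_pct = if (nrow(g2) > 0)
                        round_half_away(100 * g2_drug / nrow(g2), 1)
                      else NA_real_)
  ), class = "ae_summary")
}

#' @export
print.ae_summary <- function(x, ...) {
  cat(sprintf("Adverse events: %d total\n", x$total))
  print(x$by_grade, row.names = FALSE)
  cat(sprintf("grade >= 2: %d, of which drug-related %d (%.1f%%)\n",
              x$grade2plus$total, x$grade2plus$drug_related,
              x$grade2plus$drug_related_pct))
  invisible(x)
}

#' Pharmacokinetic series summary
#'
#' For a plasma concentration time series: the steady-state day (first day
#' whose concentration is within 10% of the mean over the final week of the
#' series), the mean plateau level, whether the plateau exceeds the 1.5 uM
#' pharmacologic threshold, and whether the drug curve lies above the CXCL12
#' target curve at every time point.
#'
#' @param series data.frame with `day`, `conc_uM` and optionally
#'   `cxcl12_uM`; needs >= 5 points spanning >= 14 days.
#' @param threshold_uM pharmacologic plasma threshold (default 1.5).
#' @return list: `steady_state_day`, `plateau_uM`, `exceeds_threshold`,
#'   `drug_over_target` (`NA` when no target series).
#' @export
pk_summary <- function(series, threshold_uM = 1.5) {
  stopifnot(all(c("day", "conc_uM") %in% names(series)))
  if (is.unsorted(series$day, strictly = TRUE))
    stop("day grid must be strictly increasing")
  if (nrow(series) < 5 || diff(range(series$day)) < 14)
    stop("need >= 5 time points spanning >= 14 days")
  final_week <- series$conc_uM[series$day >= max(series$day) - 7]
  plateau <- mean(final_week)
  at_ss <- abs(series$conc_uM - plateau) <= 0.10 * plateau
  ss_day <- series$day[which(at_ss)[1]]
  list(steady_state_day = ss_day, plateau_uM = plateau,
       exceeds_threshold = plateau > threshold_uM,
       drug_over_target = if ("cxcl12_uM" %in% names(series))
         all(series$conc_uM >= series$cxcl12_uM) else NA)
}

#' Modified 3+3 dose-escalation decision
#'
#' Rule-based decision for one dose level of a modified 3+3 design with dose
#' levels 200/400/600 mg per week: with 3 evaluable patients, zero DLTs allow
#' escalation (or declare the recommended phase-II dose when already at the
#' top level), exactly one DLT expands the cohort to 6, and two or more stop
#' escalation with the MTD at the level below (>= 33% DLT rate). With 6
#' patients, fewer than 2 DLTs allow escalation / RP2D, otherwise stop.
#' Cohorts still short of 3 (or of 6 after an expansion) continue enrolling
#' at the same level unless 2 DLTs have already occurred.
#'
#' @param n_patients evaluable patients at the level (0..6).
#' @param n_dlt dose-limiting toxicities among them.
#' @param dose_level 1-based level index.
#' @param n_levels number of planned levels (default 3; top dose 600 mg).
#' @return list: `decision` (one of "escalate", "expand_same_level",
#'   "stop_declare_MTD", "declare_RP2D"), `mtd_level` (when stopping),
#'   `rp2d_mg_per_week` (when declaring RP2D).
#' @export
escalation_decision <- function(n_patients, n_dlt, dose_level = 1,
                                n_levels = 3,
                                dose_mg = c(200, 400, 600)) {
  if (n_patients > 6) stop("protocol violation: more than 6 patients at a level")
  if (n_dlt < 0 || n_dlt > n_patients)
    stop("DLT count must lie in [0, patients treated]")
  at_top <- dose_level >= n_levels
  if (n_dlt >= 2)
    return(list(decision = "stop_declare_MTD", mtd_level = dose_level - 1,
                rp2d_mg_per_week = if (dose_level > 1) dose_mg[dose_level - 1]
                                   else NA_real_))
  if (n_patients < 3 || (n_patients > 3 && n_patients < 6) ||
      (n_patients == 3 && n_dlt == 1))
    return(list(decision = "expand_same_level", mtd_level = NA,
                rp2d_mg_per_week = NA_real_))
  # here: (n == 3, 0 DLT) or (n == 6, <= 1 DLT)
  if (at_top)
    return(list(decision = "declare_RP2D", mtd_level = dose_level,
                rp2d_mg_per_week = dose_mg[n_levels]))
  list(decision = "escalate", mtd_level = NA, rp2d_mg_per_week = NA_real_)
}
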