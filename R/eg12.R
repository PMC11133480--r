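# Composite EG12 biomarker: median-centered mean of E12 and G12, cohort-median
# dichotomization, and rank correlation with progression-free survival.

#' Composite EG12 score
#'
#' EG12 combines the CXCL12+ fractions of endothelial cells (E12) and glioma
#' cells (G12) with equal weights: each component is centered at its cohort
#' median and the two centered values are averaged,
#' \deqn{EG12_i = ((E12_i - med(E12)) + (G12_i - med(G12))) / 2,}
#' so the score takes negative as well as positive values. Medians are taken
#' within each cohort separately, so cohorts with different staining baselines
#' are dichotomized independently. Patients with an undefined component (e.g.
#' zero endothelial cells in the sample) are flagged and excluded with a
#' warning.
#'
#' @param biomarkers data.frame with columns `patient_id`, `cohort`, `E12`,
#'   `G12` (percent units).
#' @return the input with an `EG12` column appended; excluded patients are
#'   dropped from the returned table.
#' @examples
#' b <- data.frame(patient_id = 1:3, cohort = "A",
#'                 E12 = c(10, 20, 30), G12 = c(1, 3, 5))
#' eg12_scores(b)$EG12  # -6, 0, 6
#' @export
eg12_scores <- function(biomarkers) {
  stopifnot(all(c("patient_id", "cohort", "E12", "G12") %in% names(biomarkers)))
  bad <- !is.finite(biomarkers$E12) | !is.finite(biomarkers$G12)
  if (any(bad)) {
    warning("excluding ", sum(bad), " patient(s) with undefined E12 or G12: ",
            paste(biomarkers$patient_id[bad], collapse = ", "))
    biomarkers <- biomarkers[!bad, , drop = FALSE]
  }
  out <- lapply(split(biomarkers, biomarkers$cohort), function(d) {
    if (nrow(d) < 2)
      stop("cohort '", d$cohort[1], "' has fewer than 2 patients with defined ",
           "E12 and G12")
    d$EG12 <- ((d$E12 - stats::median(d$E12)) +
                 (d$G12 - stats::median(d$G12))) / 2
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$patient_id, biomarkers$patient_id)), , drop = FALSE]
}

#' Median-split classifier
#'
#' Dichotomizes scores at the within-cohort median: strictly above the median
#' is "high", at or below is "low" (ties at the median deterministically go to
#' "low"). For an even number of all-distinct scores the groups have equal
#' size.
#'
#' @param scores numeric vector.
#' @return character vector of "high"/"low" labels.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("median split needs at least 2 scores")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ifelse(scores > stats::median(scores), "high", "low")
}

#' Spearman rank correlation with a two-tailed p-value
#'
#' Tie-corrected Spearman correlation: the Pearson correlation of mid-ranks.
#' The default two-tailed p-value uses the t approximation
#' \eqn{t = r_s \sqrt{(n-2)/(1-r_s^2)}} on n-2 degrees of freedom, the method
#' behind the p-values printed by common statistics packages. For small
#' samples an exact permutation p-value (proportion of the n! rank
#' permutations with |r| at least as large as observed) is available.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param method "t" (default) or "exact" (n <= 8).
#' @return list of class `spearman_result`: `r_s`, `p`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for a constant vector")
  rs <- stats::cor(rank(x), rank(y))
  if (method == "t") {
    if (abs(rs) >= 1) {
      p <- 0
    } else {
      tval <- rs * sqrt((n - 2) / (1 - rs^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  } else {
    if (n > 8) stop("exact permutation method supported for n <= 8")
    ry <- rank(y); rx <- rank(x)
    perms <- .permutations(n)
    ref <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(ref) >= abs(rs) - 1e-12)
  }
  structure(list(r_s = rs, p = min(p, 1), n = n, method = method),
            class = "spearman_result")
}

# all permutations of 1..n, one per row
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman r_s = %.3f, p = %.4g (n = %d, %s method)\n",
              x$r_s, x$p, x$n, x$method))
  invisible(x)
}

#' Correlate a biomarker with progression-free survival
#'
#' Joins a biomarker table to PFS survival records by patient id and computes
#' the Spearman correlation between the named biomarker column and PFS days.
#' Only patients with an observed PFS event contribute: a censoring time is
#' not a progression time, so censored patients (e.g. censored at the start of
#' a new anticancer therapy) are excluded, and the returned `n` reflects that
#' (a 10-patient cohort with one censoring yields n = 9).
#'
#' @param biomarkers data.frame with `patient_id` and the column named by
#'   `variable`.
#' @param survival_records data.frame with columns `patient_id`, `endpoint`,
#'   `time_days`, `event` (see [derive_pfs_os()]).
#' @param variable column of `biomarkers` to correlate, e.g. "EG12".
#' @inheritParams spearman_cor
#' @return a `spearman_result`.
#' @export
correlate_with_pfs <- function(biomarkers, survival_records, variable = "EG12",
                               method = c("t", "exact")) {
  stopifnot(variable %in% names(biomarkers),
            all(c("patient_id", "endpoint", "time_days", "event") %in%
                  names(survival_records)))
  pfs <- survival_records[survival_records$endpoint == "PFS" &
                            survival_records$event, , drop = FALSE]
  m <- merge(biomarkers[, c("patient_id", variable)], pfs,
             by = "patient_id")
  if (nrow(m) < 3)
    stop("fewer than 3 patients with a PFS event joinable to the biomarker ",
         "table")
  spearman_cor(m[[variable]], m$time_days, method = match.arg(method))
}
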