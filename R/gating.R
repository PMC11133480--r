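# Phenotype gating of segmented mIF cell tables (HALO-style completeness
# thresholds) and CXCL12-positivity frequency profiles.

#' Marker positivity thresholds and nuclear size window
#'
#' Defaults reproduce the HALO Highplex analysis settings used for the trial's
#' CODEX panel: per-marker nucleus/cytoplasm percent-completeness thresholds
#' (expressed as fractions in (0,1)) and the nuclear-area window (um^2) that a
#' segmented object must fall in to count as a cell. Comparisons downstream are
#' inclusive (a completeness exactly at threshold is positive; an area exactly
#' at a window bound is kept).
#'
#' @param dapi,cxcl12,cd68,cd31,ki67,asma,gfap per-marker completeness
#'   thresholds as fractions in (0,1).
#' @param area_min,area_max nuclear area window in um^2.
#' @return object of class `marker_thresholds`: a list with a named numeric
#'   `thresholds` vector and `area_min`/`area_max`.
#' @examples
#' thr <- marker_thresholds()
#' thr$thresholds[["cxcl12"]]  # 0.35
#' @export
marker_thresholds <- function(dapi = 0.15, cxcl12 = 0.35, cd68 = 0.20,
                              cd31 = 0.30, ki67 = 0.30, asma = 0.35,
                              gfap = 0.30, area_min = 12, area_max = 1000) {
  thr <- c(dapi = dapi, cxcl12 = cxcl12, cd68 = cd68, cd31 = cd31,
           ki67 = ki67, asma = asma, gfap = gfap)
  if (any(thr <= 0 | thr >= 1))
    stop("marker thresholds must lie strictly inside (0, 1)")
  if (!(area_min < area_max) || area_min <= 0)
    stop("nuclear area window requires 0 < area_min < area_max")
  structure(list(thresholds = thr, area_min = area_min, area_max = area_max),
            class = "marker_thresholds")
}

# Column names a cell table must carry; completeness columns map onto the
# thresholds by the marker name embedded in the column.
.cell_marker_cols <- c(dapi = "dapi_nuc", cxcl12 = "cxcl12_nc",
                       cd31 = "cd31_nc", asma = "asma_nc", cd68 = "cd68_nc",
                       gfap = "gfap_nc", ki67 = "ki67_nuc")

.validate_cells <- function(cells) {
  need <- c("cell_id", "nuclear_area_um2", unname(.cell_marker_cols))
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cell table is missing columns: ", paste(miss, collapse = ", "))
  bad_area <- which(!is.finite(cells$nuclear_area_um2) |
                      cells$nuclear_area_um2 <= 0)
  if (length(bad_area))
    stop("non-positive nuclear area for cell id(s): ",
         paste(utils::head(cells$cell_id[bad_area], 5), collapse = ", "))
  for (col in unname(.cell_marker_cols)) {
    v <- cells[[col]]
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad))
      stop("completeness fraction outside [0, 1] in column '", col,
           "' for cell id(s): ",
           paste(utils::head(cells$cell_id[bad], 5), collapse = ", "))
  }
  invisible(cells)
}

#' Filter segmented objects down to analyzable cells
#'
#' Keeps exactly the records whose DAPI nucleus completeness reaches the DAPI
#' threshold and whose nuclear area lies inside the size window, both bounds
#' inclusive. Row order is preserved. Records failing basic validation
#' (negative area, completeness outside \[0,1\]) raise an error naming the
#' offending cell ids.
#'
#' @param cells data.frame with columns `cell_id`, `nuclear_area_um2`,
#'   `dapi_nuc`, `cxcl12_nc`, `cd31_nc`, `asma_nc`, `cd68_nc`, `gfap_nc`,
#'   `ki67_nuc` (fractions in \[0,1\]).
#' @param thr a [marker_thresholds()] object.
#' @return the filtered data.frame.
#' @export
filter_cells <- function(cells, thr = marker_thresholds()) {
  stopifnot(inherits(thr, "marker_thresholds"))
  .validate_cells(cells)
  keep <- cells$dapi_nuc >= thr$thresholds[["dapi"]] &
    cells$nuclear_area_um2 >= thr$area_min &
    cells$nuclear_area_um2 <= thr$area_max
  cells[keep, , drop = FALSE]
}

#' Per-marker positivity calls
#'
#' A cell is positive for a marker when its completeness fraction is greater
#' than or equal to the marker's threshold.
#'
#' @param cells filtered cell table (see [filter_cells()]).
#' @inheritParams filter_cells
#' @return logical matrix, one row per cell, columns `dapi`, `cxcl12`, `cd31`,
#'   `asma`, `cd68`, `gfap`, `ki67`.
#' @export
call_positivity <- function(cells, thr = marker_thresholds()) {
  stopifnot(inherits(thr, "marker_thresholds"))
  .validate_cells(cells)
  markers <- names(.cell_marker_cols)
  flags <- vapply(markers, function(m) {
    cells[[.cell_marker_cols[[m]]]] >= thr$thresholds[[m]]
  }, logical(nrow(cells)))
  if (nrow(cells) == 1L) flags <- matrix(flags, nrow = 1,
                                         dimnames = list(NULL, markers))
  flags
}

#' Phenotype gate assignment
#'
#' Evaluates the four phenotype gates on per-marker positivity flags:
#' endothelial (CD31+), pericyte (aSMA+, CD31-), macrophage/microglia (CD68+),
#' glioma (GFAP+, CD68-, CD31-, aSMA-). DAPI positivity is guaranteed by the
#' upstream filter. A cell may satisfy no gate (counted only in totals) and may
#' satisfy both the endothelial and macrophage/microglia gates; the pericyte
#' gate excludes endothelial and the glioma gate excludes all three others by
#' construction.
#'
#' @param flags logical matrix from [call_positivity()].
#' @return logical matrix with columns `endothelial`, `pericyte`,
#'   `mphi_microglia`, `glioma`.
#' @export
assign_phenotypes <- function(flags) {
  need <- c("cd31", "asma", "cd68", "gfap")
  if (!all(need %in% colnames(flags)))
    stop("flags must carry columns: ", paste(need, collapse = ", "))
  cbind(
    endothelial    = flags[, "cd31"],
    pericyte       = flags[, "asma"] & !flags[, "cd31"],
    mphi_microglia = flags[, "cd68"],
    glioma         = flags[, "gfap"] & !flags[, "cd68"] & !flags[, "cd31"] &
                       !flags[, "asma"]
  )
}

#' CXCL12-positivity frequency profile of a sample
#'
#' Applies the DAPI/area filter, gates every remaining cell, and reports per
#' phenotype the member count, the CXCL12+ member count and their ratio: E12
#' (endothelial), P12 (pericyte), M12 (macrophage/microglia) and G12 (glioma),
#' each expressed in percent. The total CXCL12+ fraction uses all filtered
#' cells (gated or not) as denominator. A phenotype with zero members reports
#' `NA` rather than zero so that downstream composite scores are not fed
#' spurious values. The Ki-67+ fraction of all filtered cells and the
#' endothelial-and-macrophage dual-gate overlap count are reported alongside.
#'
#' @param cells raw cell table; the DAPI/area filter is applied internally.
#' @inheritParams filter_cells
#' @return list of class `cx_profile` with elements `counts` (data.frame:
#'   phenotype, n, n_cxcl12_pos, pct_cxcl12_pos), `total_cells`,
#'   `total_cxcl12_pos`, `pct_total_cxcl12_pos`, `pct_ki67_pos`,
#'   `n_endo_mphi_overlap`.
#' @export
cxcl12_frequencies <- function(cells, thr = marker_thresholds()) {
  kept <- filter_cells(cells, thr)
  if (nrow(kept) == 0L) stop("no cells after filtering")
  flags <- call_positivity(kept, thr)
  gates <- assign_phenotypes(flags)
  cx <- flags[, "cxcl12"]

  phenos <- colnames(gates)
  n <- colSums(gates)
  npos <- colSums(gates & cx)
  pct <- ifelse(n > 0, 100 * npos / n, NA_real_)

  structure(list(
    counts = data.frame(phenotype = phenos, n = as.integer(n),
                        n_cxcl12_pos = as.integer(npos),
                        pct_cxcl12_pos = unname(pct),
                        row.names = NULL),
    total_cells = nrow(kept),
    total_cxcl12_pos = as.integer(sum(cx)),
    pct_total_cxcl12_pos = 100 * sum(cx) / nrow(kept),
    pct_ki67_pos = 100 * sum(flags[, "ki67"]) / nrow(kept),
    n_endo_mphi_overlap = as.integer(sum(gates[, "endothelial"] &
                                           gates[, "mphi_microglia"]))
  ), class = "cx_profile")
}

#' @export
print.cx_profile <- function(x, ...) {
  cat(sprintf("CXCL12 frequency profile: %d cells, %.1f%% CXCL12+ overall\n",
              x$total_cells, x$pct_total_cxcl12_pos))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Tidy per-sample frequency row
#'
#' Flattens a [cxcl12_frequencies()] profile into one data.frame row with the
#' E12/P12/M12/G12 percentages, suitable for binding into a cohort biomarker
#' table.
#'
#' @param profile a `cx_profile`.
#' @param patient_id,cohort identifiers carried through.
#' @return one-row data.frame with columns patient_id, cohort, E12, P12, M12,
#'   G12, pct_total_cxcl12_pos, pct_ki67_pos, total_cells.
#' @export
profile_row <- function(profile, patient_id, cohort) {
  stopifnot(inherits(profile, "cx_profile"))
  p <- stats::setNames(profile$counts$pct_cxcl12_pos, profile$counts$phenotype)
  data.frame(patient_id = patient_id, cohort = cohort,
             E12 = p[["endothelial"]], P12 = p[["pericyte"]],
             M12 = p[["mphi_microglia"]], G12 = p[["glioma"]],
             pct_total_cxcl12_pos = profile$pct_total_cxcl12_pos,
             pct_ki67_pos = profile$pct_ki67_pos,
             total_cells = profile$total_cells,
             row.names = NULL)
}
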