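#' Convert raw fluorescent counts to normalized counts
#'
#' Normalized counts are camera-independent intensities:
#' `counts / (2^bit_depth * exposure_time * gain * binning_area)`, with
#' exposure time in seconds.
#'
#' @param counts Non-negative raw counts (vector allowed; NAs pass through).
#' @param meta An [acquisition_meta()].
#' @return Normalized counts, same shape as `counts`.
#' @export
normalized_counts <- function(counts, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (meta$exposure_time <= 0 || meta$gain <= 0 || meta$binning_area < 1)
    stopf("invalid acquisition metadata")
  if (any(counts < 0, na.rm = TRUE)) stopf("counts must be non-negative")
  counts / (2^meta$bit_depth * meta$exposure_time * meta$gain *
              meta$binning_area)
}

#' Score one TMA core: nuclear expression score with QC
#'
#' The nuclear expression score (NES) of a marker is the mean normalized
#' nuclear intensity over tumour-compartment, non-saturated cells. Cores with
#' fewer than `min_tumour_cells` tumour cells (default 100) fail quality
#' control, as do cores carrying a manual-exclusion flag (damaged tissue or
#' unwarranted staining are human judgements recorded upstream).
#'
#' @param cells Cell records from [extract_cells()] (one core).
#' @param marker Scored marker name.
#' @param core_id,patient_id Identifiers carried into the result.
#' @param min_tumour_cells QC minimum; exactly `min_tumour_cells` passes.
#' @param manual_exclude Manual QC exclusion flag.
#' @return A `core_result`: list with `core_id`, `patient_id`,
#'   `n_tumour_cells`, `n_cells`, `nes`, `qc_pass`, `qc_reason`.
#' @export
score_core <- function(cells, marker, core_id = "core", patient_id = NA,
                       min_tumour_cells = 100L, manual_exclude = FALSE) {
  col <- paste0("norm_", marker)
  if (!col %in% names(cells))
    stopf("marker '%s' not present in cell records", marker)
  tum <- cells$compartment == "tumour"
  n_tum <- sum(tum)
  use <- tum & !cells$saturated & !is.na(cells[[col]])
  nes <- if (any(use)) mean(cells[[col]][use]) else NA_real_
  qc_pass <- TRUE; qc_reason <- ""
  if (manual_exclude) {
    qc_pass <- FALSE; qc_reason <- "manual_exclusion"
  } else if (n_tum < min_tumour_cells) {
    qc_pass <- FALSE; qc_reason <- "min_tumour_cells"
  }
  structure(list(core_id = core_id, patient_id = patient_id,
                 n_tumour_cells = n_tum, n_cells = nrow(cells),
                 nes = nes, qc_pass = qc_pass, qc_reason = qc_reason),
            class = "core_result")
}

#' Aggregate passing cores into a patient-level score
#'
#' The patient NES is the pooled mean over all tumour cells of all
#' QC-passing cores (cell-weighted: equivalent to re-averaging the union of
#' cells), matching a score defined across all imaged tumour cells of a
#' sample. A per-core-mean average is available as an alternative mode.
#' Patients with fewer than `min_cores` passing cores are flagged missing
#' and excluded downstream.
#'
#' @param cores List of `core_result`s for one patient.
#' @param cells_by_core List of cell-record data frames aligned with `cores`.
#' @param marker Scored marker.
#' @param min_cores Minimum passing cores (default 2).
#' @param method `"pooled"` (default) or `"core_mean"`.
#' @return A `patient_record` list: `patient_id`, `nes`, `n_cores_pass`,
#'   `n_tumour_cells`, `missing`, `missing_reason`.
#' @export
aggregate_patient <- function(cores, cells_by_core, marker,
                              min_cores = 2L,
                              method = c("pooled", "core_mean")) {
  method <- match.arg(method)
  stopifnot(length(cores) == length(cells_by_core), length(cores) >= 1)
  patient_id <- cores[[1]]$patient_id
  pass <- vapply(cores, `[[`, TRUE, "qc_pass")
  if (sum(pass) < min_cores)
    return(structure(list(patient_id = patient_id, nes = NA_real_,
                          n_cores_pass = sum(pass), n_tumour_cells = 0L,
                          missing = TRUE,
                          missing_reason = sprintf(
                            "only %d of %d cores passed QC (minimum %d)",
                            sum(pass), length(cores), min_cores)),
                     class = "patient_record"))
  col <- paste0("norm_", marker)
  vals <- unlist(lapply(which(pass), function(i) {
    cells <- cells_by_core[[i]]
    use <- cells$compartment == "tumour" & !cells$saturated &
      !is.na(cells[[col]])
    cells[[col]][use]
  }))
  nes <- if (method == "pooled") mean(vals) else
    mean(vapply(cores[pass], `[[`, 0, "nes"))
  structure(list(patient_id = patient_id, nes = nes,
                 n_cores_pass = sum(pass), n_tumour_cells = length(vals),
                 missing = FALSE, missing_reason = ""),
            class = "patient_record")
}

#' Per-cell marker positivity and percent extent
#'
#' A cell is positive when its normalized mean nuclear intensity reaches the
#' threshold: a fixed value, or Otsu's threshold over the supplied cell-level
#' distribution (cohort-wide when cells from all cores are passed together).
#' Extent is `100 * positives / cells` within the chosen compartment.
#'
#' @param cells Cell records (one or many cores pooled).
#' @param marker Marker name.
#' @param threshold `"otsu"` or a fixed numeric threshold (normalized counts).
#' @param compartment Compartment the extent refers to (default tumour);
#'   `"any"` uses all cells.
#' @return List: `positive` (logical per row of `cells`), `extent` (percent),
#'   `threshold` (value used).
#' @export
marker_positivity <- function(cells, marker, threshold = "otsu",
                              compartment = "tumour") {
  col <- paste0("norm_", marker)
  if (!col %in% names(cells)) stopf("marker '%s' not in cell records", marker)
  v <- cells[[col]]
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(v[!is.na(v)])
  } else if (is.numeric(threshold)) threshold else
    stopf("undefined threshold rule '%s'", paste(threshold, collapse = "/"))
  positive <- !is.na(v) & v >= thr
  in_comp <- if (identical(compartment, "any")) rep(TRUE, nrow(cells)) else
    cells$compartment == compartment
  n <- sum(in_comp)
  extent <- if (n == 0) NA_real_ else 100 * sum(positive & in_comp) / n
  list(positive = positive, extent = extent, threshold = thr)
}

#' Immune phenotype counts, densities and tumour/stroma ratios
#'
#' Phenotypes are boolean combinations of marker positivity (defaults:
#' cytotoxic T cell = CD3+ and CD8+, regulatory T cell = CD3+ and FOXP3+,
#' macrophage = CD163+; phenotypes whose markers are absent from the records
#' are skipped). Density is count per compartment area; the tumour/stroma
#' (T/S) ratio is the density ratio and is reported as missing (NA) when the
#' stroma density is zero, never as infinity.
#'
#' @param cells Cell records.
#' @param tumour_area,stroma_area Compartment areas in pixels (> 0 total).
#' @param phenotypes Named list of marker-name character vectors (AND rules).
#' @param threshold Positivity rule per [marker_positivity()] (shared).
#' @return `data.frame` with one row per phenotype: counts, densities and
#'   `ts_ratio`.
#' @export
immune_metrics <- function(cells, tumour_area, stroma_area,
                           phenotypes = list(T_cyt = c("CD3", "CD8"),
                                             Treg = c("CD3", "FOXP3"),
                                             macrophage = "CD163"),
                           threshold = "otsu") {
  if (tumour_area + stroma_area <= 0) stopf("zero analysable area")
  have <- function(ms) all(paste0("norm_", ms) %in% names(cells))
  phenotypes <- phenotypes[vapply(phenotypes, have, TRUE)]
  if (!length(phenotypes)) stopf("no phenotype has all its markers in the records")
  pos <- lapply(unique(unlist(phenotypes)), function(m)
    marker_positivity(cells, m, threshold = threshold)$positive)
  names(pos) <- unique(unlist(phenotypes))
  rows <- lapply(names(phenotypes), function(ph) {
    flag <- Reduce(`&`, pos[phenotypes[[ph]]])
    n_t <- sum(flag & cells$compartment == "tumour")
    n_s <- sum(flag & cells$compartment == "stroma")
    d_t <- if (tumour_area > 0) n_t / tumour_area else NA_real_
    d_s <- if (stroma_area > 0) n_s / stroma_area else NA_real_
    ts <- if (is.na(d_s) || d_s == 0) NA_real_ else d_t / d_s
    data.frame(phenotype = ph, n_tumour = n_t, n_stroma = n_s,
               density_tumour = d_t, density_stroma = d_s, ts_ratio = ts,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stratify a cohort into Q1 / IQR / Q4 by score quartiles
#'
#' Cut-points are the 25th and 75th percentiles under the linear-interpolation
#' quantile convention (R type 7); scores strictly below the 25th percentile
#' are Q1 (low), strictly above the 75th are Q4 (high), the rest IQR.
#' Quartiles are computed on the supplied cohort only, so independent cohorts
#' are stratified independently.
#'
#' @param nes Numeric patient scores; NAs allowed (returned as NA stratum).
#' @param min_n Minimum number of non-missing scores (default 8).
#' @return Factor with levels `Q1`, `IQR`, `Q4` (attribute `cutpoints`).
#' @export
stratify_cohort <- function(nes, min_n = 8L) {
  ok <- !is.na(nes)
  if (sum(ok) < min_n)
    stopf("need at least %d non-missing scores to stratify", min_n)
  if (diff(range(nes[ok])) == 0)
    stopf("degenerate score distribution: all scores identical")
  q <- quantile(nes[ok], c(0.25, 0.75), type = 7, names = FALSE)
  s <- ifelse(nes < q[1], "Q1", ifelse(nes > q[2], "Q4", "IQR"))
  out <- factor(s, levels = c("Q1", "IQR", "Q4"))
  attr(out, "cutpoints") <- q
  out
}
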