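#' Override one marker's median abundance in a simulation config
#'
#' Used to apply per-core cohort overrides (the patient's true score becomes
#' the scored marker's median abundance for that core).
#'
#' @param config A [sim_config()].
#' @param name Marker name.
#' @param median New median abundance.
#' @return The modified config.
#' @export
set_marker_median <- function(config, name, median) {
  i <- match(name, marker_names(config))
  if (is.na(i)) stopf("marker '%s' not in config", name)
  config$markers[[i]]$median <- median
  config
}

#' Process one multispectral core image into cell records
#'
#' Runs unmixing, tissue segmentation on the epithelial component, nuclear
#' segmentation on the counterstain component and per-cell extraction.
#'
#' @param image A [multispectral_image()].
#' @param library A [spectral_library()].
#' @param epithelial_marker,counterstain Endmember names driving the two
#'   segmentations.
#' @param seg_params Optional overrides for segmentation parameters: `sigma`,
#'   `min_area`, `watershed_tolerance`, `closing_radius`, `min_region_area`,
#'   `threshold`.
#' @return List: `cells` (data frame), `mask` (`tumour_mask`), `components`,
#'   `nuclei` (label matrix).
#' @export
process_core <- function(image, library, epithelial_marker = "EpCAM",
                         counterstain = "DAPI", seg_params = list()) {
  p <- utils::modifyList(list(sigma = 1.5, min_area = 20,
                              watershed_tolerance = 0.2, closing_radius = 3,
                              min_region_area = 500, threshold = "otsu"),
                         seg_params)
  cs <- unmix_image(image, library)
  mask <- segment_tissue(cs, epithelial_marker, threshold = p$threshold,
                         closing_radius = p$closing_radius,
                         min_region_area = p$min_region_area)
  nuc <- segment_nuclei(component(cs, counterstain), sigma = p$sigma,
                        min_area = p$min_area,
                        watershed_tolerance = p$watershed_tolerance)
  cells <- extract_cells(nuc, mask, cs)
  list(cells = cells, mask = mask, components = cs, nuclei = nuc)
}

#' Image, score and stratify a simulated cohort end to end
#'
#' For every core in a [simulate_cohort()] design: simulate the multispectral
#' image (with the patient's true score as the scored marker's median
#' abundance and the core's derived seed), unmix with the ground-truth
#' library, segment, extract cells and score the core; then aggregate
#' passing cores per patient, stratify the cohort by score quartiles and
#' join the clinical truth columns.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config Base [sim_config()] shared by all cores.
#' @param min_cores Minimum passing cores per patient (default 2).
#' @param seg_params Segmentation overrides, see [process_core()].
#' @return List: `patients` (data frame with `nes`, `stratum`, the survival
#'   and covariate columns, and `true_abundance` = realized mean scored
#'   abundance over the patient's simulated tumour cells), `core_results`,
#'   `n_excluded`.
#' @export
run_synthetic_cohort <- function(cohort, config, min_cores = 2L,
                                 seg_params = list()) {
  library_ <- generate_library(config)
  marker <- config$scored_marker
  counterstain <- config$markers[[match(
    "counterstain", vapply(config$markers, `[[`, "", "role"))]]$name
  epi <- config$markers[[match(
    "epithelial", vapply(config$markers, `[[`, "", "role"))]]$name
  core_results <- vector("list", nrow(cohort$cores))
  cells_store <- vector("list", nrow(cohort$cores))
  truth_means <- numeric(nrow(cohort$cores))
  truth_ncells <- integer(nrow(cohort$cores))
  for (i in seq_len(nrow(cohort$cores))) {
    row <- cohort$cores[i, ]
    cfg <- set_marker_median(config, marker, row$scored_median)
    cfg$seed <- row$seed
    sim <- simulate_core(cfg, library_)
    proc <- process_core(sim$image, library_, epithelial_marker = epi,
                         counterstain = counterstain, seg_params = seg_params)
    core_results[[i]] <- score_core(proc$cells, marker,
                                    core_id = row$core_id,
                                    patient_id = row$patient_id)
    cells_store[[i]] <- proc$cells
    tum <- sim$truth$compartment == "tumour"
    truth_means[i] <- mean(sim$truth[[paste0("abund_", marker)]][tum])
    truth_ncells[i] <- sum(tum)
  }
  by_pat <- split(seq_len(nrow(cohort$cores)), cohort$cores$patient_id)
  recs <- lapply(by_pat, function(ix)
    aggregate_patient(core_results[ix], cells_store[ix], marker,
                      min_cores = min_cores))
  pid <- names(by_pat)
  nes <- vapply(recs, `[[`, 0, "nes")
  true_ab <- vapply(by_pat, function(ix)
    sum(truth_means[ix] * truth_ncells[ix]) / sum(truth_ncells[ix]), 0)
  pat <- data.frame(patient_id = pid, nes = nes, true_abundance = true_ab,
                    n_cores_pass = vapply(recs, `[[`, 0L, "n_cores_pass"),
                    missing = vapply(recs, `[[`, TRUE, "missing"),
                    stringsAsFactors = FALSE, row.names = NULL)
  pat <- merge(cohort$patients, pat, by = "patient_id", sort = TRUE)
  pat$stratum <- NA
  ok <- !pat$missing & !is.na(pat$nes)
  pat$stratum <- factor(NA, levels = c("Q1", "IQR", "Q4"))
  if (sum(ok) >= 8) pat$stratum[ok] <- stratify_cohort(pat$nes[ok])
  list(patients = pat, core_results = core_results,
       n_excluded = sum(!ok))
}
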