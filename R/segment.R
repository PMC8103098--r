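#' Segment the tumour compartment from the epithelial-marker component
#'
#' Thresholds the epithelial (EpCAM / cytokeratin) component image — Otsu's
#' method by default, or a fixed threshold — applies morphological closing,
#' and drops connected regions smaller than `min_region_area`. The mask
#' complement within the frame is the stroma compartment.
#'
#' @param components A `component_stack` from [unmix_image()].
#' @param epithelial_marker Name of the epithelial endmember.
#' @param threshold `"otsu"` or a fixed numeric threshold on the component.
#' @param closing_radius Morphological closing radius in pixels (0 disables).
#' @param min_region_area Minimum region area kept, in pixels.
#' @return A `tumour_mask`: list with `mask` (logical H x W), `tumour_area`
#'   and `stroma_area` (pixel counts).
#' @export
segment_tissue <- function(components, epithelial_marker = "EpCAM",
                           threshold = "otsu", closing_radius = 3,
                           min_region_area = 500) {
  img <- component(components, epithelial_marker)
  if (all(img <= 0)) {
    mask <- matrix(FALSE, nrow(img), ncol(img))
  } else if (diff(range(img)) == 0) {
    mask <- img > 0                       # uniform positive: full frame
  } else if (identical(threshold, "otsu")) {
    mask <- img > otsu_threshold(img)
  } else {
    mask <- img > threshold
  }
  if (any(mask) && !all(mask)) {
    if (closing_radius > 0) {
      kern <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
      mask <- EBImage::closing(mask * 1, kern) > 0
    }
    if (min_region_area > 0) {
      lab <- EBImage::bwlabel(mask * 1)
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= min_region_area)
      mask <- matrix(lab %in% keep, nrow(img), ncol(img))
    }
  }
  structure(list(mask = mask,
                 tumour_area = sum(mask),
                 stroma_area = sum(!mask)),
            class = "tumour_mask")
}

#' Segment nuclei from the counterstain component
#'
#' Gaussian smoothing, Otsu threshold, Euclidean distance transform and
#' watershed from its regional maxima, then removal of labels below
#' `min_area`. Fully deterministic. The Otsu bins span the data range, so the
#' label count is invariant to global rescaling of the counterstain.
#'
#' @param counterstain H x W counterstain component image (e.g.
#'   `component(cs, "DAPI")`).
#' @param sigma Gaussian smoothing sd in pixels.
#' @param min_area Minimum nucleus area kept (pixels).
#' @param watershed_tolerance Minimum depth between adjacent intensity peaks
#'   for them to seed distinct nuclei (the minimum peak-separation control).
#' @param refine Restrict each label to pixels above the Otsu threshold of
#'   the raw (unsmoothed) counterstain, so the smoothing used for stable
#'   watershed seeding does not dilate the nuclear masks (default TRUE).
#' @return Integer H x W label matrix; 0 = background, 1..N = nuclei
#'   (labels renumbered consecutively).
#' @export
segment_nuclei <- function(counterstain, sigma = 1.5, min_area = 20,
                           watershed_tolerance = 0.2, refine = TRUE) {
  stopifnot(is.matrix(counterstain))
  if (all(counterstain <= 0))
    return(matrix(0L, nrow(counterstain), ncol(counterstain)))
  sm <- as.matrix(EBImage::gblur(EBImage::Image(counterstain), sigma = sigma))
  thr <- otsu_threshold(sm)
  binary <- sm > thr
  if (!any(binary))
    return(matrix(0L, nrow(counterstain), ncol(counterstain)))
  dm <- EBImage::distmap(EBImage::Image(binary * 1))
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(lab), nrow(counterstain))
  if (refine) lab[counterstain <= otsu_threshold(counterstain)] <- 0L
  # disconnected fragments left sharing one watershed label (nuclei whose
  # smoothed supports bridged) become separate nuclei
  cc <- matrix(as.integer(EBImage::bwlabel((lab > 0) * 1)),
               nrow(counterstain))
  pos <- lab > 0
  if (any(pos))
    lab[pos] <- as.integer(factor(lab[pos] + as.numeric(max(lab) + 1) * cc[pos]))
  if (min_area > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  old <- sort(unique(lab[lab > 0]))
  if (length(old)) lab[lab > 0] <- match(lab[lab > 0], old)
  lab
}

#' Extract per-cell records from labelled nuclei
#'
#' One record per nucleus label: 0-based centroid, area, compartment by
#' strict majority of nucleus pixels inside the tumour mask (exact ties go to
#' tumour), per-marker mean nuclear intensity in raw component units and in
#' normalized counts, and a saturation flag set when any nucleus pixel was at
#' the bit-depth ceiling.
#'
#' @param nuclei Integer label matrix from [segment_nuclei()].
#' @param mask A `tumour_mask` from [segment_tissue()].
#' @param components A `component_stack` from [unmix_image()].
#' @param meta Optional [acquisition_meta()]; defaults to the stack's.
#' @return `data.frame` of cell records: `cell_id`, `row`, `col`,
#'   `nucleus_area`, `compartment`, `saturated`, then `raw_<marker>` and
#'   `norm_<marker>` per non-AF endmember.
#' @export
extract_cells <- function(nuclei, mask, components, meta = NULL) {
  stopifnot(inherits(mask, "tumour_mask"), inherits(components, "component_stack"))
  d <- dim(components$abundances)
  if (!all(dim(nuclei) == d[1:2]) || !all(dim(mask$mask) == d[1:2]))
    stopf("label image, mask and components have mismatched shapes")
  meta <- meta %||% components$meta
  n <- max(nuclei)
  markers <- setdiff(components$endmembers, components$endmembers[components$af_index])
  out <- data.frame(cell_id = seq_len(n),
                    row = NA_real_, col = NA_real_,
                    nucleus_area = NA_integer_,
                    compartment = NA_character_,
                    saturated = NA,
                    stringsAsFactors = FALSE)
  if (n == 0) {
    for (m in markers) {
      out[[paste0("raw_", m)]] <- numeric(0)
      out[[paste0("norm_", m)]] <- numeric(0)
    }
    return(out)
  }
  idx <- which(nuclei > 0)
  lab <- nuclei[idx]
  rows <- (idx - 1L) %% d[1] + 1L
  cols <- (idx - 1L) %/% d[1] + 1L
  area <- tabulate(lab, n)
  out$row <- as.numeric(tapply(rows, lab, mean)) - 1
  out$col <- as.numeric(tapply(cols, lab, mean)) - 1
  out$nucleus_area <- area
  in_t <- tapply(mask$mask[idx], lab, sum)
  out$compartment <- ifelse(as.numeric(in_t) / area >= 0.5, "tumour", "stroma")
  out$saturated <- as.logical(tapply(components$saturated[idx], lab, any))
  # nuclear means use non-saturated pixels only (clipping breaks linearity);
  # a fully saturated nucleus gets NA means and carries the flag
  ok <- !components$saturated[idx]
  lab_ok <- lab[ok]; idx_ok <- idx[ok]
  for (m in markers) {
    v <- components$abundances[, , m][idx_ok]
    raw <- rep(NA_real_, n)
    mm <- tapply(v, lab_ok, mean)
    raw[as.integer(names(mm))] <- as.numeric(mm)
    out[[paste0("raw_", m)]] <- raw
    out[[paste0("norm_", m)]] <- normalized_counts(raw, meta)
  }
  out
}
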