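#' Acquisition metadata for a multispectral image
#'
#' Camera settings needed to convert raw fluorescent counts into
#' camera-independent normalized counts. Exposure time is in seconds; binning
#' area is 1 unless pixels were binned on-chip.
#'
#' @param bit_depth Camera bit depth (8, 12 or 16).
#' @param exposure_time Exposure time in seconds (> 0).
#' @param gain Unitless camera gain multiplier (> 0).
#' @param binning_area On-chip binning area in pixels (>= 1).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(bit_depth = 12L, exposure_time = 1, gain = 1,
                             binning_area = 1L) {
  if (!bit_depth %in% c(8L, 12L, 16L)) stopf("bit_depth must be 8, 12 or 16")
  if (exposure_time <= 0) stopf("exposure_time must be > 0 (seconds)")
  if (gain <= 0) stopf("gain must be > 0")
  if (binning_area < 1) stopf("binning_area must be >= 1")
  structure(list(bit_depth = as.integer(bit_depth),
                 exposure_time = exposure_time, gain = gain,
                 binning_area = binning_area),
            class = "acquisition_meta")
}

#' Multispectral image stack
#'
#' @param pixels Numeric H x W x C array of non-negative counts.
#' @param meta An [acquisition_meta()] object.
#' @param channels Optional channel names (length C).
#' @return An object of class `multispectral_image`.
#' @export
multispectral_image <- function(pixels, meta, channels = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L,
            inherits(meta, "acquisition_meta"))
  if (any(pixels < 0)) stopf("pixel counts must be non-negative")
  if (any(pixels > 2^meta$bit_depth - 1))
    stopf("pixel counts exceed the bit-depth ceiling")
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(pixels)[3]))
  structure(list(pixels = pixels, meta = meta, channels = channels),
            class = "multispectral_image")
}

#' Spectral library of endmember emission spectra
#'
#' Columns are endmembers (fluorophores plus exactly one autofluorescence
#' endmember), rows are imaging channels. Every spectrum is non-negative and
#' normalized to unit Euclidean norm, so unmixed abundances carry the
#' intensity scale.
#'
#' @param spectra Numeric channels x endmembers matrix with endmember column
#'   names.
#' @param af_name Name of the autofluorescence endmember column.
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(spectra, af_name = "AF") {
  stopifnot(is.matrix(spectra), !is.null(colnames(spectra)))
  if (any(spectra < 0)) stopf("spectra must be non-negative")
  if (!af_name %in% colnames(spectra))
    stopf("autofluorescence endmember '%s' not found in library", af_name)
  nrm <- sqrt(colSums(spectra^2))
  if (any(nrm == 0)) stopf("zero spectrum in library")
  spectra <- sweep(spectra, 2, nrm, "/")
  structure(list(spectra = spectra,
                 channel_count = nrow(spectra),
                 endmembers = colnames(spectra),
                 af_index = match(af_name, colnames(spectra))),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("Spectral library: %d channels, %d endmembers (%s; AF = '%s')\n",
              x$channel_count, length(x$endmembers),
              paste(x$endmembers, collapse = ", "),
              x$endmembers[x$af_index]))
  invisible(x)
}

#' @export
print.multispectral_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "Multispectral image: %d x %d px, %d channels, %d-bit, %gs exposure, gain %g\n",
    d[1], d[2], d[3], x$meta$bit_depth, x$meta$exposure_time, x$meta$gain))
  invisible(x)
}
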