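#' Write a multispectral image as multi-page TIFF with a metadata sidecar
#'
#' One 16-bit TIFF page per channel, counts stored as `counts / (2^bit_depth - 1)`
#' fractions, plus a YAML sidecar (`<path>.yml`) recording bit depth, exposure
#' time (seconds), gain, binning area and channel names.
#'
#' @param image A [multispectral_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_msi <- function(image, path) {
  stopifnot(inherits(image, "multispectral_image"))
  ceiling_ <- 2^image$meta$bit_depth - 1
  pages <- lapply(seq_len(dim(image$pixels)[3]), function(k)
    pmin(pmax(image$pixels[, , k] / ceiling_, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(bit_depth = image$meta$bit_depth,
               exposure_time_s = image$meta$exposure_time,
               gain = image$meta$gain,
               binning_area = image$meta$binning_area,
               channels = as.list(image$channels))
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}

#' Read a multispectral image written by [write_msi()]
#'
#' @param path TIFF path; the `<path>.yml` sidecar must be present.
#' @return A [multispectral_image()].
#' @export
read_msi <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ceiling_ <- 2^side$bit_depth - 1
  px <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) px[, , k] <- pages[[k]] * ceiling_
  multispectral_image(px,
                      acquisition_meta(side$bit_depth, side$exposure_time_s,
                                       side$gain, side$binning_area),
                      channels = unlist(side$channels))
}

#' Write / read a spectral library as a delimited table
#'
#' Tab-delimited, rows = channels, columns = endmembers, one header line of
#' endmember names.
#'
#' @param library A [spectral_library()].
#' @param path File path.
#' @return `path` invisibly for the writer; a [spectral_library()] for the
#'   reader.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  write.table(library$spectra, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @param af_name Autofluorescence column name (reader only).
#' @export
read_library <- function(path, af_name = "AF") {
  tab <- read.delim(path, check.names = FALSE)
  spectral_library(as.matrix(tab), af_name = af_name)
}

#' Write a cell or truth table as tab-delimited text
#'
#' @param x A data frame (cell records, core truth, patient tables).
#' @param path File path.
#' @export
write_cell_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  read.delim(path, check.names = FALSE)
}
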