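#' Estimate a spectral library from reference slides
#'
#' The autofluorescence (AF) spectrum is the unit-normalized mean spectrum of
#' the unstained slide. Each fluorophore spectrum is the unit-normalized mean
#' spectrum of the brightest `bright_fraction` of its single-stain slide's
#' pixels (ranked by total counts), after subtracting the AF contribution —
#' the unstained slide's mean spectrum in raw counts, which shares the
#' acquisition settings — and flooring at zero. (Projecting out the AF
#' direction instead would also remove the overlapping part of the
#' fluorophore spectrum and distort it.) Saturated pixels (any channel at
#' the bit-depth ceiling) are excluded throughout.
#'
#' @param single_stain_images Named list of [multispectral_image()]s, one per
#'   fluorophore; names become endmember names.
#' @param unstained_image [multispectral_image()] of the unstained slide.
#' @param bright_fraction Fraction of brightest pixels used, in `(0, 0.5]`.
#' @param dark_floor Minimum mean total counts (above the AF background)
#'   required of the selected bright pixels; below it the slide is deemed
#'   all-dark and estimation fails naming the endmember.
#' @return A [spectral_library()] with endmembers in input order plus `"AF"`.
#' @export
estimate_library <- function(single_stain_images, unstained_image,
                             bright_fraction = 0.02, dark_floor = 1) {
  if (length(single_stain_images) < 1) stopf("need at least one single-stain image")
  if (is.null(names(single_stain_images)) ||
      any(!nzchar(names(single_stain_images))))
    stopf("single_stain_images must be a named list")
  if (!(bright_fraction > 0 && bright_fraction <= 0.5))
    stopf("bright_fraction must be in (0, 0.5]")
  flat <- function(img) {
    d <- dim(img$pixels)
    matrix(img$pixels, d[1] * d[2], d[3])
  }
  unsat <- function(img, M) {
    ceiling_ <- 2^img$meta$bit_depth - 1
    M[rowSums(M >= ceiling_) == 0, , drop = FALSE]
  }
  U <- unsat(unstained_image, flat(unstained_image))
  af_counts <- colMeans(U)
  if (sum(af_counts^2) == 0) stopf("unstained image is empty; cannot estimate AF")
  af <- af_counts / sqrt(sum(af_counts^2))
  spectra <- vapply(names(single_stain_images), function(nm) {
    img <- single_stain_images[[nm]]
    M <- unsat(img, flat(img))
    tot <- rowSums(M)
    nb <- max(1L, floor(length(tot) * bright_fraction))
    bright <- M[order(tot, decreasing = TRUE)[seq_len(nb)], , drop = FALSE]
    m <- colMeans(bright)
    s <- pmax(m - af_counts, 0)        # remove the AF background spectrum
    if (sqrt(sum(s^2)) < dark_floor)
      stopf("single-stain slide for '%s' is all-dark; cannot estimate its spectrum",
            nm)
    s / sqrt(sum(s^2))
  }, numeric(dim(unstained_image$pixels)[3]))
  spectral_library(cbind(spectra, AF = af), af_name = "AF")
}

#' Unmix one pixel spectrum by non-negative least squares
#'
#' Solves `argmin_{a >= 0} || S a - pixel ||_2` with the Lawson-Hanson
#' active-set algorithm, where the columns of `S` are the library's
#' endmember spectra. The returned solution satisfies the KKT conditions to
#' within `1e-8`.
#'
#' @param pixel Numeric vector of counts, one per channel.
#' @param library A [spectral_library()].
#' @return Named abundance vector (one entry per endmember).
#' @export
unmix_pixel <- function(pixel, library) {
  stopifnot(inherits(library, "spectral_library"))
  if (length(pixel) != library$channel_count)
    stopf("pixel has %d channels but the library %d",
          length(pixel), library$channel_count)
  a <- nnls_cpp(library$spectra, as.numeric(pixel))
  setNames(as.numeric(a), library$endmembers)
}

#' Unmix a multispectral image into per-endmember component images
#'
#' Applies [unmix_pixel()] to every pixel (vectorized through the compiled
#' solver) and records the per-pixel reconstruction residual (Euclidean norm)
#' plus a saturation mask flagging pixels at the bit-depth ceiling in any
#' channel; saturated pixels violate the linear mixing model and are excluded
#' from downstream nuclear means.
#'
#' @param image A [multispectral_image()].
#' @param library A [spectral_library()].
#' @return A `component_stack`: list with `abundances` (H x W x K array with
#'   endmember dimnames), `residual` (H x W), `saturated` (logical H x W),
#'   `endmembers`, `af_index` and the acquisition `meta`.
#' @export
unmix_image <- function(image, library) {
  stopifnot(inherits(image, "multispectral_image"),
            inherits(library, "spectral_library"))
  d <- dim(image$pixels)
  if (d[3] != library$channel_count)
    stopf("image has %d channels but the library %d", d[3],
          library$channel_count)
  B <- matrix(image$pixels, d[1] * d[2], d[3])
  res <- nnls_matrix_cpp(library$spectra, B)
  K <- length(library$endmembers)
  ab <- array(res[, seq_len(K)], c(d[1], d[2], K),
              dimnames = list(NULL, NULL, library$endmembers))
  ceiling_ <- 2^image$meta$bit_depth - 1
  sat <- matrix(rowSums(B >= ceiling_) > 0, d[1], d[2])
  structure(list(abundances = ab,
                 residual = matrix(res[, K + 1L], d[1], d[2]),
                 saturated = sat,
                 endmembers = library$endmembers,
                 af_index = library$af_index,
                 meta = image$meta),
            class = "component_stack")
}

#' Extract one component image from a component stack
#'
#' @param components A `component_stack` from [unmix_image()].
#' @param name Endmember name.
#' @return H x W abundance matrix.
#' @export
component <- function(components, name) {
  stopifnot(inherits(components, "component_stack"))
  if (!name %in% components$endmembers)
    stopf("endmember '%s' not in component stack (have: %s)", name,
          paste(components$endmembers, collapse = ", "))
  components$abundances[, , name]
}
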