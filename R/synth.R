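#' Declare a simulated marker / fluorophore
#'
#' A marker couples a Gaussian emission spectrum (peak channel and spectral
#' width, in channel units, 1-based) to an abundance model. Abundance is in
#' photons per second per pixel, so that with the default camera model the
#' normalized-count score recovers `abundance / 2^bit_depth` exactly in the
#' noiseless limit. Roles:
#' \describe{
#'   \item{counterstain}{expressed in every nucleus (DAPI-like); lognormal
#'     per-cell abundance with median `median` and log-sd `sigma`.}
#'   \item{nuclear}{continuous nuclear marker (RAD51-like); lognormal in
#'     tumour nuclei; stroma nuclei use median `median * stroma_factor`.}
#'   \item{epithelial}{uniform abundance `median` at every tumour-compartment
#'     pixel, zero in stroma (EpCAM/cytokeratin-like tumour mask signal).}
#'   \item{bimodal}{positive in a fraction `positive_fraction` of tumour
#'     cells (Ki67-like); negatives use median `median * negative_factor`.}
#'   \item{immune}{expressed only in cells assigned an immune phenotype that
#'     includes this marker (see `immune_phenotypes` in [sim_config()]).}
#' }
#'
#' @param name Marker name.
#' @param peak_channel Emission peak, in 1-based channel units.
#' @param width Gaussian spectral width (channels); `width = 0` gives a
#'   delta spectrum on the peak channel.
#' @param role One of `"counterstain"`, `"nuclear"`, `"epithelial"`,
#'   `"bimodal"`, `"immune"`.
#' @param median Median abundance (photons / s / pixel).
#' @param sigma Lognormal log-sd of per-cell abundance.
#' @param positive_fraction Fraction of tumour cells positive (bimodal role).
#' @param negative_factor Median multiplier for negative cells (bimodal role).
#' @param stroma_factor Median multiplier for stroma nuclei (nuclear role).
#' @return A `marker_spec` list.
#' @export
marker_spec <- function(name, peak_channel, width, role, median, sigma = 0.3,
                        positive_fraction = NA_real_, negative_factor = 0.02,
                        stroma_factor = 0.5) {
  role <- match.arg(role,
                    c("counterstain", "nuclear", "epithelial", "bimodal", "immune"))
  structure(list(name = name, peak_channel = peak_channel, width = width,
                 role = role, median = median, sigma = sigma,
                 positive_fraction = positive_fraction,
                 negative_factor = negative_factor,
                 stroma_factor = stroma_factor),
            class = "marker_spec")
}

default_markers <- function() {
  list(
    marker_spec("DAPI",  1, 1.0, "counterstain", median = 20000, sigma = 0.15),
    marker_spec("RAD51", 3, 0.8, "nuclear",      median = 8000,  sigma = 0.30),
    marker_spec("EpCAM", 5, 0.8, "epithelial",   median = 6000),
    marker_spec("Ki67",  7, 0.8, "bimodal",      median = 6000,  sigma = 0.30,
                positive_fraction = 0.30),
    marker_spec("CD3",   8, 0.7, "immune",       median = 6000,  sigma = 0.30),
    marker_spec("CD8",   9, 0.7, "immune",       median = 6000,  sigma = 0.30)
  )
}

#' Configuration for the synthetic multispectral core simulator
#'
#' Defines the study conditions emulated by the generator: spectral layout,
#' core geometry, marker abundance laws, tissue-compartment geometry, camera
#' model and the random seed.
#'
#' @param n_channels Number of imaging channels.
#' @param markers List of [marker_spec()] objects (autofluorescence is added
#'   automatically as one extra broad endmember).
#' @param image_size `c(H, W)` in pixels.
#' @param n_cells Number of nuclei to place.
#' @param tumour_fraction Fraction of core area occupied by the tumour
#'   compartment, in `[0, 1]`.
#' @param nucleus_radius Nucleus disk radius (pixels, >= 1).
#' @param af_level Mean autofluorescence abundance (photons / s / pixel).
#' @param camera Camera model: `bit_depth` (8/12/16), `exposure_time`
#'   (seconds), `gain`, `binning_area`, `read_noise_sd` (counts, post-gain)
#'   and `shot_noise` (Poisson photon noise on the pre-gain signal). Setting
#'   `shot_noise = FALSE` and `read_noise_sd = 0` makes imaging exactly
#'   linear and noiseless.
#' @param scored_marker The marker scored as the nuclear expression score;
#'   defaults to `"RAD51"` when present, otherwise the first marker.
#' @param immune_phenotypes Named list; each element has `markers` (character
#'   vector of co-expressed immune markers), `freq_tumour` and `freq_stroma`
#'   (per-cell assignment probabilities by compartment).
#' @param touching_pairs Number of deliberately overlapping nucleus pairs
#'   (centre distance `2 * radius - 1`), for watershed-splitting tests; the
#'   remaining nuclei never overlap.
#' @param seed Integer master seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_channels = 10L,
                       markers = default_markers(),
                       image_size = c(192L, 192L),
                       n_cells = 240L,
                       tumour_fraction = 0.55,
                       nucleus_radius = 3L,
                       af_level = 400,
                       camera = list(bit_depth = 12L, exposure_time = 0.05,
                                     gain = 1, binning_area = 1L,
                                     read_noise_sd = 1, shot_noise = TRUE),
                       scored_marker = NULL,
                       immune_phenotypes = list(
                         T_cyt = list(markers = c("CD3", "CD8"),
                                      freq_tumour = 0.04, freq_stroma = 0.12)),
                       touching_pairs = 0L,
                       seed = 1L) {
  cam_def <- list(bit_depth = 12L, exposure_time = 0.05, gain = 1,
                  binning_area = 1L, read_noise_sd = 1, shot_noise = TRUE)
  camera <- utils::modifyList(cam_def, camera)
  if (tumour_fraction < 0 || tumour_fraction > 1)
    stopf("tumour_fraction must be in [0, 1]")
  if (nucleus_radius < 1) stopf("nucleus_radius must be >= 1")
  if (!camera$bit_depth %in% c(8L, 12L, 16L))
    stopf("bit_depth must be 8, 12 or 16")
  if (camera$exposure_time <= 0) stopf("exposure_time must be > 0")
  if (camera$gain <= 0) stopf("gain must be > 0")
  if (camera$binning_area < 1) stopf("binning_area must be >= 1")
  nm <- vapply(markers, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("duplicate marker names")
  if (is.null(scored_marker))
    scored_marker <- if ("RAD51" %in% nm) "RAD51" else nm[1]
  if (!scored_marker %in% nm) stopf("scored_marker '%s' not among markers",
                                    scored_marker)
  structure(list(n_channels = as.integer(n_channels), markers = markers,
                 image_size = as.integer(image_size),
                 n_cells = as.integer(n_cells),
                 tumour_fraction = tumour_fraction,
                 nucleus_radius = as.integer(nucleus_radius),
                 af_level = af_level, camera = camera,
                 scored_marker = scored_marker,
                 immune_phenotypes = immune_phenotypes,
                 touching_pairs = as.integer(touching_pairs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

marker_names <- function(config) vapply(config$markers, `[[`, "", "name")

#' Generate the ground-truth spectral library for a simulation
#'
#' One unit-norm Gaussian emission spectrum per marker plus a broad
#' autofluorescence endmember (wide Gaussian over the whole channel range
#' with a flat pedestal). Deterministic: no randomness enters the spectra.
#'
#' @param config A [sim_config()].
#' @return A [spectral_library()].
#' @export
generate_library <- function(config) {
  K <- length(config$markers) + 1L
  C <- config$n_channels
  if (K > C)
    stopf("unidentifiable library: %d endmembers but only %d channels", K, C)
  ch <- seq_len(C)
  spectra <- vapply(config$markers, function(m) {
    if (m$width <= 1e-12) {
      s <- numeric(C); s[round(m$peak_channel)] <- 1; s
    } else exp(-(ch - m$peak_channel)^2 / (2 * m$width^2))
  }, numeric(C))
  af <- exp(-(ch - (C + 1) / 2)^2 / (2 * C^2)) + 0.5
  spectra <- cbind(spectra, af)
  colnames(spectra) <- c(marker_names(config), "AF")
  spectral_library(spectra, af_name = "AF")
}

# Smooth random scalar field (sum of low-frequency random plane waves);
# thresholded at a quantile it yields the tumour blob mask.
smooth_field <- function(h, w, n_waves = 8L) {
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  f <- matrix(0, h, w)
  for (j in seq_len(n_waves)) {
    fr <- runif(1, 0.5, 2.5) / h
    fc <- runif(1, 0.5, 2.5) / w
    f <- f + runif(1, 0.5, 1) *
      cos(2 * pi * (fr * r + fc * c_) + runif(1, 0, 2 * pi))
  }
  f
}

disk_offsets <- function(radius) {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  d[d$dr^2 + d$dc^2 <= radius^2, ]
}

# Uniform non-overlapping placement by rejection; optionally a leading set of
# overlapping pairs at centre distance 2r - 1 for watershed tests.
place_nuclei <- function(n, h, w, radius, touching_pairs = 0L,
                         max_tries = 500L) {
  margin <- radius + 1L
  min_d2 <- (2 * radius + 2)^2
  centres <- matrix(NA_real_, n, 2)
  k <- 0L
  add_ok <- function(rc, upto) {
    if (rc[1] < margin + 1 || rc[1] > h - margin ||
        rc[2] < margin + 1 || rc[2] > w - margin) return(FALSE)
    if (upto == 0L) return(TRUE)
    d2 <- (centres[seq_len(upto), 1] - rc[1])^2 +
      (centres[seq_len(upto), 2] - rc[2])^2
    all(d2 >= min_d2)
  }
  for (p in seq_len(touching_pairs)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      a <- c(runif(1, margin + 1, h - margin), runif(1, margin + 1, w - margin))
      th <- runif(1, 0, 2 * pi)
      b <- a + (2 * radius - 1) * c(cos(th), sin(th))
      if (add_ok(a, k) && add_ok(b, k)) {
        centres[k + 1L, ] <- a; centres[k + 2L, ] <- b
        k <- k + 2L; placed <- TRUE; break
      }
    }
    if (!placed) stopf("nucleus placement failed for a touching pair")
  }
  while (k < n) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      a <- c(runif(1, margin + 1, h - margin), runif(1, margin + 1, w - margin))
      if (add_ok(a, k)) { centres[k + 1L, ] <- a; k <- k + 1L
        placed <- TRUE; break }
    }
    if (!placed)
      stopf("could not place %d nuclei of radius %d in a %d x %d image",
            n, radius, h, w)
  }
  round(centres)
}

#' Simulate one multispectral TMA core with ground truth
#'
#' Builds a smooth random tumour blob occupying `tumour_fraction` of the
#' frame, places disk nuclei, draws per-cell marker abundances from the
#' configured laws, composes the noiseless photon-rate image through the
#' spectral library, applies the camera model (Poisson shot noise on the
#' pre-gain signal, Gaussian read noise post-gain, bit-depth clipping) and
#' returns the image together with a full truth table.
#'
#' The truth table has one row per cell: `cell_id`, 0-based centre `row` /
#' `col`, `compartment` (majority of nucleus pixels inside the blob; ties go
#' to tumour), `phenotype`, and one `abund_<marker>` column per marker.
#' Attributes: `tumour_mask` (logical H x W), `true_core_mean` (mean scored
#' abundance over tumour cells), `scored_marker`.
#'
#' @param config A [sim_config()].
#' @param library The matching [spectral_library()] (see
#'   [generate_library()]).
#' @return `list(image = multispectral_image, truth = data.frame)`.
#' @export
simulate_core <- function(config, library) {
  stopifnot(inherits(config, "sim_config"), inherits(library, "spectral_library"))
  if (library$channel_count != config$n_channels)
    stopf("library has %d channels but config %d",
          library$channel_count, config$n_channels)
  nm <- marker_names(config)
  if (!all(nm %in% library$endmembers))
    stopf("library is missing marker spectra")
  with_seed(config$seed, {
    h <- config$image_size[1]; w <- config$image_size[2]
    npx <- h * w
    # tumour blob
    if (config$tumour_fraction <= 0) {
      blob <- matrix(FALSE, h, w)
    } else if (config$tumour_fraction >= 1) {
      blob <- matrix(TRUE, h, w)
    } else {
      f <- smooth_field(h, w)
      blob <- f >= quantile(f, 1 - config$tumour_fraction)
    }
    # nuclei
    centres <- place_nuclei(config$n_cells, h, w, config$nucleus_radius,
                            config$touching_pairs)
    off <- disk_offsets(config$nucleus_radius)
    pix_of_cell <- lapply(seq_len(config$n_cells), function(i) {
      rr <- centres[i, 1] + off$dr; cc <- centres[i, 2] + off$dc
      (cc - 1L) * h + rr                      # column-major linear index
    })
    in_blob_frac <- vapply(pix_of_cell, function(p) mean(blob[p]), 0)
    compartment <- ifelse(in_blob_frac >= 0.5, "tumour", "stroma")
    # immune phenotypes: at most one per cell, assigned sequentially
    phenotype <- rep("none", config$n_cells)
    for (ph in names(config$immune_phenotypes)) {
      spec <- config$immune_phenotypes[[ph]]
      pr <- ifelse(compartment == "tumour", spec$freq_tumour, spec$freq_stroma)
      hit <- phenotype == "none" & runif(config$n_cells) < pr
      phenotype[hit] <- ph
    }
    # per-cell abundances; a zero median means the marker is truly absent
    rln <- function(med, sigma) {
      out <- numeric(length(med))
      pos <- med > 0
      out[pos] <- rlnorm(sum(pos), log(med[pos]), sigma)
      out
    }
    abund <- matrix(0, config$n_cells, length(nm), dimnames = list(NULL, nm))
    for (m in config$markers) {
      a <- switch(m$role,
        counterstain = rln(rep(m$median, config$n_cells), m$sigma),
        nuclear = rln(ifelse(compartment == "tumour", m$median,
                             m$median * m$stroma_factor), m$sigma),
        epithelial = ifelse(compartment == "tumour", m$median, 0),
        bimodal = {
          pos <- compartment == "tumour" &
            runif(config$n_cells) < m$positive_fraction
          rln(ifelse(pos, m$median, m$median * m$negative_factor), m$sigma)
        },
        immune = {
          expr <- vapply(phenotype, function(p)
            p != "none" && m$name %in% config$immune_phenotypes[[p]]$markers,
            TRUE)
          ifelse(expr, rln(rep(m$median, config$n_cells), m$sigma), 0)
        })
      abund[, m$name] <- a
    }
    # compose pixel-level abundance matrix (npx x K, K = markers + AF)
    A <- matrix(0, npx, length(nm) + 1L)
    colnames(A) <- c(nm, "AF")
    roles <- vapply(config$markers, `[[`, "", "role")
    for (j in seq_along(nm)) {
      if (roles[j] == "epithelial") {
        A[as.vector(blob), j] <- config$markers[[j]]$median
      } else {
        for (i in seq_len(config$n_cells))
          A[pix_of_cell[[i]], j] <- A[pix_of_cell[[i]], j] + abund[i, j]
      }
    }
    A[, "AF"] <- config$af_level
    S <- library$spectra[, colnames(A), drop = FALSE]
    rate <- A %*% t(S)                       # photons / s per channel
    cam <- config$camera
    counts <- if (isTRUE(cam$shot_noise)) {
      matrix(rpois(length(rate), cam$exposure_time * rate),
             nrow(rate)) * cam$gain
    } else cam$gain * cam$exposure_time * rate
    if (cam$read_noise_sd > 0)
      counts <- counts + rnorm(length(counts), 0, cam$read_noise_sd)
    counts <- pmin(pmax(counts, 0), 2^cam$bit_depth - 1)
    px <- array(counts, c(h, w, config$n_channels))
    img <- multispectral_image(
      px, acquisition_meta(cam$bit_depth, cam$exposure_time, cam$gain,
                           cam$binning_area),
      channels = paste0("ch", seq_len(config$n_channels)))
    truth <- data.frame(cell_id = seq_len(config$n_cells),
                        row = centres[, 1] - 1, col = centres[, 2] - 1,
                        compartment = compartment, phenotype = phenotype,
                        stringsAsFactors = FALSE)
    for (j in nm) truth[[paste0("abund_", j)]] <- abund[, j]
    attr(truth, "tumour_mask") <- blob
    attr(truth, "scored_marker") <- config$scored_marker
    attr(truth, "true_core_mean") <-
      mean(abund[compartment == "tumour", config$scored_marker])
    list(image = img, truth = truth)
  })
}

#' Simulate reference slides for spectral library estimation
#'
#' One single-stain slide per fluorophore (that fluorophore at uniform
#' abundance plus autofluorescence) and one unstained slide (autofluorescence
#' only), imaged under the configured camera model.
#'
#' @param config A [sim_config()].
#' @param library The ground-truth [spectral_library()].
#' @param image_size Reference-slide size, default 64 x 64.
#' @return Named list of [multispectral_image()]s: one per marker plus
#'   `"unstained"`.
#' @export
simulate_reference_slides <- function(config, library,
                                      image_size = c(64L, 64L)) {
  nm <- marker_names(config)
  S <- library$spectra
  cam <- config$camera
  h <- image_size[1]; w <- image_size[2]; npx <- h * w
  make <- function(rate_vec, seed) with_seed(seed, {
    rate <- matrix(rate_vec, npx, length(rate_vec), byrow = TRUE)
    counts <- if (isTRUE(cam$shot_noise)) {
      matrix(rpois(length(rate), cam$exposure_time * rate),
             nrow(rate)) * cam$gain
    } else cam$gain * cam$exposure_time * rate
    if (cam$read_noise_sd > 0)
      counts <- counts + rnorm(length(counts), 0, cam$read_noise_sd)
    counts <- pmin(pmax(counts, 0), 2^cam$bit_depth - 1)
    multispectral_image(array(counts, c(h, w, config$n_channels)),
                        acquisition_meta(cam$bit_depth, cam$exposure_time,
                                         cam$gain, cam$binning_area))
  })
  af_rate <- config$af_level * S[, "AF"]
  out <- vector("list", length(nm) + 1L)
  names(out) <- c(nm, "unstained")
  for (k in seq_along(nm)) {
    med <- config$markers[[k]]$median
    out[[k]] <- make(med * S[, nm[k]] + af_rate, config$seed + 7919L * k)
  }
  out[["unstained"]] <- make(af_rate, config$seed + 7919L * (length(nm) + 1L))
  out
}

#' Simulate a gene-expression matrix with planted group effects
#'
#' Gaussian log-scale expression for two score strata (high = Q4, low = Q1):
#' `n_effect` genes receive a mean shift of `effect_size` standard deviations
#' in the high group; the rest are null. Used to exercise the differential
#' immune-gene stage.
#'
#' @param n_genes Total genes.
#' @param n_high,n_low Patients per stratum.
#' @param n_effect Number of true-effect genes (the first `n_effect` rows).
#' @param effect_size Shift in SD units.
#' @param seed Integer seed.
#' @return List: `expr` (genes x patients matrix), `strata` (factor of
#'   `Q4` / `Q1`), `effect_genes` (character).
#' @export
simulate_expression <- function(n_genes = 500, n_high = 30, n_low = 30,
                                n_effect = 10, effect_size = 2, seed = 1L) {
  with_seed(seed, {
    expr <- matrix(rnorm(n_genes * (n_high + n_low)), n_genes)
    rownames(expr) <- sprintf("gene%04d", seq_len(n_genes))
    if (n_effect > 0)
      expr[seq_len(n_effect), seq_len(n_high)] <-
        expr[seq_len(n_effect), seq_len(n_high)] + effect_size
    strata <- factor(rep(c("Q4", "Q1"), c(n_high, n_low)),
                     levels = c("Q1", "IQR", "Q4"))
    list(expr = expr, strata = strata,
         effect_genes = rownames(expr)[seq_len(n_effect)])
  })
}

#' Simulate a patient cohort with survival ground truth
#'
#' Patient true scores are Gaussian across patients. Event times are drawn
#' from a proportional-hazards exponential model with log-hazard linear in
#' the standardized true score; censoring times are independent exponentials
#' calibrated so that roughly `censor_rate` of subjects are censored.
#' Progression-free and overall survival are drawn from the same linear
#' predictor with different baseline hazards. Clinical covariates (age group,
#' stage, histology, grade, performance status, residual disease, HRD score)
#' are drawn independently of the score.
#'
#' @param n_patients Number of patients (>= 8).
#' @param cores_per_patient TMA cores per patient (>= 2).
#' @param beta_true Log hazard ratio per SD of true score.
#' @param baseline_hazard Baseline event rate per month (> 0) for PFS.
#' @param censor_rate Target censoring fraction in `[0, 1)`.
#' @param seed Integer master seed; per-core seeds are derived at fixed
#'   offsets.
#' @param score_mean,score_sd Gaussian parameters of the true score
#'   (abundance units, photons / s / pixel).
#' @param beta_by_hrd Optional `c(positive = ..., negative = ...)` log hazard
#'   ratios overriding `beta_true` by HRD status (for subgroup-effect
#'   simulations).
#' @param hrd_cutoff HRD positivity cut-off applied to the simulated score
#'   (default 42).
#' @param os_baseline_factor Baseline hazard multiplier for overall survival.
#' @return `list(patients = data.frame, cores = data.frame)`; `cores` carries
#'   one row per TMA core with its derived seed and the patient's true scored
#'   median, to be applied as a [sim_config()] override.
#' @export
simulate_cohort <- function(n_patients, cores_per_patient = 2L,
                            beta_true = log(2), baseline_hazard = 0.03,
                            censor_rate = 0.2, seed = 1L,
                            score_mean = 8000, score_sd = 2000,
                            beta_by_hrd = NULL, hrd_cutoff = 42,
                            os_baseline_factor = 0.6) {
  if (n_patients < 8) stopf("n_patients must be >= 8")
  if (cores_per_patient < 2) stopf("cores_per_patient must be >= 2")
  if (censor_rate < 0 || censor_rate >= 1) stopf("censor_rate must be in [0, 1)")
  if (baseline_hazard <= 0) stopf("baseline_hazard must be > 0")
  with_seed(seed, {
    n <- n_patients
    score <- pmax(rnorm(n, score_mean, score_sd), score_mean / 10)
    z <- (score - score_mean) / score_sd
    hrd_score <- pmin(pmax(rnorm(n, 32, 16), 0), 100)
    hrd_positive <- hrd_score >= hrd_cutoff
    beta <- if (is.null(beta_by_hrd)) rep(beta_true, n) else
      ifelse(hrd_positive, beta_by_hrd[["positive"]], beta_by_hrd[["negative"]])
    draw_surv <- function(h0) {
      t_event <- rexp(n, h0 * exp(beta * z))
      t_cens <- if (censor_rate == 0) rep(Inf, n) else
        rexp(n, h0 * censor_rate / (1 - censor_rate))
      list(time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens))
    }
    pfs <- draw_surv(baseline_hazard)
    os <- draw_surv(baseline_hazard * os_baseline_factor)
    age <- sample(40:82, n, replace = TRUE)
    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      true_score = score,
      true_stratum = stratify_cohort(score),
      pfs_time = pfs$time, pfs_event = pfs$event,
      os_time = os$time, os_event = os$event,
      age = age,
      age_group = ifelse(age >= 65, ">=65", "<65"),
      stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                     prob = c(0.05, 0.10, 0.60, 0.25)),
      histology = sample(c("serous", "endometrioid", "other"), n,
                         replace = TRUE, prob = c(0.8, 0.12, 0.08)),
      grade = sample(c("well", "moderate", "poor"), n, replace = TRUE,
                     prob = c(0.1, 0.3, 0.6)),
      performance_status = sample(0:2, n, replace = TRUE,
                                  prob = c(0.5, 0.35, 0.15)),
      residual_disease = sample(c("none", "<1cm", ">=1cm"), n, replace = TRUE,
                                prob = c(0.45, 0.3, 0.25)),
      hrd_score = hrd_score,
      hrd_positive = hrd_positive,
      beta_true = beta,
      stringsAsFactors = FALSE)
    idx <- seq_len(n * cores_per_patient)
    cores <- data.frame(
      patient_id = rep(patients$patient_id, each = cores_per_patient),
      core_id = sprintf("%s_C%d",
                        rep(patients$patient_id, each = cores_per_patient),
                        rep(seq_len(cores_per_patient), n)),
      seed = as.integer((as.numeric(seed) + 104729 * idx) %% 2147483647),
      scored_median = rep(score, each = cores_per_patient),
      stringsAsFactors = FALSE)
    list(patients = patients, cores = cores)
  })
}
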