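test_that("generated spectra follow the Gaussian profile and are identifiable", {
  cfg <- sim_config(n_channels = 5,
                    markers = list(
                      marker_spec("A", 2, 0.9, "nuclear", median = 100),
                      marker_spec("B", 4, 1.2, "nuclear", median = 100)),
                    seed = 1)
  lib <- generate_library(cfg)
  # hand-recomputed Gaussian profile, unit-normalized
  ch <- 1:5
  for (spec in list(c("A", 2, 0.9), c("B", 4, 1.2))) {
    g <- exp(-(ch - as.numeric(spec[2]))^2 / (2 * as.numeric(spec[3])^2))
    expect_equal(lib$spectra[, spec[1]], g / sqrt(sum(g^2)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_true(all(lib$spectra >= 0))
  expect_lt(kappa(lib$spectra), Inf)

  # delta-peak limit: width 0 concentrates on the peak channel
  cfg0 <- sim_config(n_channels = 3,
                     markers = list(marker_spec("A", 2, 0, "nuclear",
                                                median = 1)))
  expect_equal(unname(generate_library(cfg0)$spectra[, "A"]), c(0, 1, 0))

  # more endmembers than channels is unidentifiable
  cfg_bad <- sim_config(n_channels = 3,
                        markers = list(
                          marker_spec("A", 1, 0.5, "nuclear", 1),
                          marker_spec("B", 2, 0.5, "nuclear", 1),
                          marker_spec("C", 3, 0.5, "nuclear", 1)))
  expect_error(generate_library(cfg_bad), "unidentifiable")
})

test_that("simulation is deterministic for a fixed seed and config", {
  cfg <- sim_config(image_size = c(96L, 96L), n_cells = 40, seed = 7)
  lib <- generate_library(cfg)
  a <- simulate_core(cfg, lib)
  b <- simulate_core(cfg, lib)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_core(sim_config(image_size = c(96L, 96L), n_cells = 40,
                                 seed = 8), lib)
  expect_false(identical(a$image$pixels, c_$image$pixels))
})

test_that("camera model composes signal as gain * exposure * abundance * spectrum", {
  # all abundances zero, no AF, no noise: all-zero image
  dark <- lapply(default_markers(), function(m) { m$median <- 0; m })
  cfg0 <- sim_config(markers = dark, af_level = 0, image_size = c(64L, 64L),
                     n_cells = 10, camera = noiseless_camera(), seed = 2)
  lib <- generate_library(cfg0)
  sim0 <- simulate_core(cfg0, lib)
  expect_true(all(sim0$image$pixels == 0))

  # AF-only slide: every pixel equals gain * exposure * af * spectrum_AF
  cfg_af <- sim_config(markers = dark, af_level = 300,
                       image_size = c(32L, 32L), n_cells = 5,
                       camera = noiseless_camera(gain = 2), seed = 2)
  sim_af <- simulate_core(cfg_af, generate_library(cfg_af))
  expected <- 2 * 0.05 * 300 * generate_library(cfg_af)$spectra[, "AF"]
  for (ch in seq_len(cfg_af$n_channels))
    expect_equal(unique(as.vector(sim_af$image$pixels[, , ch])),
                 expected[ch], tolerance = 1e-12)

  # superposition: doubling the AF level exactly doubles the AF-only image
  cfg_af2 <- cfg_af; cfg_af2$af_level <- 600
  sim_af2 <- simulate_core(cfg_af2, generate_library(cfg_af))
  expect_equal(sim_af2$image$pixels, 2 * sim_af$image$pixels,
               tolerance = 1e-12)
})

test_that("core truth matches the requested geometry and analytic means", {
  cfg <- noiseless_config(n_cells = 200, image_size = c(224L, 224L), seed = 31)
  lib <- generate_library(cfg)
  sim <- simulate_core(cfg, lib)
  expect_equal(nrow(sim$truth), 200)
  expect_false(anyDuplicated(sim$truth$cell_id) > 0)
  expect_true(all(sim$truth$compartment %in% c("tumour", "stroma")))

  # pixel mean over an isolated stroma nucleus matches the analytic
  # expectation gain * exposure * (abundance x spectrum + AF)
  i <- which(sim$truth$compartment == "stroma")[1]
  r <- sim$truth$row[i] + 1; c_ <- sim$truth$col[i] + 1
  px <- sim$image$pixels[r, c_, ]   # centre pixel of the disk
  S <- lib$spectra
  pred <- 0.05 * (sim$truth$abund_DAPI[i] * S[, "DAPI"] +
                  sim$truth$abund_RAD51[i] * S[, "RAD51"] +
                  sim$truth$abund_Ki67[i] * S[, "Ki67"] +
                  sim$truth$abund_CD3[i] * S[, "CD3"] +
                  sim$truth$abund_CD8[i] * S[, "CD8"] +
                  cfg$af_level * S[, "AF"])
  expect_equal(unname(px), unname(pred), tolerance = 1e-10)

  # with shot noise, the nucleus mean stays within a few sd of expectation
  cfg_n <- sim_config(n_cells = 200, image_size = c(224L, 224L), seed = 31)
  reps <- vapply(1:10, function(k) {
    cfg_k <- cfg_n; cfg_k$seed <- 1000 + k
    s <- simulate_core(cfg_k, lib)
    j <- which(s$truth$compartment == "stroma")[1]
    s$image$pixels[s$truth$row[j] + 1, s$truth$col[j] + 1, 1] /
      (0.05 * (s$truth$abund_DAPI[j] * S[1, "DAPI"] +
               s$truth$abund_RAD51[j] * S[1, "RAD51"] +
               s$truth$abund_Ki67[j] * S[1, "Ki67"] +
               cfg$af_level * S[1, "AF"]))
  }, 0)
  expect_lt(abs(mean(reps) - 1), 0.05)
})

test_that("no pixel exceeds the bit-depth ceiling even for huge abundances", {
  hot <- default_markers()
  hot[[1]]$median <- 1e7
  cfg <- sim_config(markers = hot, image_size = c(48L, 48L), n_cells = 10,
                    camera = list(bit_depth = 8L), seed = 4)
  sim <- simulate_core(cfg, generate_library(cfg))
  expect_true(all(sim$image$pixels <= 255))
  expect_true(any(sim$image$pixels == 255))  # saturation actually occurs
})

test_that("impossible nucleus placement raises a placement error", {
  cfg <- sim_config(image_size = c(32L, 32L), n_cells = 100,
                    nucleus_radius = 4, seed = 1)
  expect_error(simulate_core(cfg, generate_library(cfg)), "place")
})

test_that("reference slides cover each fluorophore plus an unstained stack", {
  cfg <- noiseless_config(seed = 9)
  lib <- generate_library(cfg)
  refs <- simulate_reference_slides(cfg, lib)
  expect_length(refs, length(cfg$markers) + 1L)
  expect_named(refs, c(marker_names_of(cfg), "unstained"))

  # unstained stack is proportional to the AF spectrum in every pixel
  un <- refs$unstained
  af <- lib$spectra[, "AF"]
  for (ch in 2:cfg$n_channels)
    expect_equal(as.vector(un$pixels[, , ch] / un$pixels[, , 1]),
                 rep(af[ch] / af[1], 64 * 64), tolerance = 1e-9)

  # single-stain mean spectrum after AF subtraction is parallel to truth
  ss <- refs$RAD51
  m <- apply(ss$pixels, 3, mean) - apply(un$pixels, 3, mean)
  expect_gt(cosine_sim(m, lib$spectra[, "RAD51"]), 0.999)
})

test_that("cohort survival construction honours its parameters", {
  # censor_rate = 0: everyone has an event
  co0 <- simulate_cohort(50, censor_rate = 0, seed = 3)
  expect_true(all(co0$patients$pfs_event == 1))
  expect_true(all(co0$patients$os_event == 1))
  expect_true(all(co0$patients$pfs_time > 0))

  # parameter validation
  expect_error(simulate_cohort(4), "n_patients")
  expect_error(simulate_cohort(20, cores_per_patient = 1), "cores_per_patient")
  expect_error(simulate_cohort(20, censor_rate = 1), "censor_rate")
  expect_error(simulate_cohort(20, baseline_hazard = -1), "baseline_hazard")

  # derived per-core seeds are valid 32-bit integers, two cores per patient
  co <- simulate_cohort(20, cores_per_patient = 3, seed = 5)
  expect_equal(nrow(co$cores), 60)
  expect_true(all(co$cores$seed >= 0 & co$cores$seed < 2^31))
  expect_false(anyDuplicated(co$cores$core_id) > 0)

  # null model: log-rank p between Q4 and Q1 is approximately uniform
  pvals <- vapply(1:60, function(s) {
    co <- simulate_cohort(60, beta_true = 0, seed = 100 + s)
    d <- co$patients[co$patients$true_stratum %in% c("Q1", "Q4"), ]
    logrank_test(d$pfs_time, d$pfs_event, droplevels(d$true_stratum))$p_value
  }, 0)
  expect_gt(mean(pvals), 0.35)           # uniform mean is 0.5
  expect_lt(mean(pvals < 0.05), 0.15)    # nominal size
})

test_that("empirical hazard ratio converges to exp(beta) at large n", {
  co <- simulate_cohort(2000, beta_true = log(2), censor_rate = 0.2,
                        seed = 77)
  d <- co$patients
  z <- (d$true_score - 8000) / 2000
  fit <- survival::coxph(survival::Surv(pfs_time, pfs_event) ~ z, data = d)
  expect_lt(abs(exp(coef(fit)) - 2) / 2, 0.10)
})
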