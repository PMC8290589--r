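# Synthetic generators: references, maps with ground truth, assay plates.

test_that("simulated tracer has exactly three peaks in the band of interest", {
  refs <- make_references(map_sim_config(seed = 1))
  tr <- refs$spectra[, refs$tracked]
  w <- refs$wavenumber
  in_band <- w >= 400 & w <= 785
  is_max <- tr > c(-Inf, tr[-length(tr)]) & tr > c(tr[-1], -Inf)
  prominent <- is_max & tr > 0.05 * max(tr)
  expect_equal(sum(prominent & in_band), 3L)
})

test_that("reference validation rejects zero components and peak collisions", {
  cfg <- map_sim_config(seed = 1)
  cfg$components$lipid$amplitudes[] <- 0
  expect_error(make_references(cfg), class = "ramanpen_invalid_input")
  cfg2 <- map_sim_config(seed = 1)
  cfg2$components$scFv$peaks[1] <- 625  # within 15 cm-1 of the 622 skin peak
  expect_error(make_references(cfg2), class = "ramanpen_invalid_config")
  expect_error(map_sim_config(tracer_front_um = 200),
               class = "ramanpen_invalid_config")
})

test_that("map generation is seed-deterministic with the stated geometry", {
  cfg <- map_sim_config(seed = 42)
  a <- make_map(cfg)
  b <- make_map(cfg)
  expect_identical(a$map$intensity, b$map$intensity)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$map$intensity), 93L)  # X 10 um / Y 150 um at 5 um step
  c_ <- make_map(map_sim_config(seed = 43))
  expect_false(identical(a$map$intensity, c_$map$intensity))
  # references are deterministic too
  expect_identical(make_references(cfg)$spectra, make_references(cfg)$spectra)
})

test_that("ground-truth tracer vanishes below a sharp front", {
  sim <- make_map(map_sim_config(seed = 2, tracer_front_um = 20,
                                 front_softness_um = 0.1))
  deep <- sim$truth$y_um > 20
  expect_true(all(sim$truth$scFv[deep] < 1e-6))
  expect_true(all(sim$truth$scFv[sim$truth$y_um < 20] > 0.99))
})

test_that("designated low-signal pixels fall under the QC threshold", {
  sim <- make_map(map_sim_config(seed = 8, low_signal_pixels = 4))
  w <- sim$map$wavenumber
  sel <- w >= 1530 & w <= 1730
  forced <- sim$map$meta$low_signal_pixels
  expect_equal(nrow(forced), 4L)
  idx <- match(paste(forced$x_um, forced$y_um),
               paste(sim$map$coords$x_um, sim$map$coords$y_um))
  expect_true(all(apply(sim$map$intensity[idx, sel], 1, max) < 400))
})

test_that("noise-free, baseline-free maps round-trip through crop + normalize + NCLS", {
  cfg <- map_sim_config(seed = 6, tracer_front_um = 60,
                        baseline_coeffs = rep(0, 8), noise_sd_cts = 0)
  sim <- make_map(cfg)
  w <- sim$map$wavenumber
  sel <- w >= 400 & w <= 785
  Y <- sim$map$intensity[, sel]
  Yn <- Y / sqrt(rowSums(Y^2))
  m <- spectral_map(w[sel], Yn, sim$map$coords, step_um = 5, surface_y_um = 0)
  refs_c <- reference_set(w[sel], sim$refs$spectra[sel, ], sim$refs$names,
                          sim$refs$tracked)
  fit <- unmix(m, refs_c)
  truth <- as.matrix(sim$truth[, sim$refs$names])
  # per-pixel coefficient RATIOS equal the ground-truth abundance ratios
  got <- coef(fit)[, "scFv"] / coef(fit)[, "protein"]
  want <- truth[, "scFv"] / truth[, "protein"]
  expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)
  # full-pipeline profile shape: vector normalization rescales each pixel by
  # its spectral norm, so the exact expectation is truth/norm; against that
  # the pipeline correlates > 0.999 (the iterative baseline step is the only
  # nonlinearity left), and > 0.98 against the raw truth profile
  pre <- suppressMessages(preprocess_map(sim$map))
  fit2 <- unmix(pre, preprocess_references(sim$refs))
  prof <- depth_profile(fit2)
  nrm <- sqrt(rowSums(sim$map$intensity[, sel]^2))
  pred <- tapply(sim$truth$scFv / nrm, sim$truth$y_um, mean)
  expect_gt(cor(prof$mean_abundance, pred[as.character(prof$depth_um)]),
            0.999)
  truth_prof <- tapply(sim$truth$scFv, sim$truth$y_um, mean)
  expect_gt(cor(prof$mean_abundance, truth_prof[as.character(prof$depth_um)]),
            0.98)
})

test_that("assay simulation saturates, anchors correctly, and is deterministic", {
  # saturated limit: full neutralization at every dose
  cfg_sat <- assay_sim_config(seed = 1, residual_sd_pg = 0,
                              donor_effect_sd = 0, max_neutralization = 1,
                              half_effect_nM = 1e-6)
  plate <- make_assay(cfg_sat)
  tab <- neutralization_table(plate)
  dose_cols <- grep("nM$", names(tab))
  expect_equal(unname(as.matrix(tab[, dose_cols])),
               matrix(100, 4, 5), tolerance = 1e-6)
  # noise-free anchor equals the configured induction levels
  expect_equal(unique(plate$response[plate$condition == "hIL4_polyIC"]),
               400 + 600)
  # determinism under a fixed seed; different seeds differ
  p1 <- make_assay(assay_sim_config(seed = 11))
  p2 <- make_assay(assay_sim_config(seed = 11))
  p3 <- make_assay(assay_sim_config(seed = 12))
  expect_identical(p1, p2)
  expect_false(identical(p1$response, p3$response))
  expect_error(assay_sim_config(doses_nM = c(10, 10)),
               class = "ramanpen_invalid_config")
})

test_that("plates simulated at the published 600 nM regime cover its mean", {
  # 30 plates: the empirical spread of per-plate 600 nM means straddles 80 %
  means <- vapply(1:30, function(s) {
    tab <- neutralization_table(make_assay(assay_sim_config(seed = s)))
    mean(tab[["600 nM"]])
  }, numeric(1))
  q <- quantile(means, c(0.025, 0.975))
  expect_lt(q[1], 80)
  expect_gt(q[2], 80)
})
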