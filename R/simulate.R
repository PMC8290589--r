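# Seed-deterministic synthetic generators: reference spectra, hyperspectral
# skin maps with known ground truth, donor-structured assay plates.

default_components <- function() {
  list(
    protein = list(
      peaks = c(622, 643, 755, 855, 1003, 1450, 1655),
      widths = c(9, 9, 10, 11, 8, 16, 20),
      amplitudes = c(160, 140, 200, 180, 300, 380, 700)),
    lipid = list(
      peaks = c(717, 1080, 1130, 1300, 1440, 1745),
      widths = c(9, 12, 12, 14, 14, 12),
      amplitudes = c(120, 150, 130, 220, 320, 160)),
    scFv = list(
      peaks = c(460, 540, 685),
      widths = c(8, 8, 9),
      amplitudes = c(500, 380, 450))
  )
}

#' Configuration of the hyperspectral map simulator
#'
#' Describes the simulated acquisition and specimen: the spectral axis, the
#' map grid, the component peak models, the tracer penetration front, the
#' fluorescence-like baseline, and the noise.
#'
#' @param seed integer; fixes all randomness of the generators
#' @param axis_range spectral range in cm^-1 (default c(400, 2300))
#' @param channel_spacing_cm1 channel spacing (default 4 cm^-1)
#' @param x_extent_um,y_extent_um map extents (default 10 x 150 um)
#' @param step_um grid step (default 5 um)
#' @param components named list of peak models, each
#'   `list(peaks, widths, amplitudes)` in cm^-1 / cm^-1 / cts; the last
#'   entry plays the tracked tracer unless `tracer` says otherwise.  The
#'   tracer must have exactly three peaks inside 400-785 cm^-1.
#' @param tracer name of the tracked component (default `"scFv"`)
#' @param tracer_front_um true penetration depth: centre of the logistic
#'   abundance front (default 130 um); must lie within \[0, y_extent_um\]
#' @param front_softness_um logistic transition width (default 2 um, a
#'   near-step diffusion front)
#' @param tracer_level tracer abundance above the front (default 1.0,
#'   relative to the skin component weights — the tracer signature is
#'   clearly visible in treated regions)
#' @param baseline_coeffs `"random"` (degree-7 coefficients redrawn per
#'   pixel) or a numeric vector of `baseline_degree + 1` coefficients on
#'   the axis scaled to \[-1, 1\] (all zero disables the baseline)
#' @param baseline_scale_range range of per-pixel baseline magnitudes in
#'   cts (default c(1200, 3000), i.e. roughly 2-5x the strongest peak, so
#'   fluorescence dominates the raw signal as it does in skin)
#' @param noise_sd_cts additive Gaussian noise level (default 3 cts,
#'   i.e. well-averaged confocal acquisitions with strong peaks around
#'   500-700 cts)
#' @param low_signal_pixels how many pixels to force under the QC
#'   threshold (count, default 0), or a data.frame of `x_um`, `y_um`
#' @param min_peak_separation_cm1 minimum distance between tracer and skin
#'   peaks (default 15 cm^-1)
#' @return an object of class `map_sim_config`
#' @export
map_sim_config <- function(seed = 1L,
                           axis_range = c(400, 2300),
                           channel_spacing_cm1 = 4,
                           x_extent_um = 10, y_extent_um = 150,
                           step_um = 5,
                           components = default_components(),
                           tracer = "scFv",
                           tracer_front_um = 130,
                           front_softness_um = 2,
                           tracer_level = 1.0,
                           baseline_coeffs = "random",
                           baseline_scale_range = c(1200, 3000),
                           noise_sd_cts = 3,
                           low_signal_pixels = 0,
                           min_peak_separation_cm1 = 15) {
  if (!is_count(seed)) stop_invalid_config("seed must be an integer")
  if (length(axis_range) != 2 || axis_range[1] >= axis_range[2])
    stop_invalid_config("axis_range must be (low, high)")
  if (channel_spacing_cm1 <= 0) stop_invalid_config("channel spacing must be > 0")
  if (x_extent_um < 0 || y_extent_um <= 0 || step_um <= 0)
    stop_invalid_config("grid extents and step must be positive")
  if (!is.list(components) || is.null(names(components)) ||
      length(components) < 2)
    stop_invalid_config("components must be a named list of >= 2 peak models")
  if (!tracer %in% names(components))
    stop_invalid_config(sprintf("tracer '%s' not among components", tracer))
  if (tracer_front_um < 0 || tracer_front_um > y_extent_um)
    stop_invalid_config("tracer_front_um must lie within [0, y_extent_um]")
  if (front_softness_um <= 0) stop_invalid_config("front_softness_um must be > 0")
  if (is.character(baseline_coeffs) && !identical(baseline_coeffs, "random"))
    stop_invalid_config("baseline_coeffs must be 'random' or numeric")
  if (noise_sd_cts < 0) stop_invalid_config("noise_sd_cts must be >= 0")
  structure(
    list(seed = as.integer(seed), axis_range = as.numeric(axis_range),
         channel_spacing_cm1 = channel_spacing_cm1,
         x_extent_um = x_extent_um, y_extent_um = y_extent_um,
         step_um = step_um, components = components, tracer = tracer,
         tracer_front_um = tracer_front_um,
         front_softness_um = front_softness_um,
         tracer_level = tracer_level,
         baseline_coeffs = baseline_coeffs,
         baseline_scale_range = as.numeric(baseline_scale_range),
         noise_sd_cts = noise_sd_cts,
         low_signal_pixels = low_signal_pixels,
         min_peak_separation_cm1 = min_peak_separation_cm1),
    class = "map_sim_config"
  )
}

sim_axis <- function(cfg) {
  seq(cfg$axis_range[1], cfg$axis_range[2], by = cfg$channel_spacing_cm1)
}

gaussian_peaks <- function(w, peaks, widths, amplitudes) {
  y <- numeric(length(w))
  for (k in seq_along(peaks))
    y <- y + amplitudes[k] * exp(-0.5 * ((w - peaks[k]) / widths[k])^2)
  y
}

#' Simulate a reference-spectrum library
#'
#' Builds each component as a Gaussian-peak mixture on the full axis.  The
#' tracer must carry exactly three peaks inside the 400-785 cm^-1 band of
#' interest, all separated from every skin-component peak by at least
#' `min_peak_separation_cm1`; violations are configuration errors.
#' Deterministic: no randomness is consumed.
#'
#' @param cfg a [map_sim_config()]
#' @return a [reference_set()] with the tracer flagged as tracked
#' @export
make_references <- function(cfg) {
  if (!inherits(cfg, "map_sim_config")) stop_invalid_config("not a map_sim_config")
  w <- sim_axis(cfg)
  comp <- cfg$components
  for (nm in names(comp)) {
    pm <- comp[[nm]]
    if (length(pm$peaks) != length(pm$widths) ||
        length(pm$peaks) != length(pm$amplitudes))
      stop_invalid_config(sprintf("component '%s': peaks/widths/amplitudes lengths differ", nm))
    if (all(pm$amplitudes == 0))
      stop_invalid_input(sprintf("zero-amplitude component '%s'", nm))
  }
  tr <- comp[[cfg$tracer]]
  in_band <- tr$peaks >= 400 & tr$peaks <= 785
  if (sum(in_band) != 3L)
    stop_invalid_config("tracer must have exactly three peaks in 400-785 cm-1")
  skin_peaks <- unlist(lapply(comp[setdiff(names(comp), cfg$tracer)],
                              `[[`, "peaks"))
  sep <- outer(tr$peaks, skin_peaks, function(a, b) abs(a - b))
  if (any(sep < cfg$min_peak_separation_cm1))
    stop_invalid_config(sprintf(
      "tracer peaks within %g cm-1 of a skin peak", cfg$min_peak_separation_cm1))
  spectra <- vapply(comp, function(pm)
    gaussian_peaks(w, pm$peaks, pm$widths, pm$amplitudes),
    numeric(length(w)))
  reference_set(w, spectra, names(comp), tracked = cfg$tracer)
}

# three synthetic depth zones with distinct skin-component weights
# (stratum-corneum-like 0-20 um, epidermis-like 20-60 um, dermis-like > 60)
zone_weights <- function(depth, component) {
  zone <- ifelse(depth <= 20, 1L, ifelse(depth <= 60, 2L, 3L))
  w <- switch(component,
              protein = c(1.0, 0.85, 0.8),  # dermis stays collagen-rich
              lipid = c(0.65, 0.35, 0.18),
              c(0.8, 0.8, 0.8))
  w[zone]
}

#' Simulate a hyperspectral skin map with known ground truth
#'
#' Per pixel, true component abundances are a layered skin profile plus a
#' tracer weight following a logistic front in depth (centred at
#' `tracer_front_um`, width `front_softness_um`); the recorded spectrum is
#' the corresponding reference mixture plus a degree-7 polynomial
#' fluorescence-like baseline and additive Gaussian shot-like noise.
#' Designated low-signal pixels are attenuated below the QC threshold.
#' Fully deterministic under `cfg$seed`.
#'
#' @param cfg a [map_sim_config()]
#' @param refs the [make_references()] output for `cfg`
#' @return list with `map` (the noisy `spectral_map`), `truth` (data.frame
#'   `x_um`, `y_um`, one abundance column per component — noise-free ground
#'   truth) and `refs`
#' @export
make_map <- function(cfg, refs = make_references(cfg)) {
  if (!inherits(cfg, "map_sim_config")) stop_invalid_config("not a map_sim_config")
  if (!inherits(refs, "reference_set")) stop_invalid_input("not a reference_set")
  w <- sim_axis(cfg)
  if (!same_axis(w, refs$wavenumber))
    stop_invalid_input("reference axis does not match the configured axis")
  xs <- seq(0, cfg$x_extent_um, by = cfg$step_um)
  ys <- seq(0, cfg$y_extent_um, by = cfg$step_um)
  coords <- expand.grid(x_um = xs, y_um = ys, KEEP.OUT.ATTRS = FALSE)
  np <- nrow(coords)
  k <- length(refs$names)
  depth <- coords$y_um  # surface at y = 0 in the simulator frame

  truth <- matrix(0, np, k, dimnames = list(NULL, refs$names))
  for (nm in setdiff(refs$names, cfg$tracer))
    truth[, nm] <- zone_weights(depth, nm)
  truth[, cfg$tracer] <- cfg$tracer_level /
    (1 + exp((depth - cfg$tracer_front_um) / cfg$front_softness_um))

  n_chan <- length(w)
  t_ax <- 2 * (w - min(w)) / diff(range(w)) - 1
  V <- outer(t_ax, 0:7, `^`)

  with_seed(cfg$seed, {
    Y <- truth %*% t(refs$spectra)
    if (identical(cfg$baseline_coeffs, "random")) {
      for (i in seq_len(np)) {
        b <- as.numeric(V %*% stats::runif(8, -1, 1))
        rng <- diff(range(b))
        if (rng > 0) b <- (b - min(b)) / rng
        scale <- stats::runif(1, cfg$baseline_scale_range[1],
                              cfg$baseline_scale_range[2])
        Y[i, ] <- Y[i, ] + scale * b
      }
    } else {
      cb <- as.numeric(cfg$baseline_coeffs)
      if (length(cb) != 8)
        stop_invalid_config("baseline_coeffs must have 8 entries (degree 7)")
      b <- as.numeric(V %*% cb)
      Y <- sweep(Y, 2, b, `+`)
    }
    if (cfg$noise_sd_cts > 0)
      Y <- Y + matrix(stats::rnorm(np * n_chan, 0, cfg$noise_sd_cts),
                      np, n_chan)
    # force designated pixels under the QC threshold
    low <- cfg$low_signal_pixels
    low_idx <- integer(0)
    if (is.data.frame(low)) {
      low_idx <- which(paste(coords$x_um, coords$y_um) %in%
                         paste(low$x_um, low$y_um))
    } else if (is.numeric(low) && low > 0) {
      low_idx <- sample(np, min(np, as.integer(low)))
    }
    if (length(low_idx)) {
      sel <- w >= 1530 & w <= 1730
      for (i in low_idx) {
        bm <- max(Y[i, sel])
        if (bm > 0) Y[i, ] <- Y[i, ] * (200 / bm)  # well under 400 cts
      }
    }
    map <- spectral_map(w, Y, coords, step_um = cfg$step_um,
                        surface_y_um = 0,
                        meta = list(seed = cfg$seed,
                                    low_signal_pixels = coords[low_idx, ,
                                                               drop = FALSE]))
    list(map = map,
         truth = data.frame(coords, truth, check.names = FALSE),
         refs = refs)
  })
}

#' Condition a reference library for unmixing
#'
#' Applies the spectral conditioning stages to every reference component so
#' the library matches preprocessed pixels: Savitzky-Golay smoothing,
#' baseline correction, cropping to the band of interest, and optional
#' unit-norm scaling.  Running the references through the identical chain
#' matters: the iterative baseline fit subtracts a small "under-envelope"
#' from every corrected pixel, and references that skipped that step
#' mismatch systematically, leaking spurious abundance onto minor
#' components.
#'
#' @param refs a [reference_set()]
#' @param cfg a [preprocess_config()]
#' @param baseline correct each reference's baseline exactly as map pixels
#'   are corrected (default TRUE; disable only for already-corrected
#'   libraries)
#' @param normalize scale each reference to unit norm (default FALSE; keeps
#'   coefficients on the library's own intensity scale)
#' @return the conditioned [reference_set()]
#' @export
preprocess_references <- function(refs, cfg = preprocess_config(),
                                  baseline = TRUE, normalize = FALSE) {
  if (!inherits(refs, "reference_set")) stop_invalid_input("not a reference_set")
  cfg <- as_preprocess_config(cfg)
  cols <- lapply(seq_along(refs$names), function(j) {
    s <- raman_spectrum(refs$wavenumber, refs$spectra[, j])
    s <- smooth_savitzky_golay(s, cfg)
    if (baseline) s <- correct_baseline(s, cfg)
    s <- crop(s, cfg)
    if (normalize) s <- vector_normalize(s)
    s
  })
  reference_set(cols[[1]]$wavenumber,
                vapply(cols, `[[`, numeric(length(cols[[1]]$wavenumber)),
                       "intensity"),
                refs$names, refs$tracked)
}

#' Configuration of the assay-plate simulator
#'
#' Emulates the donor-structured neutralization study: keratinocytes from
#' several donors stimulated with poly I:C with or without hIL-4 and
#' treated with an scFv dose series.  IL-8-like responses follow a
#' monotone saturating inhibition curve plus a per-donor random effect and
#' residual noise.  Defaults describe a world resembling the published
#' four-donor study (strong donor heterogeneity, ~80 percent mean
#' neutralization at the top 600 nM dose).
#'
#' @param seed integer seed
#' @param n_donors number of donors (default 4)
#' @param doses_nM scFv doses (default 10, 100, 200, 400, 600 nM)
#' @param max_neutralization asymptotic neutralized fraction (default 0.95)
#' @param half_effect_nM dose of half-maximal neutralization (default 120)
#' @param hill Hill coefficient of the inhibition curve (default 1)
#' @param donor_effect_sd SD of the per-donor additive shift on the
#'   neutralized fraction (default 0.35 — donors differ strongly)
#' @param residual_sd_pg residual well noise on the response scale
#'   (default 30 pg/ml)
#' @param polyIC_induction response under poly I:C alone (default 400)
#' @param hIL4_potentiation additional response added by hIL-4 (default 600)
#' @param untreated_level background response (default 50)
#' @param protein_mean_ug,protein_sd_ug total protein per well (default
#'   50 +/- 5 ug)
#' @return an object of class `assay_sim_config`
#' @export
assay_sim_config <- function(seed = 1L, n_donors = 4,
                             doses_nM = c(10, 100, 200, 400, 600),
                             max_neutralization = 0.95,
                             half_effect_nM = 120, hill = 1,
                             donor_effect_sd = 0.35,
                             residual_sd_pg = 30,
                             polyIC_induction = 400,
                             hIL4_potentiation = 600,
                             untreated_level = 50,
                             protein_mean_ug = 50, protein_sd_ug = 5) {
  if (!is_count(seed)) stop_invalid_config("seed must be an integer")
  if (!is_count(n_donors) || n_donors < 1)
    stop_invalid_config("n_donors must be a positive integer")
  if (any(doses_nM <= 0) || is.unsorted(doses_nM, strictly = TRUE))
    stop_invalid_config("doses must be positive and strictly increasing")
  if (max_neutralization < 0 || half_effect_nM <= 0 || hill <= 0)
    stop_invalid_config("invalid inhibition-curve parameters")
  if (donor_effect_sd < 0 || residual_sd_pg < 0)
    stop_invalid_config("noise SDs must be >= 0")
  if (hIL4_potentiation <= 0)
    stop_invalid_config("hIL4_potentiation must be positive")
  structure(as.list(environment()), class = "assay_sim_config")
}

#' Simulate a donor-structured neutralization assay plate
#'
#' Per donor, draws anchor conditions (`untreated`, `polyIC`,
#' `hIL4_polyIC`) and the scFv dose series from the configured inhibition
#' curve: the neutralized fraction at dose d is
#' `max_neutralization * d^hill / (d^hill + half_effect_nM^hill)` plus the
#' donor's random shift, and the response is the hIL-4 potentiation scaled
#' down by that fraction, plus residual noise (responses floored at 0).
#' Deterministic under `cfg$seed`.
#'
#' @param cfg an [assay_sim_config()]
#' @return data.frame with columns `donor`, `condition`, `dose_nM`,
#'   `response`, `total_protein_ug`
#' @export
make_assay <- function(cfg) {
  if (!inherits(cfg, "assay_sim_config")) stop_invalid_config("not an assay_sim_config")
  with_seed(cfg$seed, {
    rows <- list()
    for (i in seq_len(cfg$n_donors)) {
      donor <- sprintf("D%d", i)
      shift <- stats::rnorm(1, 0, cfg$donor_effect_sd)
      r100 <- cfg$polyIC_induction
      r0 <- cfg$polyIC_induction + cfg$hIL4_potentiation
      neut <- cfg$max_neutralization * cfg$doses_nM^cfg$hill /
        (cfg$doses_nM^cfg$hill + cfg$half_effect_nM^cfg$hill) + shift
      resp <- c(cfg$untreated_level, r100, r0,
                r0 - neut * cfg$hIL4_potentiation)
      noise <- stats::rnorm(length(resp), 0, cfg$residual_sd_pg)
      protein <- pmax(1, stats::rnorm(length(resp), cfg$protein_mean_ug,
                                      cfg$protein_sd_ug))
      rows[[i]] <- data.frame(
        donor = donor,
        condition = c("untreated", "polyIC", "hIL4_polyIC",
                      rep("scFv_dose", length(cfg$doses_nM))),
        dose_nM = c(0, 0, 0, cfg$doses_nM),
        response = pmax(0, resp + noise),
        total_protein_ug = protein)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
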