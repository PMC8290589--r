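#' Preprocessing configuration
#'
#' Bundles the parameters of the five-stage spectral preprocessing pipeline:
#' Savitzky-Golay smoothing, polynomial baseline correction, low-signal
#' quality filtering, cropping to the band of interest, and vector
#' normalization.
#'
#' @param sg_window Savitzky-Golay window length in points; odd and larger
#'   than `sg_order`.  Default 11, a common spectroscopy choice that
#'   preserves peaks a few channels wide.
#' @param sg_order Savitzky-Golay polynomial order (default 2).
#' @param baseline_degree degree of the baseline polynomial (default 7).
#' @param qc_band wavenumber band (cm^-1) inspected by the quality filter
#'   (default c(1530, 1730), the amide I / C=C region).
#' @param qc_threshold minimum band-maximum intensity in counts for a pixel
#'   to be retained (default 400 cts); pixels strictly under it are
#'   suppressed.
#' @param crop_band wavenumber band retained after cropping, inclusive at
#'   both ends (default c(400, 785)).
#' @param baseline_tol relative-change convergence tolerance of the
#'   iterative baseline fit (default 1e-4).
#' @param baseline_max_iter iteration cap of the baseline fit (default 100).
#' @return an object of class `preprocess_config`
#' @export
preprocess_config <- function(sg_window = 11, sg_order = 2,
                              baseline_degree = 7,
                              qc_band = c(1530, 1730), qc_threshold = 400,
                              crop_band = c(400, 785),
                              baseline_tol = 1e-4, baseline_max_iter = 100) {
  if (!is_count(sg_window) || sg_window %% 2 == 0)
    stop_invalid_config("sg_window must be an odd integer")
  if (!is_count(sg_order) || sg_order < 0)
    stop_invalid_config("sg_order must be a nonnegative integer")
  if (sg_window <= sg_order)
    stop_invalid_config("sg_window must exceed sg_order")
  if (!is_count(baseline_degree) || baseline_degree < 1)
    stop_invalid_config("baseline_degree must be a positive integer")
  for (band in list(qc_band = qc_band, crop_band = crop_band)) {
    if (length(band) != 2 || any(!is.finite(band)) || band[1] >= band[2])
      stop_invalid_config("bands must be (low, high) with low < high")
  }
  if (!is.numeric(qc_threshold) || qc_threshold < 0)
    stop_invalid_config("qc_threshold must be >= 0")
  if (!is.numeric(baseline_tol) || baseline_tol <= 0)
    stop_invalid_config("baseline_tol must be positive")
  if (!is_count(baseline_max_iter) || baseline_max_iter < 1)
    stop_invalid_config("baseline_max_iter must be a positive integer")
  structure(
    list(sg_window = as.integer(sg_window), sg_order = as.integer(sg_order),
         baseline_degree = as.integer(baseline_degree),
         qc_band = as.numeric(qc_band),
         qc_threshold = as.numeric(qc_threshold),
         crop_band = as.numeric(crop_band),
         baseline_tol = baseline_tol,
         baseline_max_iter = as.integer(baseline_max_iter)),
    class = "preprocess_config"
  )
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat("<preprocess_config>\n")
  cat(sprintf("  Savitzky-Golay: order %d, window %d points\n",
              x$sg_order, x$sg_window))
  cat(sprintf("  baseline: degree-%d iterative polynomial (tol %g, max %d iter)\n",
              x$baseline_degree, x$baseline_tol, x$baseline_max_iter))
  cat(sprintf("  QC: band max in %g-%g cm-1 must be >= %g cts\n",
              x$qc_band[1], x$qc_band[2], x$qc_threshold))
  cat(sprintf("  crop: %g-%g cm-1 (inclusive), then unit Euclidean norm\n",
              x$crop_band[1], x$crop_band[2]))
  invisible(x)
}

as_preprocess_config <- function(cfg) {
  if (inherits(cfg, "preprocess_config")) return(cfg)
  if (is.list(cfg)) return(do.call(preprocess_config, cfg))
  stop_invalid_config("cfg must be a preprocess_config or a named list")
}

# Savitzky-Golay smoothing matrix S (n x n) for a given axis: row i holds the
# weights of the local least-squares polynomial fit, evaluated at point i.
# Interior points use the full centred window; edge points shrink the window
# to what fits inside the axis (no padding, so no invented data).  Fits are
# done in the actual wavenumber variable, so polynomials of degree <=
# sg_order are reproduced exactly even on unevenly spaced axes.
sg_matrix <- function(w, window, order) {
  n <- length(w)
  if (window > n)
    stop_invalid_config("sg_window longer than the spectrum")
  h <- (window - 1L) %/% 2L
  S <- matrix(0, n, n)
  uniform <- n > 1 && diff(range(diff(w))) < 1e-9 * mean(diff(w))
  interior_row <- NULL
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    if (uniform && lo == i - h && hi == i + h) {
      if (is.null(interior_row)) {
        X <- outer(w[lo:hi] - w[i], 0:order, `^`)
        interior_row <- solve(crossprod(X), t(X))[1L, ]
      }
      S[i, lo:hi] <- interior_row
    } else {
      J <- lo:hi
      ord <- min(order, length(J) - 1L)
      X <- outer(w[J] - w[i], 0:ord, `^`)
      S[i, J] <- solve(crossprod(X), t(X))[1L, ]
    }
  }
  S
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Replaces each intensity by the value of a local least-squares polynomial
#' of order `cfg$sg_order` fitted over `cfg$sg_window` points.  At the
#' spectrum ends the window shrinks to what is available (shrink-fit; no
#' padding).  Polynomials of degree up to `sg_order` are reproduced exactly.
#'
#' @param s a `raman_spectrum`
#' @param cfg a [preprocess_config()]
#' @return a smoothed `raman_spectrum` on the same axis
#' @examples
#' w <- seq(400, 785, by = 5)
#' s <- raman_spectrum(w, 3 * w^2 - w + 5)
#' sm <- smooth_savitzky_golay(s, preprocess_config())
#' max(abs(sm$intensity - s$intensity))  # quadratic is a fixed point
#' @export
smooth_savitzky_golay <- function(s, cfg = preprocess_config()) {
  if (!inherits(s, "raman_spectrum")) stop_invalid_input("not a raman_spectrum")
  cfg <- as_preprocess_config(cfg)
  S <- sg_matrix(s$wavenumber, cfg$sg_window, cfg$sg_order)
  raman_spectrum(s$wavenumber, as.numeric(S %*% s$intensity), meta = s$meta)
}

# Orthonormal polynomial basis (degree `degree`) on a scaled axis; Q has
# orthonormal columns so a least-squares fit is Q %*% (t(Q) %*% y).
poly_basis <- function(w, degree) {
  t <- if (diff(range(w)) > 0) 2 * (w - min(w)) / diff(range(w)) - 1 else w * 0
  V <- outer(t, 0:degree, `^`)
  qr.Q(qr(V))
}

# Iterative modified-polynomial baseline (modpoly): fit a degree-d
# polynomial, clip the working spectrum to min(spectrum, fit), refit; stop
# when the fit changes by less than `tol` relative to the input range.
modpoly_baseline <- function(y, Q, tol, max_iter) {
  scale <- max(diff(range(y)), .Machine$double.eps)
  work <- y
  fit <- as.numeric(Q %*% crossprod(Q, work))
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    work <- pmin(work, fit)
    new_fit <- as.numeric(Q %*% crossprod(Q, work))
    if (max(abs(new_fit - fit)) / scale < tol) {
      fit <- new_fit
      converged <- TRUE
      break
    }
    fit <- new_fit
  }
  list(baseline = fit, converged = converged)
}

#' Polynomial baseline correction of a spectrum
#'
#' Estimates a fluorescence-like background as a polynomial of degree
#' `cfg$baseline_degree` using iterative peak-excluding refitting (fit, clip
#' the spectrum to the pointwise minimum of spectrum and fit, refit) and
#' subtracts it.  Plain one-shot least squares would pull the baseline up
#' into the Raman peaks; the iterative clip is standard practice.
#'
#' @param s a `raman_spectrum`, longer than `baseline_degree + 1` channels
#' @param cfg a [preprocess_config()]
#' @return the corrected `raman_spectrum`; `meta$baseline_coefficients`
#'   holds the fitted polynomial coefficients (increasing powers of the
#'   axis scaled to \[-1, 1\]) and `meta$baseline_converged` the
#'   convergence flag.  Non-convergence raises a warning and returns the
#'   last iterate.
#' @export
correct_baseline <- function(s, cfg = preprocess_config()) {
  if (!inherits(s, "raman_spectrum")) stop_invalid_input("not a raman_spectrum")
  cfg <- as_preprocess_config(cfg)
  n <- length(s$wavenumber)
  if (n <= cfg$baseline_degree + 1)
    stop_invalid_input("spectrum too short for the baseline degree")
  Q <- poly_basis(s$wavenumber, cfg$baseline_degree)
  res <- modpoly_baseline(s$intensity, Q, cfg$baseline_tol, cfg$baseline_max_iter)
  if (!res$converged)
    warning("baseline fit did not converge; returning last iterate",
            call. = FALSE)
  # report coefficients in the scaled monomial basis for interpretability
  t_ax <- 2 * (s$wavenumber - min(s$wavenumber)) / diff(range(s$wavenumber)) - 1
  V <- outer(t_ax, 0:cfg$baseline_degree, `^`)
  coefs <- qr.coef(qr(V), res$baseline)
  meta <- s$meta
  meta$baseline_coefficients <- as.numeric(coefs)
  meta$baseline_converged <- res$converged
  raman_spectrum(s$wavenumber, s$intensity - res$baseline, meta = meta)
}

# per-pixel maximum intensity inside a wavenumber band
band_max <- function(wavenumber, intensity, band) {
  sel <- wavenumber >= band[1] & wavenumber <= band[2]
  if (!any(sel)) return(NULL)
  apply(intensity[, sel, drop = FALSE], 1, max)
}

#' Suppress low-signal pixels of a map
#'
#' Retains only pixels whose maximum intensity inside `cfg$qc_band` reaches
#' `cfg$qc_threshold` counts; pixels strictly under the threshold are
#' suppressed (so a band maximum of 399 cts is dropped and exactly 400 cts
#' is kept at the defaults).  If the map has already been cropped away from
#' the QC band, the band maxima cached in `meta$qc_band_max` by a previous
#' pass are reused, which makes the composed pipeline idempotent.
#'
#' @param m a `spectral_map`
#' @param cfg a [preprocess_config()]
#' @return the filtered `spectral_map`; suppressed pixel coordinates are
#'   reported via `message()` and recorded in `meta$qc_removed`,
#'   and the band maxima of the retained pixels are cached in
#'   `meta$qc_band_max`.
#' @export
filter_low_signal <- function(m, cfg = preprocess_config()) {
  if (!inherits(m, "spectral_map")) stop_invalid_input("not a spectral_map")
  cfg <- as_preprocess_config(cfg)
  vals <- band_max(m$wavenumber, m$intensity, cfg$qc_band)
  if (is.null(vals)) {
    if (!is.null(m$meta$qc_band_max) &&
        length(m$meta$qc_band_max) == nrow(m$intensity)) {
      vals <- m$meta$qc_band_max
    } else {
      stop_invalid_config("qc_band lies outside the spectral axis")
    }
  }
  keep <- vals >= cfg$qc_threshold
  removed <- m$coords[!keep, , drop = FALSE]
  if (nrow(removed))
    message(sprintf("filter_low_signal: suppressed %d pixel(s): %s",
                    nrow(removed),
                    paste(sprintf("(%g, %g)", removed$x_um, removed$y_um),
                          collapse = " ")))
  meta <- m$meta
  meta$qc_band_max <- vals[keep]
  meta$qc_removed <- removed
  spectral_map(m$wavenumber, m$intensity[keep, , drop = FALSE],
               m$coords[keep, , drop = FALSE],
               step_um = m$step_um, surface_y_um = m$surface_y_um, meta = meta)
}

#' Crop a spectrum to a wavenumber band
#'
#' Keeps the channels with `crop_band[1] <= w <= crop_band[2]`, both bounds
#' inclusive.
#'
#' @param s a `raman_spectrum`
#' @param cfg a [preprocess_config()]
#' @return the cropped `raman_spectrum`
#' @export
crop <- function(s, cfg = preprocess_config()) {
  if (!inherits(s, "raman_spectrum")) stop_invalid_input("not a raman_spectrum")
  cfg <- as_preprocess_config(cfg)
  sel <- s$wavenumber >= cfg$crop_band[1] & s$wavenumber <= cfg$crop_band[2]
  if (!any(sel))
    stop_invalid_input("crop_band does not intersect the spectral axis")
  raman_spectrum(s$wavenumber[sel], s$intensity[sel], meta = s$meta)
}

#' Scale a spectrum to unit Euclidean norm
#'
#' @param s a `raman_spectrum` with at least one nonzero intensity
#' @return the normalized `raman_spectrum` (Euclidean norm 1)
#' @export
vector_normalize <- function(s) {
  if (!inherits(s, "raman_spectrum")) stop_invalid_input("not a raman_spectrum")
  nrm <- sqrt(sum(s$intensity^2))
  if (nrm == 0)
    stop_degenerate("cannot vector-normalize an all-zero spectrum")
  raman_spectrum(s$wavenumber, s$intensity / nrm, meta = s$meta)
}

#' Run the full preprocessing pipeline on a hyperspectral map
#'
#' Applies, in order: Savitzky-Golay smoothing, iterative polynomial
#' baseline correction, low-signal pixel suppression (evaluated on the
#' corrected, pre-crop signal in the QC band), cropping to the band of
#' interest, and per-pixel vector normalization.  The order matters: QC is
#' judged before cropping (the QC band lies outside the retained band), and
#' normalization comes last so unmixing coefficients are comparable across
#' pixels.
#'
#' @param m a `spectral_map`
#' @param cfg a [preprocess_config()]
#' @return the preprocessed `spectral_map`.  `meta$stage_pixels` records the
#'   pixel count after each stage, `meta$qc_band_max` the cached QC band
#'   maxima (used to keep a second pass idempotent), and
#'   `meta$baseline_converged` the per-pixel convergence flags.
#' @export
preprocess_map <- function(m, cfg = preprocess_config()) {
  if (!inherits(m, "spectral_map")) stop_invalid_input("not a spectral_map")
  cfg <- as_preprocess_config(cfg)
  n0 <- nrow(m$intensity)
  if (n0 == 0) stop_invalid_input("empty map")

  # smoothing: one matrix multiply for all pixels
  S <- sg_matrix(m$wavenumber, cfg$sg_window, cfg$sg_order)
  Y <- m$intensity %*% t(S)

  # baseline correction, shared orthonormal basis across pixels
  if (length(m$wavenumber) <= cfg$baseline_degree + 1)
    stop_invalid_input("spectrum too short for the baseline degree")
  Q <- poly_basis(m$wavenumber, cfg$baseline_degree)
  converged <- logical(n0)
  for (i in seq_len(n0)) {
    res <- modpoly_baseline(Y[i, ], Q, cfg$baseline_tol, cfg$baseline_max_iter)
    Y[i, ] <- Y[i, ] - res$baseline
    converged[i] <- res$converged
  }
  if (!all(converged))
    warning(sprintf("baseline fit did not converge for %d pixel(s)",
                    sum(!converged)), call. = FALSE)

  meta <- m$meta
  meta$baseline_converged <- converged
  corrected <- spectral_map(m$wavenumber, Y, m$coords, step_um = m$step_um,
                            surface_y_um = m$surface_y_um, meta = meta)

  filtered <- filter_low_signal(corrected, cfg)
  n_kept <- nrow(filtered$intensity)

  sel <- filtered$wavenumber >= cfg$crop_band[1] &
    filtered$wavenumber <= cfg$crop_band[2]
  if (!any(sel))
    stop_invalid_input("crop_band does not intersect the spectral axis")
  Yc <- filtered$intensity[, sel, drop = FALSE]

  nrm <- sqrt(rowSums(Yc^2))
  if (any(nrm == 0))
    stop_degenerate("all-zero spectrum after cropping; cannot normalize")
  Yn <- Yc / nrm

  meta <- filtered$meta
  meta$stage_pixels <- c(input = n0, smoothed = n0, baseline = n0,
                         qc_filtered = n_kept, cropped = n_kept,
                         normalized = n_kept)
  spectral_map(filtered$wavenumber[sel], Yn, filtered$coords,
               step_um = m$step_um, surface_y_um = m$surface_y_um,
               meta = meta)
}
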