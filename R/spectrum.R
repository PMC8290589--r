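#' Construct a single Raman spectrum
#'
#' A spectrum is one confocal Raman acquisition: a strictly increasing
#' wavenumber axis (Raman shift, cm^-1) and the detector intensities in
#' counts (cts) at each channel, plus free-form provenance tags.
#'
#' @param wavenumber numeric vector of Raman shifts in cm^-1, strictly
#'   increasing
#' @param intensity numeric vector of intensities in counts, same length,
#'   all finite
#' @param meta named list of provenance tags
#' @return an object of class `raman_spectrum` with fields `wavenumber`,
#'   `intensity`, `meta`
#' @examples
#' s <- raman_spectrum(seq(400, 2300, by = 4), rep(100, 476))
#' print(s)
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list()) {
  if (!is.numeric(wavenumber) || !is.numeric(intensity))
    stop_invalid_input("wavenumber and intensity must be numeric")
  if (length(wavenumber) != length(intensity))
    stop_invalid_input("wavenumber and intensity must have equal length")
  if (length(wavenumber) < 1L)
    stop_invalid_input("spectrum must have at least one channel")
  if (any(!is.finite(wavenumber)) || any(diff(wavenumber) <= 0))
    stop_invalid_input("wavenumber axis must be finite and strictly increasing")
  if (any(!is.finite(intensity)))
    stop_invalid_input("intensities must be finite")
  structure(
    list(wavenumber = as.numeric(wavenumber),
         intensity = as.numeric(intensity),
         meta = as.list(meta)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d channels, %.6g-%.6g cm-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  cat(sprintf("  intensity range: %.6g to %.6g cts\n",
              min(x$intensity), max(x$intensity)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

#' Construct a hyperspectral Raman map
#'
#' A map is a rectangular grid of pixels (stage coordinates x, y in
#' micrometres) that share one wavenumber axis.  y increases into the skin;
#' `surface_y_um` marks the depth origin (the skin surface).  Intensities are
#' stored as an n_pixels x n_channels matrix.
#'
#' @param wavenumber shared wavenumber axis (cm^-1), strictly increasing
#' @param intensity numeric matrix, one row per pixel, one column per channel
#' @param coords data.frame with columns `x_um`, `y_um`; rows match
#'   `intensity` rows and (x, y) pairs are unique
#' @param step_um grid step in micrometres (default 5)
#' @param surface_y_um y coordinate of the skin surface; defaults to the
#'   shallowest pixel.  All retained pixels must satisfy y >= surface_y_um.
#' @param meta named list of provenance tags
#' @return an object of class `spectral_map`
#' @examples
#' wn <- seq(400, 2300, by = 4)
#' co <- expand.grid(x_um = c(0, 5, 10), y_um = seq(0, 150, by = 5))
#' m <- spectral_map(wn, matrix(500, nrow(co), length(wn)), co)
#' print(m)
#' @export
spectral_map <- function(wavenumber, intensity, coords, step_um = 5,
                         surface_y_um = NULL, meta = list()) {
  if (!is.matrix(intensity)) intensity <- matrix(intensity, nrow = 1)
  if (!is.numeric(wavenumber) || any(!is.finite(wavenumber)) ||
      (length(wavenumber) > 1 && any(diff(wavenumber) <= 0)))
    stop_invalid_input("wavenumber axis must be finite and strictly increasing")
  if (ncol(intensity) != length(wavenumber))
    stop_invalid_input("intensity columns must match wavenumber axis length")
  if (any(!is.finite(intensity)))
    stop_invalid_input("map intensities must be finite")
  coords <- as.data.frame(coords)
  if (!all(c("x_um", "y_um") %in% names(coords)))
    stop_invalid_input("coords must have columns x_um and y_um")
  if (nrow(coords) != nrow(intensity))
    stop_invalid_input("coords rows must match intensity rows")
  if (anyDuplicated(coords[, c("x_um", "y_um")]))
    stop_invalid_input("(x, y) pixel coordinates must be unique")
  if (is.null(surface_y_um))
    surface_y_um <- if (nrow(coords)) min(coords$y_um) else 0
  if (nrow(coords) && any(coords$y_um < surface_y_um - 1e-9))
    stop_invalid_input("all pixels must lie at y >= surface_y_um")
  if (!is.numeric(step_um) || step_um <= 0)
    stop_invalid_input("step_um must be positive")
  structure(
    list(wavenumber = as.numeric(wavenumber),
         intensity = unname(intensity),
         coords = coords[, c("x_um", "y_um")],
         step_um = as.numeric(step_um),
         surface_y_um = as.numeric(surface_y_um),
         meta = as.list(meta)),
    class = "spectral_map"
  )
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf("<spectral_map> %d pixels x %d channels\n",
              nrow(x$intensity), length(x$wavenumber)))
  if (nrow(x$coords))
    cat(sprintf("  x: %g-%g um, y: %g-%g um (surface at y = %g um), step %g um\n",
                min(x$coords$x_um), max(x$coords$x_um),
                min(x$coords$y_um), max(x$coords$y_um),
                x$surface_y_um, x$step_um))
  cat(sprintf("  axis: %.6g-%.6g cm-1\n",
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Number of pixels in a spectral map or abundance fit
#' @param x a `spectral_map` or `ncls_fit`
#' @return integer pixel count
#' @export
n_pixels <- function(x) {
  if (inherits(x, "spectral_map")) return(nrow(x$intensity))
  if (inherits(x, "ncls_fit")) return(nrow(x$coefficients))
  stop_invalid_input("n_pixels() expects a spectral_map or ncls_fit")
}

#' Extract one pixel of a map as a `raman_spectrum`
#' @param m a `spectral_map`
#' @param i pixel index (row of `m$coords`)
#' @return a `raman_spectrum`
#' @export
map_pixel <- function(m, i) {
  if (!inherits(m, "spectral_map")) stop_invalid_input("not a spectral_map")
  if (i < 1 || i > nrow(m$intensity)) stop_invalid_input("pixel index out of range")
  raman_spectrum(m$wavenumber, m$intensity[i, ],
                 meta = list(x_um = m$coords$x_um[i], y_um = m$coords$y_um[i]))
}

#' Construct a reference-spectrum library
#'
#' Named component spectra (skin constituents plus the tracked exogenous
#' species, e.g. an scFv or a full-size antibody) on one common wavenumber
#' axis.  Exactly one component is flagged as the tracked tracer.
#'
#' @param wavenumber common axis (cm^-1)
#' @param spectra numeric matrix, one column per component (channels x
#'   components); every column must be nonzero
#' @param names character vector of component names
#' @param tracked name of the tracked exogenous component
#' @return an object of class `reference_set`
#' @export
reference_set <- function(wavenumber, spectra, names, tracked) {
  if (!is.matrix(spectra)) spectra <- as.matrix(spectra)
  if (length(names) != ncol(spectra))
    stop_invalid_input("one name per reference column required")
  if (ncol(spectra) < 2L)
    stop_invalid_input("a reference set needs at least 2 components")
  if (anyDuplicated(names))
    stop_invalid_input("component names must be unique")
  if (length(wavenumber) != nrow(spectra))
    stop_invalid_input("reference rows must match the wavenumber axis")
  if (any(!is.finite(wavenumber)) || any(diff(wavenumber) <= 0))
    stop_invalid_input("wavenumber axis must be finite and strictly increasing")
  if (any(!is.finite(spectra)))
    stop_invalid_input("reference intensities must be finite")
  zero <- apply(spectra, 2, function(v) all(v == 0))
  if (any(zero))
    stop_invalid_input(paste("zero reference component:",
                             paste(names[zero], collapse = ", ")))
  if (!tracked %in% names)
    stop_invalid_input(sprintf("tracked component '%s' not in reference names", tracked))
  colnames(spectra) <- names
  structure(
    list(wavenumber = as.numeric(wavenumber), spectra = spectra,
         names = names, tracked = tracked),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d components on %d channels (%.6g-%.6g cm-1)\n",
              length(x$names), length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  cat("  components:",
      paste(ifelse(x$names == x$tracked, paste0(x$names, "*"), x$names),
            collapse = ", "),
      "(* = tracked tracer)\n")
  invisible(x)
}

# shared-axis check with a small numeric tolerance
same_axis <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(a - b) <= tol * pmax(1, abs(a)))
}
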