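# Tabular I/O in the package's CSV dialects, a minimal JCAMP-DX reader,
# and YAML configuration loading.  Floats are written with 12 significant
# digits so write-then-read round-trips are identity to ~1e-12.

write_csv12 <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_cols <- function(path, required) {
  if (!file.exists(path))
    stop_invalid_input(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_invalid_input(sprintf("%s: missing column(s) %s", path,
                               paste(miss, collapse = ", ")))
  df
}

#' Read / write a single spectrum CSV
#'
#' Dialect: two columns `wavenumber_cm1,intensity_cts`, header required.
#'
#' @param path file path
#' @return [read_spectrum_csv()] returns a `raman_spectrum`
#' @export
read_spectrum_csv <- function(path) {
  df <- read_csv_cols(path, c("wavenumber_cm1", "intensity_cts"))
  raman_spectrum(df$wavenumber_cm1, df$intensity_cts,
                 meta = list(source = path))
}

#' @rdname read_spectrum_csv
#' @param s a `raman_spectrum`
#' @export
write_spectrum_csv <- function(s, path) {
  if (!inherits(s, "raman_spectrum")) stop_invalid_input("not a raman_spectrum")
  write_csv12(data.frame(wavenumber_cm1 = s$wavenumber,
                         intensity_cts = s$intensity), path)
}

#' Read / write a hyperspectral map CSV
#'
#' Dialect: long format `x_um,y_um,wavenumber_cm1,intensity_cts`; every
#' pixel must cover the same axis.
#'
#' @param path file path
#' @param step_um,surface_y_um map geometry (see [spectral_map()])
#' @return [read_map_csv()] returns a `spectral_map`
#' @export
read_map_csv <- function(path, step_um = 5, surface_y_um = NULL) {
  df <- read_csv_cols(path, c("x_um", "y_um", "wavenumber_cm1",
                              "intensity_cts"))
  wn <- sort(unique(df$wavenumber_cm1))
  key <- paste(df$x_um, df$y_um, sep = "|")
  pix <- !duplicated(key)
  coords <- df[pix, c("x_um", "y_um")]
  Y <- matrix(NA_real_, nrow(coords), length(wn))
  row_of <- match(key, key[pix])
  col_of <- match(df$wavenumber_cm1, wn)
  Y[cbind(row_of, col_of)] <- df$intensity_cts
  if (any(is.na(Y)))
    stop_invalid_input("map CSV: pixels do not share one wavenumber axis")
  spectral_map(wn, Y, coords, step_um = step_um,
               surface_y_um = surface_y_um, meta = list(source = path))
}

#' @rdname read_map_csv
#' @param m a `spectral_map`
#' @export
write_map_csv <- function(m, path) {
  if (!inherits(m, "spectral_map")) stop_invalid_input("not a spectral_map")
  np <- nrow(m$intensity); nc <- length(m$wavenumber)
  df <- data.frame(
    x_um = rep(m$coords$x_um, each = nc),
    y_um = rep(m$coords$y_um, each = nc),
    wavenumber_cm1 = rep(m$wavenumber, times = np),
    intensity_cts = as.numeric(t(m$intensity)))
  write_csv12(df, path)
}

#' Read / write a reference library CSV
#'
#' Dialect: `component,wavenumber_cm1,intensity`, long format, all
#' components on one axis.
#'
#' @param path file path
#' @param tracked tracked component name (read)
#' @return [read_refs_csv()] returns a [reference_set()]
#' @export
read_refs_csv <- function(path, tracked) {
  df <- read_csv_cols(path, c("component", "wavenumber_cm1", "intensity"))
  comps <- unique(df$component)
  wn <- sort(unique(df$wavenumber_cm1))
  M <- vapply(comps, function(cn) {
    sub <- df[df$component == cn, ]
    if (nrow(sub) != length(wn) ||
        !isTRUE(all.equal(sort(sub$wavenumber_cm1), wn)))
      stop_invalid_input("refs CSV: components not on one common axis")
    sub$intensity[order(sub$wavenumber_cm1)]
  }, numeric(length(wn)))
  reference_set(wn, M, comps, tracked = tracked)
}

#' @rdname read_refs_csv
#' @param refs a [reference_set()]
#' @export
write_refs_csv <- function(refs, path) {
  if (!inherits(refs, "reference_set")) stop_invalid_input("not a reference_set")
  df <- do.call(rbind, lapply(refs$names, function(nm) data.frame(
    component = nm, wavenumber_cm1 = refs$wavenumber,
    intensity = refs$spectra[, nm])))
  write_csv12(df, path)
}

#' Write / read an abundance table CSV
#'
#' Dialect: `x_um,y_um,<component columns>,residual_norm`.
#'
#' @param fit a `raman_unmix` object
#' @param path file path
#' @export
write_abundance_csv <- function(fit, path) {
  if (!inherits(fit, "raman_unmix")) stop_invalid_input("not a raman_unmix fit")
  df <- data.frame(fit$coords, fit$coefficients,
                   residual_norm = fit$residual_norm, check.names = FALSE)
  write_csv12(df, path)
}

#' @rdname write_abundance_csv
#' @return [read_abundance_csv()] returns a data.frame
#' @export
read_abundance_csv <- function(path) {
  read_csv_cols(path, c("x_um", "y_um", "residual_norm"))
}

#' Write a depth profile CSV (`depth_um,mean_abundance,n_pixels`)
#' @param profile a [depth_profile()]
#' @param path file path
#' @export
write_profile_csv <- function(profile, path) {
  if (!inherits(profile, "depth_profile"))
    stop_invalid_input("not a depth_profile")
  write_csv12(as.data.frame(profile), path)
}

#' Read an assay plate CSV
#'
#' Dialect: `donor,condition,dose_nM,response,total_protein_ug`
#' (`total_protein_ug` optional for reporter plates).
#'
#' @param path file path
#' @return data.frame of measurements
#' @export
read_plate_csv <- function(path) {
  df <- read_csv_cols(path, c("donor", "condition", "dose_nM", "response"))
  check_measurements(df)
}

#' @rdname read_plate_csv
#' @param plate data.frame of measurements
#' @export
write_plate_csv <- function(plate, path) {
  write_csv12(check_measurements(plate), path)
}

#' Minimal JCAMP-DX reader for a single spectrum
#'
#' Supports the common fixed-format `##XYDATA=(X++(Y..Y))` tables (with
#' `XFACTOR`/`YFACTOR` scaling) and `##XYPOINTS=(XY..XY)` pairs — enough to
#' ingest one exported instrument spectrum.  Compressed (SQZ/DIF/DUP)
#' encodings are not supported.
#'
#' @param path path to a `.jdx`/`.dx` file
#' @return a `raman_spectrum`; the axis is sorted to be increasing
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path))
    stop_invalid_input(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name, default = NA) {
    hit <- grep(sprintf("^##%s=", name), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  xf <- suppressWarnings(as.numeric(get_field("XFACTOR", "1"))); if (is.na(xf)) xf <- 1
  yf <- suppressWarnings(as.numeric(get_field("YFACTOR", "1"))); if (is.na(yf)) yf <- 1
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  mode <- "xydata"
  if (!length(start)) {
    start <- grep("^##XYPOINTS=", lines, ignore.case = TRUE)
    mode <- "xypoints"
  }
  if (!length(start))
    stop_invalid_input("JCAMP file has no XYDATA or XYPOINTS block")
  block <- lines[(start[1] + 1):length(lines)]
  stop_at <- grep("^##", block)
  if (length(stop_at)) block <- block[seq_len(stop_at[1] - 1)]
  nums <- lapply(block, function(l)
    suppressWarnings(as.numeric(strsplit(trimws(l), "[ ,\t;]+")[[1]])))
  nums <- nums[vapply(nums, length, 1L) > 0]
  if (mode == "xydata") {
    x <- numeric(0); y <- numeric(0)
    for (v in nums) {
      if (any(is.na(v)) || length(v) < 2)
        stop_invalid_input("unsupported or malformed JCAMP XYDATA line")
      x0 <- v[1] * xf
      ys <- v[-1] * yf
      x <- c(x, x0 + seq_along(ys) - 1)  # provisional; respaced below
      y <- c(y, ys)
    }
    # re-derive the x grid from FIRSTX/LASTX/NPOINTS when available
    fx <- suppressWarnings(as.numeric(get_field("FIRSTX")))
    lx <- suppressWarnings(as.numeric(get_field("LASTX")))
    if (!is.na(fx) && !is.na(lx) && length(y) > 1)
      x <- seq(fx, lx, length.out = length(y))
  } else {
    flat <- unlist(nums)
    if (any(is.na(flat)) || length(flat) %% 2 != 0)
      stop_invalid_input("malformed JCAMP XYPOINTS block")
    x <- flat[seq(1, length(flat), by = 2)] * xf
    y <- flat[seq(2, length(flat), by = 2)] * yf
  }
  o <- order(x)
  raman_spectrum(x[o], y[o],
                 meta = list(source = path, title = get_field("TITLE", "")))
}

#' Load a run configuration from YAML
#'
#' Parameter blocks mirror the constructor arguments of
#' [preprocess_config()], [map_sim_config()] and [assay_sim_config()]
#' (keys `preprocess`, `map_sim`, `assay_sim`), plus optional top-level
#' `seed`, `out_dir` and `threshold_fraction`.  Unknown keys are rejected
#' so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path
#' @return named list of validated configuration objects
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_invalid_input(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "threshold_fraction", "preprocess",
             "map_sim", "assay_sim")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_invalid_config(sprintf("unknown config key(s): %s",
                                paste(bad, collapse = ", ")))
  check_block <- function(block, fn) {
    if (is.null(block)) return(NULL)
    bad <- setdiff(names(block), names(formals(fn)))
    if (length(bad))
      stop_invalid_config(sprintf("unknown key(s): %s",
                                  paste(bad, collapse = ", ")))
    do.call(fn, block)
  }
  list(seed = raw$seed, out_dir = raw$out_dir,
       threshold_fraction = raw$threshold_fraction,
       preprocess = check_block(raw$preprocess, preprocess_config),
       map_sim = check_block(raw$map_sim, map_sim_config),
       assay_sim = check_block(raw$assay_sim, assay_sim_config))
}
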