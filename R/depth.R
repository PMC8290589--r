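# Depth profiling of unmixed abundances and penetration-depth estimation.

#' Depth profile of a component abundance
#'
#' Collapses a per-pixel abundance fit into a one-dimensional depth profile:
#' pixels are grouped by depth (y minus the surface origin) on the map's
#' step grid and the component coefficient is averaged over the available x
#' positions at each depth.  Depth bins where every pixel was suppressed by
#' the QC filter are reported with `n_pixels = 0` and `NA` mean — they are
#' missing, not zero, and are excluded from downstream threshold logic
#' rather than interpolated.
#'
#' @param fit a `raman_unmix` object from [unmix()]
#' @param component component name (default: the tracked tracer)
#' @param surface_y_um depth origin; defaults to the fitted map's surface
#'   (the shallowest retained pixel when the map was built).  Must not
#'   exceed the shallowest pixel.
#' @return an object of class `depth_profile`: a data.frame with columns
#'   `depth_um` (bin centres, step-spaced, strictly increasing),
#'   `mean_abundance` (>= 0, `NA` for empty bins) and `n_pixels`
#' @examples
#' # see vignette("raman-penetration-workflow") for an end-to-end example
#' @export
depth_profile <- function(fit, component = NULL, surface_y_um = NULL) {
  if (!inherits(fit, "raman_unmix"))
    stop_invalid_input("depth_profile() expects a raman_unmix fit")
  if (is.null(component)) component <- fit$refs$tracked
  if (!component %in% colnames(fit$coefficients))
    stop_invalid_input(sprintf("unknown component '%s'", component))
  if (is.null(surface_y_um)) surface_y_um <- fit$map$surface_y_um
  if (nrow(fit$coords) && surface_y_um > min(fit$coords$y_um) + 1e-9)
    stop_invalid_input("surface_y_um must not exceed the shallowest pixel")
  step <- fit$map$step_um
  depth <- fit$coords$y_um - surface_y_um
  # snap observed depths onto the step grid; grid spans surface..deepest pixel
  bins <- round(depth / step)
  grid <- if (length(bins)) seq(0L, max(bins)) else integer(0)
  ab <- fit$coefficients[, component]
  mean_ab <- vapply(grid, function(b) {
    v <- ab[bins == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  n_pix <- vapply(grid, function(b) sum(bins == b), integer(1))
  out <- data.frame(depth_um = grid * step,
                    mean_abundance = mean_ab,
                    n_pixels = n_pix)
  structure(out, class = c("depth_profile", "data.frame"),
            component = component, step_um = step)
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> component '%s', %d depth bins (step %g um)\n",
              attr(x, "component"), nrow(x), attr(x, "step_um")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.depth_profile <- function(x, ...) {
  graphics::plot(x$depth_um, x$mean_abundance, type = "b",
                 xlab = "depth from surface (um)",
                 ylab = sprintf("mean %s abundance (a.u.)",
                                attr(x, "component")), ...)
  invisible(x)
}

#' Penetration depth of a tracked component
#'
#' Reads a penetration depth off a depth profile as the deepest bin whose
#' mean abundance reaches `threshold_fraction` of the profile maximum.  The
#' fractional threshold makes the read-out robust to the unmixing noise
#' floor while reproducing step-like abundance fronts.  A profile whose
#' maximum is zero yields depth 0 flagged `detected = FALSE`.
#'
#' @param profile a [depth_profile()]
#' @param threshold_fraction fraction of the profile maximum, in (0, 1);
#'   default 0.05
#' @param replicate_id optional identifier carried into replicate
#'   aggregation
#' @return an object of class `penetration_estimate`: list with `depth_um`,
#'   `detected`, `threshold_fraction`, `replicate_id` and the `profile`
#' @export
penetration_depth <- function(profile, threshold_fraction = 0.05,
                              replicate_id = NA_character_) {
  if (!inherits(profile, "depth_profile"))
    stop_invalid_input("penetration_depth() expects a depth_profile")
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1 ||
      threshold_fraction <= 0 || threshold_fraction >= 1)
    stop_invalid_config("threshold_fraction must lie in (0, 1)")
  ok <- !is.na(profile$mean_abundance)
  if (!any(ok))
    stop_invalid_input("profile has no bins with a defined mean")
  mx <- max(profile$mean_abundance[ok])
  if (mx <= 0) {
    depth <- 0
    detected <- FALSE
  } else {
    hit <- ok & profile$mean_abundance >= threshold_fraction * mx
    depth <- max(profile$depth_um[hit])
    detected <- TRUE
  }
  structure(
    list(depth_um = depth, detected = detected,
         threshold_fraction = threshold_fraction,
         replicate_id = replicate_id, profile = profile),
    class = "penetration_estimate"
  )
}

#' @export
print.penetration_estimate <- function(x, ...) {
  cat(sprintf("<penetration_estimate> %s: depth %g um (threshold %g of max)%s\n",
              attr(x$profile, "component"), x$depth_um, x$threshold_fraction,
              if (!x$detected) " [not detected]" else ""))
  invisible(x)
}

#' Aggregate penetration estimates over replicates
#'
#' The replicate structure of a depth study is typically several sections
#' per sample with several acquisitions each (e.g. 3 sections x 3
#' acquisitions = nine measures per sample); this reduces the per-replicate
#' penetration depths to an arithmetic mean and a sample standard deviation
#' (n - 1 denominator, undefined for a single replicate).
#'
#' @param estimates a list of [penetration_depth()] results (or a bare
#'   numeric vector of depths in micrometres)
#' @return list with `mean_depth_um`, `sd_depth_um` (`NA` when n = 1), `n`
#'   and `replicate_ids`
#' @export
aggregate_replicates <- function(estimates) {
  if (is.numeric(estimates)) {
    depths <- estimates
    ids <- rep(NA_character_, length(depths))
  } else if (is.list(estimates) &&
             all(vapply(estimates, inherits, logical(1),
                        "penetration_estimate"))) {
    depths <- vapply(estimates, `[[`, numeric(1), "depth_um")
    ids <- vapply(estimates, `[[`, character(1), "replicate_id")
  } else {
    stop_invalid_input(
      "estimates must be penetration_estimate objects or a numeric vector")
  }
  if (!length(depths)) stop_invalid_input("no replicates supplied")
  list(mean_depth_um = mean(depths),
       sd_depth_um = if (length(depths) > 1) stats::sd(depths) else NA_real_,
       n = length(depths),
       replicate_ids = ids)
}
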