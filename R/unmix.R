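# Non-negativity-constrained classical least squares (NCLS) unmixing.

#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Solves min ||A x - b||_2 subject to x >= 0.  Deterministic: a fixed
#' (A, b) always yields the same solution.  Rank-deficient A is solved via a
#' minimum-norm inner least-squares step rather than rejected, because real
#' reference libraries can be collinear and the residual is still
#' meaningful; the non-uniqueness is flagged by the caller.
#'
#' @param A numeric matrix (channels x components)
#' @param b numeric response vector
#' @return list with `x` (coefficients, all >= 0), `residual_norm`
#'   (Euclidean norm of b - A x) and `iterations`
#' @export
nnls_lawson_hanson <- function(A, b) {
  if (!is.matrix(A)) A <- as.matrix(A)
  if (nrow(A) != length(b))
    stop_invalid_input("A rows must match length(b)")
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  resid <- b
  w <- as.numeric(crossprod(A, resid))
  tol <- 10 * .Machine$double.eps * max(colSums(abs(A))) *
    max(sqrt(sum(b^2)), 1)
  # inner least squares tolerant of rank deficiency (aliased coefs -> 0)
  solve_passive <- function(P) {
    cf <- stats::lm.fit(A[, P, drop = FALSE], b)$coefficients
    cf[is.na(cf)] <- 0
    cf
  }
  it <- 0L
  max_it <- 30L * n
  while (any(!passive) && max(w[!passive]) > tol && it < max_it) {
    it <- it + 1L
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    s <- numeric(n)
    s[passive] <- solve_passive(passive)
    while (any(s[passive] <= 0) && it < max_it) {
      it <- it + 1L
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
      s <- numeric(n)
      if (any(passive)) s[passive] <- solve_passive(passive)
    }
    x <- s
    resid <- b - as.numeric(A %*% x)
    w <- as.numeric(crossprod(A, resid))
  }
  if (it >= max_it)
    warning("nnls_lawson_hanson: iteration cap reached; returning last iterate",
            call. = FALSE)
  list(x = pmax(x, 0), residual_norm = sqrt(sum(resid^2)), iterations = it)
}

#' NCLS decomposition of one spectrum against a reference library
#'
#' Finds the nonnegative component contributions c minimizing the Euclidean
#' norm of (s - sum_i c_i ref_i) — classical least squares with a
#' non-negativity constraint.
#'
#' @param s a `raman_spectrum` on the reference set's axis
#' @param refs a [reference_set()]
#' @return list with `coefficients` (named, all >= 0), `residual_norm`, and
#'   `rank_deficient` (TRUE when the reference matrix is collinear, in which
#'   case the minimizer may be non-unique although the residual is)
#' @examples
#' w <- seq(400, 785, by = 5)
#' refs <- reference_set(w, cbind(a = dnorm(w, 500, 10), b = dnorm(w, 700, 10)),
#'                       c("a", "b"), tracked = "a")
#' s <- raman_spectrum(w, 0.3 * refs$spectra[, 1] + 0.7 * refs$spectra[, 2])
#' ncls_fit(s, refs)$coefficients
#' @export
ncls_fit <- function(s, refs) {
  if (!inherits(s, "raman_spectrum")) stop_invalid_input("not a raman_spectrum")
  if (!inherits(refs, "reference_set")) stop_invalid_input("not a reference_set")
  if (!same_axis(s$wavenumber, refs$wavenumber))
    stop_invalid_input("spectrum and reference axes differ")
  sol <- nnls_lawson_hanson(refs$spectra, s$intensity)
  cf <- sol$x
  names(cf) <- refs$names
  list(coefficients = cf, residual_norm = sol$residual_norm,
       rank_deficient = qr(refs$spectra)$rank < ncol(refs$spectra))
}

#' Unmix a preprocessed hyperspectral map into component abundances
#'
#' The fitting function of the package: per-pixel NCLS decomposition of a
#' (smoothed, baseline-corrected, cropped, unit-norm) map into the reference
#' components, preserving pixel coordinates.  No sum-to-one constraint is
#' imposed: coefficients are contributions, made comparable across pixels by
#' the unit-norm preprocessing.
#'
#' @param m a `spectral_map` on the reference axis (normally the output of
#'   [preprocess_map()])
#' @param refs a [reference_set()]
#' @return an object of class `raman_unmix` with fields `coefficients`
#'   (pixels x components, all >= 0), `residual_norm` (per pixel), `coords`,
#'   `refs`, `map` (the input map) and `rank_deficient`.  Supports `coef()`,
#'   `fitted()`, `residuals()`, `predict()`, `summary()` and `plot()`.
#' @seealso [ncls_fit()] for a single spectrum, [depth_profile()] for the
#'   downstream depth analysis
#' @export
unmix <- function(m, refs) {
  if (!inherits(m, "spectral_map")) stop_invalid_input("not a spectral_map")
  if (!inherits(refs, "reference_set")) stop_invalid_input("not a reference_set")
  if (!same_axis(m$wavenumber, refs$wavenumber))
    stop_invalid_input("map and reference axes differ")
  np <- nrow(m$intensity)
  k <- length(refs$names)
  cf <- matrix(0, np, k, dimnames = list(NULL, refs$names))
  rn <- numeric(np)
  for (i in seq_len(np)) {
    sol <- nnls_lawson_hanson(refs$spectra, m$intensity[i, ])
    cf[i, ] <- sol$x
    rn[i] <- sol$residual_norm
  }
  structure(
    list(coefficients = cf, residual_norm = rn, coords = m$coords,
         refs = refs, map = m,
         rank_deficient = qr(refs$spectra)$rank < k),
    class = "raman_unmix"
  )
}

#' @rdname unmix
#' @export
unmix_map <- unmix

#' @export
print.raman_unmix <- function(x, ...) {
  cat(sprintf("<raman_unmix> NCLS fit: %d pixels x %d components\n",
              nrow(x$coefficients), ncol(x$coefficients)))
  cat("  components:",
      paste(ifelse(colnames(x$coefficients) == x$refs$tracked,
                   paste0(colnames(x$coefficients), "*"),
                   colnames(x$coefficients)), collapse = ", "),
      "(* = tracked)\n")
  if (length(x$residual_norm))
    cat(sprintf("  residual norm: median %.4g (max %.4g)\n",
                stats::median(x$residual_norm), max(x$residual_norm)))
  if (x$rank_deficient)
    cat("  WARNING: rank-deficient reference matrix; coefficients may be non-unique\n")
  invisible(x)
}

#' @export
coef.raman_unmix <- function(object, ...) object$coefficients

#' @export
fitted.raman_unmix <- function(object, ...) {
  object$coefficients %*% t(object$refs$spectra)
}

#' @export
residuals.raman_unmix <- function(object, ...) {
  object$map$intensity - fitted(object)
}

#' Predict abundances for new spectra from a fitted unmixing model
#' @param object a `raman_unmix` fit
#' @param newdata a `spectral_map` or `raman_spectrum` on the same axis;
#'   omitted returns the training coefficients
#' @param ... unused
#' @return coefficient matrix (pixels x components)
#' @export
predict.raman_unmix <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$coefficients)
  if (inherits(newdata, "raman_spectrum"))
    return(ncls_fit(newdata, object$refs)$coefficients)
  refit <- unmix(newdata, object$refs)
  refit$coefficients
}

#' @export
summary.raman_unmix <- function(object, ...) {
  out <- list(
    n_pixels = nrow(object$coefficients),
    components = colnames(object$coefficients),
    tracked = object$refs$tracked,
    coefficient_summary = apply(object$coefficients, 2, summary),
    residual_summary = if (length(object$residual_norm))
      summary(object$residual_norm) else NULL,
    rank_deficient = object$rank_deficient
  )
  class(out) <- "summary.raman_unmix"
  out
}

#' @export
print.summary.raman_unmix <- function(x, ...) {
  cat(sprintf("NCLS unmixing fit over %d pixels\n", x$n_pixels))
  cat(sprintf("Tracked component: %s\n", x$tracked))
  cat("Coefficient summary:\n")
  print(x$coefficient_summary)
  if (!is.null(x$residual_summary)) {
    cat("Residual norm summary:\n")
    print(x$residual_summary)
  }
  if (x$rank_deficient)
    cat("Note: reference matrix is rank deficient\n")
  invisible(x)
}

#' Plot the depth distribution of a component abundance
#' @param x a `raman_unmix` fit
#' @param component component name (default: the tracked tracer)
#' @param ... passed to [graphics::plot()]
#' @export
plot.raman_unmix <- function(x, component = x$refs$tracked, ...) {
  if (!component %in% colnames(x$coefficients))
    stop_invalid_input(sprintf("unknown component '%s'", component))
  depth <- x$coords$y_um - x$map$surface_y_um
  graphics::plot(depth, x$coefficients[, component],
                 xlab = "depth from surface (um)",
                 ylab = sprintf("%s abundance (a.u.)", component), ...)
  invisible(x)
}
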