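# Shared fixtures and independent oracles, built in code at test time.

# small well-conditioned 2-component toy reference set on a short axis
toy_refs <- function() {
  w <- seq(400, 785, by = 5)
  reference_set(
    w,
    cbind(compA = exp(-0.5 * ((w - 500) / 12)^2),
          compB = exp(-0.5 * ((w - 700) / 12)^2)),
    c("compA", "compB"), tracked = "compA")
}

# a flat-intensity map: every pixel holds `value` cts at every channel
flat_map <- function(value, wavenumber = seq(400, 2300, by = 10),
                     nx = 2, ny = 3, step = 5) {
  co <- expand.grid(x_um = seq(0, by = step, length.out = nx),
                    y_um = seq(0, by = step, length.out = ny))
  spectral_map(wavenumber, matrix(value, nrow(co), length(wavenumber)), co,
               step_um = step)
}

# Independent Savitzky-Golay oracle: an explicit least-squares polynomial
# fit in every (shrunken-at-the-edges) window, no shared code with the
# package implementation.
sg_oracle <- function(w, y, window, order) {
  n <- length(y)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    J <- max(1, i - h):min(n, i + h)
    ord <- min(order, length(J) - 1)
    fit <- stats::lm(yy ~ stats::poly(ww, ord, raw = TRUE),
                     data = data.frame(ww = w[J] - w[i], yy = y[J]))
    out[i] <- unname(stats::predict(fit, newdata = data.frame(ww = 0)))
  }
  out
}

# Brute-force NCLS oracle: coarse nonnegative grid search followed by
# iterative grid-shrink local refinement around the incumbent.
ncls_oracle_objective <- function(A, b, cmax = NULL, coarse = 10,
                                  shrink_steps = 40) {
  k <- ncol(A)
  if (is.null(cmax)) {
    ls <- qr.coef(qr(A), b)
    cmax <- max(2 * max(abs(ls)), 1e-3)
  }
  obj <- function(x) sum((b - A %*% x)^2)
  # coarse pass
  grids <- rep(list(seq(0, cmax, length.out = coarse + 1)), k)
  pts <- as.matrix(expand.grid(grids))
  vals <- apply(pts, 1, obj)
  best <- pts[which.min(vals), ]
  step <- cmax / coarse
  # local refinement: shrink a centred grid around the incumbent
  for (s in seq_len(shrink_steps)) {
    cand <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), k)))
    pts <- sweep(cand * step, 2, best, `+`)
    pts[pts < 0] <- 0
    vals <- apply(pts, 1, obj)
    best <- pts[which.min(vals), ]
    step <- step / 2
  }
  # polish: exact nonnegative coordinate minimization of the quadratic
  # (independent of the active-set solver under test)
  G <- crossprod(A)
  h <- crossprod(A, b)
  for (s in 1:500) {
    for (j in seq_len(k)) {
      r_j <- h[j] - sum(G[j, -j] * best[-j])
      best[j] <- max(0, r_j / G[j, j])
    }
  }
  sqrt(obj(best))
}

# quadrature oracle for the two-tailed Student-t p-value: integrates the
# t density (written out from its gamma-function form) numerically
t_p_oracle <- function(t_stat, df) {
  dens <- function(x)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  tail <- stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-10)$value
  2 * tail
}
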