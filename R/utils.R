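# Internal helpers: classed conditions, seeded RNG evaluation, rounding.

rp_stop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "ramanpen_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_invalid_config <- function(msg) rp_stop("ramanpen_invalid_config", msg)
stop_invalid_input  <- function(msg) rp_stop("ramanpen_invalid_input", msg)
stop_degenerate     <- function(msg) rp_stop("ramanpen_degenerate_input", msg)

#' Evaluate an expression with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero (half-up for positive values)
#'
#' `round()` rounds half to even, which turns a per-dose mean of 6.5 percent
#' into 6; report tables here use the commercial half-up convention instead.
#'
#' A tiny epsilon guards exact .5 boundaries against float noise (a mean
#' that is analytically 6.5 but computed as 6.4999999999999 still reports
#' as 7).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# 12-significant-digit formatting for CSV round-trip fidelity
fmt_num <- function(x) formatC(x, digits = 12, format = "g")

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x)

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop_invalid_input(sprintf("'%s' must be a single finite number", name))
}
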