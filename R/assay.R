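# In vitro neutralization statistics: reporter and IL-8 normalization, the
# anchored percent-neutralization statistic, per-dose summaries, t-tests.

VALID_CONDITIONS <- c("polyIC", "hIL4_polyIC", "scFv_dose", "untreated",
                      "hIL4_max")

check_measurements <- function(x) {
  x <- as.data.frame(x)
  need <- c("donor", "condition", "dose_nM", "response")
  if (!all(need %in% names(x)))
    stop_invalid_input(paste("measurements need columns:",
                             paste(need, collapse = ", ")))
  bad <- setdiff(unique(x$condition), VALID_CONDITIONS)
  if (length(bad))
    stop_invalid_input(paste("unknown condition(s):", paste(bad, collapse = ", ")))
  if (any(!is.finite(x$response)))
    stop_invalid_input("responses must be finite")
  if (any(x$dose_nM < 0)) stop_invalid_input("doses must be >= 0")
  x
}

#' Express reporter responses as percent of the cytokine-stimulated maximum
#'
#' Reporter-cell read-outs (e.g. SEAP OD620) are normalized to the mean
#' response of the maximally stimulated condition (`hIL4_max`, cells given
#' the cytokine alone), which defines 100 percent.
#'
#' @param measurements data.frame with columns `donor`, `condition`,
#'   `dose_nM`, `response`; must contain at least one `hIL4_max` row with a
#'   positive response
#' @return the data.frame with an added `percent_of_max` column
#' @examples
#' d <- data.frame(donor = "r1",
#'                 condition = c("hIL4_max", "hIL4_max", "scFv_dose"),
#'                 dose_nM = c(0, 0, 100), response = c(2, 2, 0.5))
#' normalize_reporter(d)$percent_of_max
#' @export
normalize_reporter <- function(measurements) {
  x <- check_measurements(measurements)
  mx <- x$response[x$condition == "hIL4_max"]
  if (!length(mx))
    stop_invalid_input("no hIL4_max condition present")
  m <- mean(mx)
  if (m <= 0)
    stop_invalid_input("hIL4_max mean response must be positive")
  x$percent_of_max <- 100 * x$response / m
  x
}

#' Normalize a cytokine read-out to total protein per well
#'
#' Divides each response (e.g. IL-8 in pg) by the well's total protein
#' (micrograms), yielding pg per microgram of protein so wells with
#' different cell content are comparable.
#'
#' @param measurements data.frame with columns `response` and
#'   `total_protein_ug` (strictly positive)
#' @return the data.frame with an added `response_per_ug` column
#' @export
normalize_il8 <- function(measurements) {
  x <- as.data.frame(measurements)
  if (!all(c("response", "total_protein_ug") %in% names(x)))
    stop_invalid_input("need columns response and total_protein_ug")
  if (any(is.na(x$total_protein_ug)) || any(x$total_protein_ug <= 0))
    stop_invalid_input("total_protein_ug must be present and > 0")
  x$response_per_ug <- x$response / x$total_protein_ug
  x
}

#' Anchored neutralization percentage
#'
#' The neutralization statistic anchored on two within-donor conditions: the
#' cytokine-plus-stimulus condition defines 0 percent neutralization
#' (`r_zero`) and the stimulus-alone condition defines 100 percent
#' (`r_hundred`).  A dose response `r_dose` maps to
#' `100 * (r_zero - r_dose) / (r_zero - r_hundred)`.  Values below 0 or
#' above 100 are permitted (a dose response below the stimulus-alone anchor
#' exceeds 100).  The statistic is invariant under shifting or positive
#' scaling of all three responses.
#'
#' @param r_dose response at the dose of interest
#' @param r_zero response of the 0 percent anchor (cytokine + stimulus)
#' @param r_hundred response of the 100 percent anchor (stimulus alone)
#' @return neutralization percentage (vectorized over `r_dose`)
#' @examples
#' neutralization_percent(150, r_zero = 200, r_hundred = 100)  # 50
#' @export
neutralization_percent <- function(r_dose, r_zero, r_hundred) {
  stopifnot_scalar_num(r_zero, "r_zero")
  stopifnot_scalar_num(r_hundred, "r_hundred")
  if (r_zero == r_hundred)
    stop_invalid_input("degenerate anchors: r_zero equals r_hundred")
  100 * (r_zero - r_dose) / (r_zero - r_hundred)
}

#' Per-donor anchored neutralization table
#'
#' Builds the donors x doses matrix of neutralization percentages from raw
#' assay measurements, anchoring each donor on that donor's own `polyIC`
#' (100 percent) and `hIL4_polyIC` (0 percent) conditions.  Donors lacking
#' either anchor are excluded with a warning.  Replicate wells of a
#' donor/condition/dose are averaged on the response scale before the
#' percentage is formed.
#'
#' @param measurements data.frame with columns `donor`, `condition`,
#'   `dose_nM`, `response` (use [normalize_il8()] upstream if responses need
#'   protein normalization, passing `response_per_ug` as the response)
#' @param response column name holding the response (default `"response"`)
#' @return an object of class `neutralization_table`: data.frame with one
#'   row per donor and columns `donor`, `polyIC` (exactly 100),
#'   `hIL4_polyIC` (exactly 0) and one column per dose (named
#'   `"<dose> nM"`), unrounded
#' @export
neutralization_table <- function(measurements, response = "response") {
  x <- check_measurements(measurements)
  if (!response %in% names(x))
    stop_invalid_input(sprintf("response column '%s' missing", response))
  x$.resp <- x[[response]]
  donors <- unique(x$donor)
  doses <- sort(unique(x$dose_nM[x$condition == "scFv_dose"]))
  if (!length(doses))
    stop_invalid_input("no scFv_dose rows present")
  rows <- list()
  for (d in donors) {
    xd <- x[x$donor == d, ]
    r100 <- xd$.resp[xd$condition == "polyIC"]
    r0 <- xd$.resp[xd$condition == "hIL4_polyIC"]
    missing <- c(if (!length(r100)) "polyIC",
                 if (!length(r0)) "hIL4_polyIC")
    if (length(missing)) {
      warning(sprintf("donor %s lacks anchor condition(s) %s; excluded",
                      d, paste(missing, collapse = ", ")), call. = FALSE)
      next
    }
    r100 <- mean(r100); r0 <- mean(r0)
    pct <- vapply(doses, function(dose) {
      rr <- xd$.resp[xd$condition == "scFv_dose" & xd$dose_nM == dose]
      if (!length(rr)) return(NA_real_)
      neutralization_percent(mean(rr), r_zero = r0, r_hundred = r100)
    }, numeric(1))
    rows[[as.character(d)]] <- c(100, 0, pct)
  }
  if (!length(rows))
    stop_invalid_input("no donor has both anchor conditions")
  tab <- do.call(rbind, rows)
  out <- data.frame(donor = names(rows), tab, check.names = FALSE)
  names(out) <- c("donor", "polyIC", "hIL4_polyIC", sprintf("%g nM", doses))
  rownames(out) <- NULL
  structure(out, class = c("neutralization_table", "data.frame"),
            doses_nM = doses)
}

#' Construct a neutralization table directly from percentages
#'
#' For data already expressed as anchored percentages (e.g. a published
#' per-donor table), wraps them in the `neutralization_table` container with
#' the anchor columns set to their defining values.
#'
#' @param percent matrix or data.frame (donors x doses) of percentages
#' @param donors donor identifiers
#' @param doses_nM dose levels, one per column
#' @return a `neutralization_table`
#' @export
neutralization_table_from_percent <- function(percent, donors, doses_nM) {
  percent <- as.matrix(percent)
  if (length(donors) != nrow(percent) || length(doses_nM) != ncol(percent))
    stop_invalid_input("dimensions of percent, donors, doses_nM disagree")
  out <- data.frame(donor = donors, polyIC = 100, hIL4_polyIC = 0,
                    percent, check.names = FALSE)
  names(out) <- c("donor", "polyIC", "hIL4_polyIC",
                  sprintf("%g nM", doses_nM))
  rownames(out) <- NULL
  structure(out, class = c("neutralization_table", "data.frame"),
            doses_nM = as.numeric(doses_nM))
}

#' @export
print.neutralization_table <- function(x, ...) {
  cat("<neutralization_table> percent neutralization (anchors: polyIC = 100, hIL4 + polyIC = 0)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Per-dose summary of a neutralization table
#'
#' Appends the report rows of a neutralization table: per-dose arithmetic
#' mean and sample standard deviation (n - 1 denominator) over donors,
#' rounded half-up to integer percent for the report while the unrounded
#' values are retained.  Half-up (not half-to-even) is used so a mean of 6.5
#' reports as 7.
#'
#' @param tab a [neutralization_table()]
#' @return list with `mean` and `sd` (unrounded, named by column),
#'   `mean_rounded` and `sd_rounded` (half-up integers; SD is `NA` with a
#'   flag when only one donor is present) and `report` (the donor rows plus
#'   `Average (%)` and `Standard deviation (%)` rows)
#' @export
summarize_doses <- function(tab) {
  if (!inherits(tab, "neutralization_table"))
    stop_invalid_input("summarize_doses() expects a neutralization_table")
  valcols <- setdiff(names(tab), "donor")
  vals <- as.matrix(tab[, valcols, drop = FALSE])
  mu <- colMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) stats::sd(v) else NA_real_
  })
  mu_r <- round_half_up(mu)
  sd_r <- round_half_up(sdv)
  report <- rbind(
    tab[, c("donor", valcols)],
    data.frame(donor = "Average (%)", t(mu_r), check.names = FALSE),
    data.frame(donor = "Standard deviation (%)", t(sd_r), check.names = FALSE)
  )
  rownames(report) <- NULL
  list(mean = mu, sd = sdv, mean_rounded = mu_r, sd_rounded = sd_r,
       sd_undefined = is.na(sdv), report = report)
}

#' Student's t-test with significance stars
#'
#' Two-sample Student's t-test (equal-variance pooled t for unpaired
#' comparisons; paired t on within-donor differences when donors are
#' matched units), two-tailed.  Degenerate zero-variance inputs are handled
#' explicitly instead of erroring: identical groups give t = 0, p = 1; a
#' constant nonzero shift with zero variance gives p = 0, flagged.
#'
#' @param group_a,group_b numeric response vectors, n >= 2 each; `paired`
#'   requires equal length with aligned units
#' @param paired logical (default FALSE)
#' @return list with `t`, `df`, `p` (two-tailed), `stars` (`****`, `***`,
#'   `**`, `*` at 0.0001/0.001/0.01/0.05, `NS` otherwise), `paired` and
#'   `degenerate`
#' @export
students_t <- function(group_a, group_b, paired = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_invalid_input("each group needs n >= 2")
  if (paired && length(group_a) != length(group_b))
    stop_invalid_input("paired test requires equal group sizes")
  degenerate <- FALSE
  if (paired) {
    d <- group_a - group_b
    if (stats::sd(d) == 0) {
      degenerate <- TRUE
      if (mean(d) == 0) res <- list(t = 0, df = length(d) - 1, p = 1)
      else res <- list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0)
    } else {
      tt <- stats::t.test(group_a, group_b, paired = TRUE)
      res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                  p = tt$p.value)
    }
  } else {
    va <- stats::var(group_a); vb <- stats::var(group_b)
    df <- length(group_a) + length(group_b) - 2
    if (va == 0 && vb == 0) {
      degenerate <- TRUE
      if (mean(group_a) == mean(group_b)) res <- list(t = 0, df = df, p = 1)
      else res <- list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                       df = df, p = 0)
    } else {
      tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
      res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                  p = tt$p.value)
    }
  }
  stars <- if (res$p < 1e-4) "****" else if (res$p < 1e-3) "***" else
    if (res$p < 1e-2) "**" else if (res$p < 0.05) "*" else "NS"
  c(res, list(stars = stars, paired = paired, degenerate = degenerate))
}

#' Published per-donor neutralization percentages (NHK study)
#'
#' The four-donor normal-human-keratinocyte neutralization study: percent
#' neutralization of hIL-4 by an anti-hIL4 scFv at 10, 100, 200, 400 and
#' 600 nM, anchored per donor on poly I:C alone (100 percent) and
#' hIL-4 + poly I:C (0 percent).
#'
#' @return a [neutralization_table_from_percent()] with 4 donors x 5 doses
#' @export
nhk_neutralization_data <- function() {
  pct <- rbind(
    D1 = c(-39,   4,  26,  44,  84),
    D2 = c( 69,  84, 118, 113, 127),
    D3 = c(  3,  21,  31,  46,  43),
    D4 = c( -7,  33,  28,  58,  64)
  )
  neutralization_table_from_percent(pct, donors = rownames(pct),
                                    doses_nM = c(10, 100, 200, 400, 600))
}

#' Reconstructed example assay plate
#'
#' A deterministic plate of raw IL-8-like responses whose per-donor anchored
#' percentages equal [nhk_neutralization_data()].  Donor anchors are given
#' distinct levels and protein contents so per-donor anchoring and protein
#' normalization are both exercised.
#'
#' @return data.frame with columns `donor`, `condition`, `dose_nM`,
#'   `response`, `total_protein_ug`
#' @export
nhk_example_plate <- function() {
  tab <- nhk_neutralization_data()
  doses <- attr(tab, "doses_nM")
  # per-donor anchor responses in pg/ml-equivalent units
  r_zero <- c(D1 = 820, D2 = 1040, D3 = 640, D4 = 910)  # hIL4 + polyIC
  r_hundred <- c(D1 = 310, D2 = 420, D3 = 260, D4 = 330)  # polyIC alone
  protein <- c(D1 = 48, D2 = 55, D3 = 42, D4 = 50)
  rows <- list()
  for (d in tab$donor) {
    span <- r_zero[[d]] - r_hundred[[d]]
    rows[[length(rows) + 1L]] <- data.frame(
      donor = d, condition = c("polyIC", "hIL4_polyIC"), dose_nM = 0,
      response = c(r_hundred[[d]], r_zero[[d]]),
      total_protein_ug = protein[[d]])
    pct <- as.numeric(tab[tab$donor == d, sprintf("%g nM", doses)])
    rows[[length(rows) + 1L]] <- data.frame(
      donor = d, condition = "scFv_dose", dose_nM = doses,
      response = r_zero[[d]] - pct / 100 * span,
      total_protein_ug = protein[[d]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
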