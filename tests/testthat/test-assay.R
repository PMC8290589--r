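# Assay statistics: normalizations, anchored percentages, summaries, t-tests.

test_that("reporter normalization scales to the stimulated maximum", {
  d <- data.frame(donor = "r",
                  condition = c("hIL4_max", "hIL4_max", "scFv_dose",
                                "scFv_dose", "untreated"),
                  dose_nM = c(0, 0, 10, 100, 0),
                  response = c(2.5, 1.5, 2.0, 0.5, 0))
  out <- normalize_reporter(d)  # max-condition mean = 2.0
  expect_equal(out$percent_of_max, c(125, 75, 100, 25, 0))
  expect_error(normalize_reporter(d[d$condition != "hIL4_max", ]),
               class = "ramanpen_invalid_input")
})

test_that("IL-8 normalization divides by total protein", {
  d <- data.frame(donor = "D1", condition = "scFv_dose", dose_nM = 10,
                  response = c(500, 500, 0), total_protein_ug = c(50, 100, 30))
  out <- normalize_il8(d)
  expect_equal(out$response_per_ug, c(10, 5, 0))
  d$total_protein_ug[1] <- 0
  expect_error(normalize_il8(d), class = "ramanpen_invalid_input")
})

test_that("anchored percentage hits its anchors and admits out-of-range values", {
  expect_equal(neutralization_percent(200, r_zero = 200, r_hundred = 100), 0)
  expect_equal(neutralization_percent(100, r_zero = 200, r_hundred = 100), 100)
  # a dose response below the stimulus-alone anchor exceeds 100 %
  expect_gt(neutralization_percent(80, r_zero = 200, r_hundred = 100), 100)
  expect_error(neutralization_percent(1, r_zero = 5, r_hundred = 5),
               class = "ramanpen_invalid_input")
})

test_that("anchored percentage is invariant under positive affine transforms", {
  set.seed(9)
  for (rep in 1:50) {
    r0 <- runif(1, 100, 1000)
    r100 <- runif(1, 10, r0 - 1)
    rd <- runif(1, -100, 1500)
    a <- runif(1, 0.1, 10)   # positive scale
    b <- runif(1, -50, 50)   # shift
    expect_equal(
      neutralization_percent(a * rd + b, a * r0 + b, a * r100 + b),
      neutralization_percent(rd, r0, r100), tolerance = 1e-9)
  }
})

test_that("neutralization_table anchors per donor and excludes incomplete donors", {
  plate <- nhk_example_plate()
  tab <- neutralization_table(plate)
  expect_equal(tab$polyIC, rep(100, 4))
  expect_equal(tab$hIL4_polyIC, rep(0, 4))
  ref <- nhk_neutralization_data()
  expect_equal(as.matrix(tab[, -1]), as.matrix(ref[, -1]),
               ignore_attr = TRUE, tolerance = 1e-9)
  # donor lacking an anchor is dropped with a warning; others survive
  broken <- plate[!(plate$donor == "D2" & plate$condition == "polyIC"), ]
  expect_warning(tab2 <- neutralization_table(broken), "D2")
  expect_equal(tab2$donor, c("D1", "D3", "D4"))
})

test_that("mean of per-donor percentages differs from pooled-anchor percentages", {
  # guard: anchors must be each donor's own, not pooled across donors
  plate <- nhk_example_plate()
  tab <- neutralization_table(plate)
  per_donor_mean <- mean(tab[["600 nM"]])
  pooled <- with(
    list(p = plate),
    neutralization_percent(
      mean(p$response[p$condition == "scFv_dose" & p$dose_nM == 600]),
      r_zero = mean(p$response[p$condition == "hIL4_polyIC"]),
      r_hundred = mean(p$response[p$condition == "polyIC"])))
  expect_gt(abs(per_donor_mean - pooled), 0.5)
})

test_that("dose summaries use half-up rounding and the sample SD", {
  expect_equal(round_half_up(6.5), 7)   # half-to-even would give 6
  expect_equal(round_half_up(-6.5), -7)
  tab <- nhk_neutralization_data()
  s <- summarize_doses(tab)
  expect_equal(unname(s$mean_rounded[c("10 nM", "100 nM", "200 nM",
                                       "400 nM", "600 nM")]),
               c(7, 36, 51, 65, 80))
  expect_equal(unname(s$sd_rounded[c("400 nM", "600 nM")]), c(32, 36))
  # anchors summarize to their defining values
  expect_equal(unname(s$mean_rounded[c("polyIC", "hIL4_polyIC")]), c(100, 0))
  expect_equal(unname(s$sd_rounded[c("polyIC", "hIL4_polyIC")]), c(0, 0))
  # four identical donor values: mean v, SD 0
  t2 <- neutralization_table_from_percent(matrix(42, 4, 1), paste0("D", 1:4), 50)
  s2 <- summarize_doses(t2)
  expect_equal(unname(s2$mean[["50 nM"]]), 42)
  expect_equal(unname(s2$sd[["50 nM"]]), 0)
  # single donor: SD undefined, flagged
  t1 <- neutralization_table_from_percent(matrix(10, 1, 1), "D1", 50)
  s1 <- summarize_doses(t1)
  expect_true(s1$sd_undefined[["50 nM"]])
})

test_that("Student's t-test matches a quadrature oracle and maps stars", {
  a <- c(12.1, 9.8, 11.4, 10.9, 13.2)
  b <- c(8.2, 7.9, 9.5, 6.8, 8.8)
  res <- students_t(a, b)
  expect_equal(res$p, t_p_oracle(res$t, res$df), tolerance = 1e-8)
  # cross-check the statistic itself against the pooled-variance formula
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  # paired variant
  resp <- students_t(a, b, paired = TRUE)
  expect_equal(resp$p, t_p_oracle(resp$t, resp$df), tolerance = 1e-8)
  # degenerate cases
  same <- students_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shift <- students_t(c(2, 3, 4), c(1, 2, 3), paired = TRUE)
  expect_true(shift$degenerate)
  expect_equal(shift$p, 0)
  expect_equal(shift$stars, "****")
  expect_error(students_t(1, c(1, 2)), class = "ramanpen_invalid_input")
  # star thresholds
  expect_equal(students_t(c(10, 11, 10.5, 10.2), c(10.4, 10.9, 10.1, 10.6))$stars,
               "NS")
})
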