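# End-to-end workflows: the penetration study (simulate/load maps ->
# preprocess -> unmix -> depth profile -> replicate aggregation) and the
# neutralization study (plate -> normalization -> anchored percentages ->
# summary table -> t-tests).  Every run writes a provenance record beside
# its outputs; outputs contain no timestamps so fixed-seed runs are
# bit-identical.

write_provenance <- function(out_dir, record) {
  record$package <- "ramanpen"
  record$package_version <- as.character(utils::packageVersion("ramanpen"))
  jsonlite::write_json(record, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

#' Run the penetration study end to end
#'
#' For each condition (a tracer/time label with its own simulated
#' penetration front, or a list of already-acquired maps), runs
#' preprocessing, NCLS unmixing against the conditioned reference library,
#' depth profiling and penetration-depth estimation on every replicate map,
#' then aggregates replicates to a mean and SD depth per condition.  The
#' default conditions emulate a two-species comparison: a small tracer
#' reaching 130 um at 24 h versus a large one confined near the surface,
#' with both near-surface at 6 h.
#'
#' @param out_dir output directory (created if needed); receives
#'   `depth_report.csv`, `report.md`, per-condition profile CSVs and
#'   `provenance.json`
#' @param conditions data.frame with columns `label` and `front_um`
#'   (simulated mode), or a named list `label -> list of spectral_map`
#'   (measured mode, used with `refs`)
#' @param refs a [reference_set()] for measured mode; simulated mode builds
#'   its own from `map_sim`
#' @param map_sim a [map_sim_config()] template; per replicate, the seed
#'   and front are replaced per condition
#' @param preprocess a [preprocess_config()]
#' @param threshold_fraction penetration threshold (default 0.05)
#' @param n_replicates replicate maps per condition (default 9, the
#'   3 sections x 3 acquisitions design)
#' @param seed base seed; replicate seeds are derived from it
#' @return (invisibly) a list with `report` (per-condition depth summary),
#'   `estimates` and `profiles`
#' @export
run_penetration_pipeline <- function(out_dir,
                                     conditions = data.frame(
                                       label = c("scFv_6h", "Ab_6h",
                                                 "scFv_24h", "Ab_24h"),
                                       front_um = c(15, 15, 130, 15)),
                                     refs = NULL,
                                     map_sim = map_sim_config(),
                                     preprocess = preprocess_config(),
                                     threshold_fraction = 0.05,
                                     n_replicates = 9,
                                     seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  preprocess <- as_preprocess_config(preprocess)
  simulated <- is.data.frame(conditions)
  if (!simulated && is.null(refs))
    stop_invalid_config("measured mode needs a reference_set in 'refs'")

  estimates <- list()
  profiles <- list()
  report_rows <- list()

  run_one <- function(map, refs_p, label, rep_id) {
    pre <- preprocess_map(map, preprocess)
    fit <- unmix(pre, refs_p)
    prof <- depth_profile(fit)
    penetration_depth(prof, threshold_fraction,
                      replicate_id = sprintf("%s_rep%s", label, rep_id))
  }

  if (simulated) {
    if (!all(c("label", "front_um") %in% names(conditions)))
      stop_invalid_config("conditions needs columns label and front_um")
    for (ci in seq_len(nrow(conditions))) {
      label <- conditions$label[ci]
      cond_est <- list()
      cond_prof <- NULL
      for (r in seq_len(n_replicates)) {
        cfg_r <- map_sim
        cfg_r$tracer_front_um <- conditions$front_um[ci]
        cfg_r$seed <- (as.integer(seed) * 997L + ci * 131L + r) %% 2147483647L
        sim <- make_map(cfg_r)
        refs_p <- preprocess_references(sim$refs, preprocess)
        est <- run_one(sim$map, refs_p, label, r)
        cond_est[[r]] <- est
        if (r == 1L) cond_prof <- est$profile
      }
      agg <- aggregate_replicates(cond_est)
      estimates[[label]] <- cond_est
      profiles[[label]] <- cond_prof
      report_rows[[label]] <- data.frame(
        condition = label, true_front_um = conditions$front_um[ci],
        mean_depth_um = agg$mean_depth_um, sd_depth_um = agg$sd_depth_um,
        n = agg$n)
    }
  } else {
    refs_p <- preprocess_references(refs, preprocess)
    for (label in names(conditions)) {
      maps <- conditions[[label]]
      cond_est <- lapply(seq_along(maps), function(r)
        run_one(maps[[r]], refs_p, label, r))
      agg <- aggregate_replicates(cond_est)
      estimates[[label]] <- cond_est
      profiles[[label]] <- cond_est[[1]]$profile
      report_rows[[label]] <- data.frame(
        condition = label, true_front_um = NA_real_,
        mean_depth_um = agg$mean_depth_um, sd_depth_um = agg$sd_depth_um,
        n = agg$n)
    }
  }

  report <- do.call(rbind, report_rows)
  rownames(report) <- NULL
  write_csv12(report, file.path(out_dir, "depth_report.csv"))
  for (label in names(profiles))
    write_profile_csv(profiles[[label]],
                      file.path(out_dir, sprintf("profile_%s.csv", label)))

  md <- c("# Penetration depth report", "",
          "| condition | mean depth (um) | SD (um) | n |",
          "|---|---|---|---|",
          sprintf("| %s | %.1f | %s | %d |", report$condition,
                  report$mean_depth_um,
                  ifelse(is.na(report$sd_depth_um), "-",
                         sprintf("%.1f", report$sd_depth_um)),
                  report$n))
  writeLines(md, file.path(out_dir, "report.md"))

  write_provenance(out_dir, list(
    workflow = "penetration",
    seed = as.integer(seed),
    n_replicates = n_replicates,
    threshold_fraction = threshold_fraction,
    conditions = if (simulated) conditions else names(conditions),
    preprocess = unclass(preprocess),
    map_sim = if (simulated)
      unclass(map_sim)[setdiff(names(map_sim), "components")]))

  invisible(list(report = report, estimates = estimates,
                 profiles = profiles))
}

#' Run the neutralization study end to end
#'
#' Normalizes the plate (per-well total protein for primary keratinocytes;
#' percent-of-maximum for the reporter line), forms the per-donor anchored
#' neutralization table, appends the per-dose Average / Standard deviation
#' rows, and tests each dose against the 0-percent anchor condition with a
#' Student's t-test (paired by donor for the keratinocyte mode, unpaired
#' for the cell line).
#'
#' @param out_dir output directory; receives `neutralization_table.csv`,
#'   `t_tests.csv`, `report.md` and `provenance.json`
#' @param plate data.frame of measurements or a plate CSV path; omitted
#'   with `assay_sim` set simulates one
#' @param mode `"nhk"` (primary keratinocytes, protein-normalized, paired)
#'   or `"reporter"` (cell line, percent-of-max, unpaired)
#' @param assay_sim an [assay_sim_config()] used when `plate` is missing
#' @return (invisibly) a list with `table` (the `neutralization_table`),
#'   `summary` ([summarize_doses()] output) and `tests`
#' @export
run_assay_pipeline <- function(out_dir, plate = NULL, mode = c("nhk", "reporter"),
                               assay_sim = NULL) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(plate)) {
    if (is.null(assay_sim))
      stop_invalid_config("either a plate or an assay_sim config is required")
    plate <- make_assay(assay_sim)
  } else if (is.character(plate)) {
    plate <- read_plate_csv(plate)
  } else {
    plate <- check_measurements(plate)
  }

  if (mode == "nhk") {
    has_protein <- "total_protein_ug" %in% names(plate) &&
      !all(is.na(plate$total_protein_ug))
    if (has_protein) {
      plate <- normalize_il8(plate)
      resp_col <- "response_per_ug"
    } else {
      resp_col <- "response"
    }
    tab <- neutralization_table(plate, response = resp_col)
    paired <- TRUE
    anchor_cond <- "hIL4_polyIC"
  } else {
    plate <- normalize_reporter(plate)
    resp_col <- "percent_of_max"
    # reporter anchors: cytokine-stimulated = 0 % , unstimulated = 100 %
    plate2 <- plate
    plate2$condition[plate2$condition == "hIL4_max"] <- "hIL4_polyIC"
    plate2$condition[plate2$condition == "untreated"] <- "polyIC"
    tab <- neutralization_table(plate2, response = resp_col)
    paired <- FALSE
    anchor_cond <- "hIL4_max"
  }

  summ <- summarize_doses(tab)

  doses <- attr(tab, "doses_nM")
  anchor_resp <- plate[[resp_col]][plate$condition == anchor_cond]
  tests <- do.call(rbind, lapply(doses, function(d) {
    sel <- plate$condition == "scFv_dose" & plate$dose_nM == d
    if (paired) {
      # align by donor: mean response per donor at this dose vs its anchor
      donors <- sort(unique(plate$donor[sel]))
      a <- vapply(donors, function(dn)
        mean(plate[[resp_col]][sel & plate$donor == dn]), numeric(1))
      b <- vapply(donors, function(dn)
        mean(plate[[resp_col]][plate$condition == anchor_cond &
                                 plate$donor == dn]), numeric(1))
      tt <- students_t(a, b, paired = TRUE)
    } else {
      tt <- students_t(plate[[resp_col]][sel], anchor_resp, paired = FALSE)
    }
    data.frame(dose_nM = d, t = tt$t, df = tt$df, p = tt$p,
               stars = tt$stars, degenerate = tt$degenerate)
  }))

  write_csv12(summ$report, file.path(out_dir, "neutralization_table.csv"))
  write_csv12(tests, file.path(out_dir, "t_tests.csv"))

  valcols <- setdiff(names(summ$report), "donor")
  fmt_row <- function(lbl, vals)
    sprintf("| %s | %s |", lbl, paste(vals, collapse = " | "))
  md <- c("# Neutralization report", "",
          sprintf("Mode: %s; anchors: polyIC = 100 %%, hIL4 + polyIC = 0 %%.",
                  mode), "",
          fmt_row("donor", valcols),
          fmt_row("---", rep("---", length(valcols))),
          vapply(seq_len(nrow(summ$report)), function(i)
            fmt_row(summ$report$donor[i],
                    format(unlist(summ$report[i, valcols]), trim = TRUE)),
            character(1)),
          "",
          "## Student's t-tests (dose vs 0 % anchor)", "",
          "| dose (nM) | t | p | |",
          "|---|---|---|---|",
          sprintf("| %g | %.3f | %.4g | %s |", tests$dose_nM, tests$t,
                  tests$p, tests$stars))
  writeLines(md, file.path(out_dir, "report.md"))

  write_provenance(out_dir, list(
    workflow = "assay", mode = mode, paired = paired,
    assay_sim = if (!is.null(assay_sim)) unclass(assay_sim)))

  invisible(list(table = tab, summary = summ, tests = tests))
}
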