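#' Apply the analysis-sample exclusions
#'
#' Drops, in order: subjects with any missing CCA measure, then subjects
#' with prevalent (baseline) stroke — the two exclusion steps between a
#' raw measurement file and the incidence-analysis sample. Returns the
#' remaining cohort plus an itemized tally.
#'
#' @param cohort Cohort data frame (schema of [simulate_cohort()]).
#' @return List with `cohort` (rows surviving both exclusions) and
#'   `tally`: named counts `input`, `missing_measures`, `prevalent_stroke`,
#'   `analysis`.
#' @export
apply_exclusions <- function(cohort) {
  n0 <- nrow(cohort)
  meas_cols <- c("r_imt_mm", "l_imt_mm", "r_dia_mm", "l_dia_mm")
  has_missing <- Reduce(`|`, lapply(meas_cols, function(cc) is.na(cohort[[cc]])))
  cohort <- cohort[!has_missing, , drop = FALSE]
  n_missing <- sum(has_missing)
  prevalent <- cohort$prevalent_stroke == 1
  cohort <- cohort[!prevalent, , drop = FALSE]
  list(cohort = cohort,
       tally = c(input = n0,
                 missing_measures = n_missing,
                 prevalent_stroke = sum(prevalent),
                 analysis = nrow(cohort)))
}

#' Run the full bilateral-geometry stroke-risk pipeline
#'
#' Orchestrates simulate/ingest -> exclusions -> median split &
#' classification -> concordance -> phenotype/incidence tabulation ->
#' diagnostic-accuracy panel -> side- and sex-specific Cox models, and
#' writes every report as plain TSV/CSV plus a JSON run manifest. A fixed
#' config (seed included) regenerates byte-identical reports.
#'
#' @param config A [cohort_config()], a path to a YAML file mirroring its
#'   field names (an optional top-level `input_csv` reads a cohort instead
#'   of simulating), or a list of `cohort_config()` arguments.
#' @param out_dir Output directory (created if needed).
#' @param use_reference_medians Classify against [reference_medians()]
#'   instead of medians computed from the analysis sample (default FALSE:
#'   compute from data).
#' @param n_boot Bootstrap resamples for agreement CIs.
#' @return The run manifest (list), invisibly; reports are on disk.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = "results",
                         use_reference_medians = FALSE, n_boot = 500) {
  input_csv <- NULL
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    input_csv <- raw$input_csv
    raw$input_csv <- NULL
    if (!is.null(raw$log_hazard_by_phenotype))
      raw$log_hazard_by_phenotype <- unlist(raw$log_hazard_by_phenotype)
    config <- do.call(cohort_config, raw)
  } else if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()

  cohort <- if (is.null(input_csv)) simulate_cohort(config)
            else read_cohort_csv(input_csv)
  stages$loaded <- nrow(cohort)

  excl <- apply_exclusions(cohort)
  analysis <- excl$cohort
  stages$after_exclusions <- nrow(analysis)

  medians <- if (use_reference_medians) reference_medians()
             else compute_medians(analysis)
  utils::write.table(medians, file.path(out_dir, "medians.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  classified <- classify_cohort(analysis, medians)
  write_cohort_csv_classified(classified, file.path(out_dir, "classified.csv"))
  stages$classified <- nrow(classified)

  conc <- concordance_report(classified, n_boot = n_boot, seed = config$seed)
  utils::write.table(format_numeric(conc, 1),
                     file.path(out_dir, "concordance.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  kappas <- lapply(c("M", "F", "all"), function(sx)
    cohens_kappa(build_agreement_table(classified, sx)))
  kap <- data.frame(sex = c("M", "F", "all"),
                    kappa = sapply(kappas, `[[`, "kappa"),
                    ci_low = sapply(kappas, function(k) k$ci[1]),
                    ci_high = sapply(kappas, function(k) k$ci[2]))
  utils::write.table(format_numeric(kap, 4),
                     file.path(out_dir, "kappa.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  phen <- tabulate_phenotypes(classified)
  utils::write.table(phen, file.path(out_dir, "phenotypes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  comb <- combined_counts(phen)
  utils::write.table(comb, file.path(out_dir, "combined_phenotypes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  diag_tab <- diagnostics_report(classified)
  utils::write.table(diag_tab, file.path(out_dir, "diagnostics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  cox_rows <- list()
  for (sx in c("M", "F")) for (side in c("R", "L")) {
    sub <- classified[classified$sex == sx, ]
    des <- geometry_design(sub, side)
    fit <- tryCatch(fit_cox(des$time, des$status, des$x),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      cox_rows[[paste(sx, side)]] <- data.frame(
        sex = sx, side = side, term = NA_character_, coef = NA_real_,
        se = NA_real_, hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, note = conditionMessage(fit))
      next
    }
    cox_rows[[paste(sx, side)]] <- data.frame(
      sex = sx, side = side, term = names(fit$coef),
      coef = unname(fit$coef), se = unname(fit$se), hr = unname(fit$hr),
      ci_low = unname(fit$hr_ci[, "lo"]), ci_high = unname(fit$hr_ci[, "hi"]),
      p_value = unname(fit$p_value), note = "")
  }
  cox_tab <- do.call(rbind, cox_rows)
  rownames(cox_tab) <- NULL
  utils::write.table(format_numeric(cox_tab, 4),
                     file.path(out_dir, "cox_geometry.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("carotidgeom")),
    seed = config$seed,
    n_subjects = config$n_subjects,
    input = if (is.null(input_csv)) "simulated" else input_csv,
    exclusions = as.list(excl$tally),
    stage_counts = stages,
    medians_source = if (use_reference_medians) "reference" else "sample",
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# classified cohort CSV: base schema + the three classification columns
write_cohort_csv_classified <- function(classified, path) {
  cols <- c(cohort_schema(), "r_geometry", "l_geometry", "phenotype_id")
  utils::write.csv(classified[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_numeric <- function(df, digits) {
  for (cc in names(df))
    if (is.numeric(df[[cc]]) && !is.integer(df[[cc]]))
      df[[cc]] <- round(df[[cc]], digits)
  df
}
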