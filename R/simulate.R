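#' Calibrate the within-side IMT-diameter correlation
#'
#' With a Gaussian copula, median dichotomization of two latent standard
#' normals with correlation rho puts mass
#' \deqn{P(\mathrm{both\ large}) = 1/4 + \arcsin(\rho)/(2\pi)}
#' in the "both large" orthant. This inverts that relation: given a target
#' "both large" prevalence it returns the rho that achieves it exactly in
#' distribution. Median splits are invariant to the monotone log-normal
#' transform, so the calibration holds on the measurement scale too.
#'
#' @param target_both_large Target per-side prevalence of the "both large"
#'   category, in [0.25, 0.5).
#' @return Correlation rho in [0, 1).
#' @export
#' @examples
#' calibrate_within_correlation(0.25)  # 0: independence
#' calibrate_within_correlation(0.32)  # ~0.4258
calibrate_within_correlation <- function(target_both_large) {
  if (!is.numeric(target_both_large) || length(target_both_large) != 1L ||
      is.na(target_both_large) ||
      target_both_large < 0.25 || target_both_large >= 0.5)
    stop("target_both_large must lie in [0.25, 0.5)")
  sin(2 * pi * (target_both_large - 0.25))
}

# Orthant probability of the "both >= median" quadrant for latent
# correlation rho; the forward map inverted by calibrate_within_correlation.
orthant_both_large <- function(rho) 0.25 + asin(rho) / (2 * pi)

# Pooled-sex cumulative-incidence gradient across the ten phenotypes,
# expressed as log hazard ratios vs the reference phenotype 10.
default_log_hazard <- function() {
  inc <- c(6.14, 3.20, 3.06, 0.53, 2.94, 0.52, 0.87, 1.22, 0.90, 0.66)
  stats::setNames(log(inc / inc[10]), as.character(1:10))
}

#' Cohort generator configuration
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults
#' emulate a middle-aged US community cohort: side- and sex-specific
#' median IMT / external diameter locations, a within-side IMT-diameter
#' correlation calibrated so ~32% of each side falls in the "both large"
#' category (hence ~32/18/18/32 across the four patterns), a right-left
#' correlation of 0.35 producing partial bilateral concordance, an
#' exponential stroke hazard increasing with phenotype severity, and
#' administrative censoring uniform on 10-12 years.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param fraction_female Proportion of women.
#' @param log_mean_imt,log_mean_diameter Per-sex, per-side latent location
#'   parameters (log mm): lists with elements `M` and `F`, each a named
#'   vector `c(R=, L=)`. `exp()` of each entry is the true marginal median.
#' @param sd_log Latent log-scale SD shared by all four measures.
#' @param rho_within Within-side IMT-diameter latent correlation, |rho|<1.
#' @param rho_between Right-left latent correlation of the same parameter,
#'   |rho|<1. The cross (opposite side, opposite parameter) correlation is
#'   the separable product `rho_within * rho_between`.
#' @param baseline_hazard Stroke hazard (events per person-year) in the
#'   reference phenotype.
#' @param log_hazard_by_phenotype Named numeric vector mapping phenotype id
#'   ("1".."10") to log hazard ratio vs phenotype 10.
#' @param censor_min_years,censor_max_years Administrative censoring window
#'   (uniform draw).
#' @param prevalent_fraction Probability a subject carries a baseline
#'   (prevalent) stroke flag and is excluded from incidence analyses.
#' @param missing_fraction Probability one arterial measure is set missing
#'   (exercise the exclusion flow; default 0 = complete data).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return Object of class `cohort_config` (a list).
#' @export
cohort_config <- function(n_subjects = 7437,
                          fraction_female = 4107 / 7437,
                          log_mean_imt = list(
                            M = c(R = log(0.663), L = log(0.676)),
                            F = c(R = log(0.609), L = log(0.603))),
                          log_mean_diameter = list(
                            M = c(R = log(8.092), L = log(7.997)),
                            F = c(R = log(7.303), L = log(7.199))),
                          sd_log = 0.15,
                          rho_within = calibrate_within_correlation(0.32),
                          rho_between = 0.35,
                          baseline_hazard = 0.0006,
                          log_hazard_by_phenotype = default_log_hazard(),
                          censor_min_years = 10,
                          censor_max_years = 12,
                          prevalent_fraction = 161 / 7437,
                          missing_fraction = 0,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              fraction_female = fraction_female,
              log_mean_imt = log_mean_imt,
              log_mean_diameter = log_mean_diameter,
              sd_log = sd_log,
              rho_within = rho_within,
              rho_between = rho_between,
              baseline_hazard = baseline_hazard,
              log_hazard_by_phenotype = log_hazard_by_phenotype,
              censor_min_years = censor_min_years,
              censor_max_years = censor_max_years,
              prevalent_fraction = prevalent_fraction,
              missing_fraction = missing_fraction,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1")
  if (cfg$fraction_female < 0 || cfg$fraction_female > 1)
    stop("fraction_female must lie in [0, 1]")
  if (cfg$sd_log <= 0) stop("sd_log must be positive")
  if (abs(cfg$rho_within) >= 1 || abs(cfg$rho_between) >= 1)
    stop(sprintf(paste0("latent covariance is not positive definite: ",
                        "rho_within=%.4f, rho_between=%.4f must both have ",
                        "absolute value < 1"),
                 cfg$rho_within, cfg$rho_between))
  if (cfg$baseline_hazard < 0) stop("baseline_hazard must be >= 0")
  if (cfg$censor_min_years > cfg$censor_max_years)
    stop("censor_min_years must be <= censor_max_years")
  if (cfg$censor_min_years <= 0) stop("censoring window must be positive")
  ids <- as.character(1:10)
  if (!all(ids %in% names(cfg$log_hazard_by_phenotype)))
    stop("log_hazard_by_phenotype must name every phenotype id 1..10; missing: ",
         paste(setdiff(ids, names(cfg$log_hazard_by_phenotype)), collapse = ", "))
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1)
    stop("missing_fraction must lie in [0, 1)")
  invisible(cfg)
}

# Separable 4x4 latent correlation over (r_imt, r_dia, l_imt, l_dia):
# Kronecker product of the side factor (1, rho_between) and the parameter
# factor (1, rho_within); positive definite iff both |rho| < 1.
latent_correlation <- function(rho_within, rho_between) {
  side <- matrix(c(1, rho_between, rho_between, 1), 2)
  param <- matrix(c(1, rho_within, rho_within, 1), 2)
  k <- kronecker(side, param)
  dimnames(k) <- list(c("r_imt", "r_dia", "l_imt", "l_dia"),
                      c("r_imt", "r_dia", "l_imt", "l_dia"))
  k
}

#' Draw bilateral arterial measures
#'
#' Samples `n` subjects' four CCA measures as the exponential of a
#' 4-variate Gaussian. For a given sex the marginal medians equal
#' `exp(log_mean)` exactly in distribution; the Gaussian copula carries the
#' within-side and right-left correlations.
#'
#' @param config A [cohort_config()].
#' @param n Number of subjects.
#' @param sex "M" or "F": selects the location parameters.
#' @return Data frame with columns `r_imt_mm`, `r_dia_mm`, `l_imt_mm`,
#'   `l_dia_mm`. Consumes random numbers from the current RNG stream.
#' @export
draw_arterial_measures <- function(config, n, sex = c("M", "F")) {
  validate_config(config)
  sex <- match.arg(sex)
  corr <- latent_correlation(config$rho_within, config$rho_between)
  ch <- tryCatch(chol(corr), error = function(e)
    stop(sprintf("latent covariance not positive definite (rho_within=%.4f, rho_between=%.4f)",
                 config$rho_within, config$rho_between)))
  z <- matrix(stats::rnorm(4L * n), ncol = 4L) %*% ch
  mu <- c(config$log_mean_imt[[sex]]["R"], config$log_mean_diameter[[sex]]["R"],
          config$log_mean_imt[[sex]]["L"], config$log_mean_diameter[[sex]]["L"])
  out <- exp(sweep(z * config$sd_log, 2L, mu, `+`))
  data.frame(r_imt_mm = out[, 1], r_dia_mm = out[, 2],
             l_imt_mm = out[, 3], l_dia_mm = out[, 4])
}

# True (population) median table implied by a config: exp of the latent
# location parameters, laid out like compute_medians() output.
true_medians <- function(config) {
  out <- expand.grid(sex = c("M", "F"), side = c("R", "L"),
                     parameter = c("IMT", "diameter"),
                     stringsAsFactors = FALSE)
  out$median_mm <- mapply(function(sex, side, param) {
    src <- if (param == "IMT") config$log_mean_imt else config$log_mean_diameter
    exp(unname(src[[sex]][side]))
  }, out$sex, out$side, out$parameter)
  out
}

#' Attach proportional-hazards outcomes to arterial measures
#'
#' Classifies each subject's bilateral phenotype against the generator's
#' true medians, then draws an exponential event time with rate
#' `baseline_hazard * exp(log_hazard_by_phenotype[id])` and an independent
#' uniform censoring time on the administrative window. `event` is 1 iff
#' the event time falls at or before the censoring time; `time_years` is
#' the earlier of the two.
#'
#' @param measures Data frame with the four arterial columns plus `sex`.
#' @param config A [cohort_config()].
#' @return `measures` with `event` and `time_years` appended. Consumes
#'   random numbers from the current RNG stream.
#' @export
draw_outcomes <- function(measures, config) {
  validate_config(config)
  classified <- classify_cohort(measures, medians = true_medians(config))
  loghr <- config$log_hazard_by_phenotype[as.character(classified$phenotype_id)]
  if (anyNA(loghr))
    stop("log_hazard_by_phenotype is missing ids: ",
         paste(unique(classified$phenotype_id[is.na(loghr)]), collapse = ", "))
  n <- nrow(measures)
  rate <- config$baseline_hazard * exp(unname(loghr))
  t_event <- ifelse(rate > 0, stats::rexp(n) / pmax(rate, .Machine$double.xmin), Inf)
  t_cens <- stats::runif(n, config$censor_min_years, config$censor_max_years)
  measures$event <- as.integer(t_event <= t_cens)
  measures$time_years <- pmin(t_event, t_cens)
  measures
}

#' Simulate a complete subject-level cohort
#'
#' End-to-end generation: sex assignment, bilateral arterial measures,
#' baseline covariates (age, race, standing height), prevalent-stroke
#' flags, and proportional-hazards follow-up outcomes. A single
#' `set.seed(config$seed)` at entry makes the whole cohort bit-reproducible.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `subject_id`, `sex`, `age`, `race`,
#'   `height_cm`, `r_imt_mm`, `l_imt_mm`, `r_dia_mm`, `l_dia_mm`, `event`,
#'   `time_years`, `prevalent_stroke`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  sex <- ifelse(stats::runif(n) < config$fraction_female, "F", "M")
  meas <- data.frame(r_imt_mm = numeric(n), r_dia_mm = numeric(n),
                     l_imt_mm = numeric(n), l_dia_mm = numeric(n))
  for (sx in c("M", "F")) {
    idx <- which(sex == sx)
    if (length(idx))
      meas[idx, ] <- draw_arterial_measures(config, length(idx), sx)
  }
  # covariates: middle-aged community cohort (45-64 y at baseline)
  age <- pmin(pmax(round(stats::rnorm(n, 54, 5.7)), 45), 64)
  race <- ifelse(stats::runif(n) < 0.27, "black", "white")
  height <- ifelse(sex == "M",
                   stats::rnorm(n, 176.2, 6.4),
                   stats::rnorm(n, 162.5, 5.9))
  prevalent <- as.integer(stats::runif(n) < config$prevalent_fraction)
  meas$sex <- sex
  meas <- draw_outcomes(meas, config)
  cohort <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    sex = sex, age = age, race = race, height_cm = round(height, 1),
    r_imt_mm = meas$r_imt_mm, l_imt_mm = meas$l_imt_mm,
    r_dia_mm = meas$r_dia_mm, l_dia_mm = meas$l_dia_mm,
    event = meas$event, time_years = meas$time_years,
    prevalent_stroke = prevalent,
    stringsAsFactors = FALSE)
  if (config$missing_fraction > 0) {
    hit <- stats::runif(n) < config$missing_fraction
    which_col <- sample(c("r_imt_mm", "l_imt_mm", "r_dia_mm", "l_dia_mm"),
                        n, replace = TRUE)
    for (cc in unique(which_col[hit]))
      cohort[hit & which_col == cc, cc] <- NA_real_
  }
  cohort
}

#' Write / read a cohort CSV
#'
#' Fixed schema with header
#' `subject_id,sex,age,race,height_cm,r_imt_mm,l_imt_mm,r_dia_mm,l_dia_mm,event,time_years,prevalent_stroke`.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data frame and errors on schema violations.
#' @export
write_cohort_csv <- function(cohort, path) {
  schema <- cohort_schema()
  missing_cols <- setdiff(schema, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(cohort[schema], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- cohort_schema()
  if (!identical(names(df), schema))
    stop("cohort CSV header mismatch at column(s): ",
         paste(which(names(df) != schema[seq_along(names(df))]), collapse = ", "),
         "; expected exactly: ", paste(schema, collapse = ","))
  for (col in c("event", "prevalent_stroke")) {
    bad <- which(!df[[col]] %in% c(0L, 1L))
    if (length(bad))
      stop(sprintf("column %s must be 0/1; offending row(s): %s",
                   col, paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad_t <- which(!is.na(df$time_years) & df$time_years <= 0)
  if (length(bad_t))
    stop("time_years must be positive; offending row(s): ",
         paste(utils::head(bad_t, 5), collapse = ", "))
  df
}

cohort_schema <- function() {
  c("subject_id", "sex", "age", "race", "height_cm",
    "r_imt_mm", "l_imt_mm", "r_dia_mm", "l_dia_mm",
    "event", "time_years", "prevalent_stroke")
}
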