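#' Build a 2x2 phenotype-positivity vs incident-stroke table
#'
#' A subject is test-positive iff their bilateral phenotype id belongs to
#' `positive_set`. Cells: `tp` = positive with incident stroke, `fp` =
#' positive without, `fn` = negative with stroke, `tn` = negative without.
#'
#' @param classified Classified cohort with `phenotype_id`, `event`, `sex`.
#' @param positive_set Integer phenotype ids defining test positivity
#'   (subset of 1..10), or the name of a combined set (see
#'   [combined_sets()]).
#' @param sex "M", "F", or "all".
#' @return List of class `two_by_two` with integer `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' # counts partition the stratum: tp+fp+fn+tn == n
two_by_two <- function(classified, positive_set, sex = c("all", "M", "F")) {
  sex <- match.arg(sex)
  if (is.character(positive_set)) {
    sets <- combined_sets()
    if (!positive_set %in% names(sets))
      stop("unknown combined set: ", positive_set)
    positive_set <- sets[[positive_set]]
  }
  if (!all(positive_set %in% 1:10))
    stop("positive_set must be a subset of phenotype ids 1..10")
  sub <- if (sex == "all") classified else classified[classified$sex == sex, ]
  if (!nrow(sub)) stop("empty stratum for sex = ", sex)
  pos <- sub$phenotype_id %in% positive_set
  ev <- sub$event == 1
  structure(list(tp = sum(pos & ev), fp = sum(pos & !ev),
                 fn = sum(!pos & ev), tn = sum(!pos & !ev)),
            class = "two_by_two")
}

#' 2x2 table directly from counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return A `two_by_two` object.
#' @export
two_by_two_counts <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "two_by_two")
}

#' Diagnostic-accuracy metrics with log-method likelihood-ratio CIs
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive likelihood
#' ratio `sens/(1-spec)` and negative likelihood ratio `(1-sens)/spec`.
#' The 95% CIs for the LRs use the delta method on the log of a ratio of
#' two binomial proportions (the Simel log method):
#' \deqn{SE(\ln LR^+) = \sqrt{1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)}}
#' and symmetrically with `fn`/`tn` in place of `tp`/`fp` for LR-.
#'
#' Any zero cell triggers a 0.5 continuity correction applied to all four
#' cells, flagged in the result.
#'
#' @param t A `two_by_two` table.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `sensitivity`, `specificity`, `plr`, `plr_ci`, `nlr`,
#'   `nlr_ci`, `corrected` (logical flag).
#' @export
diagnostic_metrics <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$tp + t$fn == 0) stop("no events: sensitivity undefined")
  if (t$fp + t$tn == 0) stop("no non-events: specificity undefined")
  cells <- c(t$tp, t$fp, t$fn, t$tn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  tp <- cells[1]; fp <- cells[2]; fn <- cells[3]; tn <- cells[4]
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  plr <- sens / (1 - spec)
  nlr <- (1 - sens) / spec
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_plr <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
  se_nlr <- sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
  list(sensitivity = sens, specificity = spec,
       plr = plr, plr_ci = plr * exp(c(-1, 1) * z * se_plr),
       nlr = nlr, nlr_ci = nlr * exp(c(-1, 1) * z * se_nlr),
       corrected = corrected)
}

#' Cumulative incidence in percent
#'
#' @param n_events Number of incident events.
#' @param n Number at risk (> 0).
#' @return `100 * n_events / n` (percent, full precision).
#' @export
cumulative_incidence <- function(n_events, n) {
  if (any(n <= 0)) stop("n must be positive")
  100 * n_events / n
}

#' Unadjusted relative risk of cumulative incidence
#'
#' Ratio of exposed to reference cumulative incidence with a log-delta
#' 95% CI: `SE(ln RR) = sqrt(1/a - 1/n1 + 1/b - 1/n0)`. A reference group
#' with zero events yields an infinite RR with a one-sided lower bound.
#'
#' @param exposed,reference Length-2 vectors `c(events, n)`.
#' @param conf_level Confidence level.
#' @return List with `rr` and `ci`.
#' @export
relative_risk <- function(exposed, reference, conf_level = 0.95) {
  a <- exposed[1]; n1 <- exposed[2]
  b <- reference[1]; n0 <- reference[2]
  if (n1 <= 0 || n0 <= 0) stop("group sizes must be positive")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (b == 0) {
    # one-sided: lower bound from a 0.5-corrected reference
    rr_lo <- ((a / n1) / ((b + 0.5) / n0)) *
      exp(-z * sqrt(1 / max(a, 0.5) - 1 / n1 + 1 / 0.5 - 1 / n0))
    return(list(rr = Inf, ci = c(rr_lo, Inf)))
  }
  rr <- (a / n1) / (b / n0)
  if (a == 0) return(list(rr = 0, ci = c(0, NA_real_)))
  se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n0)
  list(rr = rr, ci = rr * exp(c(-1, 1) * z * se))
}

#' Diagnostic report over phenotype positivity definitions
#'
#' Computes the full diagnostic-accuracy panel (sensitivity, specificity,
#' +/-LR with CIs) per sex for a set of positivity definitions — by
#' default phenotype 1 alone plus the six combined sets.
#'
#' @param classified Classified cohort.
#' @param definitions Named list of phenotype-id vectors.
#' @return Data frame, one row per (definition, sex).
#' @export
diagnostics_report <- function(classified,
                               definitions = c(list(BOTH_BILAT = 1L),
                                               combined_sets())) {
  sexes <- sort(unique(classified$sex))
  out <- do.call(rbind, lapply(names(definitions), function(nm) {
    do.call(rbind, lapply(sexes, function(sx) {
      t22 <- two_by_two(classified, definitions[[nm]], sx)
      m <- tryCatch(diagnostic_metrics(t22), error = function(e) NULL)
      if (is.null(m))  # stratum without events (or non-events): undefined
        m <- list(sensitivity = NA_real_, specificity = NA_real_,
                  plr = NA_real_, plr_ci = c(NA_real_, NA_real_),
                  nlr = NA_real_, nlr_ci = c(NA_real_, NA_real_))
      data.frame(definition = nm, sex = sx,
                 n_events = t22$tp + t22$fn,
                 tp = t22$tp, fp = t22$fp, fn = t22$fn, tn = t22$tn,
                 sensitivity = round(m$sensitivity, 2),
                 specificity = round(m$specificity, 2),
                 plr = round(m$plr, 2),
                 plr_lo = round(m$plr_ci[1], 2), plr_hi = round(m$plr_ci[2], 2),
                 nlr = round(m$nlr, 2),
                 nlr_lo = round(m$nlr_ci[1], 2), nlr_hi = round(m$nlr_ci[2], 2),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' 2x2 tables from a printed per-phenotype count table
#'
#' Derives the `two_by_two` for a positivity definition directly from a
#' per-id table of subjects and events (e.g. a published phenotype table),
#' without subject-level data.
#'
#' @param phenotype_table Data frame with `sex`, `phenotype_id`, `n`,
#'   `n_events` covering ids 1..10.
#' @param positive_set Phenotype ids or combined-set name.
#' @param sex Sex stratum present in the table.
#' @return A `two_by_two` object.
#' @export
two_by_two_from_counts <- function(phenotype_table, positive_set, sex) {
  if (is.character(positive_set)) {
    sets <- combined_sets()
    if (!positive_set %in% names(sets))
      stop("unknown combined set: ", positive_set)
    positive_set <- sets[[positive_set]]
  }
  sub <- phenotype_table[phenotype_table$sex == sex, ]
  if (!nrow(sub)) stop("empty stratum for sex = ", sex)
  pos <- sub$phenotype_id %in% positive_set
  tp <- sum(sub$n_events[pos]); fn <- sum(sub$n_events[!pos])
  fp <- sum(sub$n[pos]) - tp;   tn <- sum(sub$n[!pos]) - fn
  two_by_two_counts(tp, fp, fn, tn)
}
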