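#' Published per-phenotype subject and incident-stroke counts
#'
#' The per-sex counts of subjects and incident ischemic strokes across the
#' ten bilateral CCA phenotypes reported for a large US community cohort
#' of middle-aged adults (baseline ultrasound 1987-89, stroke follow-up
#' through 1999; 4014 women with 66 strokes, 3262 men with 115). These
#' printed counts are the substrate for the diagnostic-accuracy panel:
#' every sensitivity, specificity and likelihood ratio of the published
#' summary is reproducible from them via [two_by_two_from_counts()] and
#' [diagnostic_metrics()].
#'
#' @return Data frame with columns `sex`, `phenotype_id`, `n`, `n_events`.
#' @export
reference_phenotype_counts <- function() {
  rbind(
    data.frame(sex = "F", phenotype_id = 1:10,
               n = c(852L, 271L, 448L, 206L, 322L, 106L, 504L, 269L, 283L, 753L),
               n_events = c(42L, 4L, 6L, 1L, 6L, 1L, 1L, 1L, 2L, 2L)),
    data.frame(sex = "M", phenotype_id = 1:10,
               n = c(662L, 229L, 370L, 172L, 223L, 86L, 417L, 223L, 270L, 610L),
               n_events = c(51L, 12L, 19L, 1L, 10L, 0L, 7L, 5L, 3L, 7L)))
}

#' Published sex- and side-specific median arterial measures
#'
#' The reference median table (mm) for right/left CCA far-wall IMT and
#' external diameter in the same cohort: an externally supplied
#' [compute_medians()]-shaped table usable for classification in place of
#' sample medians.
#'
#' @return Data frame with columns `sex`, `side`, `parameter`, `median_mm`.
#' @export
reference_medians <- function() {
  data.frame(
    sex = rep(c("M", "F"), each = 4),
    side = rep(c("R", "R", "L", "L"), 2),
    parameter = rep(c("IMT", "diameter"), 4),
    median_mm = c(0.663, 8.092, 0.676, 7.997,
                  0.609, 7.303, 0.603, 7.199),
    stringsAsFactors = FALSE)
}
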