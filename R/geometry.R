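#' @keywords internal
"_PACKAGE"

#' Per-side geometric categories
#'
#' The four mutually exclusive patterns obtained by dichotomizing a CCA's
#' intima-media thickness (IMT) and external diameter at their sex- and
#' side-specific medians: both large, only IMT large, only diameter large,
#' or neither large (the reference pattern).
#'
#' @return Character vector of the four category codes, in display order.
#' @export
geometry_levels <- function() c("BOTH", "IMT_ONLY", "DIA_ONLY", "NEITHER")

# 4x4 lookup: rows = right category, cols = left category, in
# geometry_levels() order. Symmetric off-diagonal entries collapse the 16
# ordered pairs onto the 10 non-overlapping bilateral phenotypes.
.phenotype_lookup <- matrix(
  c(1, 2, 3, 4,
    2, 5, 6, 7,
    3, 6, 8, 9,
    4, 7, 9, 10),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("BOTH", "IMT_ONLY", "DIA_ONLY", "NEITHER"),
                  c("BOTH", "IMT_ONLY", "DIA_ONLY", "NEITHER"))
)

#' Bilateral phenotype labels
#'
#' Display labels for the ten non-overlapping bilateral CCA phenotypes,
#' ordered by phenotype id (1 = IMT and diameter both large bilaterally,
#' 10 = nothing large on either side, the reference).
#'
#' @return Named character vector of length 10 (names are the ids).
#' @export
phenotype_labels <- function() {
  c(`1`  = "IMT and diameter both large bilaterally",
    `2`  = "IMT and diameter large on one side and opposite IMT large (bilaterally large IMT)",
    `3`  = "IMT and diameter large on one side and opposite diameter large (bilaterally large diameter)",
    `4`  = "IMT and diameter large on one side and neither opposite IMT nor diameter large",
    `5`  = "Bilaterally large IMT, no large diameter",
    `6`  = "Unilaterally large IMT (R or L) and opposite diameter large",
    `7`  = "Unilaterally large IMT (R or L) and no large diameter",
    `8`  = "Bilaterally large diameter, no large IMT",
    `9`  = "Unilaterally large diameter (R or L), no large IMT",
    `10` = "No IMT or diameter large")
}

#' Combined phenotype sets
#'
#' Named unions of bilateral phenotype ids used as composite "test positive"
#' definitions, e.g. `IMT_BILAT` is "IMT large bilaterally regardless of
#' diameter" = phenotypes {1, 2, 5}.
#'
#' @return Named list of integer vectors of phenotype ids.
#' @export
combined_sets <- function() {
  list(IMT_BILAT      = c(1L, 2L, 5L),
       DIA_BILAT      = c(1L, 3L, 8L),
       ANY_BILAT      = c(1L, 2L, 3L, 5L, 8L),
       SAME_SIDE_BOTH = c(1L, 2L, 3L, 4L),
       ANY_IMT        = 1:7,
       ANY_DIA        = c(1L, 2L, 3L, 4L, 6L, 8L, 9L))
}

#' Combined-set membership of a phenotype id
#'
#' @param id Integer phenotype id in 1..10.
#' @return Character vector of the combined-set names whose defining id
#'   lists contain `id` (possibly empty).
#' @export
#' @examples
#' combined_membership(1)   # belongs to all six sets
#' combined_membership(10)  # belongs to none
combined_membership <- function(id) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 10L)
    stop("phenotype id must be a single integer in 1..10")
  sets <- combined_sets()
  names(sets)[vapply(sets, function(s) id %in% s, logical(1))]
}

#' Sex-, side- and parameter-specific medians of arterial measures
#'
#' Computes the 8-cell median table (2 sexes x 2 sides x {IMT, diameter})
#' used to dichotomize each measurement as large (>= median) or not large.
#' Sample medians use the default `stats::median` convention: for even n,
#' the mean of the two central order statistics.
#'
#' @param cohort Data frame with columns `sex` ("M"/"F"), `r_imt_mm`,
#'   `l_imt_mm`, `r_dia_mm`, `l_dia_mm`.
#' @return Data frame with columns `sex`, `side` ("R"/"L"), `parameter`
#'   ("IMT"/"diameter"), `median_mm`.
#' @export
compute_medians <- function(cohort) {
  cols <- c(R.IMT = "r_imt_mm", L.IMT = "l_imt_mm",
            R.diameter = "r_dia_mm", L.diameter = "l_dia_mm")
  missing_cols <- setdiff(c("sex", unname(cols)), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  out <- expand.grid(sex = c("M", "F"), side = c("R", "L"),
                     parameter = c("IMT", "diameter"),
                     stringsAsFactors = FALSE)
  out$median_mm <- mapply(function(sex, side, param) {
    v <- cohort[[cols[paste(side, param, sep = ".")]]][cohort$sex == sex]
    v <- v[!is.na(v)]
    if (!length(v))
      stop(sprintf("no non-missing %s %sCCA %s values to take a median of",
                   if (sex == "M") "male" else "female", side, param))
    stats::median(v)
  }, out$sex, out$side, out$parameter)
  out
}

#' Look up one cell of a median table
#'
#' @param medians Median table as returned by [compute_medians()].
#' @param sex "M" or "F".
#' @param side "R" or "L".
#' @param parameter "IMT" or "diameter".
#' @return Median in mm (scalar).
#' @export
median_for <- function(medians, sex, side, parameter) {
  i <- which(medians$sex == sex & medians$side == side &
               medians$parameter == parameter)
  if (length(i) != 1L)
    stop(sprintf("median table has no entry for sex=%s side=%s parameter=%s",
                 sex, side, parameter))
  medians$median_mm[i]
}

#' Classify one CCA side into a geometric category
#'
#' A parameter is "large" when it is at or above its median (the boundary
#' value counts as large); the four combinations of large IMT and large
#' diameter give the category.
#'
#' @param imt,dia Measured IMT and external diameter in mm (vectors).
#' @param imt_median,dia_median Dichotomization cut points in mm.
#' @return Factor with levels [geometry_levels()].
#' @export
#' @examples
#' classify_side(0.70, 8.20, 0.663, 8.092)  # BOTH
#' classify_side(0.663, 8.00, 0.663, 8.092) # IMT_ONLY (ties are large)
classify_side <- function(imt, dia, imt_median, dia_median) {
  if (anyNA(imt) || anyNA(dia))
    stop("missing arterial measurement; subjects with any missing CCA measure must be excluded")
  if (any(imt <= 0) || any(dia <= 0) || imt_median <= 0 || dia_median <= 0)
    stop("arterial measures and medians must be positive")
  imt_large <- imt >= imt_median
  dia_large <- dia >= dia_median
  code <- ifelse(imt_large & dia_large, "BOTH",
          ifelse(imt_large, "IMT_ONLY",
          ifelse(dia_large, "DIA_ONLY", "NEITHER")))
  factor(code, levels = geometry_levels())
}

#' Reduce an ordered right/left category pair to a bilateral phenotype id
#'
#' The 16 ordered pairs collapse onto 10 non-overlapping phenotypes; the
#' mapping is symmetric in right and left for all mixed pairs.
#'
#' @param right,left Geometry categories (character or factor, vectors).
#' @return Integer phenotype ids in 1..10.
#' @export
bilateral_phenotype <- function(right, left) {
  r <- as.character(right)
  l <- as.character(left)
  bad <- !(r %in% geometry_levels()) | !(l %in% geometry_levels())
  if (any(bad))
    stop("invalid geometry category: ",
         paste(unique(c(r[bad], l[bad])), collapse = ", "))
  as.integer(.phenotype_lookup[cbind(r, l)])
}

#' Classify a cohort: per-side geometries and bilateral phenotype
#'
#' Appends `r_geometry`, `l_geometry` and `phenotype_id` to a cohort table,
#' using sex- and side-specific medians either computed from the cohort
#' itself (the default, mirroring a study-sample median split) or supplied
#' externally.
#'
#' @param cohort Cohort data frame (see [compute_medians()] for required
#'   columns).
#' @param medians Optional median table; computed from `cohort` when `NULL`.
#' @return `cohort` with the three classification columns appended.
#' @export
classify_cohort <- function(cohort, medians = NULL) {
  if (is.null(medians)) medians <- compute_medians(cohort)
  for (sx in unique(cohort$sex)) {
    if (!sx %in% medians$sex)
      stop("median table has no entries for sex ", sx)
  }
  r_geom <- l_geom <- character(nrow(cohort))
  for (sx in unique(cohort$sex)) {
    idx <- cohort$sex == sx
    r_geom[idx] <- as.character(classify_side(
      cohort$r_imt_mm[idx], cohort$r_dia_mm[idx],
      median_for(medians, sx, "R", "IMT"),
      median_for(medians, sx, "R", "diameter")))
    l_geom[idx] <- as.character(classify_side(
      cohort$l_imt_mm[idx], cohort$l_dia_mm[idx],
      median_for(medians, sx, "L", "IMT"),
      median_for(medians, sx, "L", "diameter")))
  }
  cohort$r_geometry <- factor(r_geom, levels = geometry_levels())
  cohort$l_geometry <- factor(l_geom, levels = geometry_levels())
  cohort$phenotype_id <- bilateral_phenotype(r_geom, l_geom)
  cohort
}

#' Tabulate phenotype counts, incident strokes and cumulative incidence
#'
#' Produces the per-sex phenotype table: for each phenotype id 1..10 the
#' number of subjects, the number of incident events and the cumulative
#' incidence in percent (1 decimal). Counts over the ten ids always sum to
#' the stratum size.
#'
#' @param classified Classified cohort (needs `sex`, `phenotype_id`,
#'   `event`).
#' @return Data frame with columns `sex`, `phenotype_id`, `label`, `n`,
#'   `n_events`, `incidence_pct`.
#' @export
tabulate_phenotypes <- function(classified) {
  need <- c("sex", "phenotype_id", "event")
  missing_cols <- setdiff(need, names(classified))
  if (length(missing_cols))
    stop("classified cohort is missing columns: ",
         paste(missing_cols, collapse = ", "))
  sexes <- sort(unique(classified$sex))
  out <- do.call(rbind, lapply(sexes, function(sx) {
    sub <- classified[classified$sex == sx, ]
    id <- factor(sub$phenotype_id, levels = 1:10)
    n <- as.integer(table(id))
    ev <- as.integer(tapply(sub$event, id, sum, default = 0L))
    data.frame(sex = sx, phenotype_id = 1:10,
               label = unname(phenotype_labels()),
               n = n, n_events = ev,
               incidence_pct = ifelse(n > 0, round(100 * ev / n, 1), NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Combined-phenotype counts from a per-id phenotype table
#'
#' Sums subjects and events over the constituent ids of each combined
#' phenotype set. Accepts either the output of [tabulate_phenotypes()] or
#' any table of printed per-id counts with the same columns, so published
#' per-phenotype rows can be aggregated directly.
#'
#' @param phenotype_table Data frame with `sex`, `phenotype_id`, `n`,
#'   `n_events`.
#' @return Data frame with `sex`, `set`, `ids` (comma-joined), `n`,
#'   `n_events`, `incidence_pct`.
#' @export
combined_counts <- function(phenotype_table) {
  sets <- combined_sets()
  sexes <- unique(phenotype_table$sex)
  out <- do.call(rbind, lapply(sexes, function(sx) {
    sub <- phenotype_table[phenotype_table$sex == sx, ]
    do.call(rbind, lapply(names(sets), function(nm) {
      ids <- sets[[nm]]
      rows <- sub[sub$phenotype_id %in% ids, ]
      n <- sum(rows$n)
      ev <- sum(rows$n_events)
      data.frame(sex = sx, set = nm,
                 ids = paste(ids, collapse = ","),
                 n = n, n_events = ev,
                 incidence_pct = ifelse(n > 0, round(100 * ev / n, 1), NA_real_),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
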