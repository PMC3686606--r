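#' Right-left agreement table of geometry categories
#'
#' Cross-tabulates each subject's right-side category against the
#' left-side category for one sex stratum (or the pooled cohort).
#'
#' @param classified Classified cohort with `r_geometry`, `l_geometry` and
#'   `sex`.
#' @param sex "M", "F", or "all" for the pooled table.
#' @return 4x4 integer matrix, rows = right category, columns = left
#'   category, in [geometry_levels()] order.
#' @export
build_agreement_table <- function(classified, sex = c("all", "M", "F")) {
  sex <- match.arg(sex)
  sub <- if (sex == "all") classified else classified[classified$sex == sex, ]
  r <- factor(sub$r_geometry, levels = geometry_levels())
  l <- factor(sub$l_geometry, levels = geometry_levels())
  tab <- table(right = r, left = l)
  m <- matrix(as.integer(tab), 4, 4,
              dimnames = list(geometry_levels(), geometry_levels()))
  m
}

#' Cohen's kappa for a square agreement table
#'
#' Unweighted kappa: `(p_o - p_e) / (1 - p_e)` where `p_o` is the observed
#' diagonal proportion and `p_e` the chance agreement from the row and
#' column marginals. The 95% CI uses the large-sample variance
#' `p_o (1 - p_o) / (n (1 - p_e)^2)`.
#'
#' @param table Square count matrix (rows = rater 1 / right side,
#'   columns = rater 2 / left side).
#' @return List with `kappa`, `se`, `ci` (length-2), `p_o`, `p_e`, `n`.
#'   Degenerate marginals (`p_e = 1`) give `kappa = NA` with a message
#'   field explaining why.
#' @export
cohens_kappa <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != ncol(m)) stop("agreement table must be square")
  n <- sum(m)
  if (n < 2) stop("need at least 2 subjects for kappa")
  p <- m / n
  p_o <- sum(diag(p))
  p_e <- sum(rowSums(p) * colSums(p))
  if (1 - p_e < .Machine$double.eps ^ 0.5) {
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                p_o = p_o, p_e = p_e, n = n,
                message = "degenerate marginals: chance agreement is 1, kappa undefined"))
  }
  k <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  list(kappa = k, se = se, ci = k + c(-1, 1) * stats::qnorm(0.975) * se,
       p_o = p_o, p_e = p_e, n = n)
}

#' Category-specific right-left agreement with bootstrap CI
#'
#' Positive (specific) agreement for one category c:
#' `2 n_cc / (row_c + col_c)`, as a percent — the chance a randomly chosen
#' side classified as c finds the opposite side classified as c too. The
#' paper-style per-category agreement column is not formula-defined in the
#' source material for this design; specific agreement is the standard
#' companion statistic to kappa and is used here (reported as such).
#'
#' The CI resamples subjects: the 16 cells are multinomial over subjects,
#' so a seeded multinomial redraw of the full table is an exact subject
#' bootstrap.
#'
#' @param table 4x4 agreement table.
#' @param category Category code (one of [geometry_levels()]).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap stream.
#' @return List with `agreement_pct`, `ci` (percentile 95% CI), `n_cc`,
#'   `margin`. Zero combined margin gives `NA` with a message.
#' @export
category_specific_agreement <- function(table, category, n_boot = 2000,
                                        seed = 1L) {
  m <- as.matrix(table)
  lev <- geometry_levels()
  if (!category %in% lev) stop("unknown category: ", category)
  ci_idx <- match(category, lev)
  point <- specific_agreement_value(m, ci_idx)
  if (is.na(point))
    return(list(agreement_pct = NA_real_, ci = c(NA_real_, NA_real_),
                n_cc = m[ci_idx, ci_idx],
                margin = sum(m[ci_idx, ]) + sum(m[, ci_idx]),
                message = "category margin is zero: agreement undefined"))
  n <- sum(m)
  probs <- as.vector(m) / n
  set.seed(seed)
  draws <- stats::rmultinom(n_boot, size = n, prob = probs)
  boot <- apply(draws, 2, function(v)
    specific_agreement_value(matrix(v, 4, 4), ci_idx))
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(agreement_pct = point, ci = ci,
       n_cc = m[ci_idx, ci_idx],
       margin = sum(m[ci_idx, ]) + sum(m[, ci_idx]))
}

specific_agreement_value <- function(m, i) {
  denom <- sum(m[i, ]) + sum(m[, i])
  if (denom == 0) return(NA_real_)
  100 * 2 * m[i, i] / denom
}

#' Prevalence-and-concordance report table
#'
#' Per-category right and left prevalence plus the category-specific
#' right-left agreement, per sex and pooled — the concordance summary of
#' the analysis.
#'
#' @param classified Classified cohort.
#' @param n_boot,seed Passed to [category_specific_agreement()].
#' @return Data frame with columns `sex`, `category`, `n_right`,
#'   `pct_right`, `n_left`, `pct_left`, `agreement_pct`, `ci_low`,
#'   `ci_high`.
#' @export
concordance_report <- function(classified, n_boot = 2000, seed = 1L) {
  strata <- c(sort(unique(classified$sex)), "all")
  out <- do.call(rbind, lapply(strata, function(sx) {
    tab <- build_agreement_table(classified, sx)
    n <- sum(tab)
    do.call(rbind, lapply(seq_along(geometry_levels()), function(i) {
      cat_i <- geometry_levels()[i]
      ag <- category_specific_agreement(tab, cat_i, n_boot = n_boot,
                                        seed = seed + i)
      data.frame(sex = sx, category = cat_i,
                 n_right = sum(tab[i, ]),
                 pct_right = round(100 * sum(tab[i, ]) / n, 1),
                 n_left = sum(tab[, i]),
                 pct_left = round(100 * sum(tab[, i]) / n, 1),
                 agreement_pct = ag$agreement_pct,
                 ci_low = ag$ci[1], ci_high = ag$ci[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
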