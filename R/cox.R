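#' Cox proportional-hazards fit by Newton-Raphson partial likelihood
#'
#' From-scratch maximization of the Cox log partial likelihood with
#' Breslow (default) or Efron handling of tied event times. Standard
#' errors come from the inverse observed information at the maximum;
#' hazard ratios are `exp(beta)` with Wald 95% CIs.
#'
#' Convergence is declared when `max |gradient| < 1e-8` or the relative
#' change in log partial likelihood falls below `1e-10`. Step-halving
#' guards the Newton updates; a coefficient escaping past +/-15 signals a
#' monotone likelihood (complete separation) and errors explicitly.
#'
#' @param time Positive follow-up times.
#' @param status Event indicator, 1 = event, 0 = censored.
#' @param x Numeric design matrix (columns are named terms).
#' @param ties "breslow" or "efron". The two agree exactly on tie-free
#'   data.
#' @param max_iter Iteration cap.
#' @return Object of class `cox_fit`: `coef`, `se`, `hr`, `hr_ci` (matrix),
#'   `p_value`, `loglik` (c(null, final)), `iterations`, `gradient_norm`,
#'   `vcov`, `ties`, `n`, `n_events`.
#' @export
fit_cox <- function(time, status, x, ties = c("breslow", "efron"),
                    max_iter = 50L) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- length(time)
  stopifnot(length(status) == n, nrow(x) == n)
  if (any(time <= 0)) stop("all times must be positive")
  if (sum(status) < 1) stop("need at least one event")
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    drop_terms <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop("design matrix rank-deficient; collinear term(s): ",
         paste(drop_terms, collapse = ", "))
  }
  p <- ncol(x)

  # sort by decreasing time so the risk set at any event time is a prefix
  ord <- order(time, decreasing = TRUE)
  tt <- time[ord]; dd <- status[ord]; xx <- x[ord, , drop = FALSE]
  event_times <- unique(tt[dd == 1])
  # prefix end-index of each event time's risk set {j : t_j >= t}
  risk_end <- vapply(event_times, function(t0) max(which(tt == t0)), integer(1))
  death_idx <- lapply(event_times, function(t0) which(tt == t0 & dd == 1))

  pl <- function(beta) cox_pl_terms(beta, xx, risk_end, death_idx, ties)

  beta <- rep(0, p)
  cur <- pl(beta)
  loglik0 <- cur$ll
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- solve(cur$info, cur$grad)
    new_beta <- beta + step
    new <- pl(new_beta)
    halvings <- 0L
    while ((!is.finite(new$ll) || new$ll < cur$ll) && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new <- pl(new_beta)
      halvings <- halvings + 1L
    }
    if (any(abs(new_beta) > 15))
      stop("monotone partial likelihood (separation): coefficient diverging for term(s) ",
           paste(colnames(x)[abs(new_beta) > 15], collapse = ", "))
    rel_change <- abs(new$ll - cur$ll) / (abs(cur$ll) + 1e-12)
    beta <- new_beta; cur <- new
    if (max(abs(cur$grad)) < 1e-8 || rel_change < 1e-10 || iter >= max_iter)
      break
  }
  vcov <- solve(cur$info)
  se <- sqrt(diag(vcov))
  z <- stats::qnorm(0.975)
  hr_ci <- cbind(lo = exp(beta - z * se), hi = exp(beta + z * se))
  names(beta) <- names(se) <- colnames(x)
  rownames(hr_ci) <- colnames(x)
  dimnames(vcov) <- list(colnames(x), colnames(x))
  structure(list(coef = beta, se = se, hr = exp(beta), hr_ci = hr_ci,
                 p_value = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = c(null = loglik0, final = cur$ll),
                 iterations = iter, gradient_norm = max(abs(cur$grad)),
                 vcov = vcov, ties = ties, n = n, n_events = sum(status)),
            class = "cox_fit")
}

# log partial likelihood + gradient + observed information at beta.
# xx sorted by decreasing time; risk_end[k] is the prefix length of the
# k-th event time's risk set; death_idx[[k]] the tied deaths there.
cox_pl_terms <- function(beta, xx, risk_end, death_idx, ties) {
  p <- ncol(xx)
  eta <- drop(xx %*% beta)
  eta <- pmin(eta, 500)   # overflow guard; ll comparison still valid
  w <- exp(eta)
  cs0 <- cumsum(w)
  xw <- xx * w
  cs1 <- apply(xw, 2, cumsum)
  if (!is.matrix(cs1)) cs1 <- matrix(cs1, nrow = nrow(xx))
  # p x p cumulative second-moment sums, stored flattened n x (p*p)
  cs2 <- matrix(0, nrow(xx), p * p)
  for (i in seq_len(p)) for (j in i:p) {
    v <- cumsum(xx[, i] * xw[, j])
    cs2[, (i - 1) * p + j] <- v
    if (i != j) cs2[, (j - 1) * p + i] <- v
  }
  ll <- 0
  grad <- rep(0, p)
  info <- matrix(0, p, p)
  for (k in seq_along(risk_end)) {
    m <- risk_end[k]
    deaths <- death_idx[[k]]
    d <- length(deaths)
    S0 <- cs0[m]
    S1 <- cs1[m, ]
    S2 <- matrix(cs2[m, ], p, p)
    xd <- xx[deaths, , drop = FALSE]
    ll <- ll + sum(eta[deaths])
    grad <- grad + colSums(xd)
    if (ties == "breslow" || d == 1L) {
      ll <- ll - d * log(S0)
      mu <- S1 / S0
      grad <- grad - d * mu
      info <- info + d * (S2 / S0 - tcrossprod(mu))
    } else {
      s0d <- sum(w[deaths])
      s1d <- colSums(xw[deaths, , drop = FALSE])
      s2d <- crossprod(xd, xw[deaths, , drop = FALSE])
      s2d <- (s2d + t(s2d)) / 2
      for (r in 0:(d - 1L)) {
        f <- r / d
        den <- S0 - f * s0d
        num1 <- S1 - f * s1d
        num2 <- S2 - f * s2d
        ll <- ll - log(den)
        mu <- num1 / den
        grad <- grad - mu
        info <- info + num2 / den - tcrossprod(mu)
      }
    }
  }
  list(ll = ll, grad = grad, info = info)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n=%d, events=%d, iterations=%d, |grad|=%.2e\n",
              x$ties, x$n, x$n_events, x$iterations, x$gradient_norm))
  tab <- data.frame(coef = x$coef, se = x$se, hr = x$hr,
                    lo = x$hr_ci[, "lo"], hi = x$hr_ci[, "hi"],
                    p = signif(x$p_value, 3))
  print(round(tab, 4))
  invisible(x)
}

#' Wald hazard-ratio interval for one model term
#'
#' @param fit A `cox_fit`.
#' @param term Term name.
#' @param conf_level Confidence level.
#' @return Named vector `c(hr, lo, hi)`. A zero SE yields a degenerate
#'   interval and a warning.
#' @export
wald_interval <- function(fit, term, conf_level = 0.95) {
  if (!term %in% names(fit$coef)) stop("no term named ", term, " in fit")
  b <- fit$coef[[term]]; s <- fit$se[[term]]
  if (s == 0) warning("zero standard error for ", term, ": degenerate interval")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(hr = exp(b), lo = exp(b - z * s), hi = exp(b + z * s))
}

#' Side-specific geometry design matrix
#'
#' Three indicator columns for the chosen side's geometry (BOTH, IMT_ONLY,
#' DIA_ONLY vs the NEITHER reference) plus any adjustment covariates,
#' ready for [fit_cox()].
#'
#' @param classified Classified cohort.
#' @param side "R" or "L".
#' @param covariates Character vector of cohort column names to append
#'   (numeric, or character columns which are expanded to 0/1 dummies
#'   against their first level).
#' @return List with `time`, `status`, `x`.
#' @export
geometry_design <- function(classified, side = c("R", "L"),
                            covariates = c("age", "race", "height_cm")) {
  side <- match.arg(side)
  g <- if (side == "R") classified$r_geometry else classified$l_geometry
  g <- factor(g, levels = geometry_levels())
  x <- cbind(BOTH = as.numeric(g == "BOTH"),
             IMT_ONLY = as.numeric(g == "IMT_ONLY"),
             DIA_ONLY = as.numeric(g == "DIA_ONLY"))
  for (cv in covariates) {
    col <- classified[[cv]]
    if (is.null(col)) stop("no covariate column named ", cv)
    if (is.character(col) || is.factor(col)) {
      col <- factor(col)
      for (lv in levels(col)[-1]) {
        x <- cbind(x, as.numeric(col == lv))
        colnames(x)[ncol(x)] <- paste0(cv, "_", lv)
      }
    } else {
      x <- cbind(x, as.numeric(col))
      colnames(x)[ncol(x)] <- cv
    }
  }
  list(time = classified$time_years, status = classified$event, x = x)
}

#' Backward covariate elimination with a change-in-estimate guard
#'
#' The retention rule of the analysis: exposure (geometry indicator) terms
#' and base covariates are always kept; candidate covariates are dropped
#' one at a time, least significant first, but only when (a) the Wald
#' p-value is at or above `alpha` AND (b) removal changes none of the
#' exposure coefficients by more than `delta` (relative, on the
#' coefficient / log-HR scale by default; "hr" measures the relative
#' change on the hazard-ratio scale instead). Every decision is logged.
#'
#' @param time,status,x As for [fit_cox()].
#' @param exposure_terms Column names of the always-kept exposure
#'   indicators whose stability defines confounding.
#' @param base_terms Column names always kept (e.g. age, race, height).
#' @param candidate_terms Columns eligible for elimination.
#' @param alpha Significance threshold for retention (default 0.05).
#' @param delta Change-in-estimate threshold (default 0.10 = 10%).
#' @param scale "coef" or "hr" for the change-in-estimate scale.
#' @param ties Tie handling passed to [fit_cox()].
#' @return List with `fit` (final `cox_fit`), `kept`, `dropped`, and
#'   `audit` — a data frame logging each step's term, p-value, max
#'   relative exposure-coefficient change and decision.
#' @export
select_covariates <- function(time, status, x, exposure_terms,
                              base_terms = c("age", "race_white", "height_cm"),
                              candidate_terms = NULL,
                              alpha = 0.05, delta = 0.10,
                              scale = c("coef", "hr"),
                              ties = "breslow") {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  base_terms <- intersect(base_terms, colnames(x))
  if (is.null(candidate_terms))
    candidate_terms <- setdiff(colnames(x), c(exposure_terms, base_terms))
  stopifnot(all(exposure_terms %in% colnames(x)),
            all(candidate_terms %in% colnames(x)))
  current <- c(exposure_terms, base_terms, candidate_terms)
  locked <- character(0)  # candidates retained by the delta rule
  audit <- data.frame(step = integer(0), term = character(0),
                      p_value = numeric(0), max_rel_change = numeric(0),
                      decision = character(0), stringsAsFactors = FALSE)
  step_i <- 0L
  fit <- fit_cox(time, status, x[, current, drop = FALSE], ties = ties)
  repeat {
    droppable <- setdiff(intersect(candidate_terms, current), locked)
    pv <- fit$p_value[droppable]
    pv <- pv[pv >= alpha]
    if (!length(pv)) break
    # drop the least significant first; name order breaks ties
    ord <- order(-pv, names(pv))
    decided <- FALSE
    for (term in names(pv)[ord]) {
      step_i <- step_i + 1L
      trial_terms <- setdiff(current, term)
      trial <- fit_cox(time, status, x[, trial_terms, drop = FALSE], ties = ties)
      b_old <- fit$coef[exposure_terms]
      b_new <- trial$coef[exposure_terms]
      if (scale == "hr") { b_old <- exp(b_old); b_new <- exp(b_new) }
      denom <- pmax(abs(b_old), 1e-8)
      chg <- max(abs(b_new - b_old) / denom)
      if (chg > delta) {
        locked <- c(locked, term)
        audit <- rbind(audit, data.frame(
          step = step_i, term = term, p_value = unname(fit$p_value[term]),
          max_rel_change = chg, decision = "kept (confounder: >delta change)",
          stringsAsFactors = FALSE))
      } else {
        current <- trial_terms
        fit <- trial
        audit <- rbind(audit, data.frame(
          step = step_i, term = term, p_value = unname(pv[term]),
          max_rel_change = chg, decision = "dropped (p>=alpha, <delta change)",
          stringsAsFactors = FALSE))
        decided <- TRUE
        break
      }
    }
    if (!decided) break
  }
  list(fit = fit, kept = current,
       dropped = setdiff(candidate_terms, current), audit = audit)
}
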