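# shared fixture: tie-free survival data with two covariates
sim_surv <- function(n = 400, seed = 7) {
  set.seed(seed)
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  rate <- 0.1 * exp(0.5 * x[, "a"] - 0.3 * x[, "b"])
  te <- rexp(n) / rate
  status <- as.integer(te < 8)
  time <- pmin(te, 8) + runif(n, 0, 1e-9)  # jitter: tie-free
  list(time = time, status = status, x = x)
}

test_that("symmetric two-group data gives a zero coefficient", {
  # mirrored event patterns: exchanging groups leaves the data invariant
  time <- c(1, 2, 3, 1, 2, 3)
  status <- rep(1L, 6)
  x <- matrix(c(1, 1, 1, 0, 0, 0), dimnames = list(NULL, "g"))
  # pair each event time across groups -> partial likelihood symmetric in sign
  fit <- fit_cox(time, status, x)
  expect_lt(abs(fit$coef[["g"]]), 1e-6)
  expect_lt(fit$gradient_norm, 1e-6)
})

test_that("the Newton fit matches a brute-force partial-likelihood maximization", {
  # 6-subject instance with interleaved groups (finite maximum)
  time <- 1:6
  status <- rep(1L, 6)
  x <- matrix(c(1, 0, 1, 0, 1, 0), dimnames = list(NULL, "g"))
  b_hat <- fit_cox(time, status, x)$coef[["g"]]
  b_brute <- brute_cox_1d(time, status, x)
  expect_equal(b_hat, b_brute, tolerance = 1e-6)
  # when one group holds all the earliest events the partial likelihood is
  # monotone in beta (no finite maximum) and the fitter must say so
  expect_error(fit_cox(1:6, rep(1L, 6),
                       matrix(c(1, 1, 1, 0, 0, 0), dimnames = list(NULL, "g"))),
               "separation|diverging")
  # randomized <=10-subject instances with censoring
  set.seed(42)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    time_i <- sort(runif(n, 1, 10)) # tie-free
    status_i <- rbinom(n, 1, 0.7)
    if (sum(status_i) == 0) status_i[1] <- 1L
    x_i <- matrix(rbinom(n, 1, 0.5), dimnames = list(NULL, "g"))
    if (length(unique(x_i[status_i == 1])) < 2 && length(unique(x_i)) < 2) next
    fit_i <- tryCatch(fit_cox(time_i, status_i, x_i), error = function(e) NULL)
    if (is.null(fit_i)) next  # separation detected: brute force unbounded too
    expect_equal(fit_i$coef[["g"]], brute_cox_1d(time_i, status_i, x_i),
                 tolerance = 1e-6)
  }
})

test_that("the fit agrees with the reference fitter on tie-free data to 1e-6", {
  s <- sim_surv()
  fit <- fit_cox(s$time, s$status, s$x)
  ref <- survival::coxph(survival::Surv(s$time, s$status) ~ s$x,
                         ties = "breslow")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  # Efron with ties against the reference too
  t2 <- ceiling(s$time)
  for (tie in c("breslow", "efron")) {
    fit_t <- fit_cox(t2, s$status, s$x, ties = tie)
    ref_t <- survival::coxph(survival::Surv(t2, s$status) ~ s$x, ties = tie)
    expect_equal(unname(fit_t$coef), unname(coef(ref_t)), tolerance = 1e-6)
  }
})

test_that("Breslow and Efron agree exactly on tie-free data and the score vanishes", {
  s <- sim_surv(seed = 13)
  f_b <- fit_cox(s$time, s$status, s$x, ties = "breslow")
  f_e <- fit_cox(s$time, s$status, s$x, ties = "efron")
  expect_equal(f_b$coef, f_e$coef, tolerance = 1e-12)
  expect_lt(f_b$gradient_norm, 1e-6)
  # likelihood at the maximum dominates the null
  expect_gte(f_b$loglik[["final"]], f_b$loglik[["null"]])
})

test_that("separation and rank deficiency are reported explicitly", {
  # perfect separation: only the x=1 group has events, early
  time <- c(1, 2, 3, 10, 11, 12)
  status <- c(1L, 1L, 1L, 0L, 0L, 0L)
  x <- matrix(c(1, 1, 1, 0, 0, 0), dimnames = list(NULL, "g"))
  expect_error(fit_cox(time, status, x), "separation|diverging")
  # duplicated column
  s <- sim_surv(n = 60, seed = 3)
  x2 <- cbind(s$x, dup = s$x[, "a"])
  expect_error(fit_cox(s$time, s$status, x2), "collinear")
})

test_that("Wald intervals follow the closed form and flag degenerate SEs", {
  s <- sim_surv(seed = 19)
  fit <- fit_cox(s$time, s$status, s$x)
  w <- wald_interval(fit, "a")
  b <- fit$coef[["a"]]; se <- fit$se[["a"]]
  z <- qnorm(0.975)
  expect_equal(unname(w),
               c(exp(b), exp(b - z * se), exp(b + z * se)), tolerance = 1e-12)
  # beta=0, SE=0.1 -> (1.00, 0.82, 1.22) at 2 decimals
  expect_equal(round(c(exp(0), exp(-z * 0.1), exp(z * 0.1)), 2),
               c(1.00, 0.82, 1.22))
  expect_error(wald_interval(fit, "zzz"), "no term")
  fit0 <- fit
  fit0$coef[["a"]] <- log(2); fit0$se[["a"]] <- 0
  expect_warning(w0 <- wald_interval(fit0, "a"), "degenerate")
  expect_equal(unname(w0), c(2, 2, 2))
})

# Constructed covariate-selection scenario: three geometry indicators plus
# age always kept; a collinear confounder whose own effect is weak (p >=
# alpha) but whose removal shifts the BOTH coefficient far beyond 10%; and
# an inert noise covariate.
make_selection_scenario <- function(seed = 3, n = 600) {
  set.seed(seed)
  x_both <- rbinom(n, 1, 0.35)
  x_imt <- ifelse(x_both == 1, 0, rbinom(n, 1, 0.3))
  x_dia <- ifelse(x_both == 1 | x_imt == 1, 0, rbinom(n, 1, 0.4))
  conf <- 2 * x_both + rnorm(n, 0, 0.4)
  noise <- rnorm(n)
  age <- rnorm(n, 54, 5)
  rate <- 0.012 * exp(0.7 * x_both + 0.45 * x_imt + 0.4 * x_dia +
                        0.15 * conf + 0.01 * (age - 54))
  te <- rexp(n) / rate
  tc <- runif(n, 10, 12)
  list(time = pmin(te, tc), status = as.integer(te <= tc),
       x = cbind(BOTH = x_both, IMT_ONLY = x_imt, DIA_ONLY = x_dia,
                 age = age, conf = conf, noise = noise))
}

test_that("backward elimination drops noise but the delta rule retains a confounder", {
  s <- make_selection_scenario()
  sel <- select_covariates(s$time, s$status, s$x,
                           exposure_terms = c("BOTH", "IMT_ONLY", "DIA_ONLY"),
                           base_terms = "age",
                           candidate_terms = c("conf", "noise"))
  expect_true("conf" %in% sel$kept)
  expect_true("noise" %in% sel$dropped)
  aud <- sel$audit
  conf_row <- aud[aud$term == "conf", ][1, ]
  expect_gte(conf_row$p_value, 0.05)          # not retained by significance...
  expect_gt(conf_row$max_rel_change, 0.10)    # ...but by the 10% change rule
  expect_match(conf_row$decision, "confounder")
  expect_match(aud$decision[aud$term == "noise"], "dropped")
  # empty candidate set returns the base model unchanged
  base_cols <- c("BOTH", "IMT_ONLY", "DIA_ONLY", "age")
  sel0 <- select_covariates(s$time, s$status, s$x[, base_cols],
                            exposure_terms = c("BOTH", "IMT_ONLY", "DIA_ONLY"),
                            base_terms = "age", candidate_terms = character(0))
  ref <- fit_cox(s$time, s$status, s$x[, base_cols])
  expect_equal(sel0$fit$coef, ref$coef)
  expect_equal(nrow(sel0$audit), 0L)
})

test_that("geometry designs feed side- and sex-specific models end to end", {
  co <- classify_cohort(small_cohort(n = 1500, seed = 61,
                                     baseline_hazard = 0.004))
  men <- co[co$sex == "M", ]
  des <- geometry_design(men, "R")
  expect_equal(colnames(des$x)[1:3], c("BOTH", "IMT_ONLY", "DIA_ONLY"))
  expect_true("race_white" %in% colnames(des$x))
  # indicators mutually exclusive
  expect_true(all(rowSums(des$x[, 1:3]) <= 1))
  fit <- fit_cox(des$time, des$status, des$x)
  expect_lt(fit$gradient_norm, 1e-6)
  expect_equal(fit$n, nrow(men))
})
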