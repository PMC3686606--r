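# Independent oracles used to check the package's own implementations.
# These deliberately take the naive route (explicit loops, brute-force
# maximization) and share no code with R/.

# Naive Breslow log partial likelihood: double loop over events and the
# full risk set.
brute_breslow_loglik <- function(beta, time, status, x) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# 1-D brute-force maximizer of the Breslow partial likelihood.
brute_cox_1d <- function(time, status, x) {
  stats::optimize(function(b) brute_breslow_loglik(b, time, status, x),
                  interval = c(-8, 8), maximum = TRUE, tol = 1e-10)$maximum
}

# Hand-formula kappa: explicit element loops for p_o and p_e.
kappa_oracle <- function(m) {
  n <- sum(m)
  p_o <- 0
  for (i in seq_len(nrow(m))) p_o <- p_o + m[i, i] / n
  p_e <- 0
  for (i in seq_len(nrow(m)))
    p_e <- p_e + (sum(m[i, ]) / n) * (sum(m[, i]) / n)
  (p_o - p_e) / (1 - p_e)
}

# Expand a per-phenotype count table into a subject-level classified
# cohort (phenotype_id + event are all the diagnostics stage needs).
counts_to_cohort <- function(counts) {
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    data.frame(sex = r$sex,
               phenotype_id = rep(r$phenotype_id, r$n),
               event = rep(c(1L, 0L), c(r$n_events, r$n - r$n_events)))
  }))
}

# Printed reference diagnostic panel (sens/spec/+LR/-LR at two decimals)
# for phenotype 1 and the six combined definitions, both sexes.
reference_diagnostic_panel <- function() {
  rbind(
    data.frame(definition = "BOTH_BILAT", sex = "M",
               sens = 0.44, spec = 0.81, plr = 2.28, nlr = 0.69),
    data.frame(definition = "BOTH_BILAT", sex = "F",
               sens = 0.64, spec = 0.79, plr = 3.10, nlr = 0.46),
    data.frame(definition = "IMT_BILAT", sex = "M",
               sens = 0.63, spec = 0.67, plr = 1.92, nlr = 0.55),
    data.frame(definition = "IMT_BILAT", sex = "F",
               sens = 0.79, spec = 0.65, plr = 2.23, nlr = 0.33),
    data.frame(definition = "DIA_BILAT", sex = "M",
               sens = 0.65, spec = 0.63, plr = 1.74, nlr = 0.56),
    data.frame(definition = "DIA_BILAT", sex = "F",
               sens = 0.74, spec = 0.61, plr = 1.93, nlr = 0.42),
    data.frame(definition = "SAME_SIDE_BOTH", sex = "M",
               sens = 0.72, spec = 0.57, plr = 1.68, nlr = 0.49),
    data.frame(definition = "SAME_SIDE_BOTH", sex = "F",
               sens = 0.80, spec = 0.56, plr = 1.84, nlr = 0.35),
    data.frame(definition = "ANY_IMT", sex = "M",
               sens = 0.87, spec = 0.35, plr = 1.33, nlr = 0.38),
    data.frame(definition = "ANY_IMT", sex = "F",
               sens = 0.92, spec = 0.33, plr = 1.38, nlr = 0.23),
    data.frame(definition = "ANY_DIA", sex = "M",
               sens = 0.79, spec = 0.39, plr = 1.30, nlr = 0.54),
    data.frame(definition = "ANY_DIA", sex = "F",
               sens = 0.85, spec = 0.40, plr = 1.41, nlr = 0.38),
    data.frame(definition = "ANY_BILAT", sex = "M",
               sens = 0.84, spec = 0.49, plr = 1.65, nlr = 0.32),
    data.frame(definition = "ANY_BILAT", sex = "F",
               sens = 0.89, spec = 0.47, plr = 1.68, nlr = 0.23))
}

# Small, fast cohort for structural tests.
small_cohort <- function(n = 600, seed = 11, ...) {
  simulate_cohort(cohort_config(n_subjects = n, seed = seed, ...))
}
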