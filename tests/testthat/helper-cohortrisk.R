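# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as naive brute-force code, independent of the package's
# implementation paths.

# A cohort-spec row for homogeneous synthetic cohorts (identical marginals).
homog_cohort_spec <- function(cohorts, n, p_dre = 0.3, p_african = 0.15,
                              p_famhx = 0.2, p_priorneg = 0.25, miss = 0) {
  data.frame(
    cohort = cohorts, n = n,
    psa_log2_mean = 2.6, psa_log2_sd = 1.0, age_mean = 64, age_sd = 8,
    p_dre = p_dre, p_african = p_african, p_famhx = p_famhx,
    p_priorneg = p_priorneg,
    miss_dre = miss, miss_african = miss, miss_famhx = miss,
    miss_priorneg = miss,
    stringsAsFactors = FALSE
  )
}

default_betas <- function() {
  b <- c(0.75, 0.25, 0.6, 0.4, 0.35, -0.7, 0.15, -0.15, -0.15)
  names(b) <- c("log2psa_std", "age_std", "dre", "african", "famhx",
                "priorneg", "log2psa_std:dre", "age_std:dre",
                "age_std:african")
  b
}

# Homogeneous multi-cohort config with no cohort effect unless d > 0.
homog_config <- function(n_cohorts = 4L, n = 500L, intercept = -1,
                         betas = default_betas(), d = 0, seed = 1L, ...) {
  spec <- homog_cohort_spec(sprintf("C%02d", seq_len(n_cohorts)), n, ...)
  generator_config(spec, intercept = intercept, betas = betas, d = d,
                   seed = seed)
}

# Brute-force Mann-Whitney AUC by explicit pair enumeration.
brute_auc <- function(risks, outcomes) {
  cases <- risks[outcomes == 1]
  ctrls <- risks[outcomes == 0]
  s <- 0
  for (x in cases) for (y in ctrls) {
    s <- s + (x > y) + 0.5 * (x == y)
  }
  s / (length(cases) * length(ctrls))
}

# DeLong variance from scratch: placement values by explicit loops over the
# Mann-Whitney kernel, then the structural-component variance.
delong_var_oracle <- function(risks, outcomes) {
  cases <- risks[outcomes == 1]
  ctrls <- risks[outcomes == 0]
  m <- length(cases); n <- length(ctrls)
  v10 <- numeric(m); v01 <- numeric(n)
  for (i in seq_len(m)) {
    s <- 0
    for (j in seq_len(n)) s <- s + (cases[i] > ctrls[j]) + 0.5 * (cases[i] == ctrls[j])
    v10[i] <- s / n
  }
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) s <- s + (cases[i] > ctrls[j]) + 0.5 * (cases[i] == ctrls[j])
    v01[j] <- s / m
  }
  sum((v10 - mean(v10))^2) / (m - 1) / m + sum((v01 - mean(v01))^2) / (n - 1) / n
}

# Naive Hosmer-Lemeshow statistic: decile breakpoints by linear interpolation
# of the sorted risks, grouping and the two-cell statistic in explicit loops.
hl_oracle <- function(risks, outcomes, groups = 10) {
  srt <- sort(risks)
  n <- length(risks)
  qs <- numeric(groups + 1)
  for (k in 0:groups) {
    p <- k / groups
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    qs[k + 1] <- srt[lo] + (h - lo) * (srt[hi] - srt[lo])
  }
  qs <- unique(qs)
  stat <- 0
  for (g in seq_len(length(qs) - 1)) {
    if (g == 1) sel <- risks >= qs[g] & risks <= qs[g + 1]
    else sel <- risks > qs[g] & risks <= qs[g + 1]
    ng <- sum(sel)
    if (ng == 0) next
    og <- sum(outcomes[sel])
    eg <- sum(risks[sel])
    stat <- stat + (og - eg)^2 / (eg * (1 - eg / ng))
  }
  stat
}

# Monte-Carlo oracle for the mean (integrated) prediction.
mc_mean_prediction <- function(eta, d, n = 1e6, seed = 99L) {
  set.seed(seed)
  u <- stats::rnorm(n, 0, sqrt(d))
  vals <- stats::plogis(eta + u)
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(n))
}

# Hand-rolled per_center_fits object for meta-combination unit tests:
# every term in center i takes coefficient b[i] and variance v[i].
fake_per_center <- function(b, v) {
  terms <- c("(Intercept)", names(default_betas()))
  fits <- lapply(seq_along(b), function(i) {
    list(cohort = sprintf("C%d", i),
         coef = stats::setNames(rep(b[i], 10), terms),
         var = stats::setNames(rep(v[i], 10), terms),
         inestimable = character(), n = 100L)
  })
  names(fits) <- sprintf("C%d", seq_along(b))
  pre <- structure(list(psa_log2_mean = 2.6, psa_log2_sd = 1, age_mean = 64,
                        age_sd = 8, source = "training_only"),
                   class = "preproc_params")
  structure(fits, class = "per_center_fits", preprocessing = pre)
}

# Small fully observed cohort table built by hand.
toy_table <- function(n = 40L, cohorts = c("A", "B"), seed = 42L) {
  set.seed(seed)
  as_cohort_table(data.frame(
    cohort = rep(cohorts, each = n / length(cohorts)),
    outcome = rbinom(n, 1, 0.3),
    psa = round(2^rnorm(n, 2.5, 1), 2),
    age = round(rnorm(n, 64, 8)),
    dre = rbinom(n, 1, 0.3),
    african = rbinom(n, 1, 0.2),
    famhx = rbinom(n, 1, 0.2),
    priorneg = rbinom(n, 1, 0.25),
    stringsAsFactors = FALSE
  ))
}
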