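.cohort_spec_cols <- c(
  "cohort", "n", "psa_log2_mean", "psa_log2_sd", "age_mean", "age_sd",
  "p_dre", "p_african", "p_famhx", "p_priorneg",
  "miss_dre", "miss_african", "miss_famhx", "miss_priorneg"
)

#' Assemble a multi-cohort generator configuration
#'
#' The generator's data model mirrors the random-intercept logistic model read
#' as a data-generating process: within cohort `c`, covariates are drawn from
#' cohort-specific marginal distributions (log-normal base-2 PSA, truncated
#' normal age, independent Bernoulli binary factors) and the outcome is
#' Bernoulli with `logit P(y=1) = b0 + b0c + b'x`, where `b0c ~ N(0, d)` or a
#' supplied fixed per-cohort intercept. Missingness in the binary factors is
#' applied after outcome generation, independently of everything (MCAR).
#'
#' @param cohorts data frame with one row per cohort and columns `cohort`,
#'   `n`, `psa_log2_mean`, `psa_log2_sd`, `age_mean`, `age_sd`, `p_dre`,
#'   `p_african`, `p_famhx`, `p_priorneg`, and the per-factor missingness
#'   rates `miss_dre`, `miss_african`, `miss_famhx`, `miss_priorneg`.
#' @param intercept true fixed intercept `b0` (logit scale).
#' @param betas true named 9-vector on the design-matrix term order.
#' @param d random-intercept variance (>= 0).
#' @param fixed_intercepts optional named per-cohort intercept deviations;
#'   overrides the `N(0, d)` draw.
#' @param seed default seed used by [generate_cohorts()].
#' @return object of class `generator_config`.
#' @export
generator_config <- function(cohorts, intercept, betas, d = 0,
                             fixed_intercepts = NULL, seed = 1L) {
  stopifnot(is.data.frame(cohorts))
  missing_cols <- setdiff(.cohort_spec_cols, names(cohorts))
  if (length(missing_cols) > 0L) {
    stop("cohort spec missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(cohorts$n < 1)) stop("every cohort needs n >= 1", call. = FALSE)
  probs <- unlist(cohorts[, c("p_dre", "p_african", "p_famhx", "p_priorneg",
                              "miss_dre", "miss_african", "miss_famhx",
                              "miss_priorneg")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]", call. = FALSE)
  if (d < 0) stop("d must be nonnegative", call. = FALSE)
  stopifnot(length(betas) == 9L)
  names(betas) <- .term_names
  if (!is.null(fixed_intercepts)) {
    stopifnot(setequal(names(fixed_intercepts), cohorts$cohort))
  }
  structure(list(cohorts = cohorts, intercept = intercept, betas = betas,
                 d = d, fixed_intercepts = fixed_intercepts, seed = seed),
            class = "generator_config")
}

# Population standardization constants implied by a config: moments of the
# cohort-size-weighted mixture of the per-cohort covariate distributions
# (truncation ignored — negligible at the default bounds).
.truth_preprocessing <- function(config) {
  ch <- config$cohorts
  wt <- ch$n / sum(ch$n)
  mix <- function(mu, sig) {
    m <- sum(wt * mu)
    v <- sum(wt * (sig^2 + mu^2)) - m^2
    c(mean = m, sd = sqrt(v))
  }
  psa <- mix(ch$psa_log2_mean, ch$psa_log2_sd)
  age <- mix(ch$age_mean, ch$age_sd)
  structure(list(psa_log2_mean = unname(psa["mean"]),
                 psa_log2_sd = unname(psa["sd"]),
                 age_mean = unname(age["mean"]),
                 age_sd = unname(age["sd"]),
                 source = "all_data"), class = "preproc_params")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic multi-cohort dataset with known ground truth
#'
#' Draws covariates, per-cohort intercepts and outcomes per the configuration
#' (see [generator_config()] for the data model), then applies MCAR
#' missingness to the binary factors. Age is truncated to [40, 90] years and
#' PSA to [0.1, 50] ng/ml to keep the support clinically plausible.
#' Deterministic given the seed.
#'
#' @param config a `generator_config`.
#' @param seed integer seed; defaults to the config's.
#' @return list with `table` (a cohort table, including any missing values)
#'   and `truth` (class `truth_record`: the config, the population
#'   standardization constants the linear predictor used, realized per-cohort
#'   intercepts and realized prevalences).
#' @export
generate_cohorts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  pre <- .truth_preprocessing(config)
  ch <- config$cohorts
  if (is.null(config$fixed_intercepts)) {
    b0c <- stats::rnorm(nrow(ch), 0, sqrt(config$d))
    names(b0c) <- ch$cohort
  } else {
    b0c <- config$fixed_intercepts[ch$cohort]
  }
  pieces <- vector("list", nrow(ch))
  for (i in seq_len(nrow(ch))) {
    s <- ch[i, ]
    n <- s$n
    lpsa <- .rtruncnorm(n, s$psa_log2_mean, s$psa_log2_sd, log2(0.1), log2(50))
    age <- .rtruncnorm(n, s$age_mean, s$age_sd, 40, 90)
    tab <- data.frame(
      cohort = s$cohort,
      outcome = 0,
      psa = 2^lpsa,
      age = age,
      dre = stats::rbinom(n, 1, s$p_dre),
      african = stats::rbinom(n, 1, s$p_african),
      famhx = stats::rbinom(n, 1, s$p_famhx),
      priorneg = stats::rbinom(n, 1, s$p_priorneg),
      stringsAsFactors = FALSE
    )
    dm <- build_design_matrix(as_cohort_table(tab), pre)
    eta <- config$intercept + b0c[[s$cohort]] +
      as.numeric(dm$x %*% config$betas)
    tab$outcome <- stats::rbinom(n, 1, stats::plogis(eta))
    # MCAR missingness, applied after the outcome so it cannot depend on it
    for (f in .binary_factors) {
      rate <- s[[paste0("miss_", f)]]
      if (rate > 0) tab[[f]][stats::runif(n) < rate] <- NA
    }
    pieces[[i]] <- tab
  }
  table <- as_cohort_table(do.call(rbind, pieces))
  rownames(table) <- NULL
  truth <- structure(list(
    config = config,
    preprocessing = pre,
    cohort_intercepts = b0c,
    realized_prevalence = tapply(table$outcome, table$cohort, mean)[ch$cohort],
    seed = seed
  ), class = "truth_record")
  list(table = table, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("Synthetic multi-cohort truth record\n")
  cat(sprintf("  b0 = %.3f, d = %.3f, seed = %d\n",
              x$config$intercept, x$config$d, as.integer(x$seed)))
  df <- data.frame(intercept_dev = round(x$cohort_intercepts, 3),
                   prevalence = round(as.numeric(x$realized_prevalence), 3))
  print(df)
  invisible(x)
}

# Expected outcome prevalence in one cohort given a total intercept, by
# exact summation over the 16 binary-factor combinations and 2-D
# Gauss-Hermite quadrature over the two standardized continuous covariates.
.expected_prevalence <- function(total_intercept, spec, betas, pre,
                                 nodes = 24L) {
  gh <- pracma::gaussHermite(nodes)
  mu1 <- (spec$psa_log2_mean - pre$psa_log2_mean) / pre$psa_log2_sd
  s1 <- spec$psa_log2_sd / pre$psa_log2_sd
  mu2 <- (spec$age_mean - pre$age_mean) / pre$age_sd
  s2 <- spec$age_sd / pre$age_sd
  z1 <- mu1 + sqrt(2) * s1 * gh$x
  z2 <- mu2 + sqrt(2) * s2 * gh$x
  w <- gh$w / sqrt(pi)
  total <- 0
  for (dre in 0:1) for (afr in 0:1) for (fam in 0:1) for (pri in 0:1) {
    pcomb <- (if (dre) spec$p_dre else 1 - spec$p_dre) *
      (if (afr) spec$p_african else 1 - spec$p_african) *
      (if (fam) spec$p_famhx else 1 - spec$p_famhx) *
      (if (pri) spec$p_priorneg else 1 - spec$p_priorneg)
    if (pcomb == 0) next
    base <- total_intercept + betas[["dre"]] * dre + betas[["african"]] * afr +
      betas[["famhx"]] * fam + betas[["priorneg"]] * pri
    c1 <- betas[["log2psa_std"]] + betas[["log2psa_std:dre"]] * dre
    c2 <- betas[["age_std"]] + betas[["age_std:dre"]] * dre +
      betas[["age_std:african"]] * afr
    # E over the two independent standardized normals
    inner <- outer(c1 * z1, c2 * z2, function(a, b) stats::plogis(base + a + b))
    total <- total + pcomb * as.numeric(w %*% inner %*% w)
  }
  total
}

#' Solve per-cohort intercepts for target prevalences
#'
#' Finds, for each cohort, the total intercept that makes the expected outcome
#' prevalence (under the config's covariate distribution and coefficients)
#' equal the target. Deterministic: the expectation is evaluated by exact
#' enumeration of the binary-factor combinations and Gauss-Hermite quadrature
#' over the continuous covariates.
#'
#' @param cohorts cohort spec data frame (see [generator_config()]).
#' @param betas true 9-vector.
#' @param targets named vector of target prevalences per cohort.
#' @return named vector of total intercepts (logit scale).
#' @export
solve_cohort_intercepts <- function(cohorts, betas, targets) {
  stopifnot(setequal(names(targets), cohorts$cohort))
  names(betas) <- .term_names
  cfg_pre <- .truth_preprocessing(list(cohorts = cohorts))
  out <- stats::setNames(numeric(nrow(cohorts)), cohorts$cohort)
  for (i in seq_len(nrow(cohorts))) {
    spec <- cohorts[i, ]
    tgt <- targets[[spec$cohort]]
    out[spec$cohort] <- stats::uniroot(
      function(t) .expected_prevalence(t, spec, betas, cfg_pre) - tgt,
      interval = c(-8, 8), tol = 1e-8)$root
  }
  out
}

#' Consortium-like synthetic preset
#'
#' Ten heterogeneous cohorts emulating the published marginal facts of a
#' multi-center prostate biopsy consortium: sizes spanning 299 to 1863
#' biopsies (total ~8500), outcome prevalences spanning 18% to 39%, one
#' cohort with 63% African ancestry, one with 51% abnormal DRE, and one
#' low-prevalence cohort with no African-ancestry patients, 2.8% family
#' history and 40% prior negative biopsies. True coefficients carry the
#' sign structure of the published pooled model: risk increases with PSA,
#' age, abnormal DRE, African ancestry and family history, decreases with a
#' prior negative biopsy; an abnormal DRE magnifies the PSA effect while
#' age's effect is attenuated under abnormal DRE or African ancestry.
#' Per-cohort intercepts are solved deterministically so expected prevalences
#' hit the targets ([solve_cohort_intercepts()]).
#'
#' @param size_factor multiplier on every cohort's size (1 = full scale);
#'   useful for fast smoke runs, the covariate/effect structure is unchanged.
#' @return a `generator_config` with fixed per-cohort intercepts.
#' @export
pbcg_like_preset <- function(size_factor = 1) {
  cohorts <- data.frame(
    cohort = c("UTHealth", "DurhamVA", "SanRaffaele", "MayoClinic",
               "Sunnybrook", "SanJuanVA", "UCSF", "MSKCC",
               "ClevelandClinic", "Zurich"),
    n = c(899, 800, 600, 850, 581, 299, 750, 900, 950, 1863),
    psa_log2_mean = c(2.7, 2.6, 2.6, 2.6, 2.7, 2.5, 2.5, 2.6, 2.6, 2.4),
    psa_log2_sd   = c(1.0, 1.0, 0.9, 0.9, 1.0, 0.9, 0.9, 1.0, 1.0, 0.9),
    age_mean = c(64, 65, 66, 65, 64, 66, 63, 64, 64, 62),
    age_sd   = c(8, 7, 7.5, 8, 8, 7, 8, 8, 8, 8.5),
    p_dre     = c(0.28, 0.30, 0.25, 0.24, 0.26, 0.51, 0.22, 0.24, 0.45, 0.20),
    p_african = c(0.18, 0.63, 0.01, 0.02, 0.05, 0.12, 0.02, 0.06, 0.15, 0.00),
    p_famhx   = c(0.18, 0.20, 0.16, 0.22, 0.19, 0.17, 0.21, 0.23, 0.20, 0.028),
    p_priorneg = c(0.12, 0.15, 0.25, 0.28, 0.24, 0.18, 0.30, 0.27, 0.26, 0.40),
    miss_dre     = c(0.03, 0.04, 0.02, 0.02, 0.03, 0.05, 0.02, 0.02, 0.03, 0.02),
    miss_african = c(0.01, 0.01, 0.02, 0.01, 0.01, 0.02, 0.01, 0.01, 0.01, 0.01),
    miss_famhx   = c(0.06, 0.07, 0.05, 0.04, 0.05, 0.08, 0.04, 0.05, 0.05, 0.04),
    miss_priorneg = c(0.02, 0.03, 0.02, 0.02, 0.02, 0.04, 0.02, 0.02, 0.02, 0.02),
    stringsAsFactors = FALSE
  )
  cohorts$n <- pmax(1L, as.integer(round(cohorts$n * size_factor)))
  betas <- c(0.75, 0.25, 0.60, 0.40, 0.35, -0.70, 0.15, -0.15, -0.15)
  names(betas) <- .term_names
  targets <- c(UTHealth = 0.39, DurhamVA = 0.35, SanRaffaele = 0.33,
               MayoClinic = 0.32, Sunnybrook = 0.31, SanJuanVA = 0.30,
               UCSF = 0.29, MSKCC = 0.28, ClevelandClinic = 0.27,
               Zurich = 0.18)
  totals <- solve_cohort_intercepts(cohorts, betas, targets)
  b0 <- mean(totals)
  offsets <- totals - b0
  # reference d: the dispersion of the solved cohort intercepts
  generator_config(cohorts, intercept = b0, betas = betas,
                   d = stats::var(offsets), fixed_intercepts = offsets,
                   seed = 20191015L)
}
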