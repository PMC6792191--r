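# Fits use synthetic data with known ground truth from the generator module.

make_dm <- function(g) {
  tab <- impute_binary_missing(g$table)
  build_design_matrix(tab, fit_preprocessing(tab, "all_data"))
}

test_that("pooled fit recovers a null model and known coefficients", {
  # all true betas zero: intercept-only truth
  null_cfg <- homog_config(n_cohorts = 2L, n = 10000L,
                           intercept = qlogis(0.25),
                           betas = rep(0, 9), d = 0, seed = 11L)
  g <- generate_cohorts(null_cfg)
  m <- fit_pooled(make_dm(g))
  expect_equal(m$intercept, qlogis(0.25), tolerance = 0.12)
  expect_lt(max(abs(m$betas)), 0.1)

  # full truth at n = 20000
  cfg <- homog_config(n_cohorts = 2L, n = 10000L, intercept = -1,
                      d = 0, seed = 12L)
  m2 <- fit_pooled(make_dm(generate_cohorts(cfg)))
  expect_lt(max(abs(m2$betas - default_betas())), 0.15)
  expect_equal(m2$intercept, -1, tolerance = 0.15)
  expect_equal(m2$method, "pooled")
})

test_that("perfectly separated data raise a fitting error", {
  tab <- toy_table(n = 30L, cohorts = "A", seed = 5L)
  tab$outcome <- as.numeric(tab$psa > median(tab$psa))
  dm <- build_design_matrix(tab, fit_preprocessing(tab))
  expect_error(fit_pooled(dm), "separat|converge")
})

test_that("random-intercept fit collapses to pooled when d = 0", {
  cfg <- homog_config(n_cohorts = 4L, n = 2000L, intercept = -1,
                      d = 0, seed = 13L)
  dm <- make_dm(generate_cohorts(cfg))
  pooled <- fit_pooled(dm)
  re <- suppressWarnings(fit_random_intercept(dm))
  expect_lt(re$d, 0.02)
  expect_lt(max(abs(coef(re) - coef(pooled))), 0.05)
  expect_true(re$method %in% c("re_median", "re_mean"))
})

test_that("random-intercept fit requires at least two cohorts", {
  tab <- toy_table(n = 40L, cohorts = "A")
  dm <- build_design_matrix(tab, fit_preprocessing(tab))
  expect_error(fit_random_intercept(dm), "2 cohorts")
})

test_that("per-center fits are symmetric and flag inestimable terms", {
  tab <- toy_table(n = 200L, cohorts = "A", seed = 21L)
  twin <- tab
  twin$cohort <- "B"
  both <- as_cohort_table(rbind(tab, twin))
  dm <- build_design_matrix(both, fit_preprocessing(both))
  pc <- fit_per_center(dm)
  expect_length(pc, 2L)
  expect_equal(pc[["A"]]$coef, pc[["B"]]$coef)
  expect_equal(pc[["A"]]$var, pc[["B"]]$var)

  # a center with no African-ancestry patients cannot estimate those terms
  tab2 <- tab
  tab2$african <- 0
  tab2$cohort <- "C"
  mix <- as_cohort_table(rbind(tab, tab2))
  dmx <- build_design_matrix(mix, fit_preprocessing(mix))
  pcx <- fit_per_center(dmx)
  expect_true(all(c("african", "age_std:african") %in%
                    pcx[["C"]]$inestimable))
  expect_true(is.na(pcx[["C"]]$coef[["african"]]))
})

test_that("fixed-effects meta-combination is the inverse-variance mean", {
  # identical centers: combined value equals the common value
  expect_equal(combine_meta_fixed(fake_per_center(c(2, 2, 2), c(1, 2, 3)))$betas,
               setNames(rep(2, 9), names(default_betas())))
  # equal variances: plain average
  m <- combine_meta_fixed(fake_per_center(c(1, 3), c(1, 1)))
  expect_equal(unname(m$betas[1]), 2)
  expect_equal(m$intercept, 2)
  # unequal variances: (1*1 + 3*(1/3)) / (1 + 1/3) = 1.5
  m2 <- combine_meta_fixed(fake_per_center(c(1, 3), c(1, 3)))
  expect_equal(unname(m2$betas[1]), 1.5)
})

test_that("DerSimonian-Laird combination matches hand and reference values", {
  # two centers, b = {0, 2}, var = {0.1, 0.1}: Q = 20, S1 = 20, S2 = 200,
  # b_between = (20 - 1)/(20 - 10) = 1.9; equal weights -> combined 1
  m <- combine_meta_random(fake_per_center(c(0, 2), c(0.1, 0.1)))
  expect_equal(unname(m$between_var[1]), 1.9)
  expect_equal(unname(m$betas[1]), 1)

  # homogeneous centers: truncation at zero, equals fixed-effects result
  hom <- fake_per_center(c(1.5, 1.5, 1.5), c(0.5, 1, 2))
  expect_equal(combine_meta_random(hom)$betas,
               combine_meta_fixed(hom)$betas)
  expect_equal(unname(combine_meta_random(hom)$between_var), rep(0, 10))

  skip_if_not_installed("metafor")
  set.seed(31)
  b <- rnorm(6, 1, 0.8)
  v <- runif(6, 0.05, 0.4)
  m3 <- combine_meta_random(fake_per_center(b, v))
  ref <- metafor::rma(yi = b, vi = v, method = "DL")
  expect_equal(unname(m3$betas[1]), as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(unname(m3$between_var[1]), ref$tau2, tolerance = 1e-10)
})

test_that("meta combination is invariant to center ordering", {
  set.seed(32)
  b <- rnorm(5)
  v <- runif(5, 0.1, 0.5)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(combine_meta_random(fake_per_center(b, v))$betas,
               combine_meta_random(fake_per_center(b[perm], v[perm]))$betas)
})

test_that("median prediction is the inverse logit of the linear predictor", {
  tab <- toy_table(n = 20L)
  p <- fit_preprocessing(tab)
  dm <- build_design_matrix(tab, p)
  mk <- function(b0, betas) {
    structure(list(method = "pooled", intercept = b0,
                   betas = setNames(betas, names(default_betas())),
                   d = NULL, preprocessing = p), class = "risk_model")
  }
  expect_equal(predict_median(mk(0, rep(0, 9)), dm), rep(0.5, 20))
  expect_equal(predict_median(mk(qlogis(0.15), rep(0, 9)), dm), rep(0.15, 20))
  # hand-computed single row
  m <- mk(-1, c(0.5, rep(0, 8)))
  eta <- -1 + 0.5 * dm$x[1, "log2psa_std"]
  expect_equal(predict_median(m, dm)[1], unname(plogis(eta)))
  expect_true(all(predict_median(m, dm) > 0 & predict_median(m, dm) < 1))
})

test_that("mean prediction integrates over the random-intercept distribution", {
  tab <- toy_table(n = 6L)
  p <- fit_preprocessing(tab)
  dm <- build_design_matrix(tab, p)
  mk <- function(d) {
    structure(list(method = "re_mean", intercept = 0,
                   betas = setNames(rep(0, 9), names(default_betas())),
                   d = d, preprocessing = p), class = "risk_model")
  }
  # d = 0 collapses exactly to the median prediction
  expect_identical(predict_mean_integrated(mk(0), dm),
                   predict_median(mk(0), dm))

  # d = 1, eta = 2: agree with a 10^6-draw Monte-Carlo oracle within 3 SE
  m <- mk(1)
  m$intercept <- 2
  got <- predict_mean_integrated(m, dm)[1]
  mc <- mc_mean_prediction(eta = 2, d = 1)
  expect_lt(abs(got - mc$mean), 3 * mc$se)

  # shrinkage toward 0.5: below expit(eta) for eta > 0, above for eta < 0
  for (eta in c(-3, -1, 1, 3)) {
    mm <- mk(0.8)
    mm$intercept <- eta
    pred <- predict_mean_integrated(mm, dm)[1]
    if (eta > 0) expect_lt(pred, plogis(eta)) else expect_gt(pred, plogis(eta))
  }

  # model without d refuses mean prediction
  bad <- mk(1)
  bad$d <- NULL
  expect_error(predict_mean_integrated(bad, dm), "d")
})

test_that("quadrature is converged at the default node count", {
  tab <- toy_table(n = 1L, cohorts = "A")
  tab$psa <- 4; tab$age <- 64
  p <- structure(list(psa_log2_mean = 2, psa_log2_sd = 1, age_mean = 64,
                      age_sd = 8, source = "all_data"),
                 class = "preproc_params")
  dm <- build_design_matrix(impute_binary_missing(tab), p)
  for (d in c(0.1, 1, 4)) for (eta in c(-10, -2, 0, 2, 10)) {
    m <- structure(list(method = "re_mean", intercept = eta,
                        betas = setNames(rep(0, 9), names(default_betas())),
                        d = d, preprocessing = p), class = "risk_model")
    expect_lt(abs(predict_mean_integrated(m, dm, nodes = 50L) -
                    predict_mean_integrated(m, dm, nodes = 100L)), 1e-8)
  }
})

test_that("the dispatcher routes to the five strategies", {
  g <- generate_cohorts(homog_config(n_cohorts = 3L, n = 400L, seed = 41L))
  dm <- make_dm(g)
  expect_equal(coef(fit_risk_model(dm, "pooled")), coef(fit_pooled(dm)))
  mm <- suppressWarnings(fit_risk_model(dm, "re_mean"))
  expect_equal(mm$method, "re_mean")
  expect_true(mm$d >= 0)
  mf <- fit_risk_model(dm, "meta_fixed")
  expect_equal(mf$method, "meta_fixed")
  expect_error(fit_risk_model(dm, "mystery"))

  # cohort-table entry point builds its own preprocessing
  m2 <- fit_risk_model(g$table, "pooled")
  expect_s3_class(m2$preprocessing, "preproc_params")
  risks <- predict(m2, g$table)
  expect_true(all(risks > 0 & risks < 1))
})

test_that("model JSON serialization round-trips coefficients bit-exactly", {
  g <- generate_cohorts(homog_config(n_cohorts = 3L, n = 300L, seed = 43L))
  dm <- make_dm(g)
  m <- combine_meta_random(fit_per_center(dm))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_identical(back$intercept, m$intercept)
  expect_identical(back$betas, m$betas)
  expect_identical(back$between_var, m$between_var)
  expect_identical(back$method, m$method)
  expect_equal(back$preprocessing$psa_log2_mean, m$preprocessing$psa_log2_mean)
  expect_equal(back$per_center[["C01"]]$coef, m$per_center[["C01"]]$coef)
  # a serialized model predicts identically
  expect_identical(predict_median(back, dm), predict_median(m, dm))
})
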