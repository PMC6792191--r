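.methods <- c("pooled", "re_median", "re_mean", "meta_fixed", "meta_random")

.new_risk_model <- function(method, intercept, betas, preprocessing,
                            d = NULL, per_center = NULL, between_var = NULL,
                            diagnostics = list()) {
  stopifnot(length(betas) == 9L)
  names(betas) <- .term_names
  structure(list(
    method = method,
    intercept = unname(intercept),
    betas = betas,
    d = d,
    per_center = per_center,
    between_var = between_var,
    preprocessing = preprocessing,
    diagnostics = diagnostics
  ), class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Multi-cohort risk model [", x$method, "]\n", sep = "")
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  print(round(x$betas, 4))
  if (!is.null(x$d)) cat(sprintf("  random-intercept variance d: %.4f\n", x$d))
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$betas)
}

.check_glm_fit <- function(fit, context) {
  if (!fit$converged) {
    stop("logistic regression did not converge (", context, ")", call. = FALSE)
  }
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    stop("coefficients diverged (", context,
         "); data are likely separated", call. = FALSE)
  }
  invisible(fit)
}

#' Pooled logistic regression, cohort ignored
#'
#' Maximum-likelihood logistic fit to all individuals pooled across cohorts,
#' with the cohort label discarded.
#'
#' @param dm a [build_design_matrix()] result.
#' @return a `risk_model` with `method = "pooled"`.
#' @export
fit_pooled <- function(dm) {
  stopifnot(inherits(dm, "design_matrix"))
  y <- dm$outcome
  if (length(unique(y)) < 2L) stop("need at least 1 case and 1 control", call. = FALSE)
  df <- data.frame(y = y, dm$x, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial())
  )
  .check_glm_fit(fit, "pooled fit")
  cf <- stats::coef(fit)
  .new_risk_model("pooled", cf[1L], cf[-1L], dm$preprocessing,
                  diagnostics = list(converged = fit$converged,
                                     loglik = as.numeric(stats::logLik(fit)),
                                     n = length(y)))
}

#' Random-intercept logistic regression
#'
#' One-stage meta-analysis: pooled individual-level fit with a Gaussian random
#' intercept per cohort, `b0c ~ N(0, d)`, estimated by maximizing the marginal
#' likelihood with the random intercept integrated out by adaptive
#' Gauss-Hermite quadrature (default 15 nodes; falls back to the Laplace
#' approximation with a warning if quadrature fails). The same fit serves both
#' the median-prediction and mean-prediction rules; `method` records which one
#' will be used at prediction time.
#'
#' @param dm a [build_design_matrix()] result with at least two cohorts.
#' @param method `"re_median"` or `"re_mean"` (prediction rule tag).
#' @param nAGQ number of adaptive quadrature nodes.
#' @return a `risk_model` with random-intercept variance in `$d`.
#' @export
fit_random_intercept <- function(dm, method = c("re_median", "re_mean"),
                                 nAGQ = 15L) {
  stopifnot(inherits(dm, "design_matrix"))
  method <- match.arg(method)
  if (length(unique(dm$cohort)) < 2L) {
    stop("random-intercept model requires at least 2 cohorts", call. = FALSE)
  }
  df <- data.frame(y = dm$outcome, dm$x, cohort = dm$cohort, check.names = FALSE)
  fml <- stats::reformulate(
    c(sprintf("`%s`", .term_names), "(1 | cohort)"), response = "y")
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::glmer(fml, data = df, family = stats::binomial(), nAGQ = nAGQ)
    )),
    error = function(e) {
      warning("adaptive quadrature failed (", conditionMessage(e),
              "); falling back to Laplace approximation", call. = FALSE)
      suppressWarnings(suppressMessages(
        lme4::glmer(fml, data = df, family = stats::binomial(), nAGQ = 1L)
      ))
    }
  )
  fe <- lme4::fixef(fit)
  d <- as.numeric(lme4::VarCorr(fit)$cohort[1L, 1L])
  if (d < 1e-10) {
    warning("random-intercept variance estimated at the boundary (d ~ 0)",
            call. = FALSE)
  }
  .new_risk_model(method, fe[1L], fe[-1L], dm$preprocessing, d = max(d, 0),
                  diagnostics = list(
                    loglik = as.numeric(stats::logLik(fit)),
                    n = nrow(df), nAGQ = nAGQ))
}

#' Separate logistic regression per center
#'
#' First stage of the two-stage meta-analysis strategies: an independent
#' logistic regression in each cohort. A term whose covariate has zero
#' variation within a center (e.g. African ancestry in an all-European cohort)
#' is inestimable there; it is flagged and excluded from that center's fit,
#' and the center simply does not contribute to that term's combination.
#' Centers without outcome variation are dropped with a warning.
#'
#' @param dm a [build_design_matrix()] result.
#' @return object of class `per_center_fits`: one entry per retained center
#'   with named coefficient and variance vectors (intercept + 9 terms; `NA`
#'   where inestimable) and the names of inestimable terms.
#' @export
fit_per_center <- function(dm) {
  stopifnot(inherits(dm, "design_matrix"))
  out <- list()
  for (cid in sort(unique(dm$cohort))) {
    idx <- dm$cohort == cid
    y <- dm$outcome[idx]
    if (length(unique(y)) < 2L) {
      warning("center '", cid, "' has no outcome variation; dropped",
              call. = FALSE)
      next
    }
    xm <- dm$x[idx, , drop = FALSE]
    estim <- apply(xm, 2L, function(v) stats::var(v) > 0)
    df <- data.frame(y = y, xm[, estim, drop = FALSE], check.names = FALSE)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df, family = stats::binomial())
    )
    full <- c("(Intercept)", .term_names)
    cf <- vr <- stats::setNames(rep(NA_real_, 10L), full)
    got <- stats::coef(fit)
    names(got) <- gsub("`", "", names(got))
    cf[names(got)] <- got
    vg <- diag(stats::vcov(fit))
    names(vg) <- gsub("`", "", names(vg))
    vr[names(vg)] <- vg
    # coefficients that blew up (quasi-separation within a small center) carry
    # enormous variances and so near-zero meta weight; keep them but flag
    unstable <- !is.na(cf) & (abs(cf) > 15 | vr > 1e4)
    cf[unstable] <- NA_real_
    vr[unstable] <- NA_real_
    inest <- full[is.na(cf)]
    out[[cid]] <- list(cohort = cid, coef = cf, var = vr,
                       inestimable = inest, n = sum(idx))
  }
  if (length(out) == 0L) stop("no center with outcome variation", call. = FALSE)
  structure(out, class = "per_center_fits", preprocessing = dm$preprocessing)
}

#' @export
print.per_center_fits <- function(x, ...) {
  cat("Per-center logistic fits: ", length(x), " centers\n", sep = "")
  for (f in x) {
    cat(sprintf("  %s (n=%d)%s\n", f$cohort, f$n,
                if (length(f$inestimable))
                  paste0("; inestimable: ",
                         paste(f$inestimable, collapse = ", ")) else ""))
  }
  invisible(x)
}

# Shared scaffolding for the two meta combiners. For each coefficient k
# (intercept included) collect the centers where it is estimable and return
# the inverse-variance machinery.
.meta_collect <- function(fits, term) {
  b <- vapply(fits, function(f) f$coef[[term]], numeric(1))
  v <- vapply(fits, function(f) f$var[[term]], numeric(1))
  ok <- is.finite(b) & is.finite(v) & v > 0
  if (sum(ok) < 2L) {
    stop("fewer than 2 centers contribute to term '", term,
         "'; meta-analysis not possible", call. = FALSE)
  }
  list(b = b[ok], v = v[ok], n_centers = sum(ok))
}

#' Fixed-effects meta-analysis of per-center coefficients
#'
#' Second stage of the two-stage strategy: each coefficient (intercept and the
#' nine covariate terms, combined independently) is the inverse-variance
#' weighted mean of the per-center estimates, weights `w_kc = 1/var(b_kc)`.
#'
#' @param fits a [fit_per_center()] result.
#' @return a `risk_model` with `method = "meta_fixed"` and the per-center fits
#'   retained in `$per_center`.
#' @export
combine_meta_fixed <- function(fits) {
  stopifnot(inherits(fits, "per_center_fits"))
  terms <- c("(Intercept)", .term_names)
  est <- contrib <- stats::setNames(numeric(length(terms)), terms)
  for (k in terms) {
    m <- .meta_collect(fits, k)
    w <- 1 / m$v
    est[k] <- sum(w * m$b) / sum(w)
    contrib[k] <- m$n_centers
  }
  .new_risk_model("meta_fixed", est[1L], est[-1L],
                  attr(fits, "preprocessing"), per_center = fits,
                  diagnostics = list(contributing_centers = contrib))
}

# Per-coefficient DerSimonian-Laird moment estimator of between-center
# variance: b = max(0, (Q - (C-1)) / (S1 - S2/S1)) with fixed weights w = 1/v.
.dl_between_var <- function(b, v) {
  w <- 1 / v
  s1 <- sum(w)
  s2 <- sum(w^2)
  bbar <- sum(w * b) / s1
  q <- sum(w * (b - bbar)^2)
  max(0, (q - (length(b) - 1)) / (s1 - s2 / s1))
}

#' Random-effects meta-analysis of per-center coefficients
#'
#' As [combine_meta_fixed()], but each coefficient's weights are
#' `w_kc = 1/(var(b_kc) + b_k)` with `b_k` the between-center variance for that
#' coefficient, estimated by the DerSimonian-Laird method of moments
#' (truncated at zero). Coefficients are combined independently; with
#' homogeneous centers every `b_k` truncates to 0 and the result equals the
#' fixed-effects combination.
#'
#' @param fits a [fit_per_center()] result.
#' @return a `risk_model` with `method = "meta_random"`; `$between_var` holds
#'   the 10 per-coefficient between-center variances.
#' @export
combine_meta_random <- function(fits) {
  stopifnot(inherits(fits, "per_center_fits"))
  terms <- c("(Intercept)", .term_names)
  est <- bv <- contrib <- stats::setNames(numeric(length(terms)), terms)
  for (k in terms) {
    m <- .meta_collect(fits, k)
    bv[k] <- .dl_between_var(m$b, m$v)
    w <- 1 / (m$v + bv[k])
    est[k] <- sum(w * m$b) / sum(w)
    contrib[k] <- m$n_centers
  }
  .new_risk_model("meta_random", est[1L], est[-1L],
                  attr(fits, "preprocessing"), per_center = fits,
                  between_var = bv,
                  diagnostics = list(contributing_centers = contrib))
}

#' Fit one of the five multi-cohort modeling strategies
#'
#' Dispatcher over the five strategies: `pooled` (single logistic regression,
#' cohort ignored), `re_median` / `re_mean` (random-intercept logistic
#' regression with median resp. mean prediction), `meta_fixed` / `meta_random`
#' (per-center logistic regressions combined by fixed- resp. random-effects
#' meta-analysis).
#'
#' @param data a cohort table (exclusions applied; binary factors imputed) or
#'   a prebuilt `design_matrix`.
#' @param method one of `"pooled"`, `"re_median"`, `"re_mean"`,
#'   `"meta_fixed"`, `"meta_random"`.
#' @param preprocessing optional `preproc_params`; fitted from `data`
#'   (training-only source) when omitted and `data` is a cohort table.
#' @param nAGQ quadrature nodes for the random-intercept fit.
#' @return a `risk_model`.
#' @export
fit_risk_model <- function(data, method = .methods, preprocessing = NULL,
                           nAGQ = 15L) {
  method <- match.arg(method)
  if (inherits(data, "design_matrix")) {
    dm <- data
  } else {
    data <- impute_binary_missing(as_cohort_table(data))
    if (is.null(preprocessing)) preprocessing <- fit_preprocessing(data)
    dm <- build_design_matrix(data, preprocessing)
  }
  switch(method,
    pooled      = fit_pooled(dm),
    re_median   = fit_random_intercept(dm, "re_median", nAGQ = nAGQ),
    re_mean     = fit_random_intercept(dm, "re_mean", nAGQ = nAGQ),
    meta_fixed  = combine_meta_fixed(fit_per_center(dm)),
    meta_random = combine_meta_random(fit_per_center(dm))
  )
}

.linear_predictor <- function(m, dm) {
  stopifnot(inherits(m, "risk_model"), inherits(dm, "design_matrix"))
  as.numeric(m$intercept + dm$x[, .term_names, drop = FALSE] %*% m$betas)
}

#' Median prediction
#'
#' Risk for a new individual with any cohort effect set to its prior mean of
#' zero: `expit(b0 + b'x)`. This is the prediction rule for the pooled model,
#' the random-intercept model under median prediction, and both meta-analysis
#' models.
#'
#' @param m a `risk_model`.
#' @param dm a design matrix built with `m$preprocessing`.
#' @return numeric vector of risks in (0, 1).
#' @export
predict_median <- function(m, dm) {
  stats::plogis(.linear_predictor(m, dm))
}

#' Mean (integrated) prediction
#'
#' Risk for a new individual obtained by integrating the inverse-logit over
#' the Gaussian random-intercept distribution `N(0, d)`:
#' `integral expit(b0 + u + b'x) dPhi(u; 0, d)`, evaluated by Gauss-Hermite
#' quadrature (default 50 nodes). Collapses exactly to [predict_median()] when
#' `d = 0`. Because the integral averages the logistic curve over intercept
#' noise, mean predictions are shrunk toward 0.5 relative to median
#' predictions.
#'
#' @param m a `risk_model` with random-intercept variance `d`.
#' @param dm a design matrix built with `m$preprocessing`.
#' @param nodes number of Gauss-Hermite nodes.
#' @return numeric vector of risks in (0, 1).
#' @export
predict_mean_integrated <- function(m, dm, nodes = 50L) {
  if (is.null(m$d)) {
    stop("model carries no random-intercept variance d; ",
         "mean prediction requires a random-intercept fit", call. = FALSE)
  }
  eta <- .linear_predictor(m, dm)
  if (m$d == 0) return(stats::plogis(eta))
  gh <- pracma::gaussHermite(nodes)
  # E[expit(eta + u)], u ~ N(0, d): substitute u = sqrt(2 d) t
  shift <- sqrt(2 * m$d) * gh$x
  w <- gh$w / sqrt(pi)
  vapply(eta, function(e) sum(w * stats::plogis(e + shift)), numeric(1))
}

#' Predict risks from a fitted multi-cohort model
#'
#' Applies the prediction rule matching the model's method: mean (integrated)
#' prediction for `re_mean`, median prediction otherwise.
#'
#' @param object a `risk_model`.
#' @param newdata a cohort table or design matrix. A cohort table is imputed
#'   and encoded with the model's stored standardization constants.
#' @param ... unused.
#' @return numeric vector of risks in (0, 1).
#' @export
predict.risk_model <- function(object, newdata, ...) {
  if (!inherits(newdata, "design_matrix")) {
    newdata <- build_design_matrix(
      impute_binary_missing(as_cohort_table(newdata)), object$preprocessing)
  }
  if (identical(object$method, "re_mean")) {
    predict_mean_integrated(object, newdata)
  } else {
    predict_median(object, newdata)
  }
}

#' Serialize a fitted model to JSON
#'
#' Writes method, coefficients, random-intercept variance, per-center
#' coefficient sets, between-center variances and the standardization
#' constants at full precision, under a versioned schema.
#'
#' @param m a `risk_model`.
#' @param path output path.
#' @export
write_model_json <- function(m, path) {
  stopifnot(inherits(m, "risk_model"))
  pc <- NULL
  if (!is.null(m$per_center)) {
    pc <- lapply(unclass(m$per_center), function(f) {
      list(cohort = f$cohort, coef = as.list(f$coef), var = as.list(f$var),
           inestimable = f$inestimable, n = f$n)
    })
    names(pc) <- NULL
  }
  obj <- list(
    schema_version = "1",
    method = m$method,
    intercept = m$intercept,
    betas = as.list(m$betas),
    d = m$d,
    between_var = if (is.null(m$between_var)) NULL else as.list(m$between_var),
    per_center = pc,
    preprocessing = unclass(m$preprocessing),
    fit_diagnostics = m$diagnostics
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a serialized model back
#'
#' @param path path written by [write_model_json()].
#' @return a `risk_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  pre <- structure(lapply(obj$preprocessing, identity), class = "preproc_params")
  pc <- NULL
  if (!is.null(obj$per_center)) {
    pc <- lapply(obj$per_center, function(f) {
      list(cohort = f$cohort,
           coef = unlist(lapply(f$coef, function(v) if (is.null(v)) NA_real_ else v)),
           var  = unlist(lapply(f$var, function(v) if (is.null(v)) NA_real_ else v)),
           inestimable = as.character(unlist(f$inestimable)),
           n = f$n)
    })
    names(pc) <- vapply(pc, `[[`, character(1), "cohort")
    pc <- structure(pc, class = "per_center_fits", preprocessing = pre)
  }
  .new_risk_model(
    obj$method, obj$intercept, unlist(obj$betas), pre,
    d = obj$d, per_center = pc,
    between_var = if (is.null(obj$between_var)) NULL else unlist(obj$between_var),
    diagnostics = obj$fit_diagnostics)
}
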