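.new_metric_result <- function(name, estimate, interval = NULL,
                               interval_type = c("none", "analytic",
                                                 "bootstrap_percentile"),
                               threshold = NULL, n_test = NA_integer_,
                               extra = list()) {
  interval_type <- match.arg(interval_type)
  if (!is.null(interval)) {
    stopifnot(length(interval) == 2L, interval[1L] <= interval[2L])
  }
  structure(c(list(name = name, estimate = unname(estimate),
                   interval = interval, interval_type = interval_type,
                   threshold = threshold, n_test = n_test), extra),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$name, x$estimate))
  if (!is.null(x$interval)) {
    cat(sprintf(" [%.4f, %.4f] (%s)", x$interval[1L], x$interval[2L],
                x$interval_type))
  }
  if (!is.null(x$threshold)) cat(sprintf(" @ threshold %.2f", x$threshold))
  cat(sprintf("  (n = %d)\n", x$n_test))
  invisible(x)
}

.check_two_classes <- function(outcomes) {
  if (anyNA(outcomes) || !all(outcomes %in% c(0, 1))) {
    stop("outcomes must be 0/1 without missing values", call. = FALSE)
  }
  if (length(unique(outcomes)) < 2L) {
    stop("metric requires at least one case and one control", call. = FALSE)
  }
}

.auc_point <- function(risks, outcomes) {
  r <- rank(risks)
  n1 <- as.numeric(sum(outcomes == 1))
  n0 <- as.numeric(sum(outcomes == 0))
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the probability that a randomly chosen case
#' receives a higher predicted risk than a randomly chosen control, ties
#' credited one half. Ranges from 0.5 (random prediction) to 1.0 (perfect
#' prediction).
#'
#' @param risks numeric vector of predicted risks (any monotone score works).
#' @param outcomes 0/1 vector of the same length.
#' @return a `metric_result` named `auc`.
#' @export
auc <- function(risks, outcomes) {
  .check_two_classes(outcomes)
  .new_metric_result("auc", .auc_point(risks, outcomes),
                     n_test = length(outcomes))
}

# Placement values: for each case, the fraction of controls it outranks
# (ties half); and symmetrically for each control. The DeLong variance is
# var(V10)/m + var(V01)/n.
.placements <- function(risks, outcomes) {
  cases <- risks[outcomes == 1]
  ctrls <- risks[outcomes == 0]
  v10 <- vapply(cases, function(x) mean((x > ctrls) + 0.5 * (x == ctrls)),
                numeric(1))
  v01 <- vapply(ctrls, function(x) mean((cases > x) + 0.5 * (cases == x)),
                numeric(1))
  list(v10 = v10, v01 = v01)
}

#' AUC with analytic (DeLong) confidence interval
#'
#' @inheritParams auc
#' @param level confidence level.
#' @return a `metric_result` with an analytic normal interval; the variance is
#'   available as `$variance`.
#' @export
auc_ci <- function(risks, outcomes, level = 0.95) {
  .check_two_classes(outcomes)
  est <- .auc_point(risks, outcomes)
  p <- .placements(risks, outcomes)
  v <- stats::var(p$v10) / length(p$v10) + stats::var(p$v01) / length(p$v01)
  z <- stats::qnorm(1 - (1 - level) / 2)
  .new_metric_result("auc", est,
                     interval = est + c(-1, 1) * z * sqrt(v),
                     interval_type = "analytic",
                     n_test = length(outcomes),
                     extra = list(variance = v))
}

#' Paired AUC difference with analytic (DeLong) interval
#'
#' Difference `auc(risks_a) - auc(risks_b)` for two models evaluated on the
#' same individuals, with the paired DeLong variance that accounts for the
#' correlation induced by the shared test set. Identical risk vectors give a
#' difference of zero with a degenerate interval.
#'
#' @param risks_a,risks_b predicted risks from the two models, same rows.
#' @param outcomes 0/1 vector.
#' @param level confidence level.
#' @return a `metric_result` named `auc_diff`.
#' @export
auc_diff_ci <- function(risks_a, risks_b, outcomes, level = 0.95) {
  .check_two_classes(outcomes)
  stopifnot(length(risks_a) == length(risks_b))
  est <- .auc_point(risks_a, outcomes) - .auc_point(risks_b, outcomes)
  pa <- .placements(risks_a, outcomes)
  pb <- .placements(risks_b, outcomes)
  m <- length(pa$v10)
  n <- length(pa$v01)
  v <- (stats::var(pa$v10) + stats::var(pb$v10) -
          2 * stats::cov(pa$v10, pb$v10)) / m +
       (stats::var(pa$v01) + stats::var(pb$v01) -
          2 * stats::cov(pa$v01, pb$v01)) / n
  v <- max(v, 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  .new_metric_result("auc_diff", est,
                     interval = est + c(-1, 1) * z * sqrt(v),
                     interval_type = "analytic",
                     n_test = length(outcomes),
                     extra = list(variance = v))
}

#' Hosmer-Lemeshow calibration statistic
#'
#' Individuals are sorted by predicted risk and cut at the sample deciles of
#' risk into (by default) ten groups; tied risks stay together even if group
#' sizes become unequal. With observed event count `O_g`, expected count
#' `E_g = sum of risks` and size `n_g` per group, the statistic is
#' `sum (O_g - E_g)^2 / (E_g (1 - E_g/n_g))`, asymptotically chi-square with
#' `groups - 2` degrees of freedom for an in-sample fit of a correctly
#' specified model. Lower is better; for reporting alongside the AUC the
#' negated statistic (-HLS) is used so that higher is better everywhere.
#'
#' `form = "risk"` gives an alternative risk-scale variant,
#' `sum (obar_g - ebar_g)^2 / ebar_g` on the group mean risks.
#'
#' @param risks predicted risks in (0, 1).
#' @param outcomes 0/1 vector.
#' @param groups number of risk groups (default 10).
#' @param form `"count"` (standard) or `"risk"`.
#' @return a `metric_result` named `hls`; the per-group table is in `$groups`.
#' @export
hosmer_lemeshow <- function(risks, outcomes, groups = 10L,
                            form = c("count", "risk")) {
  form <- match.arg(form)
  .check_two_classes(outcomes)
  if (length(risks) < groups) {
    stop("need at least as many observations as groups", call. = FALSE)
  }
  breaks <- unique(stats::quantile(risks, probs = seq(0, 1, length.out = groups + 1),
                                   type = 7, names = FALSE))
  if (length(breaks) < 2L) {
    stop("all risks identical; calibration groups are degenerate — ",
         "check the model's predictions", call. = FALSE)
  }
  g <- cut(risks, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  ng <- tapply(rep(1, length(g)), g, sum)
  og <- tapply(outcomes, g, sum)
  eg <- tapply(risks, g, sum)
  if (any(ng == 0)) {
    stop("empty risk group after tie handling; reduce `groups`", call. = FALSE)
  }
  tab <- data.frame(group = as.integer(names(ng)), n = as.numeric(ng),
                    observed = as.numeric(og), expected = as.numeric(eg))
  if (form == "count") {
    denom <- tab$expected * (1 - tab$expected / tab$n)
    term <- (tab$observed - tab$expected)^2 / denom
    term[tab$observed == tab$expected & denom == 0] <- 0
    if (any(!is.finite(term))) {
      stop("degenerate expected counts (0 or n) in a risk group; ",
           "predictions too extreme for ", groups, " groups", call. = FALSE)
    }
  } else {
    obar <- tab$observed / tab$n
    ebar <- tab$expected / tab$n
    term <- (obar - ebar)^2 / ebar
  }
  .new_metric_result("hls", sum(term), n_test = length(outcomes),
                     extra = list(groups = tab, df = length(breaks) - 1L - 2L,
                                  form = form))
}

#' Decision-curve net benefit at a risk threshold
#'
#' Net benefit of biopsy referral by model-computed risk at threshold `t`:
#' `NB_model = TP/n - (FP/n) t/(1-t)` with a positive call being risk >= t.
#' Also returns the treat-all benchmark `NB_all = pi - (1-pi) t/(1-t)` (pi the
#' outcome prevalence) and the difference `NB_model - NB_all`, the gain in
#' clinical utility over referring everyone.
#'
#' @param risks predicted risks.
#' @param outcomes 0/1 vector.
#' @param threshold risk threshold in (0, 1); the consortium analyses use 0.15.
#' @return a `metric_result` named `net_benefit` with `$nb_all` and
#'   `$nb_delta_all`.
#' @export
net_benefit <- function(risks, outcomes, threshold = 0.15) {
  stopifnot(threshold > 0, threshold < 1)
  if (anyNA(outcomes) || !all(outcomes %in% c(0, 1))) {
    stop("outcomes must be 0/1 without missing values", call. = FALSE)
  }
  n <- length(outcomes)
  pos <- risks >= threshold
  tp <- sum(pos & outcomes == 1)
  fp <- sum(pos & outcomes == 0)
  odds <- threshold / (1 - threshold)
  nb_model <- tp / n - (fp / n) * odds
  prev <- mean(outcomes)
  nb_all <- prev - (1 - prev) * odds
  .new_metric_result("net_benefit", nb_model, threshold = threshold,
                     n_test = n,
                     extra = list(nb_all = nb_all,
                                  nb_delta_all = nb_model - nb_all,
                                  tp = tp, fp = fp))
}

#' Bootstrap percentile interval for a test-set metric
#'
#' Resamples test-set rows with replacement `B` times and returns the
#' empirical 2.5/97.5 percentile interval of the metric. Resamples containing
#' a single outcome class are redrawn (counted; an error is raised if the
#' redraw cap is exceeded). Deterministic given `seed`.
#'
#' @param metric_fn function `(risks, outcomes) -> numeric scalar`.
#' @param risks,outcomes the test set.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed (required, for reproducibility).
#' @param level interval coverage.
#' @param max_redraws cap on single-class redraws.
#' @return a `metric_result` with a `bootstrap_percentile` interval; the
#'   resampled values are in `$replicates`.
#' @export
bootstrap_percentile <- function(metric_fn, risks, outcomes, B = 1000L, seed,
                                 level = 0.95, max_redraws = 10L * B) {
  stopifnot(B >= 2L)
  if (missing(seed)) stop("a seed is required for the bootstrap", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- length(outcomes)
  vals <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcomes[idx])) == 2L) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("bootstrap redraw cap exceeded; outcome class too rare",
             call. = FALSE)
      }
    }
    vals[b] <- metric_fn(risks[idx], outcomes[idx])
  }
  alpha <- (1 - level) / 2
  est <- metric_fn(risks, outcomes)
  .new_metric_result("bootstrap", est,
                     interval = unname(stats::quantile(vals, c(alpha, 1 - alpha),
                                                       type = 7)),
                     interval_type = "bootstrap_percentile",
                     n_test = n,
                     extra = list(replicates = vals, redraws = redraws))
}
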