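#' Enumerate all cohort train/test partitions
#'
#' All `choose(C, test_size)` ways of holding out `test_size` of the `C`
#' cohorts for testing, with the remainder for training, in deterministic
#' lexicographic order of the sorted cohort labels. Ten cohorts with
#' five-cohort test sets give the full permutation set of 252 partitions.
#'
#' @param cohort_ids character vector (or set) of cohort labels.
#' @param test_size number of cohorts held out for testing.
#' @return list of `list(train =, test =)` pairs.
#' @export
enumerate_splits <- function(cohort_ids, test_size) {
  ids <- sort(unique(as.character(cohort_ids)))
  if (test_size <= 0 || test_size >= length(ids)) {
    stop("test_size must satisfy 0 < test_size < number of cohorts",
         call. = FALSE)
  }
  combos <- utils::combn(ids, test_size, simplify = FALSE)
  lapply(combos, function(ts) list(train = setdiff(ids, ts), test = ts))
}

.metric_triple <- function(risks, outcomes, threshold) {
  c(auc = .auc_point(risks, outcomes),
    neg_hls = -hosmer_lemeshow(risks, outcomes)$estimate,
    net_benefit = net_benefit(risks, outcomes, threshold)$estimate)
}

#' Exhaustive cohort-split internal validation
#'
#' For every cohort partition and every requested modeling method:
#' standardization constants are fitted on the training cohorts only, the
#' model is fitted on the training cohorts, risks are predicted for the pooled
#' rows of the test cohorts, and three out-of-sample metrics are computed —
#' AUC, negated Hosmer-Lemeshow statistic (-HLS, higher is better) and net
#' benefit at the given risk threshold. Fits that the random-intercept model
#' shares between median and mean prediction, and per-center fits shared by
#' the two meta-analysis combinations, are computed once per split.
#'
#' Per-split fitting failures are recorded, not fatal; the run aborts only if
#' more than 10% of split-method fits fail.
#'
#' @param table a cohort table (binary factors may contain missing values;
#'   they are reference-imputed internally).
#' @param methods subset of the five methods.
#' @param test_size cohorts per test set (default 5).
#' @param threshold net-benefit risk threshold (default 0.15).
#' @param seed integer seed (recorded; the computation itself is
#'   deterministic).
#' @param nAGQ quadrature nodes for random-intercept fits.
#' @param splits optional pre-enumerated split list (default: all splits).
#' @return data frame of class `split_validation`: one row per split x
#'   method with columns `split_id`, `train_cohorts`, `test_cohorts`,
#'   `method`, `auc`, `neg_hls`, `net_benefit`, `error`.
#' @export
run_split_validation <- function(table, methods = .methods, test_size = 5L,
                                 threshold = 0.15, seed = 1L, nAGQ = 15L,
                                 splits = NULL) {
  methods <- match.arg(methods, .methods, several.ok = TRUE)
  table <- impute_binary_missing(as_cohort_table(table))
  if (anyNA(table[, c("psa", "age", "outcome")])) {
    stop("apply_exclusions() before validation", call. = FALSE)
  }
  if (is.null(splits)) splits <- enumerate_splits(table$cohort, test_size)
  set.seed(seed)
  rows <- list()
  n_fail <- 0L
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    train <- table[table$cohort %in% sp$train, , drop = FALSE]
    test <- table[table$cohort %in% sp$test, , drop = FALSE]
    params <- fit_preprocessing(train, source = "training_only")
    dm_train <- build_design_matrix(train, params)
    dm_test <- build_design_matrix(test, params)
    shared <- new.env(parent = emptyenv())
    get_fit <- function(method) {
      if (method %in% c("re_median", "re_mean")) {
        if (is.null(shared$re)) {
          shared$re <- suppressWarnings(
            fit_random_intercept(dm_train, nAGQ = nAGQ))
        }
        m <- shared$re
        m$method <- method
        m
      } else if (method %in% c("meta_fixed", "meta_random")) {
        if (is.null(shared$pc)) {
          shared$pc <- suppressWarnings(fit_per_center(dm_train))
        }
        if (method == "meta_fixed") combine_meta_fixed(shared$pc)
        else combine_meta_random(shared$pc)
      } else {
        fit_pooled(dm_train)
      }
    }
    for (method in methods) {
      res <- tryCatch({
        m <- get_fit(method)
        risks <- if (method == "re_mean") predict_mean_integrated(m, dm_test)
                 else predict_median(m, dm_test)
        as.list(.metric_triple(risks, test$outcome, threshold))
      }, error = function(e) {
        list(auc = NA_real_, neg_hls = NA_real_, net_benefit = NA_real_,
             error = conditionMessage(e))
      })
      if (!is.null(res$error)) n_fail <- n_fail + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        split_id = si,
        train_cohorts = paste(sp$train, collapse = "+"),
        test_cohorts = paste(sp$test, collapse = "+"),
        method = method,
        auc = res$auc, neg_hls = res$neg_hls, net_benefit = res$net_benefit,
        error = if (is.null(res$error)) NA_character_ else res$error,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (n_fail > 0.10 * nrow(out)) {
    failed <- out[!is.na(out$error), c("split_id", "method", "error")]
    stop("more than 10% of split fits failed:\n",
         paste(utils::capture.output(print(failed)), collapse = "\n"),
         call. = FALSE)
  }
  attr(out, "threshold") <- threshold
  attr(out, "seed") <- seed
  class(out) <- c("split_validation", class(out))
  out
}

.quantile_summary <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  c(q2.5 = q[1L], median = q[2L], q97.5 = q[3L])
}

#' Pairwise method comparison over the permutation distribution
#'
#' For each ordered pair of methods and each metric, the per-split difference
#' `metric(method_a) - metric(method_b)` is computed across the shared split
#' set and summarized by its median and 2.5/97.5 percentiles (the permutation
#' distribution over cohort partitions). Positive differences favor the
#' first-listed method. Splits where either method failed are dropped
#' pairwise-listwise.
#'
#' @param records a [run_split_validation()] result.
#' @param pairs optional list of `c(method_a, method_b)` pairs; default all
#'   ordered pairs of distinct methods present.
#' @return data frame of class `pairwise_summary`: `method_a`, `method_b`,
#'   `metric`, `median`, `q2.5`, `q97.5`, `n_splits`.
#' @export
compare_methods_pairwise <- function(records, pairs = NULL) {
  stopifnot(inherits(records, "split_validation"))
  methods <- unique(records$method)
  split_sets <- lapply(split(records$split_id, records$method),
                       function(x) sort(unique(x)))
  if (!all(vapply(split_sets, identical, logical(1), split_sets[[1L]]))) {
    stop("methods do not cover identical split sets", call. = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- list()
    for (a in methods) for (b in methods) {
      if (a != b) pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  metrics <- c("auc", "neg_hls", "net_benefit")
  out <- list()
  for (p in pairs) {
    ra <- records[records$method == p[1L], ]
    rb <- records[records$method == p[2L], ]
    ra <- ra[order(ra$split_id), ]
    rb <- rb[order(rb$split_id), ]
    stopifnot(identical(ra$split_id, rb$split_id))
    for (met in metrics) {
      diff <- ra[[met]] - rb[[met]]
      diff <- diff[is.finite(diff)]
      q <- .quantile_summary(diff)
      out[[length(out) + 1L]] <- data.frame(
        method_a = p[1L], method_b = p[2L], metric = met,
        median = q[["median"]], q2.5 = q[["q2.5"]], q97.5 = q[["q97.5"]],
        n_splits = length(diff), stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out),
            class = c("pairwise_summary", "data.frame"))
}

#' Leave-one-cohort-out influence on the validation distribution
#'
#' Repeats the exhaustive split validation once with all cohorts (baseline)
#' and once per excluded cohort on the reduced cohort set, summarizing each
#' metric's permutation distribution (median, 2.5/97.5 percentiles). On a
#' reduced set the test size is capped at one less than the number of
#' remaining cohorts so both halves stay nonempty.
#'
#' @inheritParams run_split_validation
#' @return list of class `loco_result` with `baseline` (records), `excluded`
#'   (named list of records) and `summary` (data frame: `excluded_cohort`
#'   — `"<none>"` for the baseline — `method`, `metric`, `median`, `q2.5`,
#'   `q97.5`, `n_splits`).
#' @export
leave_one_cohort_out <- function(table, methods = .methods, test_size = 5L,
                                 threshold = 0.15, seed = 1L, nAGQ = 15L) {
  table <- as_cohort_table(table)
  ids <- sort(unique(table$cohort))
  if (length(ids) < 3L) stop("need at least 3 cohorts", call. = FALSE)
  summarize <- function(records, label) {
    out <- list()
    for (method in unique(records$method)) {
      r <- records[records$method == method, ]
      for (met in c("auc", "neg_hls", "net_benefit")) {
        v <- r[[met]][is.finite(r[[met]])]
        q <- .quantile_summary(v)
        out[[length(out) + 1L]] <- data.frame(
          excluded_cohort = label, method = method, metric = met,
          median = q[["median"]], q2.5 = q[["q2.5"]], q97.5 = q[["q97.5"]],
          n_splits = length(v), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  ts_base <- min(test_size, length(ids) - 1L)
  baseline <- run_split_validation(table, methods, ts_base, threshold,
                                   seed, nAGQ)
  excluded <- list()
  summaries <- list(summarize(baseline, "<none>"))
  for (ex in ids) {
    sub <- table[table$cohort != ex, , drop = FALSE]
    ts <- min(test_size, length(ids) - 2L)
    recs <- run_split_validation(sub, methods, ts, threshold, seed, nAGQ)
    excluded[[ex]] <- recs
    summaries[[length(summaries) + 1L]] <- summarize(recs, ex)
  }
  structure(list(baseline = baseline, excluded = excluded,
                 summary = do.call(rbind, summaries)),
            class = "loco_result")
}

#' @export
print.loco_result <- function(x, ...) {
  cat("Leave-one-cohort-out validation summary\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Influence of a designated cohort on single-cohort validation
#'
#' Addresses whether one designated cohort should stay in the model-building
#' pool. Each remaining cohort serves in turn as the sole test set; a model is
#' fitted on all other cohorts including the designated cohort and again on
#' all others excluding it, and the difference in each metric —
#' metric(with designated cohort in training) minus metric(without) — is
#' reported, so positive values mean its inclusion helps that test cohort.
#' The AUC difference carries a paired analytic (DeLong) 95% interval; the
#' -HLS and net-benefit differences carry bootstrap 2.5-97.5 percentile
#' intervals computed on resamples of test-set individuals shared by the two
#' models.
#'
#' @param table a cohort table with at least 3 cohorts.
#' @param excluded cohort id whose influence is assessed.
#' @param threshold net-benefit risk threshold.
#' @param B bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param method modeling method used for both fits (default pooled, the
#'   strategy a final consortium model would use).
#' @param nAGQ quadrature nodes if a random-intercept method is chosen.
#' @return data frame of class `exclusion_influence`: `test_cohort`, `metric`,
#'   `estimate` (difference), `lo`, `hi`, `interval_type`.
#' @export
cohort_exclusion_influence <- function(table, excluded, threshold = 0.15,
                                       B = 1000L, seed = 1L,
                                       method = "pooled", nAGQ = 15L) {
  table <- impute_binary_missing(as_cohort_table(table))
  ids <- sort(unique(table$cohort))
  if (!excluded %in% ids) stop("unknown cohort: ", excluded, call. = FALSE)
  if (length(ids) < 3L) stop("need at least 3 cohorts", call. = FALSE)
  out <- list()
  for (tst in setdiff(ids, excluded)) {
    test <- table[table$cohort == tst, , drop = FALSE]
    train_full <- table[!table$cohort %in% c(tst), , drop = FALSE]
    train_red <- table[!table$cohort %in% c(tst, excluded), , drop = FALSE]
    fit_one <- function(train) {
      params <- fit_preprocessing(train, source = "training_only")
      m <- fit_risk_model(build_design_matrix(train, params), method,
                          nAGQ = nAGQ)
      stats::predict(m, build_design_matrix(test, params))
    }
    risks_full <- fit_one(train_full)
    risks_red <- fit_one(train_red)
    y <- test$outcome
    # AUC: paired analytic interval
    a <- auc_diff_ci(risks_full, risks_red, y)
    out[[length(out) + 1L]] <- data.frame(
      test_cohort = tst, metric = "auc", estimate = a$estimate,
      lo = a$interval[1L], hi = a$interval[2L], interval_type = "analytic",
      stringsAsFactors = FALSE)
    # -HLS and net benefit: bootstrap with shared resamples
    neg_hls <- function(r, o) -hosmer_lemeshow(r, o)$estimate
    nb <- function(r, o) net_benefit(r, o, threshold)$estimate
    boots <- .paired_bootstrap_diff(
      list(neg_hls = neg_hls, net_benefit = nb),
      risks_full, risks_red, y, B = B,
      seed = seed + match(tst, ids))
    for (met in names(boots)) {
      b <- boots[[met]]
      out[[length(out) + 1L]] <- data.frame(
        test_cohort = tst, metric = met, estimate = b$estimate,
        lo = b$lo, hi = b$hi, interval_type = "bootstrap_percentile",
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out),
            class = c("exclusion_influence", "data.frame"),
            excluded = excluded, threshold = threshold, B = B, seed = seed)
}

# Bootstrap percentile intervals for differences of several metrics between
# two risk vectors on the same test rows, sharing the resample indices.
.paired_bootstrap_diff <- function(metric_fns, risks_a, risks_b, outcomes,
                                   B, seed, max_redraws = 10L * B) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- length(outcomes)
  draws <- matrix(NA_real_, nrow = B, ncol = length(metric_fns),
                  dimnames = list(NULL, names(metric_fns)))
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcomes[idx])) == 2L) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("bootstrap redraw cap exceeded", call. = FALSE)
      }
    }
    for (met in names(metric_fns)) {
      f <- metric_fns[[met]]
      draws[b, met] <- f(risks_a[idx], outcomes[idx]) -
        f(risks_b[idx], outcomes[idx])
    }
  }
  out <- list()
  for (met in names(metric_fns)) {
    f <- metric_fns[[met]]
    q <- stats::quantile(draws[, met], c(0.025, 0.975), type = 7, names = FALSE)
    out[[met]] <- list(
      estimate = f(risks_a, outcomes) - f(risks_b, outcomes),
      lo = q[1L], hi = q[2L])
  }
  out
}
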