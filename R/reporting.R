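#' Per-cohort univariate odds ratios for the six risk factors
#'
#' For each cohort and each risk factor, the 2x2-table odds ratio for
#' association with the high-grade outcome, with a Wald interval and p-value
#' on the log-odds-ratio scale. For display purposes the two continuous
#' factors are binarized: PSA at 4 ng/ml and age at 65 years (the low-risk
#' strata being PSA <= 4 and age <= 65). Rows with the factor missing are
#' excluded from that factor's table (not imputed). Cohort-factor cells with
#' any count below `min_cell` are suppressed — too few events to estimate the
#' odds ratio reliably. A zero cell at or above `min_cell` (only possible with
#' `min_cell = 0`) gets the Haldane-Anscombe 0.5 correction.
#'
#' @param table a cohort table.
#' @param min_cell minimum 2x2 cell count below which the estimate is
#'   suppressed (default 5).
#' @return data frame of class `univariate_ors`: `cohort`, `factor`, `or`,
#'   `lo`, `hi`, `p_value`, `prevalence` (of the factor in the cohort),
#'   `suppressed`.
#' @export
univariate_ors <- function(table, min_cell = 5L) {
  table <- as_cohort_table(table)
  factors <- list(
    psa_gt4 = function(t) ifelse(is.na(t$psa), NA, as.numeric(t$psa > 4)),
    age_gt65 = function(t) ifelse(is.na(t$age), NA, as.numeric(t$age > 65)),
    dre = function(t) t$dre,
    african = function(t) t$african,
    famhx = function(t) t$famhx,
    priorneg = function(t) t$priorneg
  )
  out <- list()
  for (cid in sort(unique(table$cohort))) {
    sub <- table[table$cohort == cid, , drop = FALSE]
    for (fname in names(factors)) {
      e <- factors[[fname]](sub)
      keep <- !is.na(e) & !is.na(sub$outcome)
      e <- e[keep]
      y <- sub$outcome[keep]
      cells <- c(a = sum(e == 1 & y == 1), b = sum(e == 1 & y == 0),
                 c = sum(e == 0 & y == 1), d = sum(e == 0 & y == 0))
      prev <- if (length(e)) mean(e) else NA_real_
      if (any(cells < min_cell) || length(e) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          cohort = cid, factor = fname, or = NA_real_, lo = NA_real_,
          hi = NA_real_, p_value = NA_real_, prevalence = prev,
          suppressed = TRUE, stringsAsFactors = FALSE)
        next
      }
      if (any(cells == 0)) cells <- cells + 0.5
      lor <- log(cells["a"]) + log(cells["d"]) - log(cells["b"]) - log(cells["c"])
      se <- sqrt(sum(1 / cells))
      z <- lor / se
      out[[length(out) + 1L]] <- data.frame(
        cohort = cid, factor = fname, or = exp(lor),
        lo = exp(lor - 1.96 * se), hi = exp(lor + 1.96 * se),
        p_value = 2 * stats::pnorm(-abs(z)), prevalence = prev,
        suppressed = FALSE, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out),
            class = c("univariate_ors", "data.frame"),
            min_cell = min_cell)
}

.cohorts_by_prevalence <- function(table) {
  prev <- tapply(table$outcome, table$cohort, mean, na.rm = TRUE)
  names(sort(prev, decreasing = TRUE))
}

#' Cohort prevalence bar chart
#'
#' Prevalence of the high-grade outcome per cohort, ordered from highest to
#' lowest, with the cohort sample size annotated on each bar.
#'
#' @param table a cohort table.
#' @param file optional path; when given the figure is also written there.
#' @return a ggplot object (invisibly written to `file` if requested).
#' @export
plot_prevalence <- function(table, file = NULL) {
  table <- as_cohort_table(table)
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  df <- do.call(rbind, lapply(split(table, table$cohort), function(s) {
    data.frame(cohort = s$cohort[1L], prevalence = mean(s$outcome),
               n = nrow(s), stringsAsFactors = FALSE)
  }))
  df$cohort <- factor(df$cohort, levels = .cohorts_by_prevalence(table))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cohort, y = .data$prevalence)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Prevalence of high-grade cancer") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 7, height = 4, dpi = 150)
  p
}

#' Stacked risk-factor distributions per cohort
#'
#' For each of the six risk factors (PSA and age binarized at 4 ng/ml and 65
#' years), the per-cohort proportions of the low-risk, high-risk and missing
#' categories, stacked, with cohorts ordered by outcome prevalence (highest
#' at top) as in [plot_prevalence()].
#'
#' @inheritParams plot_prevalence
#' @return a ggplot object.
#' @export
plot_factor_stacks <- function(table, file = NULL) {
  table <- as_cohort_table(table)
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  lvl <- rev(.cohorts_by_prevalence(table))
  vals <- list(
    psa_gt4 = as.numeric(table$psa > 4),
    age_gt65 = as.numeric(table$age > 65),
    dre = table$dre, african = table$african,
    famhx = table$famhx, priorneg = table$priorneg
  )
  pieces <- list()
  for (fname in names(vals)) {
    v <- vals[[fname]]
    cat3 <- ifelse(is.na(v), "NA", ifelse(v == 1, "yes", "no"))
    tab <- as.data.frame(table(cohort = table$cohort, category = cat3),
                         stringsAsFactors = FALSE)
    tab$factor <- fname
    pieces[[fname]] <- tab
  }
  df <- do.call(rbind, pieces)
  df$cohort <- factor(df$cohort, levels = lvl)
  df$category <- factor(df$category, levels = c("yes", "no", "NA"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Freq, y = .data$cohort,
                                        fill = .data$category)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::facet_wrap(~factor, nrow = 2) +
    ggplot2::scale_fill_manual(values = c(yes = "grey20", no = "grey70",
                                          "NA" = "tomato")) +
    ggplot2::labs(x = "Proportion of biopsies", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 9, height = 5, dpi = 150)
  p
}

#' Odds ratio versus risk-factor prevalence
#'
#' Scatter of each cohort's univariate odds ratio (log scale) against the
#' factor's prevalence in that cohort, one panel per factor; estimates
#' significant at the 0.05 level are drawn solid, others hollow. Suppressed
#' cohort-factor cells are omitted.
#'
#' @param ors a [univariate_ors()] result.
#' @param file optional output path.
#' @return a ggplot object.
#' @export
plot_or_vs_prevalence <- function(ors, file = NULL) {
  stopifnot(inherits(ors, "univariate_ors"))
  df <- ors[!ors$suppressed, , drop = FALSE]
  if (nrow(df) == 0L) stop("all odds ratios suppressed", call. = FALSE)
  df$significant <- df$p_value < 0.05
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$prevalence, y = .data$or,
                                        shape = .data$significant)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, color = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$cohort), vjust = -0.8,
                       size = 2.5) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                labels = c(`TRUE` = "p < 0.05",
                                           `FALSE` = "n.s.")) +
    ggplot2::facet_wrap(~factor, scales = "free") +
    ggplot2::labs(x = "Risk-factor prevalence in cohort",
                  y = "Univariate odds ratio (log scale)", shape = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 9, height = 6, dpi = 150)
  p
}

#' Write a reproducibility manifest for a run
#'
#' Records input-file MD5 hashes, the configuration used, the seed, R and
#' package versions, and the declared output paths (with hashes for those that
#' exist), so a seeded run can be replayed and checked bit-for-bit.
#'
#' @param path manifest output path (JSON).
#' @param inputs character vector of input file paths.
#' @param config list of configuration values (seed included here or via
#'   `seed`).
#' @param seed integer seed used by the run.
#' @param outputs character vector of output file paths.
#' @return the manifest list, invisibly; written to `path`.
#' @export
write_run_manifest <- function(path, inputs = character(), config = list(),
                               seed = NULL, outputs = character()) {
  hash <- function(files) {
    if (length(files) == 0L) return(NULL)
    h <- as.list(tools::md5sum(files))
    names(h) <- files
    h
  }
  pkgs <- c("cohortrisk", "lme4", "pracma", "jsonlite", "ggplot2")
  versions <- lapply(pkgs, function(p)
    tryCatch(as.character(utils::packageVersion(p)), error = function(e) NA))
  names(versions) <- pkgs
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = as.character(getRversion()),
    packages = versions,
    seed = seed,
    config = config,
    inputs = hash(inputs),
    outputs = hash(outputs[file.exists(outputs)]),
    declared_outputs = as.list(outputs)
  )
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir,
                             call. = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
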