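# Cohort-level descriptive statistics over per-child metric records:
# Spearman correlations with Benjamini-Hochberg adjustment, the count
# transform, the age x childcare regression, rank-sum group comparison,
# and the summary/correlation report tables.

#' Spearman rank correlation with two-sided p-value
#'
#' Average-rank tie handling; pairs with a missing value in either vector
#' are dropped listwise.  The p-value uses the t approximation (the standard
#' tie-robust choice).
#'
#' @param x,y paired numeric vectors.
#' @return list: `statistic` (`"rho"`), `value`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    return(list(statistic = "rho", value = NA_real_, p_value = NA_real_, n = n))
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
  list(statistic = "rho", value = unname(ct$estimate),
       p_value = ct$p.value, n = n)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a vector of p-values; `NA`s are passed through.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Square-root-plus-half transform for small counts
#'
#' `sqrt(x + 0.5)`, the classical variance-stabilizing transform applied to
#' network size before regression.
#'
#' @param x numeric vector of nonnegative counts.
#' @return transformed vector.
#' @export
sqrt_half_transform <- function(x) {
  stopifnot(all(x >= 0, na.rm = TRUE))
  sqrt(x + 0.5)
}

#' Regression of network size on age, childcare and their interaction
#'
#' Ordinary least squares of the sqrt+0.5-transformed network size on child
#' age (months), out-of-home childcare (logical) and the age x childcare
#' interaction.
#'
#' @param metrics a `csnq_metrics` data.frame (needs `network_size`,
#'   `age_months`, `childcare_out_of_home`).
#' @return list: `fit` (the `lm` object), `r_squared`, `f_statistic`, `df`,
#'   `p_value`, and `coefficients` (data.frame term/beta/p).
#' @export
regression_age_childcare <- function(metrics) {
  d <- data.frame(y = sqrt_half_transform(metrics$network_size),
                  age = metrics$age_months,
                  childcare = metrics$childcare_out_of_home)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  for (v in c("age", "childcare"))
    if (length(unique(d[[v]])) < 2L)
      stop(sprintf("constant predictor '%s'; cannot fit interaction model", v),
           call. = FALSE)
  fit <- stats::lm(y ~ age * childcare, data = d)
  sm <- summary(fit)
  co <- stats::coef(sm)
  fstat <- sm$fstatistic
  list(fit = fit,
       r_squared = sm$r.squared,
       f_statistic = unname(fstat[1]),
       df = unname(fstat[2:3]),
       p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       coefficients = data.frame(term = rownames(co),
                                 beta = co[, "Estimate"],
                                 p_value = co[, "Pr(>|t|)"],
                                 row.names = NULL))
}

#' Two-sample rank-sum comparison
#'
#' Wilcoxon rank-sum (Mann-Whitney) comparison of two independent groups,
#' reporting the Mann-Whitney `W` statistic for the first group.  Small
#' samples (total n at most `exact_max_n`) use exact enumeration of the
#' permutation null (two-sided by distance from the null mean, which
#' handles ties); larger samples use the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param group_a,group_b numeric vectors (NAs dropped).
#' @param exact_max_n largest total sample size for the exact enumeration
#'   path (default 20).
#' @return list: `statistic` (`"W"`), `value`, `p_value`, `n` (total).
#' @export
rank_sum_test <- function(group_a, group_b, exact_max_n = 20) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max_n) {
    combs <- utils::combn(n1 + n2, n1)
    Ws <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-12)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
  list(statistic = "W", value = W, p_value = p, n = n1 + n2)
}

# metric columns reported in the standard tables, in display order
metric_columns <- function() {
  c("network_size", "n_low_intensity", "n_high_intensity",
    "prop_high_intensity", "prop_kin", "prop_adult", "density",
    "n_components", "component_ratio", "racial_entropy", "racial_ei",
    "language_entropy", "linguistic_ei")
}

#' Cohort summary table (mean, SD, range per metric)
#'
#' @param metrics a `csnq_metrics` data.frame.
#' @param columns metric columns to summarize (default: the standard set
#'   present in `metrics`).
#' @return data.frame with columns `metric`, `mean`, `sd`, `min`, `max`, `n`
#'   (non-missing count per metric).
#' @export
summary_table <- function(metrics, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(metric_columns(), names(metrics))
  rows <- lapply(columns, function(col) {
    v <- metrics[[col]]
    v <- v[!is.na(v)]
    data.frame(metric = col,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation table against anchor variables
#'
#' Spearman rho of each metric against each anchor (by default network size
#' and child age), with Benjamini-Hochberg adjustment across all cells of
#' the emitted table.  Rows for metrics observed only on a subset (e.g.
#' density) use the pairs where both values exist.
#'
#' @param metrics a `csnq_metrics` data.frame.
#' @param anchors named list of anchor vectors; default
#'   `list(network_size = ..., age_months = ...)` taken from `metrics`.
#' @param columns metric columns to correlate (default: standard set minus
#'   the anchor itself per cell).
#' @return data.frame with columns `metric`, `anchor`, `rho`, `p_value`,
#'   `adjusted_p`, `n`; attribute `"adjust_method" = "BH"`.
#' @export
correlation_table <- function(metrics, anchors = NULL, columns = NULL) {
  if (is.null(anchors))
    anchors <- list(network_size = metrics$network_size,
                    age_months = metrics$age_months)
  if (is.null(columns))
    columns <- intersect(metric_columns(), names(metrics))
  rows <- list()
  for (anch in names(anchors)) {
    for (col in setdiff(columns, anch)) {
      r <- spearman_rho(metrics[[col]], anchors[[anch]])
      rows[[length(rows) + 1L]] <-
        data.frame(metric = col, anchor = anch, rho = r$value,
                   p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- fdr_adjust(out$p_value)
  out <- out[, c("metric", "anchor", "rho", "p_value", "adjusted_p", "n")]
  rownames(out) <- NULL
  attr(out, "adjust_method") <- "BH"
  out
}

#' Full cohort descriptive analysis
#'
#' Runs the standard descriptive battery over a scored cohort: the summary
#' table, the correlation table against network size and age (FDR
#' corrected), the age x childcare regression on transformed network size,
#' and the rank-sum comparison of network size between childcare groups.
#'
#' @param metrics a `csnq_metrics` data.frame.
#' @return object of class `csnq_analysis`: list with `summary_table`,
#'   `correlation_table`, `age_regression` (or NULL if childcare is
#'   unavailable/constant), `childcare_ranksum` (ditto), `n`.
#' @export
csnq_analyze <- function(metrics) {
  reg <- tryCatch(regression_age_childcare(metrics), error = function(e) NULL)
  rs <- NULL
  cc <- metrics$childcare_out_of_home
  if (!is.null(cc) && length(unique(cc[!is.na(cc)])) == 2L) {
    rs <- rank_sum_test(metrics$network_size[which(cc)],
                        metrics$network_size[which(!cc)])
  }
  structure(list(summary_table = summary_table(metrics),
                 correlation_table = correlation_table(metrics),
                 age_regression = reg,
                 childcare_ranksum = rs,
                 n = nrow(metrics)),
            class = "csnq_analysis")
}

#' Write a cohort analysis to report files
#'
#' Emits `table1.csv` (per-metric mean/SD/range/n) and `table2.csv`
#' (Spearman rho and BH-adjusted p against network size and age) into a
#' directory, each with a JSON metadata sidecar
#' (see [write_run_metadata()]).
#'
#' @param analysis a `csnq_analysis` object.
#' @param dir output directory (created if needed).
#' @param ... extra metadata fields recorded in the sidecars.
#' @return character vector of the files written, invisibly.
#' @export
write_analysis <- function(analysis, dir, ...) {
  stopifnot(inherits(analysis, "csnq_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t1 <- file.path(dir, "table1.csv")
  t2 <- file.path(dir, "table2.csv")
  utils::write.csv(analysis$summary_table, t1, row.names = FALSE)
  utils::write.csv(analysis$correlation_table, t2, row.names = FALSE)
  write_run_metadata(t1, n = analysis$n, ...)
  write_run_metadata(t2, n = analysis$n, adjust_method = "BH", ...)
  invisible(c(t1, t2))
}

#' @export
print.csnq_analysis <- function(x, ...) {
  cat(sprintf("CSNQ cohort analysis (n = %d children)\n\n", x$n))
  cat("Per-metric summary (mean, SD, range, n):\n")
  print(x$summary_table, digits = 3)
  cat("\nSpearman correlations vs network size and age (BH-adjusted):\n")
  print(x$correlation_table, digits = 3)
  if (!is.null(x$age_regression)) {
    r <- x$age_regression
    cat(sprintf(
      "\nOLS sqrt(size+0.5) ~ age * childcare: R^2 = %.3f, F(%d, %d) = %.1f, p = %.3g\n",
      r$r_squared, r$df[1], r$df[2], r$f_statistic, r$p_value))
    print(r$coefficients, digits = 3)
  }
  if (!is.null(x$childcare_ranksum)) {
    rs <- x$childcare_ranksum
    cat(sprintf("\nRank-sum, size by childcare: W = %.0f, p = %.3g (n = %d)\n",
                rs$value, rs$p_value, rs$n))
  }
  invisible(x)
}
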