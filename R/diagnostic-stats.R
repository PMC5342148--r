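#' Cross-tabulate two categorical variables
#'
#' Builds a labeled r x c count table from a per-case tibble. Cases missing
#' either variable are excluded and the excluded count is reported
#' alongside, never silently dropped.
#'
#' @param data Per-case tibble (e.g. an annotated cohort).
#' @param row_var,col_var Column names (strings) of categorical variables.
#' @param row_levels,col_levels Optional explicit level orders. Defaults:
#'   factor levels, `TRUE` before `FALSE` for logicals, sorted unique values
#'   otherwise.
#' @return An object of class `ragc_crosstab`: a list with the count
#'   `matrix` (`counts`), the variable names, and `n_excluded`.
#' @examples
#' df <- tibble::tibble(a = c("x", "x", "y"), b = c("u", "v", "u"))
#' crosstab(df, "a", "b")
#' @export
crosstab <- function(data, row_var, col_var,
                     row_levels = NULL, col_levels = NULL) {
  for (v in c(row_var, col_var)) {
    if (!v %in% names(data)) {
      abort(sprintf("Variable `%s` not found. Available: %s.",
                    v, paste(names(data), collapse = ", ")))
    }
  }
  default_levels <- function(x) {
    if (is.factor(x)) levels(x)
    else if (is.logical(x)) c(TRUE, FALSE)
    else sort(unique(x[!is.na(x)]))
  }
  r <- data[[row_var]]
  cc <- data[[col_var]]
  keep <- !is.na(r) & !is.na(cc)
  row_levels <- row_levels %||% default_levels(r)
  col_levels <- col_levels %||% default_levels(cc)
  counts <- table(
    factor(r[keep], levels = row_levels),
    factor(cc[keep], levels = col_levels)
  )
  counts <- matrix(as.integer(counts), nrow = length(row_levels),
                   dimnames = list(as.character(row_levels),
                                   as.character(col_levels)))
  structure(
    list(counts = counts, row_var = row_var, col_var = col_var,
         n_excluded = sum(!keep)),
    class = "ragc_crosstab"
  )
}

#' @export
print.ragc_crosstab <- function(x, ...) {
  cat(sprintf("<ragc_crosstab> %s x %s (%d excluded)\n",
              x$row_var, x$col_var, x$n_excluded))
  print(x$counts)
  invisible(x)
}

#' @export
as.matrix.ragc_crosstab <- function(x, ...) x$counts

#' @importFrom generics tidy
#' @export
tidy.ragc_crosstab <- function(x, ...) {
  as_tibble(as.data.frame.table(as.table(x$counts),
                                responseName = "n",
                                stringsAsFactors = FALSE)) |>
    setNames(c(x$row_var, x$col_var, "n"))
}

as_count_matrix <- function(x) {
  if (inherits(x, "ragc_crosstab")) x <- x$counts
  x <- as.matrix(x)
  if (any(x < 0) || any(x != round(x))) {
    abort("Counts must be non-negative integers.")
  }
  x
}

#' Screening sensitivity and specificity
#'
#' For a 2 x 2 table with screen status in rows (screen-positive first) and
#' truth in columns (truth-positive first): sensitivity is the share of
#' truth-positive cases captured by the screen-positive group,
#' `100 * tp / (tp + fn)`; specificity is the share of truth-negative cases
#' outside it, `100 * tn / (tn + fp)`.
#'
#' @param x A 2 x 2 matrix / [crosstab()] in the orientation above, or
#'   `NULL` when the four cells are given directly.
#' @param tp,fp,fn,tn Cell counts (alternative to `x`).
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity` (percent, full precision).
#' @examples
#' screening_accuracy(tp = 91, fp = 584, fn = 13, tn = 305)
#' @export
screening_accuracy <- function(x = NULL, tp = NULL, fp = NULL,
                               fn = NULL, tn = NULL) {
  if (!is.null(x)) {
    m <- as_count_matrix(x)
    if (!all(dim(m) == c(2, 2))) {
      abort("`x` must be a 2 x 2 table.")
    }
    tp <- m[1, 1]; fp <- m[1, 2]; fn <- m[2, 1]; tn <- m[2, 2]
  }
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) abort("Cell counts must be non-negative.")
  if (tp + fn == 0) {
    abort("Sensitivity undefined: no truth-positive cases.",
          class = "ragc_degenerate_error")
  }
  tibble(
    tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), tn = as.integer(tn),
    sensitivity = 100 * tp / (tp + fn),
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  )
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square (expected counts from the margins,
#' `df = (r-1)(c-1)`), matching the conventional cross-table analysis of
#' statistical packages; the Yates continuity-corrected statistic is also
#' reported for 2 x 2 tables for transparency.
#'
#' @param x Count matrix or [crosstab()].
#' @return One-row tibble: `statistic`, `df`, `p_value`, and (2 x 2 only)
#'   `statistic_yates`, `p_value_yates`.
#' @export
pearson_chi_square <- function(x) {
  m <- as_count_matrix(x)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Degenerate table: a row or column margin is zero.",
          class = "ragc_degenerate_error")
  }
  fit <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  out <- tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value
  )
  if (all(dim(m) == c(2, 2))) {
    yates <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    out$statistic_yates <- unname(yates$statistic)
    out$p_value_yates <- yates$p.value
  }
  out
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided exact p-value: with margins fixed, the probabilities of all
#' tables no more likely than the observed one are summed (the standard
#' two-sided rule for 2 x 2 tables).
#'
#' @param x 2 x 2 count matrix or [crosstab()].
#' @return One-row tibble with `p_value` and the conditional ML
#'   `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(x) {
  m <- as_count_matrix(x)
  if (!all(dim(m) == c(2, 2))) {
    abort("`x` must be a 2 x 2 table.")
  }
  fit <- stats::fisher.test(m)
  tibble(p_value = fit$p.value, odds_ratio = unname(fit$estimate))
}

#' Association test with conventional auto-selection
#'
#' Uses Fisher's exact test when any expected cell of a 2 x 2 table is
#' below 5, and the uncorrected Pearson chi-square otherwise. The chosen
#' method is reported so every table's test is logged.
#'
#' @param x Count matrix or [crosstab()].
#' @return One-row tibble: `method`, `statistic` (`NA` for Fisher), `df`,
#'   `p_value`.
#' @export
test_association <- function(x) {
  m <- as_count_matrix(x)
  use_fisher <- FALSE
  if (all(dim(m) == c(2, 2))) {
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    use_fisher <- any(expected < 5)
  }
  if (use_fisher) {
    res <- fisher_exact_2x2(m)
    tibble(method = "fisher_exact", statistic = NA_real_, df = NA_integer_,
           p_value = res$p_value)
  } else {
    res <- pearson_chi_square(m)
    tibble(method = "pearson_chi_square", statistic = res$statistic,
           df = as.integer(res$df), p_value = res$p_value)
  }
}

#' Two-sample Student t test
#'
#' Pooled-variance two-tailed t test, computable either from raw samples or
#' from the summary statistics (mean, SD, n) printed in cohort tables.
#' `welch = TRUE` gives the unequal-variance alternative (raw or summary
#' input alike).
#'
#' @param x,y Optional raw numeric samples.
#' @param mean1,sd1,n1,mean2,sd2,n2 Summary statistics (used when `x`/`y`
#'   are not supplied).
#' @param welch Use the Welch-Satterthwaite approximation instead of the
#'   pooled variance. Default `FALSE`.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_diff`.
#' @examples
#' two_sample_t(mean1 = 60.3, sd1 = 9.7, n1 = 104,
#'              mean2 = 55.6, sd2 = 12.7, n2 = 889)
#' @export
two_sample_t <- function(x = NULL, y = NULL,
                         mean1 = NULL, sd1 = NULL, n1 = NULL,
                         mean2 = NULL, sd2 = NULL, n2 = NULL,
                         welch = FALSE) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) abort("Supply both `x` and `y`.")
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) {
    abort("Each group must have at least 2 observations.",
          class = "ragc_degenerate_error")
  }
  if (sd1 <= 0 || sd2 <= 0) {
    abort("Group standard deviations must be positive.",
          class = "ragc_degenerate_error")
  }
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df),
         mean_diff = mean1 - mean2)
}

#' Spearman rank correlation
#'
#' Spearman's rho with midranks for ties (Pearson correlation of the rank
#' vectors), suitable for binary or ordinal marker variables.
#'
#' @param x,y Numeric, logical or ordered vectors of equal length >= 3.
#' @return One-row tibble: `rho`, `n`.
#' @export
rank_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must be equal-length vectors with >= 3 complete pairs.")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("Correlation undefined for a constant vector.",
          class = "ragc_degenerate_error")
  }
  tibble(rho = stats::cor(x, y, method = "spearman"), n = length(x))
}
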