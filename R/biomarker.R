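#' Encode a response category as a biomarker-correlation rank
#'
#' Correlation analyses against biomarker expression use a reversed ordinal
#' coding, 1 = best response to 5 = worst: MCR -> 1, CR -> 2, PR -> 3,
#' SD -> 4, PD -> 5.
#'
#' @param category A `"response_call"` or category string.
#' @return Integer rank in 1..5.
#' @export
rank_encode <- function(category) {
  if (inherits(category, "response_call")) category <- category$category
  category <- match.arg(category, RESPONSE_LEVELS)
  6L - match(category, RESPONSE_LEVELS)
}

#' Correlate biomarker expression with ordinal response
#'
#' Pearson correlation between normalized expression (e.g. a protein band
#' intensity over its loading control) and the 1-5 response rank, treating
#' the rank as numeric.  The two-sided p-value comes from
#' t = r sqrt(n-2)/sqrt(1-r^2) on n-2 degrees of freedom; the 95% CI for r
#' uses the Fisher z-transform.  Spearman's rho is reported alongside as a
#' rank-based robustness companion.
#'
#' @param expression Numeric expression values, >= 0.
#' @param rank Integer response ranks 1-5 (see [rank_encode()]), or response
#'   category strings, which are encoded automatically.
#' @return List of class `"biomarker_cor"`: `n`, `pearson_r`, `p`, `ci95`
#'   (length-2), `spearman_rho`, `spearman_p`.
#' @export
correlate_biomarker <- function(expression, rank) {
  if (is.character(rank)) rank <- vapply(rank, rank_encode, integer(1))
  rank <- as.numeric(rank)
  expression <- as.numeric(expression)
  n <- length(expression)
  if (n != length(rank)) stop("inputs must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 records", call. = FALSE)
  if (stats::sd(expression) == 0 || stats::sd(rank) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  pt <- stats::cor.test(expression, rank, method = "pearson",
                        alternative = "two.sided", conf.level = 0.95)
  st <- suppressWarnings(
    stats::cor.test(expression, rank, method = "spearman",
                    alternative = "two.sided"))
  structure(list(n = n,
                 pearson_r = unname(pt$estimate),
                 p = pt$p.value,
                 ci95 = as.numeric(pt$conf.int),
                 spearman_rho = unname(st$estimate),
                 spearman_p = st$p.value),
            class = "biomarker_cor")
}

#' Two-sided Pearson p-value from a correlation coefficient
#'
#' The t-based p-value implied by a reported (r, n) pair, useful for checking
#' published coefficients: t = r sqrt(n-2)/sqrt(1-r^2) against t(n-2).
#'
#' @param r Pearson correlation coefficient, |r| < 1.
#' @param n Sample size, >= 3.
#' @return Two-sided p-value.
#' @examples
#' pearson_p_from_r(0.88, 6)   # ~0.021
#' @export
pearson_p_from_r <- function(r, n) {
  stopifnot(abs(r) < 1, n >= 3)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' @export
print.biomarker_cor <- function(x, ...) {
  cat(sprintf("Biomarker vs response (n = %d): Pearson r = %.3f (95%% CI %.3f..%.3f), p = %.4g\n",
              x$n, x$pearson_r, x$ci95[1], x$ci95[2], x$p))
  cat(sprintf("  Spearman rho = %.3f, p = %.4g\n", x$spearman_rho,
              x$spearman_p))
  invisible(x)
}

#' Read a biomarker table and correlate with response
#'
#' CSV columns: `model_id,expression,category`.
#'
#' @param path CSV path.
#' @return A `"biomarker_cor"` (see [correlate_biomarker()]).
#' @export
read_biomarker <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("model_id", "expression", "category")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("biomarker CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  correlate_biomarker(df$expression, df$category)
}
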