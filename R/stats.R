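# Nonparametric test battery. All functions return a common `TestResult`
# list (statistic, p_two_sided, n, test_name, degenerate) so pipeline
# reports can tabulate them uniformly; the computations are delegated to
# the standard stats implementations.

test_result <- function(statistic, p, n, name, degenerate = FALSE,
                        extra = list()) {
  structure(c(list(statistic = unname(statistic),
                   p_two_sided = unname(p), n = n, test_name = name,
                   degenerate = degenerate), extra),
            class = "rsvp_test")
}

#' @export
print.rsvp_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, n = %s%s\n", x$test_name,
              x$statistic, x$p_two_sided, paste(x$n, collapse = "/"),
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Paired median comparison (Wilcoxon signed rank, two-tailed)
#'
#' Zero differences are dropped before ranking.  The p value is exact for
#' up to 25 nonzero untied differences and uses the normal approximation
#' with continuity correction otherwise.
#'
#' @param x,y Equal-length paired samples.
#' @return A `TestResult`; degenerate when all differences are zero.
#' @export
paired_median_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(test_result(NA_real_, NA_real_, 0, "wilcoxon_signed_rank",
                       degenerate = TRUE))
  ties <- any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(
    d, exact = (n <= 25 && !ties), correct = TRUE))
  test_result(wt$statistic, wt$p.value, n, "wilcoxon_signed_rank")
}

#' Independent-samples comparison (Mann-Whitney U, two-tailed)
#'
#' Ties are handled by midranks with the tie-corrected variance in the
#' normal approximation; small untied samples use the exact distribution.
#'
#' @param a,b Samples from the two groups (both nonempty).
#' @return A `TestResult` with the U statistic for group `a`.
#' @export
independent_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) < 50 && length(b) < 50
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  test_result(wt$statistic, wt$p.value, c(length(a), length(b)),
              "mann_whitney_u")
}

#' Spearman rank-order correlation
#'
#' Midrank-based rho with a two-sided p value from the t approximation.
#'
#' @param x,y Equal-length samples, `n >= 3`.
#' @return A `TestResult` with `rho`; degenerate when either vector is
#'   constant.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(test_result(NA_real_, NA_real_, n, "spearman",
                       degenerate = TRUE, extra = list(rho = NA_real_)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  test_result(ct$statistic, ct$p.value, n, "spearman",
              extra = list(rho = unname(ct$estimate)))
}

#' Shapiro-Wilk normality check
#'
#' @param x Sample with `3 <= n <= 5000`.
#' @return A `TestResult` with the W statistic; degenerate for constant
#'   input.
#' @export
normality_check <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0)
    return(test_result(NA_real_, NA_real_, n, "shapiro_wilk",
                       degenerate = TRUE))
  st <- stats::shapiro.test(x)
  test_result(st$statistic, st$p.value, n, "shapiro_wilk")
}
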