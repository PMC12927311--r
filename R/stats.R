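new_test_result <- function(statistic, p_value, method, n1, n2 = NA_integer_,
                            p_corrected = NA_real_) {
  structure(list(statistic = statistic, p_value = p_value,
                 p_corrected = p_corrected, n1 = n1, n2 = n2,
                 method = method),
            class = "efr_test")
}

#' @export
print.efr_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, p = %.4g%s (n1 = %d%s)\n", x$method,
              x$statistic, x$p_value,
              if (!is.na(x$p_corrected))
                sprintf(", corrected p = %.4g", x$p_corrected) else "",
              x$n1,
              if (!is.na(x$n2)) sprintf(", n2 = %d", x$n2) else ""))
  invisible(x)
}

#' Wilcoxon rank-sum test (normal approximation, signed z)
#'
#' Two-sample rank-sum test with tie-corrected variance and optional
#' continuity correction, reported as a signed z statistic: negative z
#' means the first sample tends to be smaller than the second (so with the
#' weaker group passed first, z is negative, matching the usual reporting
#' convention for group comparisons).
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param continuity Apply the 0.5 continuity correction (default TRUE).
#' @return An `"efr_test"` with `statistic` = z and two-sided `p_value`.
#' @export
rank_sum_test <- function(x, y, continuity = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2, all(is.finite(c(x, y))))
  N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  E <- n1 * (N + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(new_test_result(0, 1, "Wilcoxon rank-sum", n1, n2))
  cc <- if (continuity) 0.5 * sign(W - E) else 0
  z <- (W - E - cc) / sqrt(sigma2)
  new_test_result(z, 2 * stats::pnorm(-abs(z)), "Wilcoxon rank-sum", n1, n2)
}

#' Wilcoxon signed-rank test (normal approximation, signed z)
#'
#' Paired test on `x - y`: zero differences are dropped, |differences| are
#' ranked with average ranks for ties, and the positive-rank sum is
#' compared to its null expectation with tie-corrected variance and
#' continuity correction. Negative z means `x` tends to be smaller than
#' `y`.
#'
#' @param x,y Paired numeric samples of equal length.
#' @param continuity Apply the 0.5 continuity correction (default TRUE).
#' @return An `"efr_test"` with `statistic` = z and two-sided `p_value`.
#' @export
signed_rank_test <- function(x, y, continuity = TRUE) {
  stopifnot(length(x) == length(y), all(is.finite(c(x, y))))
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(new_test_result(0, 1, "Wilcoxon signed-rank", length(x)))
  if (n < 2) stop("fewer than 2 non-zero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  E <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(new_test_result(0, 1, "Wilcoxon signed-rank", n))
  cc <- if (continuity) 0.5 * sign(V - E) else 0
  z <- (V - E - cc) / sqrt(sigma2)
  new_test_result(z, 2 * stats::pnorm(-abs(z)), "Wilcoxon signed-rank", n)
}

#' Bonferroni correction
#'
#' `min(m * p, 1)` per element; `m` defaults to the number of tests
#' (31 frequencies in the standard per-frequency battery).
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @param m Number of tests (default `length(p_values)`).
#' @return Corrected p values, same length and order.
#' @export
bonferroni_correct <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1), m >= 1)
  pmin(m * p_values, 1)
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks (average ranks for ties), with a
#' t-approximation two-sided p value.
#'
#' @param x,y Numeric samples, n >= 3.
#' @return List with `rho`, `p_value`, `n`. `rho` is NA (with a warning)
#'   when either sample has zero rank variance.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(c(x, y))))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Chi-square test of independence (2 x 2)
#'
#' Pearson chi-square without continuity correction, df = 1, upper-tail p.
#'
#' @param table 2 x 2 matrix of counts.
#' @return An `"efr_test"` with `statistic` = chi-square.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  ct <- stats::chisq.test(table, correct = FALSE)
  if (any(ct$expected <= 0)) stop("expected counts must be positive")
  new_test_result(unname(ct$statistic), ct$p.value,
                  "Chi-square independence",
                  n1 = sum(table[1, ]), n2 = sum(table[2, ]))
}

#' Per-frequency group comparison
#'
#' Compares two groups of per-subject frequency curves at every grid
#' frequency with the rank-sum test, Bonferroni-corrects over the number
#' of frequencies, and flags frequencies significant at the corrected
#' alpha. Group A is the first argument, so negative z means group A
#' responds more weakly.
#'
#' @param curves_a,curves_b Lists of `"efr_curve"` objects (>= 2 subjects
#'   each) on identical frequency grids.
#' @param alpha Significance level after correction (default 0.05).
#' @param continuity Continuity correction for the rank-sum z.
#' @return A list of class `"efr_group_comparison"`: `table` (data.frame
#'   with frequency_hz, mean/SE per group, z, p, p_bonferroni,
#'   significant), `significant_freqs`, `alpha`, `m`.
#' @export
compare_groups_per_frequency <- function(curves_a, curves_b, alpha = 0.05,
                                         continuity = TRUE) {
  stopifnot(length(curves_a) >= 2, length(curves_b) >= 2)
  freqs <- curves_a[[1]]$freqs
  ok <- function(cv) isTRUE(all.equal(cv$freqs, freqs))
  if (!all(vapply(curves_a, ok, logical(1))) ||
      !all(vapply(curves_b, ok, logical(1))))
    stop("all curves must share the same frequency grid")
  A <- do.call(rbind, lapply(curves_a, function(cv) cv$values))
  B <- do.call(rbind, lapply(curves_b, function(cv) cv$values))
  se <- function(v) stats::sd(v) / sqrt(length(v))
  tests <- lapply(seq_along(freqs), function(k)
    rank_sum_test(A[, k], B[, k], continuity = continuity))
  p <- vapply(tests, function(tt) tt$p_value, numeric(1))
  z <- vapply(tests, function(tt) tt$statistic, numeric(1))
  p_corr <- bonferroni_correct(p, m = length(freqs))
  tab <- data.frame(frequency_hz = freqs,
                    mean_a = colMeans(A), se_a = apply(A, 2, se),
                    mean_b = colMeans(B), se_b = apply(B, 2, se),
                    z = z, p = p, p_bonferroni = p_corr,
                    significant = p_corr < alpha)
  structure(list(table = tab, significant_freqs = freqs[tab$significant],
                 alpha = alpha, m = length(freqs)),
            class = "efr_group_comparison")
}

#' @export
print.efr_group_comparison <- function(x, ...) {
  sig <- x$significant_freqs
  cat(sprintf(
    "Per-frequency group comparison (%d frequencies, Bonferroni m = %d, alpha = %g)\n",
    nrow(x$table), x$m, x$alpha))
  if (length(sig))
    cat("  significant at: ", paste(sig, collapse = ", "), " Hz\n", sep = "")
  else cat("  no significant frequencies\n")
  invisible(x)
}
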