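# Interobserver agreement: Bland-Altman limits, two-way absolute-agreement
# ICC, and classification-level concordance on the MPR dichotomy.

#' Bland-Altman limits of agreement between two readers
#'
#' Mean inter-reader difference plus limits at mean +/- 1.96 SD of the
#' differences; about 95% of paired differences are expected inside the
#' limits when differences are Gaussian.
#'
#' @param reader_a,reader_b Paired percentage readings, equal length, n >= 2.
#' @return List of class `limits_of_agreement`: `mean_diff`, `sd_diff`,
#'   `lower`, `upper`, `prop_within`, `n`.
#' @examples
#' limits_of_agreement(c(10, 20, 30), c(12, 18, 33))
#' @export
limits_of_agreement <- function(reader_a, reader_b) {
  if (length(reader_a) != length(reader_b)) {
    stop("readers must supply the same number of paired readings",
         call. = FALSE)
  }
  if (length(reader_a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- reader_a - reader_b
  m <- mean(d)
  s <- stats::sd(d)
  lower <- m - 1.96 * s
  upper <- m + 1.96 * s
  structure(
    list(mean_diff = m, sd_diff = s, lower = lower, upper = upper,
         prop_within = mean(d >= lower & d <= upper), n = length(d)),
    class = "limits_of_agreement"
  )
}

#' @export
print.limits_of_agreement <- function(x, digits = 3, ...) {
  cat("Bland-Altman limits of agreement (n =", x$n, ")\n")
  cat("  mean difference:", round(x$mean_diff, digits),
      " limits: [", round(x$lower, digits), ",", round(x$upper, digits), "]\n")
  cat("  proportion of pairs within limits:", round(x$prop_within, digits), "\n")
  invisible(x)
}

#' Two-way absolute-agreement intraclass correlation, single measurement
#'
#' ICC(2,1): cases and raters are both treated as random effects and
#' systematic rater differences count against agreement — the form
#' appropriate when pathologists are interchangeable. Computed from the
#' two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `MSR` the
#' between-case, `MSC` the between-rater and `MSE` the residual mean square.
#'
#' @param readings Complete numeric matrix, one row per case, one column per
#'   rater (n >= 2 cases, k >= 2 raters, no missing cells).
#' @return The ICC estimate (a single number).
#' @examples
#' m <- cbind(r1 = c(9, 6, 8), r2 = c(2, 1, 4), r3 = c(5, 3, 6))
#' icc_two_way(m)
#' @export
icc_two_way <- function(readings) {
  readings <- as.matrix(readings)
  if (anyNA(readings)) stop("readings matrix must be complete", call. = FALSE)
  n <- nrow(readings)
  k <- ncol(readings)
  if (n < 2L || k < 2L) {
    stop("need at least 2 cases and 2 raters", call. = FALSE)
  }
  grand <- mean(readings)
  row_m <- rowMeans(readings)
  col_m <- colMeans(readings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)                  # cases
  msc <- n * sum((col_m - grand)^2) / (k - 1)                  # raters
  sse <- sum((readings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Concordance of two readers on the MPR dichotomy
#'
#' Dichotomizes both readers' mean viable-tumor percentages at the MPR
#' threshold and reports raw percent agreement and Cohen's kappa
#' (`(p_o - p_e) / (1 - p_e)` with the usual marginal chance agreement).
#'
#' @param reader_a_means,reader_b_means Paired per-case mean viable
#'   percentages.
#' @param threshold MPR cutoff (default 10).
#' @return List with `percent_agreement` (0-100), `cohen_kappa`, and the
#'   2 x 2 `table` of MPR calls.
#' @export
mpr_concordance <- function(reader_a_means, reader_b_means, threshold = 10) {
  if (length(reader_a_means) != length(reader_b_means)) {
    stop("readers must supply the same number of cases", call. = FALSE)
  }
  a <- factor(reader_a_means <= threshold, levels = c(TRUE, FALSE),
              labels = c("mpr", "no_mpr"))
  b <- factor(reader_b_means <= threshold, levels = c(TRUE, FALSE),
              labels = c("mpr", "no_mpr"))
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) {
    # both raters unanimous: agreement is degenerate; kappa 1 iff identical
    if (po == 1) 1 else 0
  } else {
    (po - pe) / (1 - pe)
  }
  list(percent_agreement = 100 * po, cohen_kappa = kappa, table = tab)
}
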