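#' Baseline balance tests on individual-level characteristics
#'
#' Pearson chi-square test of independence for an r x c contingency table of
#' counts, without continuity correction (the convention for multi-cell
#' baseline tables), and a summary-statistic two-sample t test for
#' continuous characteristics. Both operate at the individual level and are
#' meant for checking randomization balance between training arms.
#'
#' @param counts Matrix (or object coercible to one) of non-negative integer
#'   counts, rows = categories, columns = groups.
#' @return A `balance_test` list: `statistic`, `df`, `p`, `kind`, plus
#'   `expected` for the chi-square.
#' @examples
#' gender <- rbind(female = c(60, 55), male = c(35, 36))
#' chi_square_independence(gender)
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("table has an all-zero margin")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop("a cell has zero expected count; use an exact test instead")
  }
  ht <- stats::chisq.test(counts, correct = FALSE)
  structure(
    list(
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p = ht$p.value, kind = "chi_square", expected = ht$expected
    ),
    class = "balance_test"
  )
}

#' @param mean1,sd1,n1 Summary statistics of the first group (`sd1 > 0`,
#'   `n1 >= 2`).
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @param variant `"pooled"` (equal-variance, default) or `"welch"`.
#' @param tails 2 (default, two-sided) or 1.
#' @rdname chi_square_independence
#' @examples
#' t_two_sample(7.6, 9.8, 95, 8.6, 8.98, 91)
#' @export
t_two_sample <- function(mean1, sd1, n1, mean2, sd2, n2,
                         variant = c("pooled", "welch"), tails = 2) {
  variant <- match.arg(variant)
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2, tails %in% c(1, 2))
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (mean1 - mean2) / se
  p <- tails * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(
    list(statistic = tstat, df = df, p = p, kind = "t_two_sample",
         variant = variant, tails = tails),
    class = "balance_test"
  )
}

#' @export
print.balance_test <- function(x, ...) {
  cat(switch(x$kind,
    chi_square = "Pearson chi-square test (no continuity correction)",
    t_two_sample = sprintf("Two-sample t test (%s, %d-sided)", x$variant, x$tails)
  ), "\n")
  cat(sprintf("  statistic = %.4f, df = %s, p = %.4g\n",
              x$statistic, format(round(x$df, 2)), x$p))
  invisible(x)
}

#' A priori sample size for a paired pre/post comparison
#'
#' Smallest number of paired units n such that the paired t test on pre/post
#' differences, with effect size d (mean difference in SD-of-difference
#' units), reaches the target power. Power is computed exactly from the
#' noncentral t distribution with ncp = d * sqrt(n) and df = n - 1.
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param tails 2 (default) or 1.
#' @return List of class `sample_size`: `required_n`, `achieved_power`, and
#'   the inputs. `achieved_power` at `required_n` meets the target while
#'   `required_n - 1` does not.
#' @examples
#' paired_pre_post_sample_size(d = 0.5)            # n = 34
#' paired_pre_post_sample_size(d = 0.5, tails = 1) # n = 27
#' @export
paired_pre_post_sample_size <- function(d, alpha = 0.05, power = 0.80, tails = 2) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > alpha, power < 1, tails %in% c(1, 2))
  pw <- function(n) {
    df <- n - 1
    ncp <- d * sqrt(n)
    tcrit <- stats::qt(1 - alpha / tails, df)
    p <- stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
    if (tails == 2) p <- p + stats::pt(-tcrit, df, ncp = ncp)
    p
  }
  n <- 2L
  while (pw(n) < power) n <- n + 1L
  structure(
    list(required_n = n, achieved_power = pw(n),
         d = d, alpha = alpha, power_target = power, tails = tails),
    class = "sample_size"
  )
}

#' @export
print.sample_size <- function(x, ...) {
  cat(sprintf(
    "Paired pre/post sample size: n = %d (d = %g, alpha = %g, %d-sided)\n",
    x$required_n, x$d, x$alpha, x$tails))
  cat(sprintf("  achieved power at n: %.4f (target %.2f)\n",
              x$achieved_power, x$power_target))
  invisible(x)
}
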