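# Mendelian goodness-of-fit testing for two-class phenotype counts.

#' Upper-tail probability of the chi-squared distribution
#'
#' Survival function of chi-squared with `df` degrees of freedom; for
#' `df = 1` this equals `2 * (1 - pnorm(sqrt(x)))`.
#'
#' @param x Non-negative statistic value(s).
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' chi2_upper_tail(3.84, 1)  # ~0.05
#' @export
chi2_upper_tail <- function(x, df = 1) {
  if (any(x < 0)) stop("statistic must be non-negative")
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Pearson chi-square goodness-of-fit test for a phenotype segregation ratio
#'
#' Tests observed yellow/green counts against a hypothesized Mendelian ratio
#' (e.g. 3:1 for an F2 under a single dominant locus, 1:1 for a backcross to
#' the recessive parent). Uses the plain Pearson statistic
#' `sum((O - E)^2 / E)` on the two classes, 1 degree of freedom, no
#' continuity correction; the verdict applies the conventional 5% level
#' (critical value 3.84).
#'
#' @param n_yellow,n_green Observed counts (non-negative, total > 0).
#' @param ratio Hypothesized yellow:green ratio as a length-2 positive vector
#'   (default `c(3, 1)`).
#' @return An object of class `segregation_test`: list with `n_yellow`,
#'   `n_green`, `ratio`, `expected`, `chi2`, `df`, `p`, `verdict`
#'   (`"fits"` iff `p > 0.05`).
#' @examples
#' chi_square_gof(443, 180, c(3, 1))
#' @export
chi_square_gof <- function(n_yellow, n_green, ratio = c(3, 1)) {
  stopifnot(length(ratio) == 2, all(ratio > 0),
            n_yellow >= 0, n_green >= 0)
  total <- n_yellow + n_green
  if (total < 1) stop("total count must be positive")
  expected <- total * ratio / sum(ratio)
  if (any(expected == 0)) stop("expected counts must be positive")
  obs <- c(n_yellow, n_green)
  chi2 <- sum((obs - expected)^2 / expected)
  p <- chi2_upper_tail(chi2, df = 1)
  structure(list(n_yellow = n_yellow, n_green = n_green, ratio = ratio,
                 expected = expected, chi2 = chi2, df = 1L, p = p,
                 verdict = if (p > 0.05) "fits" else "rejected"),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf(
    "Segregation test: %d yellow : %d green vs %g:%g\n  chi2 = %.4f (df = 1), P = %.4f -> %s the ratio at alpha = 0.05\n",
    x$n_yellow, x$n_green, x$ratio[1], x$ratio[2], x$chi2, x$p,
    if (x$verdict == "fits") "fits" else "rejects"))
  invisible(x)
}
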