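# Group comparison and correlation utilities. The two-sample tests are
# pooled-variance by default (df = n1 + n2 - 2), which matches the
# degrees of freedom reported for the 10-vs-10 group comparisons;
# Welch is available as an option.

#' Pooled two-sample t-test from summary statistics
#'
#' Computes an unpaired two-sample t-test directly from group means,
#' standard deviations and sizes, as needed when only printed summaries
#' are available. The default pooled-variance test has
#' `df = n_1 + n_2 - 2`; the sign of `t` follows `mean_1 - mean_2`.
#'
#' @param mean_1,sd_1,n_1 Summary statistics for the first group.
#' @param mean_2,sd_2,n_2 Summary statistics for the second group.
#' @param welch Use the Welch (unequal-variance) test instead of the
#'   pooled test. Default `FALSE`.
#' @return A one-row data.frame of class `pp_ttest` with `t`, `df`,
#'   `p_value`, and the input summaries.
#' @export
t_test_from_summary <- function(mean_1, sd_1, n_1, mean_2, sd_2, n_2,
                                welch = FALSE) {
  if (n_1 < 2 || n_2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd_1 < 0 || sd_2 < 0) stop("standard deviations must be >= 0",
                                 call. = FALSE)
  if (sd_1 == 0 && sd_2 == 0 && mean_1 == mean_2) {
    stop("t is undefined: both groups are constant and equal", call. = FALSE)
  }
  if (welch) {
    se2_1 <- sd_1^2 / n_1; se2_2 <- sd_2^2 / n_2
    se <- sqrt(se2_1 + se2_2)
    df <- (se2_1 + se2_2)^2 /
      (se2_1^2 / (n_1 - 1) + se2_2^2 / (n_2 - 1))
  } else {
    pooled_var <- ((n_1 - 1) * sd_1^2 + (n_2 - 1) * sd_2^2) / (n_1 + n_2 - 2)
    se <- sqrt(pooled_var * (1 / n_1 + 1 / n_2))
    df <- n_1 + n_2 - 2
  }
  tval <- (mean_1 - mean_2) / se
  out <- data.frame(t = tval, df = df,
                    p_value = 2 * pt(-abs(tval), df),
                    mean_1 = mean_1, mean_2 = mean_2,
                    sd_1 = sd_1, sd_2 = sd_2, n_1 = n_1, n_2 = n_2)
  class(out) <- c("pp_ttest", "data.frame")
  out
}

#' Pooled two-sample t-test from raw data
#'
#' Raw-data twin of [t_test_from_summary()]: identical to applying the
#' summary test to the vectors' means, standard deviations and sizes.
#'
#' @param values_1,values_2 Numeric vectors, each of length >= 2.
#' @param welch Use the Welch test. Default `FALSE` (pooled variance).
#' @return A one-row `pp_ttest` data.frame as in
#'   [t_test_from_summary()].
#' @export
t_test_raw <- function(values_1, values_2, welch = FALSE) {
  if (length(values_1) < 2 || length(values_2) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  ht <- t.test(values_1, values_2, var.equal = !welch)
  out <- data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
                    p_value = ht$p.value,
                    mean_1 = mean(values_1), mean_2 = mean(values_2),
                    sd_1 = stats::sd(values_1), sd_2 = stats::sd(values_2),
                    n_1 = length(values_1), n_2 = length(values_2))
  class(out) <- c("pp_ttest", "data.frame")
  out
}

#' Spearman rank correlation
#'
#' Spearman's rho computed as the Pearson correlation of average-ranked
#' values (ties receive their mean rank). The p-value uses the
#' large-sample t approximation with `df = n - 2`; for `n <= 10`
#' without ties an exact p-value (via the null permutation
#' distribution) can be requested.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact Use the exact null distribution when `n <= 10` and
#'   there are no ties; falls back to the t approximation (with a
#'   warning) otherwise. Default `FALSE`.
#' @return A one-row data.frame with `rho`, `n`, `p_value`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("correlation is undefined for a constant vector", call. = FALSE)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- cor(rx, ry)
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (exact && n <= 10 && !has_ties) {
    p <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    if (exact) {
      warning("exact p-value unavailable (n > 10 or ties); ",
              "using t approximation")
    }
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tval), n - 2)
    }
  }
  data.frame(rho = rho, n = n, p_value = p)
}

#' Compare two model fits by AIC
#'
#' Returns the fit with the lower AIC and the AIC difference. Both
#' fits must be on the same observations; ties go to the first fit by
#' convention.
#'
#' @param fit_a,fit_b `pp_modelfit` objects (see [fit_mixed_logit()]),
#'   or any lists with `aic` and `n_obs` fields.
#' @param labels Length-2 character vector naming the fits.
#' @return A list with `preferred` (label of the lower-AIC fit),
#'   `preferred_fit`, `delta_aic` (AIC of the rejected fit minus AIC of
#'   the preferred fit, >= 0) and `tie`.
#' @export
compare_aic <- function(fit_a, fit_b, labels = c("a", "b")) {
  if (!is.null(fit_a$n_obs) && !is.null(fit_b$n_obs) &&
      fit_a$n_obs != fit_b$n_obs) {
    stop("fits are not comparable: different numbers of observations (",
         fit_a$n_obs, " vs ", fit_b$n_obs, ")", call. = FALSE)
  }
  tie <- fit_a$aic == fit_b$aic
  first <- fit_a$aic <= fit_b$aic
  list(preferred = if (first) labels[1] else labels[2],
       preferred_fit = if (first) fit_a else fit_b,
       delta_aic = abs(fit_b$aic - fit_a$aic),
       tie = tie)
}
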