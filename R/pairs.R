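#' Conditional logistic odds ratio for 1:1 matched pairs
#'
#' Fits the conditional logistic regression for matched pairs with treatment
#' as the only covariate. For 1:1 pairs this likelihood depends on the data
#' only through the discordant pairs, and the maximum-likelihood estimate
#' has the closed form `n10 / n01`, where `n10` counts pairs whose treated
#' member had the outcome and the control did not, and `n01` the reverse.
#' Concordant pairs contribute nothing. The 95% confidence interval is Wald
#' on the log scale, `exp(log(n10/n01) +/- z * sqrt(1/n10 + 1/n01))` with
#' `z = qnorm(0.975)`. If either discordant count is zero the MLE lies on
#' the boundary: the estimate is reported as undefined (`defined = FALSE`)
#' and both significance flags are `FALSE`.
#'
#' @param matched a non-empty `matched_set`.
#' @param cohort the cohort the pairs index into.
#' @return An object of class `paired_estimate`: list with `or_hat`,
#'   `ci_low`, `ci_high`, `n10`, `n01`, `n_pairs`, `defined`,
#'   `significant_low` (CI entirely below 1) and `significant_high`
#'   (CI entirely above 1).
#' @export
conditional_or <- function(matched, cohort) {
  stopifnot(inherits(matched, "matched_set"), inherits(cohort, "cohort"))
  if (nrow(matched$pairs) == 0) {
    stop("matched set is empty; no pairs to analyze")
  }
  yt <- cohort$y[matched$pairs$treated_id]
  yc <- cohort$y[matched$pairs$control_id]
  n10 <- sum(yt == 1L & yc == 0L)
  n01 <- sum(yt == 0L & yc == 1L)
  defined <- n10 > 0L && n01 > 0L
  if (defined) {
    or_hat <- n10 / n01
    se <- sqrt(1 / n10 + 1 / n01)
    z <- qnorm(0.975)
    ci <- exp(log(or_hat) + c(-1, 1) * z * se)
    sig_low <- ci[2] < 1
    sig_high <- ci[1] > 1
  } else {
    or_hat <- NA_real_
    ci <- c(NA_real_, NA_real_)
    sig_low <- FALSE
    sig_high <- FALSE
  }
  structure(
    list(or_hat = or_hat, ci_low = ci[1], ci_high = ci[2],
         n10 = n10, n01 = n01, n_pairs = nrow(matched$pairs),
         defined = defined, significant_low = sig_low,
         significant_high = sig_high),
    class = "paired_estimate"
  )
}

#' @export
print.paired_estimate <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("Matched-pair OR %.3f (95%% CI %.3f-%.3f), n10 = %d, n01 = %d\n",
                x$or_hat, x$ci_low, x$ci_high, x$n10, x$n01))
  } else {
    cat(sprintf("Matched-pair OR undefined (n10 = %d, n01 = %d)\n",
                x$n10, x$n01))
  }
  invisible(x)
}

#' Covariate balance of a matched set
#'
#' Computes, for every covariate, the absolute standardized mean difference
#' (SMD) between the matched treated and matched control groups:
#' `|mean_t - mean_c| / sqrt((s2_t + s2_c) / 2)` with sample variances
#' (denominator n-1); binary covariates enter as their 0/1 means. A matched
#' set is deemed successfully matched when every SMD is at most
#' `threshold` (0.1 by convention). Degenerate cases: both variances zero
#' with equal means gives SMD 0; zero denominator with unequal means gives
#' `Inf`, which forces failure.
#'
#' @param matched a non-empty `matched_set`.
#' @param cohort the cohort the pairs index into.
#' @param threshold imbalance threshold on the SMD scale (default 0.1).
#' @return An object of class `balance_report`: list with `smd` (named
#'   vector over covariates), `max_smd`, `threshold`, `successful`.
#' @export
balance <- function(matched, cohort, threshold = 0.1) {
  stopifnot(inherits(matched, "matched_set"), inherits(cohort, "cohort"))
  if (nrow(matched$pairs) == 0) {
    stop("matched set is empty; balance undefined")
  }
  Xt <- cohort$X[matched$pairs$treated_id, , drop = FALSE]
  Xc <- cohort$X[matched$pairs$control_id, , drop = FALSE]
  mt <- colMeans(Xt)
  mc <- colMeans(Xc)
  vt <- apply(Xt, 2, var)
  vc <- apply(Xc, 2, var)
  if (nrow(Xt) == 1) {
    vt <- rep(0, ncol(Xt))
    vc <- rep(0, ncol(Xc))
  }
  denom <- sqrt((vt + vc) / 2)
  num <- abs(mt - mc)
  smd <- ifelse(denom > 0, num / denom, ifelse(num == 0, 0, Inf))
  names(smd) <- colnames(cohort$X)
  structure(
    list(smd = smd, max_smd = max(smd), threshold = threshold,
         successful = max(smd) <= threshold),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("Balance: max |SMD| = %.4f (threshold %.2f) -> %s\n",
              x$max_smd, x$threshold,
              if (x$successful) "successful" else "unsuccessful"))
  print(round(x$smd, 4))
  invisible(x)
}

#' Crude (unadjusted) odds ratio in the full cohort
#'
#' The 2x2 treatment-by-outcome cross-product ratio before any matching,
#' `(n11 * n00) / (n10 * n01)`. With confounders present this differs from
#' the conditional odds ratio the outcome model encodes; the gap is the
#' confounding the matching is meant to remove.
#'
#' @param cohort a `cohort`.
#' @return The crude odds ratio, or `NA_real_` if any cell of the 2x2
#'   table is zero (undefined).
#' @examples
#' ch <- simulate_cohort(scenario(1000, 0.5, 0.5, 1, seed = 3, n_cal = 1000))
#' crude_or(ch)
#' @export
crude_or <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  n11 <- as.numeric(sum(cohort$t == 1L & cohort$y == 1L))
  n10 <- as.numeric(sum(cohort$t == 1L & cohort$y == 0L))
  n01 <- as.numeric(sum(cohort$t == 0L & cohort$y == 1L))
  n00 <- as.numeric(sum(cohort$t == 0L & cohort$y == 0L))
  if (min(n11, n10, n01, n00) == 0L) return(NA_real_)
  (n11 * n00) / (n10 * n01)
}
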