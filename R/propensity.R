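#' Fit the propensity-score model
#'
#' Estimates the probability of treatment given the covariates by
#' maximum-likelihood logistic regression of `t` on all columns of the
#' cohort's covariate matrix (main effects plus intercept), the standard
#' propensity-score model. Fitting is by iteratively reweighted least
#' squares with a tight convergence tolerance and is fully deterministic
#' given the cohort. Complete or quasi-complete separation is flagged via
#' `converged = FALSE` (fitted probabilities pinned to 0/1) rather than
#' returning silently unstable coefficients.
#'
#' @param cohort a `cohort` from [simulate_cohort()] or [read_cohort()].
#' @return An object of class `propensity_fit`: list with `coefficients`
#'   (intercept first), `ps` (fitted probabilities), `sd_ps` (sample SD of
#'   the scores over the full cohort, denominator n-1), and `converged`.
#' @examples
#' ch <- simulate_cohort(scenario(500, 0.5, 0.5, 1, seed = 1, n_cal = 1000))
#' fit <- fit_propensity(ch)
#' fit$sd_ps
#' @export
fit_propensity <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  t <- cohort$t
  if (all(t == 1L) || all(t == 0L)) {
    stop("cohort must contain both treated and untreated subjects")
  }
  Xd <- cbind(`(Intercept)` = 1, cohort$X)
  fit <- suppressWarnings(glm.fit(
    x = Xd, y = t, family = binomial(),
    control = glm.control(epsilon = 1e-12, maxit = 100)
  ))
  ps <- fit$fitted.values
  separated <- any(ps < 1e-10 | ps > 1 - 1e-10)
  structure(
    list(coefficients = fit$coefficients, ps = as.numeric(ps),
         sd_ps = sd(ps), converged = isTRUE(fit$converged) && !separated),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf(
    "Propensity-score fit: n = %d, sd(ps) = %.4f, converged: %s\n",
    length(x$ps), x$sd_ps, x$converged))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Caliper width as a multiple of the propensity-score SD
#'
#' The caliper is expressed on the probability scale as
#' `multiplier * sd_ps`, where `sd_ps` is the standard deviation of the
#' estimated propensity scores over the full cohort before matching.
#' Multipliers of 0.2 and 0.01 are the widths studied here.
#'
#' @param fit a `propensity_fit`.
#' @param multiplier positive scalar.
#' @return The caliper width on the probability scale.
#' @export
caliper_width <- function(fit, multiplier) {
  stopifnot(inherits(fit, "propensity_fit"),
            is.numeric(multiplier), length(multiplier) == 1,
            is.finite(multiplier))
  if (multiplier <= 0) stop("caliper multiplier must be > 0")
  if (!is.finite(fit$sd_ps) || fit$sd_ps <= 0) {
    stop("propensity scores are constant; caliper width undefined")
  }
  multiplier * fit$sd_ps
}

#' Export per-subject propensity scores as CSV
#'
#' @param fit a `propensity_fit`.
#' @param cohort the cohort the fit was computed on.
#' @param path file path; columns `id`, `t`, `y`, `ps`.
#' @export
write_propensity <- function(fit, cohort, path) {
  stopifnot(inherits(fit, "propensity_fit"), inherits(cohort, "cohort"))
  df <- data.frame(id = seq_along(cohort$t), t = cohort$t, y = cohort$y,
                   ps = fit$ps)
  write_numeric_csv(df, path)
  invisible(path)
}
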