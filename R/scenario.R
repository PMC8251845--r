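#' Define a simulation scenario
#'
#' A scenario is one cell of the simulation design: cohort size, target
#' treatment prevalence, target outcome prevalence, the true conditional
#' treatment-outcome odds ratio, and the covariate specification shared by
#' the treatment and outcome models. Model intercepts are not part of the
#' scenario; they are calibrated numerically by [simulate_cohort()] so that
#' the realized prevalences hit their targets.
#'
#' @param n cohort size (number of subjects).
#' @param p_treat target marginal treatment prevalence, in (0, 1).
#' @param p_outcome target marginal outcome prevalence, in (0, 1).
#' @param true_or true conditional treatment-outcome odds ratio; the outcome
#'   model coefficient of treatment is `log(true_or)`.
#' @param covariates a [covariate_spec()]; defaults to [default_covariates()].
#' @param seed integer seed for drawing the cohort.
#' @param cal_seed integer seed for the intercept-calibration sample; fixed
#'   by default so calibration is reproducible independently of `seed`.
#' @param n_cal size of the calibration sample (default 1e6).
#' @param id optional scenario label used in outputs.
#'
#' @return An object of class `scenario`.
#' @examples
#' sc <- scenario(n = 500, p_treat = 0.2, p_outcome = 0.5, true_or = 0.75,
#'                seed = 1)
#' @export
scenario <- function(n, p_treat, p_outcome, true_or,
                     covariates = default_covariates(), seed = 1L,
                     cal_seed = 760813L, n_cal = 1e6, id = NULL) {
  stopifnot(
    is.numeric(n), length(n) == 1, n >= 2, n == floor(n),
    is.numeric(p_treat), p_treat > 0, p_treat < 1,
    is.numeric(p_outcome), p_outcome > 0, p_outcome < 1,
    is.numeric(true_or), true_or > 0,
    is.numeric(n_cal), n_cal >= 1000
  )
  validate_covariate_spec(covariates)
  if (is.null(id)) {
    id <- sprintf("n%d_t%02d_o%02d_or%s", as.integer(n),
                  round(100 * p_treat), round(100 * p_outcome),
                  format(true_or))
  }
  structure(
    list(n = as.integer(n), p_treat = p_treat, p_outcome = p_outcome,
         true_or = true_or, covariates = covariates,
         seed = as.integer(seed), cal_seed = as.integer(cal_seed),
         n_cal = n_cal, id = id),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("Simulation scenario", x$id, "\n")
  cat(sprintf("  n = %d, treatment prevalence %.2f, outcome prevalence %.2f\n",
              x$n, x$p_treat, x$p_outcome))
  cat(sprintf("  true conditional OR %.3g, %d covariates, cohort seed %d\n",
              x$true_or, nrow(x$covariates), x$seed))
  invisible(x)
}

#' Build the full scenario grid of the simulation study
#'
#' Crosses cohort size \{500, 2500, 10000\}, treatment prevalence
#' \{0.2, 0.5\}, outcome prevalence \{0.1, 0.5\} and true odds ratio
#' \{0.75, 1.0, 1.5\}, yielding 36 scenarios. Each scenario receives its own
#' cohort seed derived from `master_seed` by a fixed offset.
#'
#' @param n,p_treat,p_outcome,true_or vectors of design levels to cross.
#' @param master_seed integer; per-scenario cohort seeds are
#'   `master_seed + 7919 * index`.
#' @param covariates a [covariate_spec()] shared by all scenarios.
#' @param n_cal calibration-sample size passed to each scenario.
#' @return A list of `scenario` objects.
#' @examples
#' length(scenario_grid()) # 36
#' @export
scenario_grid <- function(n = c(500, 2500, 10000), p_treat = c(0.2, 0.5),
                          p_outcome = c(0.1, 0.5),
                          true_or = c(0.75, 1.0, 1.5), master_seed = 1L,
                          covariates = default_covariates(), n_cal = 1e6) {
  cells <- expand.grid(n = n, p_treat = p_treat, p_outcome = p_outcome,
                       true_or = true_or, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cells)), function(i) {
    scenario(
      n = cells$n[i], p_treat = cells$p_treat[i],
      p_outcome = cells$p_outcome[i], true_or = cells$true_or[i],
      covariates = covariates, n_cal = n_cal,
      seed = as.integer(master_seed + 7919L * i)
    )
  })
}
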