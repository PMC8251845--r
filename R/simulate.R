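#' Draw a covariate matrix
#'
#' Draws `n` independent subjects from a [covariate_spec()]: binary columns
#' are Bernoulli with the specified prevalence, continuous columns Gaussian
#' with the specified mean and variance. Columns are drawn one covariate at a
#' time from the current RNG stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param spec a [covariate_spec()].
#' @param n number of subjects (rows), `>= 1`.
#' @return An `n` x `nrow(spec)` numeric matrix with the spec's covariate
#'   names as column names.
#' @examples
#' set.seed(1)
#' X <- simulate_covariates(default_covariates(), 100)
#' colMeans(X)
#' @export
simulate_covariates <- function(spec, n) {
  validate_covariate_spec(spec)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  X <- matrix(0, nrow = n, ncol = nrow(spec),
              dimnames = list(NULL, spec$name))
  for (i in seq_len(nrow(spec))) {
    X[, i] <- if (spec$kind[i] == "binary") {
      rbinom(n, 1L, spec$prevalence[i])
    } else {
      rnorm(n, spec$mean[i], sqrt(spec$variance[i]))
    }
  }
  X
}

#' Calibrate a logistic-model intercept to a target prevalence
#'
#' Finds the intercept `c` such that `mean(plogis(c + linear_predictor))`
#' equals `target`. The expectation is strictly increasing in `c`, so the
#' root is found by bracketed root-finding on the log-odds interval
#' \[-20, 20\]. The `linear_predictor` should be evaluated on a large
#' calibration sample (deterministically seeded) so the Monte-Carlo error of
#' the calibrated prevalence is negligible; for the outcome model it includes
#' the treatment term `log(true_or) * T` with `T` drawn from the calibrated
#' treatment model, so the marginal outcome prevalence hits the target.
#'
#' @param linear_predictor numeric vector of per-subject linear predictors
#'   excluding the intercept.
#' @param target target prevalence in (0, 1).
#' @param tol root-finding tolerance on the intercept.
#' @return The calibrated intercept (log-odds scale).
#' @examples
#' calibrate_intercept(rep(0, 10), 0.5) # exactly 0
#' calibrate_intercept(rep(0, 10), 0.2) # log(0.25)
#' @export
calibrate_intercept <- function(linear_predictor, target, tol = 1e-10) {
  stopifnot(is.numeric(linear_predictor), length(linear_predictor) >= 1,
            all(is.finite(linear_predictor)),
            is.numeric(target), length(target) == 1,
            target > 0, target < 1)
  f <- function(c0) mean(plogis(c0 + linear_predictor)) - target
  lo <- -20
  hi <- 20
  if (f(lo) > 0 || f(hi) < 0) {
    stop("cannot bracket the intercept in log-odds [-20, 20]; ",
         "target prevalence unreachable for this linear predictor")
  }
  uniroot(f, c(lo, hi), tol = tol)$root
}

#' Simulate a cohort under a scenario
#'
#' Generates one cohort from the scenario's data-generating process:
#' covariates are drawn from the covariate specification, the treatment
#' indicator from a main-effects logistic model with coefficients
#' `log(or_treatment)`, and the outcome indicator from a main-effects
#' logistic model with coefficients `log(or_outcome)` plus the treatment
#' term `log(true_or) * T`. Both intercepts are calibrated on an independent
#' calibration sample (seed `cal_seed`, size `n_cal`) so the marginal
#' treatment and outcome prevalences hit the scenario targets; the cohort
#' itself is then drawn under seed `seed`.
#'
#' @param scn a [scenario()].
#' @return An object of class `cohort`: a list with the covariate matrix
#'   `X`, integer treatment vector `t`, integer outcome vector `y`, the
#'   calibrated intercepts `alpha0` and `beta0`, and the generating
#'   `scenario`.
#' @examples
#' sc <- scenario(n = 200, p_treat = 0.5, p_outcome = 0.5, true_or = 1,
#'                seed = 1, n_cal = 1000)
#' ch <- simulate_cohort(sc)
#' mean(ch$t)
#' @export
simulate_cohort <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  spec <- scn$covariates
  a <- log(spec$or_treatment)
  b <- log(spec$or_outcome)
  bT <- log(scn$true_or)

  # intercept calibration on its own deterministic sample
  set.seed(scn$cal_seed)
  Xc <- simulate_covariates(spec, scn$n_cal)
  eta_t <- drop(Xc %*% a)
  alpha0 <- calibrate_intercept(eta_t, scn$p_treat)
  t_cal <- rbinom(nrow(Xc), 1L, plogis(alpha0 + eta_t))
  eta_y <- drop(Xc %*% b) + bT * t_cal
  beta0 <- calibrate_intercept(eta_y, scn$p_outcome)
  rm(Xc, eta_t, eta_y, t_cal)

  # the analysis cohort
  set.seed(scn$seed)
  X <- simulate_covariates(spec, scn$n)
  t <- rbinom(scn$n, 1L, plogis(alpha0 + drop(X %*% a)))
  y <- rbinom(scn$n, 1L, plogis(beta0 + drop(X %*% b) + bT * t))

  structure(
    list(X = X, t = as.integer(t), y = as.integer(y),
         alpha0 = alpha0, beta0 = beta0, scenario = scn),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort (%s): n = %d, treated %d (%.1f%%), outcomes %d (%.1f%%)\n",
    x$scenario$id, length(x$t), sum(x$t), 100 * mean(x$t),
    sum(x$y), 100 * mean(x$y)))
  cat(sprintf("  calibrated intercepts: treatment %.4f, outcome %.4f\n",
              x$alpha0, x$beta0))
  invisible(x)
}

#' Write or read a cohort as CSV
#'
#' The on-disk format has one row per subject with columns `x1..xK`, `t`,
#' `y` and a header row; binary fields are 0/1 integers.
#'
#' @param cohort a `cohort` object.
#' @param path file path.
#' @return `read_cohort()` returns a `cohort` (without scenario metadata or
#'   intercepts, which are not stored in the CSV).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort$X)
  df$t <- cohort$t
  df$y <- cohort$y
  write_numeric_csv(df, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, comment.char = "#")
  stopifnot(all(c("t", "y") %in% names(df)))
  xcols <- setdiff(names(df), c("t", "y"))
  structure(
    list(X = as.matrix(df[, xcols, drop = FALSE]),
         t = as.integer(df$t), y = as.integer(df$y),
         alpha0 = NA_real_, beta0 = NA_real_, scenario = NULL),
    class = "cohort"
  )
}
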