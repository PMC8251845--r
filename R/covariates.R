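#' Covariate specification for the simulation models
#'
#' A covariate specification describes the marginal distribution of each
#' baseline covariate together with its association (as an odds ratio) with
#' treatment assignment and with the outcome. Binary covariates are Bernoulli
#' with a given prevalence; continuous covariates are Gaussian with a given
#' mean and variance. All covariates are drawn independently.
#'
#' @param kind character vector, `"binary"` or `"continuous"` per covariate.
#' @param prevalence Bernoulli success probability (binary covariates; `NA`
#'   for continuous ones).
#' @param mean,variance Gaussian parameters (continuous covariates; `NA` for
#'   binary ones). `variance` is on the variance scale, not SD.
#' @param or_treatment odds ratio of the covariate in the logistic treatment
#'   model; the model coefficient is `log(or_treatment)`.
#' @param or_outcome odds ratio of the covariate in the logistic outcome
#'   model; the model coefficient is `log(or_outcome)`.
#'
#' @return A `data.frame` of class `covariate_spec` with one row per
#'   covariate and columns `name`, `kind`, `prevalence`, `mean`, `variance`,
#'   `or_treatment`, `or_outcome`.
#' @examples
#' default_covariates()
#' @export
covariate_spec <- function(kind, prevalence = NA_real_, mean = NA_real_,
                           variance = NA_real_, or_treatment = 1,
                           or_outcome = 1) {
  k <- length(kind)
  spec <- data.frame(
    name = paste0("x", seq_len(k)),
    kind = kind,
    prevalence = rep_len(prevalence, k),
    mean = rep_len(mean, k),
    variance = rep_len(variance, k),
    or_treatment = rep_len(or_treatment, k),
    or_outcome = rep_len(or_outcome, k),
    stringsAsFactors = FALSE
  )
  class(spec) <- c("covariate_spec", "data.frame")
  validate_covariate_spec(spec)
  spec
}

#' @rdname covariate_spec
#' @details `default_covariates()` returns the eight-covariate specification
#'   used throughout the simulation study: six independent Bernoulli(0.2)
#'   covariates and two independent Normal(0, 0.5) covariates, with treatment
#'   odds ratios (2, 1, 0.5, 2, 1, 0.5, 1.5, 0.5) and outcome odds ratios
#'   (1, 2, 0.5, 0.5, 1, 2, 0.5, 1.5). Covariates with both odds ratios != 1
#'   are confounders; the mix yields a crude odds ratio biased away from the
#'   conditional one.
#' @export
default_covariates <- function() {
  covariate_spec(
    kind = c(rep("binary", 6), rep("continuous", 2)),
    prevalence = c(rep(0.2, 6), NA, NA),
    mean = c(rep(NA, 6), 0, 0),
    variance = c(rep(NA, 6), 0.5, 0.5),
    or_treatment = c(2, 1, 0.5, 2, 1, 0.5, 1.5, 0.5),
    or_outcome = c(1, 2, 0.5, 0.5, 1, 2, 0.5, 1.5)
  )
}

validate_covariate_spec <- function(spec) {
  stopifnot(is.data.frame(spec), nrow(spec) >= 1)
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    label <- row$name
    if (!row$kind %in% c("binary", "continuous")) {
      stop("covariate ", label, ": kind must be 'binary' or 'continuous'")
    }
    if (row$kind == "binary") {
      if (!is.finite(row$prevalence) || row$prevalence < 0 ||
          row$prevalence > 1) {
        stop("covariate ", label, ": binary prevalence must lie in [0, 1]")
      }
    } else {
      if (!is.finite(row$variance) || row$variance <= 0) {
        stop("covariate ", label, ": continuous variance must be > 0")
      }
      if (!is.finite(row$mean)) {
        stop("covariate ", label, ": continuous mean must be finite")
      }
    }
    if (!is.finite(row$or_treatment) || row$or_treatment <= 0) {
      stop("covariate ", label, ": or_treatment must be > 0")
    }
    if (!is.finite(row$or_outcome) || row$or_outcome <= 0) {
      stop("covariate ", label, ": or_outcome must be > 0")
    }
  }
  invisible(spec)
}
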