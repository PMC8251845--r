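#' Repeat matching and analysis on one simulated cohort
#'
#' Runs the core experiment for one scenario: simulate a single cohort, fit
#' the propensity-score model once, then repeat each matching algorithm `R`
#' times with a different seed per repetition (seed `base_seed + r` for
#' repetition `r`, so every repetition is independently reproducible).
#' Every matched set is analyzed by [conditional_or()] and [balance()].
#' All algorithms and caliper multipliers run on the identical cohort and
#' propensity fit, so their across-seed distributions are directly
#' comparable; any variation between repetitions comes from the random
#' ordering and random within-caliper choices alone.
#'
#' @param scn a [scenario()].
#' @param R number of matching repetitions per algorithm (default 1000).
#' @param algorithms matching algorithms to run.
#' @param caliper_multipliers caliper widths, as multiples of the PS SD.
#' @param base_seed integer; repetition `r` uses matching seed
#'   `base_seed + r`.
#' @param cohort optionally a pre-simulated `cohort` to reuse instead of
#'   simulating from `scn`.
#' @return An object of class `replication_result`: list with `scenario`,
#'   `crude_or`, `fit`, `replications` (one data.frame row per repetition:
#'   `algorithm`, `caliper_multiplier`, `rep`, `seed`, `n_pairs`, `or_hat`,
#'   `ci_low`, `ci_high`, `defined`, `significant_low`, `significant_high`,
#'   `max_smd`, `successful`) and `summaries` (one [summarize_replications()]
#'   row per algorithm x multiplier).
#' @examples
#' sc <- scenario(400, 0.5, 0.5, 1, seed = 5, n_cal = 1000)
#' rr <- run_scenario(sc, R = 5, base_seed = 10)
#' rr$summaries
#' @export
run_scenario <- function(scn, R = 1000,
                         algorithms = c("caliper_random", "nn_caliper"),
                         caliper_multipliers = 0.2, base_seed = 1L,
                         cohort = NULL) {
  stopifnot(inherits(scn, "scenario"), R >= 1)
  algorithms <- match.arg(algorithms, c("caliper_random", "nn_caliper"),
                          several.ok = TRUE)
  if (is.null(cohort)) cohort <- simulate_cohort(scn)
  fit <- fit_propensity(cohort)
  crude <- crude_or(cohort)

  rows <- vector("list", length(algorithms) * length(caliper_multipliers))
  k <- 0
  for (mult in caliper_multipliers) {
    for (alg in algorithms) {
      reps <- replicate_matching(fit, cohort, alg, mult, R, base_seed)
      k <- k + 1
      rows[[k]] <- reps
    }
  }
  replications <- do.call(rbind, rows)
  summaries <- do.call(rbind, lapply(split(
    replications,
    list(replications$algorithm, replications$caliper_multiplier),
    drop = TRUE
  ), function(df) {
    cbind(
      data.frame(scenario_id = scn$id, n = scn$n, p_treat = scn$p_treat,
                 p_outcome = scn$p_outcome, true_or = scn$true_or,
                 algorithm = df$algorithm[1],
                 caliper_multiplier = df$caliper_multiplier[1],
                 stringsAsFactors = FALSE),
      summarize_replications(df),
      data.frame(crude_or = crude)
    )
  }))
  rownames(summaries) <- NULL
  structure(
    list(scenario = scn, crude_or = crude, fit = fit,
         replications = replications, summaries = summaries),
    class = "replication_result"
  )
}

replicate_matching <- function(fit, cohort, algorithm, multiplier, R,
                               base_seed) {
  base_seed <- as.integer(base_seed)
  out <- data.frame(
    algorithm = rep(algorithm, R), caliper_multiplier = rep(multiplier, R),
    rep = seq_len(R), seed = base_seed + seq_len(R), n_pairs = 0L,
    or_hat = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    defined = FALSE, significant_low = FALSE, significant_high = FALSE,
    max_smd = NA_real_, successful = FALSE, stringsAsFactors = FALSE
  )
  for (r in seq_len(R)) {
    cfg <- match_config(algorithm, multiplier, base_seed + r)
    m <- run_match(fit, cohort, cfg)
    out$n_pairs[r] <- nrow(m$pairs)
    if (nrow(m$pairs) == 0) next
    est <- conditional_or(m, cohort)
    bal <- balance(m, cohort)
    out$or_hat[r] <- est$or_hat
    out$ci_low[r] <- est$ci_low
    out$ci_high[r] <- est$ci_high
    out$defined[r] <- est$defined
    out$significant_low[r] <- est$significant_low
    out$significant_high[r] <- est$significant_high
    out$max_smd[r] <- bal$max_smd
    out$successful[r] <- bal$successful
  }
  out
}

#' @export
print.replication_result <- function(x, ...) {
  cat("Replicated matching on one cohort:", x$scenario$id, "\n")
  cat(sprintf("  crude OR %.3f; %d repetitions per algorithm\n",
              x$crude_or, max(x$replications$rep)))
  print(x$summaries, digits = 4)
  invisible(x)
}

#' Summarize the across-seed distribution of matched estimates
#'
#' Aggregates per-repetition results into the per-scenario summary row:
#' median, interquartile range and full range of the defined odds ratios
#' (type-7 linear-interpolation quantiles), the percentage of repetitions
#' with a significantly decreased or increased risk (denominator: all
#' repetitions), the mean number of matched subjects (2 x mean pair count),
#' the percentage of unsuccessfully matched sets (some covariate SMD above
#' threshold), and the number of repetitions with an undefined OR.
#'
#' @param reps data.frame of per-repetition rows as produced by
#'   [run_scenario()] (columns `or_hat`, `defined`, `significant_low`,
#'   `significant_high`, `successful`, `n_pairs`).
#' @return A one-row data.frame with columns `n_reps`, `median_or`,
#'   `iqr_low`, `iqr_high`, `range_low`, `range_high`, `pct_sig_low`,
#'   `pct_sig_high`, `mean_matched_subjects`, `pct_unsuccessful`,
#'   `n_undefined`, `valid`.
#' @export
summarize_replications <- function(reps) {
  stopifnot(is.data.frame(reps), nrow(reps) >= 1)
  R <- nrow(reps)
  ors <- reps$or_hat[reps$defined]
  valid <- length(ors) > 0
  if (valid) {
    q <- unname(quantile(ors, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  } else {
    q <- rep(NA_real_, 5)
  }
  data.frame(
    n_reps = R,
    median_or = q[3], iqr_low = q[2], iqr_high = q[4],
    range_low = q[1], range_high = q[5],
    pct_sig_low = 100 * sum(reps$significant_low) / R,
    pct_sig_high = 100 * sum(reps$significant_high) / R,
    mean_matched_subjects = mean(2 * reps$n_pairs),
    pct_unsuccessful = 100 * sum(!reps$successful) / R,
    n_undefined = sum(!reps$defined),
    valid = valid
  )
}

#' Sensitivity analysis restricted to successfully matched sets
#'
#' Recomputes the [summarize_replications()] row over the subset of
#' repetitions whose matched sets passed the balance check (all covariate
#' SMDs at or below threshold). Percentages use the subset size as
#' denominator.
#'
#' @param reps per-repetition data.frame (see [summarize_replications()]).
#' @return A one-row summary data.frame; errors if no repetition was
#'   successful.
#' @export
sensitivity_successful_only <- function(reps) {
  stopifnot(is.data.frame(reps))
  keep <- reps[reps$successful, , drop = FALSE]
  if (nrow(keep) == 0) {
    stop("no successfully matched repetitions; sensitivity summary invalid")
  }
  summarize_replications(keep)
}

#' Run the whole scenario grid
#'
#' Executes [run_scenario()] for every scenario in the grid and binds the
#' summary rows into one long-format table (one row per scenario x
#' algorithm x caliper multiplier). Per-scenario matching seeds are derived
#' from `master_seed` by fixed offsets so a rerun with the same seed
#' reproduces the table exactly. Failures in individual scenarios are
#' caught, recorded as a warning, and do not stop the grid.
#'
#' @param scenarios list of [scenario()] objects, e.g. [scenario_grid()].
#' @param R repetitions per algorithm per scenario.
#' @param algorithms,caliper_multipliers passed to [run_scenario()].
#' @param master_seed integer; scenario `i` uses matching base seed
#'   `master_seed + 1000000 * i`.
#' @param progress logical; log one line per scenario to stderr.
#' @return A data.frame of summary rows; failed scenarios are omitted.
#' @export
run_grid <- function(scenarios, R = 1000,
                     algorithms = c("caliper_random", "nn_caliper"),
                     caliper_multipliers = c(0.2, 0.01), master_seed = 1L,
                     progress = TRUE) {
  stopifnot(is.list(scenarios), length(scenarios) >= 1)
  out <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    scn <- scenarios[[i]]
    if (progress) {
      message(sprintf("[%d/%d] scenario %s", i, length(scenarios), scn$id))
    }
    res <- tryCatch(
      run_scenario(scn, R = R, algorithms = algorithms,
                   caliper_multipliers = caliper_multipliers,
                   base_seed = as.integer(master_seed + 1000000 * i)),
      error = function(e) {
        warning(sprintf("scenario %s failed: %s", scn$id, conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
    if (!is.null(res)) out[[i]] <- res$summaries
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
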