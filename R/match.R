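#' Matching configuration
#'
#' Bundles the matching algorithm, the caliper multiplier and the seed that
#' drives both the random ordering of treated subjects and any random
#' choices during matching.
#'
#' @param algorithm `"caliper_random"` (the control is drawn uniformly at
#'   random from all unmatched controls within the caliper) or
#'   `"nn_caliper"` (the closest-PS unmatched control is taken, accepted
#'   only if within the caliper; exact distance ties broken uniformly at
#'   random).
#' @param caliper_multiplier positive multiple of the propensity-score SD;
#'   0.2 and 0.01 are the widths studied here.
#' @param seed integer seed for this matching repetition.
#' @return An object of class `match_config`.
#' @export
match_config <- function(algorithm = c("caliper_random", "nn_caliper"),
                         caliper_multiplier = 0.2, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(is.numeric(caliper_multiplier), length(caliper_multiplier) == 1,
            is.finite(caliper_multiplier))
  if (caliper_multiplier <= 0) stop("caliper_multiplier must be > 0")
  structure(
    list(algorithm = algorithm, caliper_multiplier = caliper_multiplier,
         seed = as.integer(seed)),
    class = "match_config"
  )
}

#' Greedy 1:1 propensity-score matching without replacement
#'
#' Both algorithms visit the treated subjects in a uniformly random
#' permutation driven by `config$seed` and match each one, if possible, to
#' a not-yet-matched control whose propensity score lies within the caliper
#' (`caliper_multiplier * sd_ps`, probability scale). A matched control is
#' never reused; a treated subject with no eligible control is left
#' unmatched. `greedy_caliper_match()` draws the control uniformly at random
#' among all eligible controls; `nn_caliper_match()` takes the control with
#' the smallest absolute score difference, breaking exact-distance ties
#' uniformly at random. Neither algorithm revisits earlier matches, so both
#' depend on the random order of the treated subjects — the instability this
#' package measures.
#'
#' @param fit a `propensity_fit` for `cohort`.
#' @param cohort the `cohort` being matched.
#' @param config a [match_config()]; `algorithm` must agree with the
#'   function called.
#' @return An object of class `matched_set`: list with `pairs` (data.frame
#'   with `treated_id`, `control_id`, `ps_treated`, `ps_control`, in the
#'   order pairs were formed), `n_treated`, `n_treated_unmatched`,
#'   `caliper`, `algorithm` and `seed`.
#' @examples
#' ch <- simulate_cohort(scenario(400, 0.5, 0.5, 1, seed = 2, n_cal = 1000))
#' fit <- fit_propensity(ch)
#' m <- greedy_caliper_match(fit, ch, match_config(seed = 7))
#' nrow(m$pairs)
#' @export
greedy_caliper_match <- function(fit, cohort, config) {
  if (config$algorithm != "caliper_random") {
    stop("config$algorithm must be 'caliper_random'")
  }
  run_match(fit, cohort, config)
}

#' @rdname greedy_caliper_match
#' @export
nn_caliper_match <- function(fit, cohort, config) {
  if (config$algorithm != "nn_caliper") {
    stop("config$algorithm must be 'nn_caliper'")
  }
  run_match(fit, cohort, config)
}

run_match <- function(fit, cohort, config) {
  stopifnot(inherits(fit, "propensity_fit"), inherits(cohort, "cohort"),
            inherits(config, "match_config"),
            length(fit$ps) == length(cohort$t))
  width <- caliper_width(fit, config$caliper_multiplier)
  treated <- which(cohort$t == 1L)
  controls <- which(cohort$t == 0L)
  if (length(treated) == 0 || length(controls) == 0) {
    stop("matching needs at least one treated and one control subject")
  }
  # controls sorted by (ps, id) so selection order is well defined
  ord <- order(fit$ps[controls], controls)
  cids <- controls[ord]
  psc <- fit$ps[cids]

  set.seed(config$seed)
  visit <- treated[sample.int(length(treated))]
  pst <- fit$ps[visit]
  sel <- .match_core(pst, psc, width, config$algorithm == "nn_caliper")

  hit <- sel > 0L
  pairs <- data.frame(
    treated_id = visit[hit],
    control_id = cids[sel[hit]],
    ps_treated = pst[hit],
    ps_control = psc[sel[hit]]
  )
  structure(
    list(pairs = pairs, n_treated = length(treated),
         n_treated_unmatched = sum(!hit), caliper = width,
         algorithm = config$algorithm, seed = config$seed),
    class = "matched_set"
  )
}

#' @export
print.matched_set <- function(x, ...) {
  cat(sprintf(
    "Matched set (%s, caliper %.5f, seed %d): %d pairs, %d of %d treated unmatched\n",
    x$algorithm, x$caliper, x$seed, nrow(x$pairs), x$n_treated_unmatched,
    x$n_treated))
  invisible(x)
}

#' Export matched pairs as CSV
#'
#' @param matched a `matched_set`.
#' @param path file path; columns `pair_id`, `treated_id`, `control_id`,
#'   `ps_treated`, `ps_control`.
#' @export
write_matched_set <- function(matched, path) {
  stopifnot(inherits(matched, "matched_set"))
  df <- cbind(pair_id = seq_len(nrow(matched$pairs)), matched$pairs)
  write_numeric_csv(df, path)
  invisible(path)
}
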