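# Independent oracles and fixture builders used across the test files.

# Build a minimal cohort object by hand (bypassing the DGP).
make_cohort <- function(t, y, X = NULL) {
  n <- length(t)
  if (is.null(X)) X <- matrix(0, n, 1, dimnames = list(NULL, "x1"))
  structure(list(X = X, t = as.integer(t), y = as.integer(y),
                 alpha0 = NA_real_, beta0 = NA_real_, scenario = NULL),
            class = "cohort")
}

# Build a propensity_fit with prescribed scores (bypassing the model fit).
make_fit <- function(ps, sd_ps = sd(ps)) {
  structure(list(coefficients = NULL, ps = as.numeric(ps), sd_ps = sd_ps,
                 converged = TRUE),
            class = "propensity_fit")
}

# Toy matching instance: treated subjects first, then controls, with given
# scores. The fit's score SD is pinned to 1 so the caliper multiplier IS the
# absolute caliper width, with no floating-point round trip.
toy_match_setup <- function(ps_treated, ps_control, caliper) {
  nt <- length(ps_treated)
  nc <- length(ps_control)
  ps <- c(ps_treated, ps_control)
  fit <- make_fit(ps, sd_ps = 1)
  cohort <- make_cohort(t = c(rep(1L, nt), rep(0L, nc)),
                        y = rep(0L, nt + nc))
  list(fit = fit, cohort = cohort, multiplier = caliper,
       treated_ids = seq_len(nt), control_ids = nt + seq_len(nc))
}

# Canonical key for a matched set: sorted "treated:control" pairs.
set_key <- function(pairs) {
  if (nrow(pairs) == 0) return("<empty>")
  paste(sort(paste0(pairs$treated_id, ":", pairs$control_id)),
        collapse = ",")
}

# ---------------------------------------------------------------------------
# Naive pure-R matching reference. Consumes R's RNG stream exactly like the
# compiled implementation (one runif(1) per random choice, index
# floor(u * k) + 1 over candidates in PS-sorted order), so results must be
# bit-identical, not merely distributionally equal.
naive_match <- function(fit, cohort, config) {
  width <- caliper_width(fit, config$caliper_multiplier)
  treated <- which(cohort$t == 1L)
  controls <- which(cohort$t == 0L)
  ord <- order(fit$ps[controls], controls)
  cids <- controls[ord]
  psc <- fit$ps[cids]
  alive <- rep(TRUE, length(cids))

  set.seed(config$seed)
  visit <- treated[sample.int(length(treated))]
  pst <- fit$ps[visit]
  sel <- integer(length(visit))
  for (i in seq_along(visit)) {
    if (!any(alive)) break
    pt <- pst[i]
    if (config$algorithm == "caliper_random") {
      elig <- which(alive & psc >= pt - width & psc <= pt + width)
      k <- length(elig)
      if (k == 0) next
      idx <- elig[min(floor(runif(1) * k) + 1, k)]
    } else {
      d <- abs(psc - pt)
      d[!alive] <- Inf
      dm <- min(d)
      if (!(dm <= width)) next
      cand <- which(d == dm)
      k <- length(cand)
      idx <- if (k == 1) cand else cand[min(floor(runif(1) * k) + 1, k)]
    }
    sel[i] <- idx
    alive[idx] <- FALSE
  }
  hit <- sel > 0L
  data.frame(treated_id = visit[hit], control_id = cids[sel[hit]],
             ps_treated = pst[hit], ps_control = psc[sel[hit]])
}

# ---------------------------------------------------------------------------
# Exact matched-set distribution on small instances by brute-force
# enumeration of (treated permutation) x (random within-caliper or tied
# choices). Returns a named probability vector keyed by set_key().
enumerate_match_dist <- function(ps_treated, ps_control, caliper,
                                 algorithm = c("caliper_random",
                                               "nn_caliper")) {
  algorithm <- match.arg(algorithm)
  nt <- length(ps_treated)
  nc <- length(ps_control)
  treated_ids <- seq_len(nt)
  control_ids <- nt + seq_len(nc)
  probs <- new.env(parent = emptyenv())

  add_prob <- function(key, p) {
    assign(key, p + (if (exists(key, probs)) get(key, probs) else 0), probs)
  }

  recurse <- function(order_left, alive, pairs, p) {
    if (length(order_left) == 0) {
      key <- if (nrow(pairs) == 0) "<empty>" else set_key(pairs)
      add_prob(key, p)
      return(invisible())
    }
    for (ti in order_left) {
      p_perm <- p / length(order_left)
      rest <- setdiff(order_left, ti)
      pt <- ps_treated[ti]
      if (algorithm == "caliper_random") {
        cand <- which(alive & abs(ps_control - pt) <= caliper)
      } else {
        d <- abs(ps_control - pt)
        d[!alive] <- Inf
        dm <- min(d)
        cand <- if (is.finite(dm) && dm <= caliper) which(d == dm)
                else integer(0)
      }
      if (length(cand) == 0) {
        recurse(rest, alive, pairs, p_perm)
      } else {
        for (ci in cand) {
          alive2 <- alive
          alive2[ci] <- FALSE
          pairs2 <- rbind(pairs, data.frame(treated_id = ti,
                                            control_id = control_ids[ci]))
          recurse(rest, alive2, pairs2, p_perm / length(cand))
        }
      }
    }
  }
  recurse(treated_ids, rep(TRUE, nc),
          data.frame(treated_id = integer(0), control_id = integer(0)), 1)
  p <- unlist(as.list(probs))
  p / sum(p)
}

# Empirical matched-set distribution over seeds 1..n_seeds.
empirical_match_dist <- function(ps_treated, ps_control, caliper,
                                 algorithm, n_seeds) {
  setup <- toy_match_setup(ps_treated, ps_control, caliper)
  keys <- vapply(seq_len(n_seeds), function(s) {
    cfg <- match_config(algorithm, setup$multiplier, s)
    m <- if (algorithm == "nn_caliper") {
      nn_caliper_match(setup$fit, setup$cohort, cfg)
    } else {
      greedy_caliper_match(setup$fit, setup$cohort, cfg)
    }
    set_key(m$pairs)
  }, character(1))
  table(keys) / n_seeds
}

# ---------------------------------------------------------------------------
# Numeric maximizer of the pair-conditional logistic log-likelihood with a
# single treatment term: only discordant pairs contribute, each a term
# b*z - log(1 + exp(b)) with z = 1 for treated-outcome pairs.
conditional_or_oracle <- function(n10, n01) {
  nll <- function(b) -(n10 * b - (n10 + n01) * log1p(exp(b)))
  exp(optimize(nll, c(-15, 15), tol = 1e-10)$minimum)
}

# Sort-based quartile oracle: type-7 linear interpolation, written
# independently of stats::quantile.
quartiles_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  interp <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    x[lo + 1] + (h - lo) * (x[min(lo + 2, n)] - x[lo + 1])
  }
  c(q1 = interp(0.25), med = interp(0.5), q3 = interp(0.75))
}

# Coarse-then-fine grid maximizer of the (intercept + one covariate)
# logistic log-likelihood, independent of glm's IRLS path.
grid_logistic_oracle <- function(x, t, lim = 6, steps = 3) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(t * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0)
  span <- lim
  for (s in seq_len(steps)) {
    b0s <- seq(centre[1] - span, centre[1] + span, length.out = 81)
    b1s <- seq(centre[2] - span, centre[2] + span, length.out = 81)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    centre <- c(b0s[best[1]], b1s[best[2]])
    span <- span / 20
  }
  centre
}
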