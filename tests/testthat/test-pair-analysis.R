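# Conditional logistic OR for pairs, balance diagnostics, crude OR.

# matched set + cohort realizing given discordant/concordant pair counts
make_pair_fixture <- function(n10, n01, n11 = 0, n00 = 0) {
  np <- n10 + n01 + n11 + n00
  yt <- c(rep(1L, n10), rep(0L, n01), rep(1L, n11), rep(0L, n00))
  yc <- c(rep(0L, n10), rep(1L, n01), rep(1L, n11), rep(0L, n00))
  cohort <- make_cohort(t = rep(c(1L, 0L), each = np), y = c(yt, yc))
  pairs <- data.frame(treated_id = seq_len(np), control_id = np + seq_len(np),
                      ps_treated = 0.5, ps_control = 0.5)
  matched <- structure(
    list(pairs = pairs, n_treated = np, n_treated_unmatched = 0L,
         caliper = 1, algorithm = "caliper_random", seed = 1L),
    class = "matched_set")
  list(matched = matched, cohort = cohort)
}

test_that("discordant-pair closed form matches its worked example", {
  fx <- make_pair_fixture(n10 = 20, n01 = 10, n11 = 5, n00 = 7)
  est <- conditional_or(fx$matched, fx$cohort)
  expect_true(est$defined)
  expect_equal(est$or_hat, 2.0)
  expect_equal(est$ci_low, 0.936, tolerance = 1e-3)
  expect_equal(est$ci_high, 4.272, tolerance = 1e-3)
  expect_false(est$significant_low)
  expect_false(est$significant_high)
})

test_that("closed form equals the numeric conditional-likelihood maximizer
           on random pair tables", {
  set.seed(202)
  for (i in 1:50) {
    n10 <- sample(1:80, 1)
    n01 <- sample(1:80, 1)
    fx <- make_pair_fixture(n10, n01, sample(0:20, 1), sample(0:20, 1))
    est <- conditional_or(fx$matched, fx$cohort)
    expect_equal(est$or_hat, conditional_or_oracle(n10, n01),
                 tolerance = 1e-4)
  }
})

test_that("closed form agrees with survival::clogit", {
  skip_if_not_installed("survival")
  fx <- make_pair_fixture(n10 = 18, n01 = 31, n11 = 9, n00 = 12)
  est <- conditional_or(fx$matched, fx$cohort)
  np <- nrow(fx$matched$pairs)
  df <- data.frame(
    y = c(fx$cohort$y[fx$matched$pairs$treated_id],
          fx$cohort$y[fx$matched$pairs$control_id]),
    treat = rep(c(1, 0), each = np),
    stratum = rep(seq_len(np), 2)
  )
  cl <- survival::coxph(
    survival::Surv(rep(1, nrow(df)), df$y) ~ df$treat +
      survival::strata(df$stratum),
    method = "exact")
  expect_equal(unname(exp(coef(cl))), est$or_hat, tolerance = 1e-6)
  ci <- exp(confint(cl))
  expect_equal(unname(ci[1]), est$ci_low, tolerance = 1e-6)
  expect_equal(unname(ci[2]), est$ci_high, tolerance = 1e-6)
})

test_that("balanced discordance gives OR 1 with a log-symmetric CI", {
  fx <- make_pair_fixture(n10 = 15, n01 = 15)
  est <- conditional_or(fx$matched, fx$cohort)
  expect_equal(est$or_hat, 1.0)
  expect_equal(log(est$ci_low), -log(est$ci_high), tolerance = 1e-12)
})

test_that("zero discordance in either direction is reported undefined", {
  fx <- make_pair_fixture(n10 = 0, n01 = 5)
  est <- conditional_or(fx$matched, fx$cohort)
  expect_false(est$defined)
  expect_true(is.na(est$or_hat))
  expect_false(est$significant_low)
  expect_false(est$significant_high)
  expect_error(conditional_or(structure(
    list(pairs = data.frame()), class = "matched_set"), fx$cohort), "empty")
})

test_that("swapping treated and control labels inverts the OR", {
  fx <- make_pair_fixture(n10 = 40, n01 = 12)
  est <- conditional_or(fx$matched, fx$cohort)
  swapped <- fx$matched
  swapped$pairs$treated_id <- fx$matched$pairs$control_id
  swapped$pairs$control_id <- fx$matched$pairs$treated_id
  est2 <- conditional_or(swapped, fx$cohort)
  expect_equal(est2$or_hat, 1 / est$or_hat, tolerance = 1e-12)
  expect_equal(est2$significant_low, est$significant_high)
  expect_equal(est2$significant_high, est$significant_low)
})

test_that("balance is zero for identical matched groups and follows the
           SMD formula otherwise", {
  # identical covariate rows -> all SMDs zero
  X <- cbind(x1 = c(rep(1, 5), rep(0, 5)), x2 = rnorm(10))
  ch <- make_cohort(t = rep(c(1L, 0L), 10), y = rep(0L, 20),
                    X = rbind(X, X))
  pairs <- data.frame(treated_id = 1:10, control_id = 11:20,
                      ps_treated = 0.5, ps_control = 0.5)
  m <- structure(list(pairs = pairs, n_treated = 10L,
                      n_treated_unmatched = 0L, caliper = 1,
                      algorithm = "nn_caliper", seed = 1L),
                 class = "matched_set")
  ch$t <- rep(c(1L, 0L), each = 10)
  rep_ <- balance(m, ch)
  expect_equal(unname(rep_$smd), c(0, 0))
  expect_true(rep_$successful)

  # binary covariate, means 0.3 vs 0.2 -> SMD from the direct formula
  n <- 1000
  xt <- rep(c(1, 0), c(300, 700))
  xc <- rep(c(1, 0), c(200, 800))
  ch2 <- make_cohort(t = rep(c(1L, 0L), each = n), y = rep(0L, 2 * n),
                     X = matrix(c(xt, xc), ncol = 1,
                                dimnames = list(NULL, "x1")))
  m2 <- structure(list(pairs = data.frame(treated_id = 1:n,
                                          control_id = n + 1:n,
                                          ps_treated = 0.5,
                                          ps_control = 0.5),
                       n_treated = n, n_treated_unmatched = 0L,
                       caliper = 1, algorithm = "nn_caliper", seed = 1L),
                  class = "matched_set")
  rep2 <- balance(m2, ch2)
  oracle <- abs(mean(xt) - mean(xc)) / sqrt((var(xt) + var(xc)) / 2)
  expect_equal(unname(rep2$smd), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.1 / sqrt(0.185), tolerance = 2e-3)
  expect_false(rep2$successful)

  # equal means, unequal variances -> SMD zero
  xt3 <- c(-2, -1, 0, 1, 2)
  xc3 <- c(-4, -2, 0, 2, 4)
  ch3 <- make_cohort(t = rep(c(1L, 0L), each = 5), y = rep(0L, 10),
                     X = matrix(c(xt3, xc3), ncol = 1,
                                dimnames = list(NULL, "x1")))
  m3 <- m
  m3$pairs <- data.frame(treated_id = 1:5, control_id = 6:10,
                         ps_treated = 0.5, ps_control = 0.5)
  rep3 <- balance(m3, ch3)
  expect_equal(unname(rep3$smd), 0)
  expect_true(rep3$successful)
})

test_that("balance is invariant to pair order", {
  sc <- scenario(n = 500, p_treat = 0.5, p_outcome = 0.5, true_or = 1,
                 seed = 77, n_cal = 5e4)
  ch <- simulate_cohort(sc)
  fit <- fit_propensity(ch)
  m <- greedy_caliper_match(fit, ch, match_config("caliper_random", 0.2, 4))
  shuffled <- m
  set.seed(1)
  shuffled$pairs <- m$pairs[sample.int(nrow(m$pairs)), ]
  expect_equal(balance(m, ch)$smd, balance(shuffled, ch)$smd)
})

test_that("crude OR follows the 2x2 closed form and flags zero cells", {
  ch <- make_cohort(
    t = rep(c(1L, 1L, 0L, 0L), c(100, 50, 50, 100)),
    y = rep(c(1L, 0L, 1L, 0L), c(100, 50, 50, 100))
  )
  expect_equal(crude_or(ch), 4.0)
  ch0 <- make_cohort(t = c(1L, 1L, 0L, 0L), y = c(1L, 1L, 1L, 0L))
  expect_true(is.na(crude_or(ch0)))
  set.seed(88)
  ch_null <- make_cohort(t = rbinom(1e5, 1, 0.5), y = rbinom(1e5, 1, 0.3))
  expect_lt(abs(crude_or(ch_null) - 1), 0.05)
})
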