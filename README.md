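# matchvar

Monte-Carlo framework for quantifying how strongly treatment-effect
estimates obtained after greedy 1:1 propensity-score (PS) matching depend
on the random order in which treated subjects are matched.

Greedy caliper matching — the most common PS-matching recipe in applied
pharmacoepidemiology — visits treated subjects in random order and matches
each to an untreated subject within a caliper, either a random eligible
one (*caliper-random*) or the nearest one (*NN-caliper*). Because the
algorithm never revisits a match, the matched sample, the estimated odds
ratio (OR) and sometimes the significance verdict all depend on the random
seed. `matchvar` is for methodologists and analysts who want to measure
that dependence: it simulates confounded binary-outcome cohorts, reruns the
matching with many seeds on the *same* cohort, and summarizes the
across-seed distribution of the estimates.

## The model in brief

Cohorts are drawn from main-effects logistic models over eight independent
covariates (six Bernoulli(0.2), two N(0, 0.5)):

    P(T=1 | X) = logit^-1(α₀ + Σ αₖ Xₖ)
    P(Y=1 | T, X) = logit^-1(β₀ + Σ βₖ Xₖ + β_T T)

with coefficients given as log odds ratios and the intercepts calibrated
numerically so the marginal treatment and outcome prevalences hit their
targets. The PS is the fitted probability from a logistic regression of
`T` on all covariates; the caliper is a multiple (0.2 or 0.01) of the SD
of the fitted scores. Each matched set is analyzed by conditional logistic
regression for pairs, whose MLE is the discordant-pair ratio
`n10 / n01` with a Wald CI on the log scale; covariate balance is judged
by standardized mean differences (failure if any SMD > 0.1). A scenario
grid crosses n ∈ {500, 2500, 10000}, treatment prevalence {0.2, 0.5},
outcome prevalence {0.1, 0.5} and true conditional OR {0.75, 1.0, 1.5}
(36 cells).

## Worked example

Repeat both matching algorithms 200 times with different seeds on one
simulated cohort of 2500 subjects (20% treated, 50% outcome prevalence,
true conditional OR 0.75):

```r
library(matchvar)
sc <- scenario(n = 2500, p_treat = 0.2, p_outcome = 0.5, true_or = 0.75,
               seed = 42)
ch <- simulate_cohort(sc)
ch
#> Simulated cohort (n2500_t20_o50_or0.75): n = 2500, treated 502 (20.1%), outcomes 1230 (49.2%)
#>   calibrated intercepts: treatment -1.5596, outcome 0.0560

rr <- run_scenario(sc, R = 200, caliper_multipliers = 0.2, base_seed = 42)
rr$summaries[, c("algorithm", "median_or", "iqr_low", "iqr_high",
                 "range_low", "range_high", "pct_sig_low",
                 "mean_matched_subjects", "pct_unsuccessful", "crude_or")]
#>       algorithm median_or iqr_low iqr_high range_low range_high pct_sig_low
#>  caliper_random     0.802   0.764    0.852     0.667      0.946          28
#>      nn_caliper     0.821   0.811    0.832     0.784      0.858           0
#>  mean_matched_subjects pct_unsuccessful crude_or
#>                    979                3     0.61
#>                    971                0     0.61
```

Reading the numbers: the crude OR (0.61) is badly confounded relative to
the true conditional OR 0.75. Matching removes most of that bias, but
rerunning caliper-random matching with different seeds moves the OR across
a 0.667–0.946 range *in the identical cohort* — 28% of the repetitions
reach low-risk significance while 72% do not, so the analyst's seed decides
the headline conclusion. NN-caliper matching is much more stable (IQR
0.811–0.832) but not seed-free. ~979 of the 1004 matchable subjects end up
matched; 3% of caliper-random repetitions fail the SMD ≤ 0.1 balance check.

`run_grid(scenario_grid(), ...)` runs all 36 design cells;
`sensitivity_successful_only()` restricts summaries to balance-passing
repetitions; cohorts, matched sets and summary tables round-trip through
plain CSV (see `write_cohort()`, `write_matched_set()`, `write_summary()`).
A thin command-line front end with `simulate` / `match` / `run-scenario` /
`run-grid` subcommands is installed at
`system.file("scripts", "matchvar-cli.R", package = "matchvar")`, with YAML
run configs as in `system.file("extdata", "full-grid.yaml", package =
"matchvar")`.

See the methods vignette (`vignettes/matching-variability.Rmd`) for the
full model, algorithmic details, numerical choices and limitations.

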