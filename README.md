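# tempreg

Simulation and analysis of how the temporal regularity of the
environment shapes perceived stimulus timing.

## The problem

Listeners exposed to rhythmic sequences form expectations about *when*
the next stimulus will occur. tempreg implements a Bayesian-observer
account of this: the predicted onset of the next tone is a Gaussian
prior that is fused with noisy sensory evidence at every tone
(precision-weighted averaging), and the posterior — shifted one
inter-onset interval ahead — becomes the next prediction. A final tone
that deviates from the regular grid by an anisochrony $a$ is then
perceived at $w \cdot a$ in expectation, with shrinkage weight

$$w = \frac{\sigma_p^2}{\sigma_p^2 + \sigma_s^2},$$

where $\sigma_p$ is the prediction SD at the final tone and $\sigma_s$
the sensory noise. In a temporally regular environment the prior is
sharp ($w$ small): deviants are perceptually pulled toward the expected
moment — *temporal regularisation*. In an irregular environment the
prior is wide and perception is near-veridical. The package provides:

* **Trial designs** of two psychophysics experiments on five-tone
  sequences (700 ms base IOI, uniform per-interval jitter, signed
  final-tone anisochrony): regularity judgments (15 anisochronies × 4
  jitter levels × 8 reps) and audiovisual temporal-order judgments
  (±40 ms deviants × 9 SOAs × 4 jitter levels × 10 reps, plus a
  single-tone practice phase).
* **A seedable observer simulator** with recursive prior updating,
  environment-statistics learning, a two-noisy-criteria regularity
  response rule, lapses, and cohort-level parameter heterogeneity.
* **Spearman–Kärber estimation** of the point of subjective simultaneity
  (PSS) and just noticeable difference (JND) as the first two moments of
  the discrete derivative of the response-proportion curve (±250 ms
  padding, weighted pooled-adjacent-violators monotonization).
* **The two-noisy-criteria model fit** (difference of two cumulative
  Gaussians) by multi-start binomial maximum likelihood.
* **End-to-end drivers** with the JND exclusion rule (over 250 ms in
  practice, 200 ms in test) and the regularisation index — the
  late-minus-early PSS difference as a percentage of the 80 ms physical
  separation, equal to $100\,(1 - w)$ for the model observer.

## Worked example

One observer in the regular environment, temporal-order test phase,
0-jitter cells:

```r
library(tempreg)

obs <- observer_params(env_learning_rate = 0.05)
grid <- shuffle_grid(build_exp2_grid("regular", 10), seed = 12)
session <- simulate_session(grid, obs, seed = 12)

# analysis axis: light-lead time (positive PSS = light must lead)
session$light_lead_ms <- -session$soa_ms
zero <- session[session$jitter_level_ms == 0, ]
early <- sk_from_responses(zero[zero$anisochrony_ms == -40, ],
                           "light_lead_ms", "light_first")
late  <- sk_from_responses(zero[zero$anisochrony_ms ==  40, ],
                           "light_lead_ms", "light_first")
rbind(early, late)
#>   pss_ms jnd_ms monotonized n_trials
#> 1    -18  64.78       FALSE       90
#> 2      8  31.24       FALSE       90
regularisation_index(early$pss_ms, late$pss_ms)
#> [1] 32.5
100 * (1 - shrinkage_weight(obs))   # closed-form prediction
#> [1] 32.02962
```

The early deviant's PSS is negative (the tone, perceptually delayed
toward the expected moment, needs the light *later* to appear
simultaneous) and the late deviant's positive: this observer regularises
32.5% of the 80 ms separation, against a closed-form expectation of
32.0%. Single-session estimates carry sizable Spearman–Kärber noise
(roughly ±20 percentage points on the index at 10 repetitions per SOA);
cohort-level runs average it out:

```r
res <- run_experiment2(cohort_config(n_observers_per_group = 12), seed = 1)
subset(res$regularisation, jitter_level_ms == 0)
#>   group     jitter_level_ms pss_early pss_late index_percent index_se ...
#>   irregular               0     -1.74     7.84          12.0     8.39
#>   regular                 0     -8.86    12.2           26.3     6.30
```

The regular-environment cohort regularises substantially; the
irregular-environment cohort — identical 0-jitter sequences, different
context — much less. The full workflow (design tables, both cohorts,
both analyses) is scripted in four numbered stages under `analysis/`,
writing CSVs beneath `results/`:

```sh
Rscript analysis/01_design_grids.R
Rscript analysis/02_simulate_cohorts.R
Rscript analysis/03_experiment1_analysis.R
Rscript analysis/04_experiment2_analysis.R
```

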