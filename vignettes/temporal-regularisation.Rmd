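---
title: "Modelling temporal regularisation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temporal regularisation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempreg)
```

## The scientific question

When a sequence of tones is (nearly) isochronous, listeners build an
expectation of *when* the next tone will occur. tempreg models the
hypothesis that this expectation acts as a Bayesian prior on perceived
timing: a final tone presented slightly earlier than the regular grid is
perceptually delayed toward the expected moment (and a late tone
accelerated), so that small deviations are perceptually *regularised* —
and that the strength of this pull depends on the temporal statistics of
the listener's environment. An observer exposed mostly to irregular
sequences should hold a wide, weakly informative prior and perceive
deviants close to veridically; an observer in a regular environment
should hold a sharp prior and compress deviations.

The package simulates the two experiment designs used to probe this:

1. **Regularity judgments.** Five tones at a 700 ms base inter-onset
   interval (IOI); the three intervals among tones 1–4 each receive an
   independent uniform jitter on $[-j, +j]$ (with $j \in \{0,10,20,30\}$ ms
   in the regular environment, $\{0,50,100,150\}$ ms in the irregular
   one); the fifth tone deviates from the nominal grid by a signed
   anisochrony $a \in \{0, \pm20, \ldots, \pm200\}$ ms. The observer
   reports whether the sequence was regular. Eight repetitions per cell.
2. **Temporal-order judgments.** The same sequences with $a = \pm 40$ ms
   and a flash probe at one of nine stimulus-onset asynchronies
   (0, ±40, ±80, ±120, ±200 ms) relative to the final tone; the observer
   reports whether light or sound came first. Ten repetitions per cell;
   one quarter of all trials are fully isochronous. A practice phase
   (single tone + flash, SOAs up to ±350 ms, six repetitions) screens
   temporal-order sensitivity.

## The observer model

The observer tracks the onset time of the next tone with a Gaussian
belief. Writing $m_k, \sigma_{p,k}$ for the predicted mean and SD before
tone $k$, and $x_k$ for the noisy sensed onset
($x_k = t_k + \varepsilon_k$, $\varepsilon_k \sim \mathcal N(0,
\sigma_s^2)$), each tone is perceived at the posterior mean of the
conjugate Gaussian fusion

$$
\hat t_k \;=\; \frac{m_k/\sigma_{p,k}^2 + x_k/\sigma_s^2}
                    {1/\sigma_{p,k}^2 + 1/\sigma_s^2},
\qquad
\sigma_{post,k}^{-2} \;=\; \sigma_{p,k}^{-2} + \sigma_s^{-2},
$$

and the posterior, shifted one interval ahead, becomes the next
prediction: $m_{k+1} = \hat t_k + \mathrm{IOI}$,
$\sigma_{p,k+1}^2 = \sigma_{post,k}^2 + v^2$. The inflation term $v$
(`interval_sd`) encodes how variable the observer believes the
environment's intervals to be; it is the single parameter through which
the environment enters. At the final tone, the perceived anisochrony is
$\hat t_5 - m_5$, whose expectation is $w \cdot a$ with the shrinkage
weight

$$
w = \frac{\sigma_{p,5}^2}{\sigma_{p,5}^2 + \sigma_s^2} \in (0, 1].
$$

$1 - w$ is exactly the fraction of the deviation that is perceptually
regularised, which is what the regularisation index measures downstream.
`shrinkage_weight()` exposes this closed form; the Monte-Carlo mean of
`perceive_final()` agrees with it (a property the test suite checks at
$10^4$ draws).

**Environment learning.** With `env_learning_rate` $\rho > 0$, after each
multi-tone trial the observer updates `interval_sd` toward the
root-mean-square of that trial's prediction errors (innovations at tones
2–4) by exponential smoothing on the SD scale:
$v \leftarrow (1-\rho)v + \rho\,\mathrm{RMS}$. The final, deviant tone is
excluded from the innovation set so that the environment statistic tracks
the sequence context rather than the experimental probe. Since trials of
all jitter levels are interleaved, both groups' observers converge to a
single environment-wide $v$ — small in the regular group, large in the
irregular one — which is precisely the mechanism that makes the
regularisation index differ between groups at identical (0-jitter)
sequences.

**Response rules.** Regularity: two criteria are drawn per trial,
$c_e \sim \mathcal N(\mu_e, \sigma_e^2)$ and
$c_l \sim \mathcal N(\mu_l, \sigma_l^2)$, and the observer reports
"regular" iff the perceived anisochrony lies between them. Temporal
order: the flash is perceived at its onset plus
$\mathcal N(0, \sigma_v^2)$ latency noise, and "light first" is reported
iff the perceived flash time does not exceed the perceived tone time
(ties, a measure-zero event, go to light-first by convention). A
symmetric lapse flips either response with probability `lapse_rate`.

### Default parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `sensory_sd` | 25 | ms | auditory onset-timing noise of the order of tens of ms, consistent with audiovisual JNDs near 60–70 ms once visual noise is added |
| `initial_prior_sd` | 120 | ms | weakly informative before any sequence evidence |
| `interval_sd` | 30 | ms | mid-range starting belief, overwritten by learning |
| `env_learning_rate` | 0 (0.05 in cohorts) | – | slow tracking; converges well within a session of several hundred trials |
| `criterion_early/late` | ∓80 | ms | regular-response region of the order the regularity curves suggest |
| `criterion_sd_early/late` | 25 | ms | trial-to-trial criterion wobble |
| `visual_latency_sd` | 50 | ms | dominates the audiovisual JND (~60 ms at these settings) |
| `lapse_rate` | 0.02 | – | standard small lapse |

Cohort heterogeneity (`cohort_config()$observer_sds`) draws each
observer's parameters from truncated Gaussians around these means with
modest SDs (e.g. 5 ms on `sensory_sd`, 10 ms on the criteria). These
defaults are the package's fixed study conditions; they were chosen for
plausibility, not fitted to any data set.

## Psychophysical estimators

**Spearman–Kärber.** For levels $L_1 < \dots < L_K$ with positive-response
proportions $p_i$, the series is padded with $(L_0, p_0) = (-250, 0)$ and
$(L_{K+1}, p_{K+1}) = (+250, 1)$; with midpoints
$s_i = (L_{i+1} + L_i)/2$ and increments $dp_i = p_{i+1} - p_i$,

$$
\mathrm{PSS} = \frac{\sum_i s_i\,dp_i}{\sum_i dp_i}, \qquad
\mathrm{JND} = \sqrt{\frac{\sum_i dp_i (s_i - \mathrm{PSS})^2}{\sum_i dp_i}}.
$$

The JND is deliberately the *square root of the normalized second central
moment*: that is the one-SD offset producing the .16/.84 response
proportions, which is how the JND is defined operationally. Two numerical
choices:

* **Monotonization.** Sampled proportions need not be monotone and the
  padding alone does not make them so; negative $dp_i$ would act as
  signed mass. Non-monotone series are first projected onto the monotone
  cone by trial-count-weighted pooled-adjacent-violators, and the result
  is flagged (`monotonized = TRUE`). The equal-weight case is verified
  against `stats::isoreg`.
* **Padding bounds.** ±250 ms is the default (and strictly brackets the
  nine test-phase SOAs, whose extreme is ±200 ms). The practice phase
  uses SOAs up to ±350 ms, so its estimates use ±400 ms pads — the
  bounds must strictly bracket the levels for the padded distribution to
  be well defined.

**Sign conventions.** Trial tables store `soa_ms` as flash-minus-tone.
The analysis axis for the temporal-order task is the light-lead time
`light_lead_ms = -soa_ms` (tone onset minus flash onset): on this axis
the proportion of light-first responses is increasing, the 0/1 padding is
on the correct side, and a *positive* PSS means the light must be
presented before the sound to appear simultaneous. Under this convention
an early deviant ($a = -40$) that is perceptually delayed yields a
negative PSS, a late deviant a positive one, and the regularisation index

$$
\mathrm{index} = 100 \times \frac{\mathrm{PSS}_{late} -
\mathrm{PSS}_{early}}{80\ \mathrm{ms}} = 100\,(1 - w)
$$

is positive under regularisation and 0 for a flat-prior observer. The
80 ms denominator is the full early-to-late separation; the one-sided
40 ms reading would double the index, and `regularisation_index()` takes
the span as an argument so either convention is computable.

**Two-noisy-criteria model.** The regularity psychometric curve is fitted
as $\Phi\!\big((x - c_e)/\sigma_e\big) - \Phi\!\big((x - c_l)/\sigma_l\big)$
by binomial maximum likelihood. The exact generative probability of the
draw-two-criteria process is the product
$\Phi\!\big((x-c_e)/\sigma_e\big)\,\Phi\!\big((c_l-x)/\sigma_l\big)$; the
difference form is the standard fitting approximation and the two
coincide for well-separated criteria (the simulator uses the generative
draw, the fitter the difference form — the test suite checks their
agreement in the well-separated regime). Fitting details: parameters are
optimized in the transformed space $(c_e, \log(c_l - c_e), \log\sigma_e,
\log\sigma_l)$ so the order and positivity constraints hold by
construction, with box constraints $\sigma \in [1, 500]$ ms and criteria
within ±500 ms; 20 jittered restarts around moment-based (half-crossing)
initial values, Nelder-Mead then a BFGS polish; probabilities clipped to
$[10^{-6}, 1 - 10^{-6}]$ inside the log-likelihood. Constant response
vectors are non-identifiable and returned with `converged = FALSE`.
Because the criterion-σ convention of slope reporting varies, both the σ
parameters and the density-at-threshold slopes $1/(\sigma\sqrt{2\pi})$
are emitted.

## Exclusion rule and pipeline

Observers are excluded if their JND exceeds 250 ms in the practice phase
or 200 ms in the test phase — strictly above, so a JND exactly at the
threshold is retained. The observer-level test JND pools all test-phase
responses across cells; per-cell (jitter × anisochrony) estimates then
use each cell's nine SOAs. `run_experiment1()` / `run_experiment2()`
chain design → simulation → estimation → exclusion → summary and are pure
functions of `(config, seed)`; `report_tables()` writes byte-stable CSVs
plus a run log. The analysis scripts under `analysis/` drive these
functions in four numbered stages and constitute the command-line
interface of the package.

## Design decisions where the design was open

* **Final-tone anchoring.** Jitter applies independently to the three
  intervals among tones 1–4; the final tone sits on the *nominal* grid at
  $4 \times \mathrm{IOI} + a$. Anchoring to the jittered fourth onset
  would make "expected" ill-defined under jitter; the nominal grid keeps
  the anisochrony an exact property of the stimulus.
* **Flash anchoring.** The flash follows the *actual* final tone
  (`flash = final tone + soa`), so any PSS shift directly measures a
  shift in perceived tone timing.
* **Prior over onsets, not intervals.** The belief is a Gaussian over the
  absolute onset time of the next tone, the minimal formalization in
  which "the posterior becomes the next prediction" is exact; joint
  inference of the IOI itself is out of scope and the interval estimate
  is fixed at 700 ms.
* **Innovation set.** Environment learning uses tones 2–4 only (the
  deviant probe is excluded), and smooths on the SD scale.

## What the simulations do and do not show

The generator emulates the factorial designs, uniform jitter, Gaussian
sensory/criterion/latency noise, lapses, and between-observer parameter
spread. It does not emulate attention or entrainment dynamics, sequential
(trial-history) effects beyond the interval-SD update, audiovisual
latency offsets (any fixed offset is absorbed into the PSS and set to 0),
or duration-based timing mechanisms. Passing tests therefore show that
the pipeline correctly implements and recovers *this* model family on
designs of the stated size — not that the model is the true account of
human data, whose headline effect sizes depend on observer parameters no
desk simulation can pin down.

Problem sizes used by the tests and the acceptance script: cohorts of 12
observers per group at the full trial counts (480 regularity trials, 66
practice + 720 test trials per observer); parameter recovery at 200
trials per level over the 15 anisochrony levels with 100 replicate fits;
Monte-Carlo checks at $10^4$ draws. A full two-cohort replication of the
temporal-order experiment runs in well under a minute on one CPU.

## Known limitations

* The innovation RMS conflates environmental jitter with the observer's
  own sensory noise, so even the regular-environment cohort learns a
  nonzero `interval_sd` and the irregular cohort's shrinkage weight stays
  below 1; the irregular group's index is accordingly small but not
  exactly 0 at finite noise.
* The Spearman–Kärber JND is bounded above by the padding half-width;
  flat (random) response curves yield JNDs near the pad midpoints rather
  than infinity — which is what makes the exclusion rule effective.
* With only 10 repetitions per SOA, per-cell PSS estimates carry
  ~5–10 ms standard errors; the per-observer regularisation index
  inherits ~10–25 percentage points of noise, matching the variability
  the original cohort sizes imply.
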