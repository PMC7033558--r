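---
title: "Racing hand-posture simulators: model, pipeline, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Racing hand-posture simulators: model, pipeline, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handrace)
```

## The model

A *hand posture simulator* decides whether a viewed hand posture could be
produced with one specific hand. It is a two-boundary Wiener diffusion: latent
evidence starts between a reject boundary at 0 and an accept boundary at the
total separation $a$, and drifts at rate $+v$ when the stimulus matches the
simulator's hand and $-v$ otherwise, with diffusion coefficient $s$
(evidence/$\sqrt{s}$). Two features distinguish it from a textbook diffusion
model:

* **A quit-timer.** Each trial draws a random deadline from a log-normal
  distribution; if it elapses before either boundary is reached, the simulator
  *rejects* ("I give up, it's not this hand"). The censoring is asymmetric —
  quits only ever produce rejections — and this asymmetry is what generates a
  response bias toward the "missing hand" in the one-simulator architecture.
* **A race architecture.** Two-handed observers run one simulator per hand in
  parallel; the earliest terminal event decides the trial. An accept means
  "respond this simulator's hand"; a reject or quit means "respond the other
  hand". A congenital one-hander has only the intact-hand simulator, so accept
  maps to "intact" and everything else to "missing". Response time is the
  deciding event's decision time plus a shared non-decision time $T_{er}$.

Because evidence for the correct response effectively arrives through two
channels in the race (the congruent simulator accepting, or the incongruent
one rejecting), two simulators are faster on average than one, and their two
independent quit-timers censor both response options roughly equally —
balancing accuracy across hands. A single simulator funnels every time-out
into "missing", producing the intact-hand accuracy deficit.

## Parameters

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `drift_rate` ($v$) | evidence/s | 0.1 | congruence sets the sign |
| `threshold` ($a$) | evidence | 0.34 / 0.276 | total separation; controls / congenital |
| `start_bias` ($z$) | evidence | 0.006 | $+z$ for the dominant simulator, $-z$ for the other |
| `nondecision_time` ($T_{er}$) | s | 0.3 | added once per trial |
| `quit_mean`, `quit_sigma` | s | 1.6, 1 | arithmetic mean / SD of the quit-time |
| `noise_coef` ($s$) | evidence/$\sqrt{s}$ | 0.1 | the classic scaling convention |
| `dt` | s | 0.001 | Euler step |

Three parameterisation choices deserve justification:

* **Thresholds as half-separations.** The published group values (0.17 for
  controls, 0.138 for congenital one-handers) only reproduce the group-level
  pattern — near-balanced control accuracies, a congenital deficit confined to
  intact-hand images, slower congenital RTs on a realistic 1–1.5 s scale —
  when read as *half*-separations, i.e. boundaries at $\pm a$ around the start
  point. Read as total separations they predict a *larger* per-hand imbalance
  for controls than for congenitals, reversing the pattern, and decision times
  three times too fast. The architecture constructors therefore default to
  total separations of 0.34 and 0.276, while `simulator_params()` itself
  always speaks in total separations; the convention is echoed into the YAML
  serialisation for reproducibility.
* **The quit-time distribution** is specified by its *arithmetic* mean and SD
  and converted to the underlying normal's meanlog/sdlog by moment matching
  ($\mathrm{sdlog}^2 = \log(1 + \sigma^2/\mu^2)$). The source description of a
  "logarithmic distribution with a mean of 1.6 s and a sigma of 1 s" is
  ambiguous between arithmetic- and log-space moments; the arithmetic reading
  keeps the printed numbers on the seconds scale users reason about, and
  `quit_log_space = TRUE` switches to the log-space reading.
* **The diffusion coefficient is not published.** Thresholds and drifts are
  only meaningful relative to it; `noise_coef = 0.1` is the classic
  convention under which the printed drift and thresholds produce sensible
  accuracies, and it is exposed rather than hidden.

## Numerical scheme

Integration is Euler–Maruyama at `dt = 1` ms, with boundary crossings detected
at step granularity — the behaviour of typical simulation code for this model
class, and the default for every model run in this package. Step-granular
detection carries a known $O(\sqrt{dt})$ bias: the discrete walk misses
within-step excursions, which acts like shifting each boundary outward by
$0.5826\, s\sqrt{dt}$ ($\approx 0.0018$ evidence units at the defaults). That
bias is invisible for model fitting (it is shared by every candidate) but
matters when validating the simulator against continuous-time closed forms at
Monte-Carlo precision, so `simulate_passage(bridge = TRUE)` adds a
Brownian-bridge hit test inside each step: with probability
$\exp(-2(b - x_{t})(b - x_{t+dt})/(s^2 dt))$ the bridge touched boundary $b$
between observations. Validation tests use the bridge mode against
`absorption_oracle()` (absorption probability and, by optional stopping, mean
exit time); model runs do not.

Other numerical choices: a quit and a crossing in the same step resolve in
favour of the crossing; each simulator draws its own quit-time per trial; the
rare exact tie between the two simulators' terminal times is broken uniformly
at random (any deterministic rule would favour one hand); `dt` must be small
relative to the mean quit-time or construction fails.

## Fitting

`fit_parameters()` is an exhaustive grid search (the reproducible counterpart
of the original hand-tuning) over any subset of drift, threshold, bias,
non-decision time and quit mean. The loss is an equal-weight sum of squared
per-hand accuracy errors (proportion scale) and squared mean-correct-RT errors
(seconds scale) — the two scales are numerically comparable here (both
$O(0.1)$) and the weights are arguments, since no objective was published.
Every candidate is evaluated with the same seed and simulation size, so the
noisy objective is deterministic across the grid (common random numbers) and
self-generated targets are recovered exactly. The validation suite recovers
threshold and drift from independently simulated targets to within one cell of
a 5×5 grid at 4,000 trials per hand per evaluation.

## The behavioural pipeline

* **Hand mapping**: left/right stimulus sides are recoded per subject —
  missing side for one-handers, non-dominant side for controls — into
  intact/missing, the frame in which groups are compared.
* **Validity filtering**: noisy-recording and no-response trials are dropped;
  accuracy is correct/valid. Subjects whose no-response rate reaches 27% (the
  rate at which a participant is considered unusable) are *flagged*, not
  silently removed — mirroring analyses repeated with and without outliers.
* **RT trimming**: natural-log transform (the base affects neither trimming
  nor rank statistics; it is recorded in the output), then a *single-pass*
  removal of trials beyond 3 SD of the subject × condition cell mean,
  correct trials only. Iterated re-trimming is deliberately avoided: removal
  counts are expected to be tiny, and iteration is under-determined. Cells
  with fewer than 3 trials are left untrimmed with a warning; a cell SD of
  zero trims nothing.
* **Difficulty**: per-image medians of a reference group's correct-trial RTs,
  median-split over images; ties at the median fall to "easy" so the rule is
  deterministic. Mirrored left/right images are split per-image, not
  per-pair; with mirrored reference data the two coincide.
* **Signal detection**: signal = "the intact hand was shown"; d′ =
  $z(H) - z(F)$ and criterion $c = -(z(H) + z(F))/2$, so positive $c$ means
  over-reporting "missing". Extreme rates use the 1/(2N) correction — the
  common default where no correction is named.
* **Scores**: phantom motor control is the mean of five finger–thumb
  opposition cycle times (or total/5); prosthesis usage is the sum of
  within-cohort z-scores of the activity-log and wear-time ratings.

## Rank correlations and dependent-correlation inference

`spearman_corr()` delegates to `stats::cor.test` (exact permutation p without
ties, t approximation with ties). `dependent_corr_test()` compares two
correlations sharing a variable: the default is Steiger's $\bar Z_1^*$ with
the pooled estimate $\bar r = (r_{jk} + r_{jh})/2$ in the covariance factor;
the Hotelling–Williams $t$ ($df = n - 3$) is the configurable alternative —
these are the two standard candidates for the published description, which
names no formula. Applying the machinery to Spearman rhos inherits a common
practice rather than an exact theory; the Monte-Carlo calibration test (type-I
error within [0.03, 0.07] at $\alpha = 0.05$, $n = 15$, 10⁴ trivariate-normal
null replicates) checks that the approximation is serviceable at the study's
sample size.

## The synthetic cohort generator

`generate_cohort()` emulates the study's *structure* so the entire pipeline is
testable without any data download: 21/16/17 subjects per group, 2 blocks × 48
images (24 mirrored pairs), an easy/hard split (hard postures get a
multiplicative RT inflation, default 1.25), 2.8% noisy-recording trials, and
per-subject no-response rates drawn from a scaled Beta with mean 2% and
maximum 10.4%. Trials come from the racing-simulator model itself; the
generator is therefore also the test-bed for parameter recovery. Three
modelling choices go beyond the published model and are ours:

* **Amputees** use the controls (two-simulator) architecture plus a
  subject-level log-normal RT slowdown multiplier — the published model covers
  only controls and congenitals, but amputees behave like controls empirically
  while their RT tracks phantom motor control.
* **The phantom coupling** is a Gaussian copula between the amputee's slowdown
  multiplier and their phantom motor time (log-normal, median ≈ 20 s, spanning
  the observed 9–230 s range), targeting a *population* Spearman correlation
  (default 0.7) via $r_P = 2\sin(\pi\rho_S/6)$. Note that the *sample*
  Spearman statistic is biased toward zero at $n = 16$ (expected value ≈ 0.67
  for a population 0.7), so validation compares cohort averages to that
  expected-sample-statistic closed form, not to 0.7 itself.
* **Covariates** (age, age at amputation 17–45, prosthesis ratings) use
  simple uniform/normal shapes within the observed ranges; nothing in the
  analyses depends on their exact shapes.

Generated RTs above the 5 s display limit become no-response trials, as they
would in the real task. A cohort regenerates byte-identically from its spec
and master seed.

What the generator does *not* emulate: image-level idiosyncrasies beyond the
binary easy/hard split, voice-onset measurement artifacts beyond a flat
noisy-recording rate, session or block-order effects, and any subject-level
variation in model parameters other than the RT multiplier. Passing tests
therefore demonstrate that the pipeline and fitting machinery do what they
claim on data with this statistical structure — not that the model captures
every feature of real laterality data.

## Problem sizes used in validation

Closed-form equivalence uses 10⁵ passages (quit disabled) with three-SE
Monte-Carlo bands; the group-pattern checks use 50,000 trials per hand per
architecture; parameter recovery a 5×5 grid at 4,000 trials per hand per
evaluation against 20,000-per-hand targets; calibration 10⁴ null replicates at
n = 15; generator rate recovery 100 cohorts at full study size.

## Known limitations

* Only group-mean fitting is supported — no trial-level likelihoods for the
  censored race process, and no hierarchical subject-level fitting.
* The race's "first terminal event decides" rule resolves a genuine ambiguity
  in the verbal model description (a reject/quit by one simulator responds
  "other hand" immediately rather than waiting for the second simulator); the
  alternative reading would change quit-heavy regimes.
* Acquired amputees are a generator convenience, not a fitted model.
* The congenital accuracy asymmetry the model produces at the published
  parameters is larger than the empirical one; the parameters were published
  as-is, and no re-tuning is attempted here.
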