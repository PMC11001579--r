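---
title: "Models and methods in forageVI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in forageVI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forageVI)
```

forageVI studies self-paced foraging on two concurrent variable-interval
(VI) reward schedules — the design used in freely moving primate
experiments where an animal walks between two widely separated reward
boxes, choosing *when* and *where* to press. The package provides the
reward process itself, normative and heuristic agents, the behavioral
reward-predictor analyses, a synthetic generator of locomotion and
spiking populations, and the latent-space analyses (sparse CCA and
time-resolved decoding) that connect neural activity to upcoming
choices. Everything runs on synthetic data; no recordings are required.

## The reward process

Each box runs an independent latching Bernoulli ("telegraph") process:
in every bin of width $dt$ (10 ms by default) an unavailable reward
becomes available with probability $dt/\mathrm{VI}$, and once available
it stays latched until the box is pressed. The probability that a
reward is waiting after $t$ seconds without a press is therefore

$$P_{\mathrm{rew}}(t) = 1 - (1 - dt/\mathrm{VI})^{t/dt},$$

which rises exponentially toward 1 with time constant set by the
schedule and converges to $1 - e^{-t/\mathrm{VI}}$ as $dt \to 0$
(first order in $dt$). `prob_reward_available()` evaluates the closed
form; the simulator draws the latching times lazily from the geometric
first-success distribution, which is distributionally identical to
stepping every bin (the test suite verifies this against a literal
per-bin stepping oracle) and keeps multi-thousand-press simulations
fast. Because the per-bin process is memoryless, an unrewarded press
changes nothing, and a mid-delay schedule change is handled exactly by
re-drawing the pending delay under the new rate.

Schedules are block-structured: a block ends silently after its
`n_rewards`-th delivered reward, supporting the unbalanced-pair
reversals (for example VI 15 against VI 25, swapping each block) used
throughout the acceptance analyses.

## The two strategy agents

**Threshold agent (win-stay/lose-switch).** Stays until the run of
consecutive unrewarded presses reaches a per-visit threshold drawn from
a Gaussian (`loss_mean` 3, `loss_sd` 1.5 by default), waits drawn from
a log-normal (median 6 s, `sdlog` 0.5). The agent sees only reward
outcomes: permuting the schedule labels while replaying the same
outcome sequence leaves its choices bit-identical (a tested property).
It undermatches: regressing the per-block log press ratio on the log
obtained-reward ratio gives a slope of roughly 0.6 under the unbalanced
pairs.

**MVT agent.** Has complete schedule knowledge, tracks
$P_{\mathrm{rew}}$ on both boxes, and switches when the other box's
availability exceeds the current box's by a fixed `switching_cost`. Its
press timing is configurable (`wait_policy`), since the switch rule
alone does not fix it:

* `"threshold"` (default): press when the current box's availability
  reaches `theta_press` (0.6), jittered per wait on the log-odds scale
  (`press_jitter_sd` 0.8). With `switching_cost` 0.8 this yields
  slight overmatching (slope ≈ 1.05–1.2), stable across seeds — the
  qualitative signature of the fully informed strategy.
* `"sampled"`: waits drawn from a log-normal irrespective of the
  schedule; on switching, the agent relocates and waits a fresh
  interval before pressing. This policy produces the wide,
  schedule-independent waiting-time distributions seen in animals and
  is used for the behavioral reward-predictor analyses.

The press threshold, switching cost and wait samplers were chosen once,
by scanning for the regime where the two agents reproduce the
under-/over-matching ordering robustly across seeds, and then frozen.

**Belief noise.** An optional AR(1) latent $\varepsilon(t)$ (time
constant 10 s) perturbs the agent's *subjective* estimate of the
alternative box on the log-odds scale:
$\tilde p_{\mathrm{other}} =
\sigma(\sigma^{-1}(p_{\mathrm{other}}) + \varepsilon)$. Positive
excursions inflate the unseen option and trigger early switches, so the
latent is systematically higher on switch presses (tested). Press
timing is deliberately left to private jitter that does not enter the
latent: subjective misestimation then shapes *where* the animal goes
next, while the reward outcome remains a function of the objective
availability — this separation is what makes the decoding orderings
below testable. The latent is shared with the spiking generator, which
is the package's minimal mechanism for the headline phenomenon that
neural activity predicts choices better than the true task variables.

## Behavioral reward predictors

`build_press_table()` derives, per press: the waiting time (time since
the preceding press on either box, presses above 60 s excluded), the
causal half-Gaussian-filtered **reward ratio** (share of recent
rewards from the pressed box; press-domain filter, lags ≥ 1, weights
normalized over available history, and 0.5 when no reward history
exists), the oracle availability probability (from the pressed box's
own clock and the block schedule), the scheduled rate, the stay/switch
choice (location of the *next* press) and the next waiting time.
`tune_filter_width()` follows the experimental procedure of choosing
the filter width that best tracks the scheduled reward ratio; ties go
to the smallest width. `bin_and_correlate()` sorts presses by a
predictor, bins them 50 at a time, and correlates bin means with the
binned rewarded fraction; `conditional_wait_analysis()` and
`switch_probability()` compare next waits and switch rates after
rewarded versus unrewarded presses within short/medium/long wait (or
reward-ratio) categories, either by terciles or by the preset 3–5 /
5–8 / 8–60 s bounds.

## The synthetic bundle

`generate_dataset()` produces a complete session: behavior from an
agent, a 6 Hz locomotion trace (dwelling at the pressed box, 120 cm
cosine transits during switches, smoothed Gaussian jitter), and an
inhomogeneous-Poisson population. Each unit's rate on a 10 ms grid is

$$r_u(t) = \mathrm{softplus}\!\Big(b_u + \textstyle\sum_c w_{uc}\,
z_c(t)\Big),$$

with z-scored latent channels: the within-interval waiting-time ramp,
the piecewise-constant reward ratio, 200 ms-scale post-press,
post-reward and post-choice kernels, locomotion speed, the shared
belief latent, and a private slow AR(1) noise channel. The softplus
link (rather than an exponential) keeps rates bounded under the
power-5 feature regime downstream. Weights are Gaussian per unit and
channel — mixed selectivity by construction — with channel gains
(0.8/0.8/1/1/0.8/0.6/1.5) and baselines uniform on 2–10 spikes/s.

The default bundle — the study condition for the latent-space
analyses — is a balanced VI 20/VI 20 session of 300 rewards
(roughly 450 analyzed presses) with 60 units and the MVT agent under
strong belief noise (`belief_sd` 2, `switching_cost` 0.95). On a balanced schedule the observable task
state carries little information about *where* the agent will go next,
so switches are dominated by the belief latent; the high switching
cost keeps switches rare enough that rewards remain governed by
waiting time. These conditions were calibrated once so that the
planted effects sit at a detectable signal-to-noise ratio and were
then frozen; they are conditions of the synthetic study, not free
knobs of the analyses. What passing tests on this bundle demonstrate
is that the pipeline recovers structure *that is present by
construction*; they say nothing about effect sizes in real recordings,
where selectivity is weaker, noise is correlated, and the true belief
process is unknown.

## Neural preprocessing

`bin_and_smooth()` grids spike counts (200 ms bins) and smooths with a
1 s boxcar (zero-padded, count-conserving). `engagement_mask()` keeps
only bins within 5 s of a press. `press_locked()` aligns 200 ms
windows on presses over a configurable span, excluding presses less
than 2 s after their predecessor; `prepress_counts()` uses the
−1.1 to −0.1 s window. `remove_locomotion()` projects each unit's rate
vector onto the orthogonal complement of the locomotion speed
regressor, $r^{\perp} = r - \Pi r$ with
$\Pi = L(L^{\top}L)^{-1}L^{\top}$. The regressor and rates are
mean-centered before projecting by default, so every residual row has
*Pearson* correlation zero with locomotion to machine precision —
centering is what makes that exactness statement true; the bare
uncentered formula (residuals orthogonal in the dot-product sense
only) remains available via `center = FALSE`. The projection is
idempotent and never increases a row's centered energy. Scalar speed
(the magnitude of the frame-to-frame displacement over time) is used,
interpolated from the 6 Hz camera clock to the analysis grid.

## The 51-column task design

`build_feature_matrix()` expands six task variables on the analysis
grid: press events through 7 pre-press tiles covering [−1.4, 0) s and
7 post-press tiles [0, 1.4); choice (switch) events through 7
post-choice tiles; reward deliveries through 10 tiles spanning 2 s;
and the continuous waiting time, reward ratio, and 2-D location, each
through instantaneous monomials with powers 0.5, 1, 2, 3, 5 —
7+7+7+10+5+5+10 = 51 columns. The 200 ms tiles are contiguous (the
counts and the 2 s reward span are fixed; contiguity is the simplest
layout consistent with them), partition their windows, and each
isolated event activates exactly one tile per time. Continuous traces
are min-max rescaled to [0, 1] per session before exponentiation: the
rescaling is monotone and invertible and prevents the fifth power from
dominating. Columns stay on their natural scale in the matrix;
standardization happens inside the CCA, where scale actually matters.
Location enters as two coordinates times five powers, which is what
the 51-column count forces.

## Sparse CCA

`fit_scca()` z-scores and whitens both sides, then applies a penalized
singular value decomposition to the whitened cross-covariance with
rank-one deflation. The task-side $\ell_1$ budget follows the
penalized-matrix-decomposition convention,
$c = 1 + f(\sqrt{p} - 1)$ with the *fullness* constant $f = 0.3$ by
default; the neural side is $\ell_2$-constrained only. With $f = 1$
the penalty disappears and the procedure reduces exactly to classical
CCA — the test suite checks agreement with the generalized-eigenproblem
oracle (`stats::cancor`) to $10^{-8}$ on random instances, and
decreasing $f$ never increases the number of active task weights.
Because the fitted directions live in a whitened basis, per-column
interpretation uses structure correlations (the correlation of each
task column with a component's task projection); component→variable
assignment picks, for each variable, the component whose loading
pattern concentrates most on that variable's columns, with ties going
to the lower (higher-correlation) index. Cross-validation refits the
whole decomposition on every training fold; folds are the gap-based
press blocks, and each grid bin inherits the block of its nearest
press so held-out time never touches the fit.

`cluster_neurons_by_reconstruction()` provides the baseline
comparison: per-unit ridge reconstructions from the task features,
average-linkage hierarchical clustering on correlation distance (cut
chosen by mean silhouette), clusters under 5 members discarded.
`component_recovery()` and `component_vs_single_unit()` report
held-out correlations of the assigned components with the true latent
traces, against the best single unit and best cluster mean selected on
training folds.

## Time-resolved prediction

`time_resolved_prediction()` predicts each press's reward outcome,
stay/switch choice, and next waiting time from three predictor
families on identical folds and time grids: projections of the task
features restricted to the ten waiting-time/reward-ratio columns onto
canonical directions (unsparsified), the matching neural-side
projections, and the raw population. Per 200 ms bin from 3 s before to
1 s after the press, a ridge-stabilized (fixed $\lambda = 10^{-6}$)
logistic regression (binary targets) or log-link Gamma GLM (next
wait — the log link respects positivity; a linear model on the log
wait is the fallback) is trained on the training blocks and scored on
the held-out block; held-out scores are pooled across folds and
summarized by AUC or Pearson r per bin. The peak statistic is the mean
of the five best pre-press bins. Prediction uses *unsmoothed* 200 ms
rates: the 1 s smoother would leak post-press reward activity into
nominally pre-press bins and fabricate pre-press predictability.
`neuron_dropping_curve()` repeats a decode over random unit subsets
(20 draws per size) to show how information accumulates with
population size.

On the default bundle the expected ordering holds: the task components
predict the reward outcome best (the reward is a function of the
objective task state, which the neural code only transmits noisily),
while the neural components predict the upcoming choice better than
the task components — they carry the planted belief latent — and about
as well as the full population.

## Problem sizes and numerical choices

The packaged analyses run on desk-scale data: sessions of 40–300
rewards (up to ≈ 500 presses, tens of minutes to a few hours of
simulated time), 20–60 units,
a 200 ms analysis grid (≈ 10⁴ bins), and leave-one-block-out folds
over 4–18 gap-defined blocks. Matching-law simulations pool three
unbalanced schedule pairs with ≥ 3,000 presses each. Whitening uses an
eigenvalue cutoff of $10^{-10}$ relative to the largest eigenvalue
(rank-deficient inputs reduce the component count with a warning); the
$\ell_1$ budget is met by 60 bisection steps; degenerate folds
(single-class labels, constant targets) are skipped and counted. All
randomness descends from one root seed through named child streams, so
every bundle and analysis is reproducible from `(config, seed)`.

## Limitations

The generator is a linear-Gaussian latent model with Poisson emission;
it does not emulate correlated noise, non-stationarity, adaptation, or
realistic spike-sorting artifacts, and the belief-noise mechanism is
the simplest shared latent that produces the choice-prediction
ordering, not a model of primate belief formation. The agents are
intentionally minimal: one is blind to time, the other fully informed;
neither is fit to animal data. Conclusions from this package are about
the *analyses* — their correctness, calibration, and failure modes —
not about the biology of any particular dataset.
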