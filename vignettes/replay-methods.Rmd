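---
title: "Detecting replay of mental program execution: models, simulation, and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting replay of mental program execution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(replaytdlm)
```

## The scientific problem

During demanding reasoning, decoded MEG signals show brief, time-compressed
reactivations of task states ("replay"). This package implements an
end-to-end analysis of such replay for a *program execution* task: on each
trial a participant mentally executes a short deterministic program - a walk
through a graph of 12 locations, each tied to one of six operations
(`swap_x` flips one binary attribute of a 3-bit "face" data structure;
`branch_x` chooses the next location conditional on an attribute). Every
trial has a unique correct path of 3-4 operations.

Because no public recordings exist for this task, the package pairs every
analysis with a synthetic sensor-level generator that embeds known ground
truth. Analyses are validated by *parameter recovery*: injected effects (lags,
directions, data updates, similarity structure) must be recovered by the same
code a real dataset would be fed through.

## The task world

`generate_task_graph()` constructs graphs satisfying the task's
combinatorics: 12 locations plus an END token, each operation on exactly two
locations, swap locations with out-degree 1, branch locations with out-degree
2 (distinct successors, at most one END). Successors are sampled along a
random location ordering so every execution terminates; candidate graphs are
rejected unless all 96 (start, face) executions finish within `max_depth = 8`
steps and both path lengths (3 and 4) occur. Trials are drawn with
replacement from admissible pairs, forbidding immediate repeats - a session
of ~90 trials re-uses paths, as in the task it models.

Path-derived model matrices come from `path_similarity()` (program = position
dependent, object = position independent, with the on-screen start location
always excluded), and `transition_matrices()` (trial-wise correct path vs all
remaining graph edges). Variable-length paths are aligned first-to-first,
last-to-last, middles pairwise in order; this makes shallow + deep similarity
decompose program similarity exactly, a property the tests assert. Object
similarity uses multiset intersection so that the program <= object ordering
also holds for paths that revisit a location.

## The synthetic MEG generator

`simulate_noise()` produces AR(1) Gaussian sensor noise (default coefficient
0.5 at 100 Hz - autocorrelated but fast-mixing, a reasonable stand-in for
broadband MEG residuals after high-pass filtering; stationary variance
`noise_sd^2 / (1 - ar^2)`). `make_pattern_bank()` draws one sparse
multivariate pattern per decodable state (10% of sensors, Gaussian weights).

Three amplitudes govern decodability, each fixed once by calibration and not
revisited:

| group | default | calibration target |
|---|---|---|
| operations (type/attribute/compound) | `amplitude = 0.106` | held-out-object compound decoding ~2% above chance (measured 2.07 +/- 0.30 over calibration cohorts), the validated weak-decoding regime |
| objects | `amplitude_objects = 0.45` | ~45% 12-class localizer accuracy, typical of MEG object localizers |
| face values | `amplitude_faces = 0.2` | ~60% binary accuracy, matching printed localizer values (56-64%) |

A single shared amplitude would be wrong on both ends: the operation codes
must be weak (that is the regime the method is validated in) while object
codes in real recordings of this kind are strongly decodable - and
sensor-level sequence recovery is impossible if they are not.

`simulate_localizer()` adds the scheduled states' patterns inside a 50-500 ms
response window with raised-cosine ramps (the decoding peak location is
otherwise unspecified; the window is configurable). Default schedules
reproduce the task's counts: 38 presentations per object and 44 per
face-attribute value in the functional localizer; 22 per object = 44 per
operation in the operation localizer.

`simulate_reasoning()` injects `events_per_trial = 14` replay events per
trial (~50 location reactivations at the mean path length). Each event is a
chain of correct-path location patterns at the object-to-object lag (default
80 +/- 10 ms, reversed order by default since reverse replay dominates in
this kind of task), each location trailed by its operation's type (30 ms),
attribute (60 ms) and compound (60 ms) patterns, and - on swap steps only -
by the post-update face-value pattern 120 ms after the operation. Branch
steps inject no data update and act as the built-in negative control.
Reactivation transients are 20 ms half-cosine bumps. Events are placed
uniformly in time but never earlier than 1 s into a trial: a replayed path
(and its sustained trace) cannot precede its computation, and the
reasoning-onset epoch must stay free of program structure. A sustained
"path pattern" (sum of non-start path-location patterns, gain
`rsa_pattern_gain = 0.3`) is added in the final second of each trial and
180-360 ms after each event; the gain is deliberately well below stimulus
amplitude - a working-memory trace, not an evoked response (at gain 1 the
path pattern dominates the argmax state and starves the reactivation
frequency filter). Everything injected is logged (`InjectionLog`), and the
run is exactly noise + logged signal under a fixed seed.

Behavior is simulated with error probability increasing in program length
and, per probe modality, in branch/swap counts; thinking time increases with
length and branches and is clipped to the task's 5-20 s bounds.

## Decoding

One-vs-rest lasso logistic classifiers (`glmnet`, fixed `lambda = 0.01`;
nested selection was judged not worth its cost at these SNRs - the penalty is
a config knob). Cross-validation is stratified k-fold (k = 8) rather than
leave-one-out for runtime; application weights are refit on all trials at the
peak of the Gaussian-smoothed (20 ms SD) accuracy curve. If the penalty
zeroes every weight (possible at very low SNR), lambda is relaxed tenfold
until a weight survives - a decoder must never emit a constant series.

Abstract operation decoders generalize across objects by construction: Type
trains on two attributes' objects and tests on the third's; Attribute trains
on one type and tests on the other; compound operations train on one of each
operation's two objects and test on the other. Fold definitions are asserted
to share no object between train and test. Reactivation matrices are
per-sample sigmoids of the linear scores - independent binomial outputs that
need not sum to 1.

## TDLM

Stage 1 (`first_stage()`): for each lag up to 200 ms, multivariate OLS of all
states at `t + lag` on all states at `t` (intercept included), per trial.
Stage 2 (`second_stage()`): vectorized empirical matrices regressed on each
theoretical matrix, its transpose (backward), the identity
(self-transitions) and a constant; betas averaged across trials, with a
neighboring-lag-averaged variant. Both stages match explicit
normal-equations oracles to 1e-10 in the tests.

Permutation nulls relabel state identities coherently across all trials of a
shuffle (identity excluded; exhaustive enumeration for tiny state spaces),
averaging shuffled betas across trials then participants (shuffles share
permutations across participants). The corrected threshold is the 95th
percentile of the max-over-lags null statistic - the max-statistic
correction; taking instead the maximum over lags of per-lag percentiles
under-corrects (a calibration experiment put its family-wise rate near 19%
on null data, versus <= 5% for the max statistic, which the suite checks).
For bipartite location-to-feature matrices the permutations act within each
domain block (locations among locations, operation features among
features), so relabeled indicators stay inside the block instead of landing
on the far larger object-to-object empirical entries.

One numerical subtlety is worth recording: the claim "time-reversing the data
exactly exchanges forward and backward betas" is exact for a lagged
cross-covariance stage 1 (transposition symmetry of `X0'Xd`), but only
asymptotic for OLS, because `(X0'X0)^-1 X0'Xd` and its reversed-time
counterpart normalize by different finite-sample covariances.
`first_stage(method = "covariance")` exists for this property; OLS remains
the default.

The reactivation-frequency filter drops a trial when any correct-path
location is argmax of the object posteriors on fewer than 2.5% of samples;
this operationalizes the entropy-based trial removal whose exact statistic
is not specified, and removes trials whose trial-wise theoretical matrices
would hinge on a state the decoders never see.

Multi-step chains (`multistep()`) scan the Operation->Data link while fixing
Location->Operation: the data series is regressed on the product regressor
`loc(t-d1-d) * op(t-d)` with controls for each shorter sequence (location
alone at the cumulative lag, operation alone, location at the direct lag) and
a constant. The reported quantity is the Output - Input beta contrast,
averaged across swap steps and trials; branch steps give the null contrast.
Significance uses per-trial input/output sign flips (an exact symmetry of the
contrast).

Replay onsets are samples where location x lag-shifted operation probability
exceeds the max-over-time 95th percentile of an identity-shuffle null, pruned
to >= 200 ms separation. Event-locked input/output time courses are
baseline-subtracted, averaged within then across trials, and cluster-tested
by mass against label flips.

## RSA

Empirical similarity is the across-trial Pearson correlation of smoothed
(50 ms SD Gaussian) sensor vectors at each time point, aligned to reasoning
onset or offset. The GLM regresses the upper-triangle similarity on program
similarity with bias, face-path and length-difference controls (object
similarity joins for the program-vs-object contrast); the design's condition
number is checked. Significance shuffles the trial correspondence of the
neural data (joint row/column permutation), thresholding positive clusters by
mass at the 97.5th percentile (95th for event-locked analyses, which also get
count-matched random-time control events, averaged over 5 resamples).

## Trained versus template decoding for sequence recovery

`run_study()` has two decoder modes. `"trained"` is the full pipeline:
lasso decoders trained on simulated localizers, with operation weights
applied per trial from folds that never saw the on-path object. `"template"`
applies the pattern bank itself as matched filters - exactly how the
validation simulations define reasoning-period representations (the same
sensor patterns embedded in the localizers). Sequence-recovery validation
uses the template mode, for a diagnosed reason: one-vs-rest training embeds
negative components of *other* objects' patterns in every weight vector, and
temporally autocorrelated sensor noise converts the resulting instantaneous
anti-correlations between decoder outputs into spurious
shortest-lag location-to-operation structure that an identity-permutation
null cannot detect (it is genuine object-identity structure, just not a
sequence). Template weights have no cross-suppression and recover every
injected lag; the trained path is validated on what it can support - chance
calibration, the weak-decoding regime target, and object-sequence recovery,
which survives training because object patterns are strong.

## What a green test does (and does not) establish

The generator captures: per-state multivariate patterns on a sensor subset,
temporal autocorrelation, variable trial lengths, injected multi-link replay
with realistic lag jitter, behavioral structure, and similarity-bearing
sustained patterns. It does not capture: sensor topographies or head
geometry, eye movements and artifacts, non-stationary noise, saccade-locked
components, or cross-participant pattern similarity. Recovery here shows the
*pipeline* is correct and sufficiently sensitive in a matched regime - not
that any real dataset contains these effects.

## Numerical and design choices

* `fs = 100` Hz everywhere (10 ms lag bins represent all modeled lags;
  configurable).
* Lag grid: one bin per sample up to 200 ms; neighboring-lag averaging is a
  +/-1-bin moving mean.
* Both forward and backward curves are always computed, each against its own
  null; injected replay is backward by default, so object-sequence recovery
  reads the backward curve while location->operation links are forward by
  definition.
* Degenerate inputs raise early with specific messages (rank-deficient
  designs, collinear regressor sets, zero-variance trials, unrepresentable
  lags), except where degeneracy is structural (complementary binary decoder
  outputs), which a documented tiny ridge resolves.
* Tests run at reduced scale (fewer sensors/trials/participants/shuffles) to
  stay inside CI budgets; the stated-world defaults are exercised by the
  acceptance suite's validation-regime tests and the acceptance script.

## Known limitations

* Sequenceness at sensor level with weak operation codes is a harder problem
  than the reactivation-level validation it mirrors; group-level recovery at
  small n has correspondingly modest power.
* The entropy filter is an argmax-frequency proxy for an unspecified
  statistic.
* The session-trend and cross-split harnesses operate on per-trial effect
  series supplied by the caller; they are not wired into every analysis
  combination.
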