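# replaytdlm

Simulation-validated analysis of fast neural replay during mental program
execution, in R.

## The problem

In a program-execution task, a participant sees a start location (one of 12
image objects arranged in a learned directed graph) and a cartoon face with
three binary attributes (shape, limb, hat). Each location carries one of six
operations - `swap_<attribute>` flips the attribute and moves to the single
successor; `branch_<attribute>` leaves the face unchanged and moves to the
successor selected by the attribute's current value. The participant mentally
executes the implied program (3-4 operations) to the END token and answers
two probe questions. MEG studies of such tasks report that, during the
thinking period, decoded task states reactivate in fast sequences ("replay"):
path locations ~80 ms apart, each accompanied by its operation's type (~30
ms), attribute (~60 ms) and compound identity (~60 ms), followed ~120 ms
later by the updated face attribute on swap steps, with multivariate activity
increasingly resembling similar programs by the end of the trial.

Because no public recordings of this task exist, every analysis here is
validated by parameter recovery on a synthetic sensor-level MEG generator
with complete ground-truth logs.

## The statistic at its core

Sequenceness is estimated with temporally delayed linear modeling (TDLM), a
two-stage GLM on decoded reactivation probabilities `X(t)` (time x states):

1. First stage, per lag `d` and trial:
   `X(t + d) = X(t) B_d + intercept`, giving an empirical transition matrix
   `B_d` (states x states).
2. Second stage, per lag:
   `vec(B_d) = b_f vec(T) + b_b vec(T') + b_s vec(I) + b_0`,
   where `T` is the hypothesized (trial-wise) transition structure. `b_f` and
   `b_b` are forward and backward sequenceness.

Significance uses state-identity permutations of `T` (coherent across trials,
identity excluded); the corrected threshold is the maximum over lags of the
per-lag 95th percentile of shuffle means. Multi-step chains
(Location -> Operation -> Data) use product regressors with controls for
every shorter sequence; representational similarity analysis (RSA) regresses
across-trial sensor correlations on program/object similarity model matrices.

## Worked example

```r
library(replaytdlm)

cfg <- sim_config(n_participants = 2L, n_trials = 20L, seed = 42L)
res <- run_study(cfg, stages = c("sequenceness", "loc_op", "multistep"),
                 n_shuffles = 100L, decoders = "template")
res$report
```

```
    effect injected recovered   threshold suprathreshold  pass
1  obj_obj       80        80 0.014035941           TRUE  TRUE
2 loc_type       30        30          NA             NA  TRUE
3 loc_attr       60        60          NA             NA  TRUE
4   loc_op       60        60 0.001494423          FALSE  TRUE
5  op_data      120       100          NA             NA FALSE
```

Two simulated participants at the stated-world sensor defaults (~11 s).
Each row compares an injected effect with its recovery: the backward
object-to-object lag (replay is injected in reverse order), the forward
location-to-type/attribute/operation lags, and the scanned
operation-to-data lag from the swap-step Output - Input contrast.
`recovered` is the peak lag in ms; `pass` means within one 10 ms lag bin;
`suprathreshold` compares the peak beta with the corrected permutation
threshold where a null was computed. At this toy scale the weakest link
(the data update, carried by brief low-amplitude face-value transients)
misses by two bins and the location-operation effect does not clear its
threshold; at the validated scale (5+ participants, 60+ trials, as run by
`tests/testthat/test-acceptance.R`) all five lags recover within one bin
and the location-operation effect is suprathreshold.

## Package layout

- `R/world.R`, `R/task_graph.R`, `R/trials.R`, `R/similarity.R` - the task
  world: graphs, deterministic execution, trials/probes, model matrices.
- `R/sim_config.R`, `R/simulate.R`, `R/simulate_reasoning.R` - synthetic MEG
  generator and behavior model.
- `R/decoding.R`, `R/decoding_abstract.R` - lasso logistic decoders,
  held-out-object generalization, cluster permutation tests.
- `R/tdlm.R`, `R/sequence_analyses.R` - TDLM stages, permutation nulls,
  multi-step chains, replay onsets, event-locked reactivation, session trend.
- `R/rsa.R` - time-resolved and replay-aligned RSA.
- `R/pipeline.R` - study orchestration, recovery report, serialization, CLI
  (`inst/cli/replaytdlm.R`).

See `vignettes/replay-methods.Rmd` for the model, parameter meanings,
calibration rationale, numerical choices, and limitations.
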