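## Shared validation-regime study used by the acceptance tests (sequence lag
## recovery, suprathreshold Location -> Operation sequenceness, RSA
## recovery). Simulated once per test run at the stated-world SNR defaults
## with sizes reduced where the criteria permit scaling (n = 5 participants,
## 60 trials, 100 shuffles) - never the SNR regime itself.
##
## Sequence recovery uses template decoding (the pattern bank applied as
## matched filters), mirroring the validation-simulation procedure in which
## reasoning-period representations are defined by the same sensor patterns
## embedded in the localizers; decoder training is validated separately.

acceptance_cfg <- function(seed = 303L) {
  sim_config(n_participants = 5L, n_trials = 60L, seed = seed)
}

acceptance_study <- function() memo("acceptance_study", {
  run_study(acceptance_cfg(),
            stages = c("sequenceness", "loc_op", "multistep", "rsa"),
            n_shuffles = 100L, decoders = "template")
})
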