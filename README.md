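# seiztrack

Real-time seizure-state tracking from multichannel scalp EEG.

Most seizure detectors emit a binary yes/no per epoch. For closed-loop
neuromodulation (VNS/DBS titration) and for quantifying treatment response,
a *continuous* estimate of how likely and how severe a seizure is at every
time step is far more useful. `seiztrack` implements a causal, per-sample
state-space approach for clinicians and neural-engineering researchers
working with annotated scalp EEG (e.g. EDF recordings with per-session
seizure intervals):

1. **Features.** Each bipolar channel is decomposed by a sliding 1-s FFT
   window into absolute band powers for Delta (0.1–4 Hz), Theta (4–7 Hz),
   Alpha (8–15 Hz) and Beta (16–31 Hz); Gamma is excluded as
   muscle-artifact-prone. Powers are dB-transformed and min/max-normalized
   against the first minute of each session.
2. **Selection.** A modified greedy wrapper picks N = 5 pairs of features —
   one continuous, one binary per pair — by training cost-weighted linear
   discriminants (LDA) on the training session and scoring
   F1 = 2·precision·recall/(precision+recall) on the validation session.
   Selected binary features are binarized afterwards by per-feature LDAs.
3. **Mixed filter.** Each pair drives one latent seizure state
   `x_k = ρ x_{k−1} + η_k`, observed through a Gaussian channel
   `v_k = α + β x_k + ε_k` (the dB feature) and a Bernoulli channel
   `λ_k ~ Bern(p_k)`, `p_k = logistic(μ + x_k)` (the binarized feature),
   with μ pinned by the chance probability of seizure. The causal filter
   alternates an AR(1) predict step with a posterior-mode (Newton) update;
   (ρ, α, β, σ²_η, σ²_ε) are learned offline by EM (forward filter +
   RTS-form smoother, closed-form M-steps).
4. **Fusion.** The N filtered trajectories `x_k` are treated as noisy
   observations `x_k = B + C z_k + ν_k` of one combined seizure state
   `z_k = A z_{k−1} + ω_k`, estimated with a numerically robust
   square-root (QR array) Kalman filter; (A, B, C, Σ²_ω, Σ²_ν) are learned
   by a second, exact linear-Gaussian EM.
5. **Binarization.** A final 1-D cost-weighted LDA thresholds `z_k`,
   yielding per-step accuracy/sensitivity/specificity plus the continuous
   seizure probability `logistic(μ + z_k)`.

Everything runs forward-only at inference time (no smoother), so the
method is real-time applicable. A built-in synthetic-subject generator
(band-limited oscillations with waxing/waning envelopes, planted seizure
band-power gains, EDF output) makes the entire pipeline testable without
any external data.

## Worked example

```r
library(seiztrack)

spec     <- synthetic_subject_spec(seed = 11)   # 2 ch x 4 bands, 6 dB planted gain
sessions <- simulate_subject(spec)              # three 30-min sessions, 1 seizure each
bundle   <- fit_pipeline(sessions)              # train S01, validate S02
print(bundle)
#> <seizure_model> 5 estimation pair(s), p_chance=0.0333
#> <selection_result> 5 feature pair(s)
#>   1. cont CH2|Beta|db + bin CH2|Beta|power  (val F1 0.929)
#>   2. cont CH1|Theta|db + bin CH1|Delta|power  (val F1 0.947)
#>   ...

res <- track(bundle, sessions[[3]])             # causal tracking, held-out session
print(res$metrics)
#> <seizure_metrics> accuracy 0.999 | sensitivity 0.967 | specificity 1.000 | F1 0.983
head(res$p_seizure)                              # continuous seizure probability
```

The subject's chance probability (fraction of train+validation time in
seizure) is 0.0333; both planted channel-bands (`CH2|Beta`, `CH1|Theta`)
are found in the first two pairs; and on the held-out session 96.7% of
seizure steps and 100% of non-seizure steps are classified correctly by
thresholding the fused state.

A thin CLI covering `simulate | extract | select | fit | track | evaluate`
lives in `inst/cli/seiztrack.R`; each subcommand takes `--config <yaml>`
and writes CSV/JSON outputs plus a run log.

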