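---
title: "Methods: mixed-filter seizure-state tracking and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-filter seizure-state tracking and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seiztrack)
```

This vignette explains the model the package implements, the assumptions
behind it, the parameters that matter, and the places where the design was
genuinely open and a choice had to be made. It states no empirical result
that the test suite or `scripts/acceptance.R` do not themselves compute.

## The model

The central object is a continuous latent *seizure state*. For each of
`N` estimations (default 5), the state follows a first-order
autoregression

$$x_k = \rho\, x_{k-1} + \eta_k, \qquad \eta_k \sim N(0, \sigma^2_\eta),
\quad 0 < \rho < 1,$$

observed through two channels of different type that share it:

* a **continuous** channel, a dB-scale band-power feature,
  $v_k = \alpha + \beta x_k + \epsilon_k$, $\epsilon_k \sim N(0, \sigma^2_\epsilon)$;
* a **binary** channel, an LDA-binarized band-power feature,
  $\lambda_k \sim \text{Bernoulli}(p_k)$ with
  $p_k = \frac{e^{\mu + x_k}}{1 + e^{\mu + x_k}}$.

The logistic link bounds the seizure probability in (0, 1) and makes
$p_k$ interpretable directly. The offset $\mu$ is *not* estimated: it is
pinned at the logit of the chance probability — the fraction of the
combined training + validation duration labeled as seizure — so that the
resting state $x = 0$ corresponds exactly to the base rate.

Two assumptions matter. First, the continuous feature must be
(approximately) monotone in the latent state; raw oscillatory EEG
amplitude is not, which is why band *power* is used. Second, the Gaussian
channel noise should be roughly homoscedastic; this drives the processing
order discussed below.

### Causal filtering and EM

The forward filter alternates the AR(1) prediction
($x_{k|k-1} = \rho x_{k-1|k-1}$,
$\sigma^2_{k|k-1} = \rho^2 \sigma^2_{k-1|k-1} + \sigma^2_\eta$) with a
posterior-mode update: $x_{k|k}$ solves

$$x = x_{k|k-1} + \sigma^2_{k|k-1}\Big[\tfrac{\beta}{\sigma^2_\epsilon}
(v_k - \alpha - \beta x) + \big(\lambda_k - p(x)\big)\Big],$$

a strictly monotone equation with a unique root, solved by
Newton–Raphson (up to 50 iterations, relative step tolerance $10^{-12}$)
with a bracketing-bisection fallback. The filtered variance is the
inverse curvature
$[\,1/\sigma^2_{k|k-1} + \beta^2/\sigma^2_\epsilon + p(1-p)\,]^{-1}$ at
the mode. The filter is strictly causal, which the tests assert by
truncation.

Parameters $(\rho, \alpha, \beta, \sigma^2_\eta, \sigma^2_\epsilon)$ are
learned by EM on training + validation data. The E-step runs the forward
filter plus an RTS-form fixed-interval smoother with a Gaussian
approximation at the posterior mode; the M-step updates all five
parameters in closed form from the smoothed first and second moments
(transition sums over $k = 2..K$; the initial state is held at 0 with the
stationary prior variance). Because the E-step is approximate for the
Bernoulli channel, the *observed-data* likelihood is not guaranteed
monotone; what is guaranteed — and tested — is that each M-step does not
decrease the expected complete-data log-likelihood at that iteration's
posterior moments (the Bernoulli block has no free parameters because
$\mu$ is pinned). Defaults: initialization $\rho = 0.9$,
$\alpha = \bar v$, $\beta = 1$, $\sigma^2_\epsilon = \mathrm{var}(v)/2$,
$\sigma^2_\eta = 0.1$; stopping at relative parameter change $< 10^{-4}$
or 200 iterations. $\beta$ is kept positive (the Gaussian channel cannot
identify the joint sign of $(\beta, x)$); its sign is flipped after an
M-step if needed.

### Fusing N estimations

The `N` filtered trajectories are stacked into an `N x K` matrix and
modeled as noisy affine observations of a single combined state,

$$z_k = A z_{k-1} + \omega_k, \qquad
\mathbf{x}_k = B + C z_k + \nu_k,$$

with scalar $A$, length-`N` bias `B` and gain `C`, scalar process
variance and a full symmetric positive-definite measurement covariance
(a diagonal-only mode is available via `diagonal_cov`). Inference uses a
square-root Kalman filter: each measurement update QR-triangularizes the
stacked pre-array $[\,L_R,\; C s;\; 0,\; s\,]$ (with $L_R$ the Cholesky
factor of the measurement covariance and $s$ the predicted-state factor),
with signs fixed so the post-array has a non-negative diagonal. The
reconstructed covariance is therefore symmetric non-negative by
construction even when the measurement covariance is conditioned as badly
as $10^{10}$, where the plain covariance recursion can fail; tests verify
agreement with a textbook covariance-form filter to $10^{-8}$ on healthy
systems.

The combiner parameters are learned by exact linear-Gaussian EM (Kalman
filter + RTS smoother E-step, closed-form M-steps), so the exact
innovations log-likelihood is non-decreasing at every iteration — an
asserted invariant. Two conventions close the model's indeterminacies:

* **Scale/sign.** $(C, z)$ are jointly scale- and sign-unidentifiable.
  After each M-step the model is rescaled to $\lVert C\rVert_2 = \sqrt N$
  and the sign set so $\sum_n C_n \ge 0$ (largest-magnitude element
  positive as the tie-break); both are likelihood-invariant
  reparameterizations.
* **Initial state.** Inside EM the prior variance of the first state is
  frozen at its value under the initial parameters (rescaled along with
  the convention above). Re-tying the prior to the *current* stationary
  variance every E-step would couple the prior to the parameters being
  maximized and break the exact monotone-ascent guarantee, so the frozen
  prior is preferred; the user-facing `sqrt_kalman_filter()` defaults to
  the stationary prior of whatever parameters it is given.

EM is initialized with $A = 0.9$, `B` the row means, `C` the first
principal direction of the row-centered tracks (scaled to the
convention), diagonal residual variances, and process variance 0.1.

### Features, selection, binarization

Band powers are sums of squared FFT magnitudes over the one-sided bins in
`[f_lo, f_hi)` of a trailing rectangular 1-s window; half-open membership
partitions the bins despite the adjacent printed band edges. The default
step is one sample (sample-by-sample estimation); the pipeline default is
1 s for tractability, and the step is a config knob throughout.

The continuous feature path is **dB first, then min/max normalization**
against the first minute of the session. The reverse order
(normalize-then-log) was tried and rejected: any value below the
baseline-minute minimum clips to the dB floor (−60 dB at the default
$\epsilon = 10^{-6}$), which happens on a nontrivial fraction of steps for
a stationary series and injects heavy-tailed spikes that violate the
Gaussian-channel assumption and destabilize per-session offsets.
Log-then-scale keeps the feature affine in log-power and unbounded on
both sides, exactly what the Gaussian channel wants. Binary candidates
stay on the normalized raw-power scale (their LDA binarization is
affine-equivariant, so the choice is immaterial there). A constant
baseline minute yields an all-zero series plus a warning rather than an
error.

Selection is a greedy forward wrapper with a budget of `N` pairs: at each
iteration, every remaining continuous candidate is scored by the
validation-set F1 of an LDA trained (with previously selected features)
on the training set, the arg-max joins the model, then the binary pool is
scanned the same way. Binary candidates are evaluated on their continuous
(normalized) values; binarization happens only after selection, both to
save computation and because binarizing first would leak the validation
set into the candidate scoring. Selected features are removed from their
pools — re-selection is disallowed. Ties break toward the lowest pool
index (channel order, then Delta < Theta < Alpha < Beta). Equality of the
first greedy iteration with exhaustive search is asserted against an
enumeration oracle.

The misclassification cost in every LDA is duration-proportional:
cost(missed seizure)/cost(false alarm) equals the non-seizure/seizure
duration ratio of the fitting data. Folded into the bias together with
the log prior odds, the two terms cancel exactly, so the decision
threshold sits at the midpoint of the projected class means — the
balanced choice under heavy class imbalance. Degenerate fits (constant
features, singular pooled covariance) fall back to an all-negative rule
or a trace-scaled ridge ($10^{-6}$), each with a warning.

The final binarizer is a 1-D LDA on the fused state $z_k$ alone, and the
user-facing seizure probability is $\text{logistic}(\mu + z_k)$ with the
same pinned $\mu$ — a stated interpretation, configurable, since nothing
in the model forces a particular link between the *combined* state and a
probability.

## The synthetic subject

The generator emulates what the method needs from real data and no more.
Each channel is a sum of four band-limited oscillations (one per EEG
band: 2, 5, 11, 23 Hz) with amplitudes from a 1/f-flavored background
spectrum (20, 10, 8, 5 µV), plus white noise (5 µV). Each oscillation
waxes and wanes under an independent log-normal envelope
$e^{d\,u_t}$ with $u_t$ a unit-variance AR(1) of 2-s time constant and
depth $d = 0.15$ (≈ 1.3 dB band-power spread) — the amplitude-modulation
character of real EEG rhythms. During annotated seizure intervals the
informative channel-bands multiply their amplitude by $10^{g/20}$
($g = 6$ dB by default) with 1-s linear ramps, so band power rises
smoothly and the latent-state estimate shows graded onset.

The reference subject is fixed: 2 channels × 4 bands (8 candidate
channel-bands, 2 informative), three 30-minute sessions at 256 Hz with
one 60-s seizure each, seed 42. The envelope depth is pinned by two
requirements pulling in opposite directions: variability must be large
enough that single-feature validation F1 is strictly below 1 — otherwise
every candidate ties at F1 = 1.0 and the lowest-index tie-break, not
informativeness, decides selection — and small enough that a 6 dB gain
remains clearly detectable end-to-end (per-step accuracy, sensitivity and
specificity ≥ 0.90 on the held-out session). Both properties are
asserted in the test suite.

What the generator does **not** emulate: physiological seizure
morphology (spikes, rhythmic evolution, postictal suppression), artifacts
(ocular, EMG, electrode pops), inter-channel correlation of background
rhythms, and non-stationary drift beyond the 2-s envelope. Passing tests
therefore demonstrate the estimation machinery — not clinical
performance on real EEG, where feature quality, artifact load and
session-to-session drift dominate.

## Numerical choices and degenerate inputs

* Logistic evaluated overflow-safely and clamped into the open (0, 1)
  interval at machine epsilon; filtered probabilities and variances are
  tested to stay strictly positive.
* dB floor $\epsilon = 10^{-6}$ before the log; applied only to guard
  exact zeros under the chosen processing order.
* Newton fallback: if 50 iterations fail to converge, bisection on an
  expanding bracket; only then a runtime error naming the step.
* EM variance floors at $10^{-12}$; $\rho$ clipped to
  $(10^{-6}, 1 - 10^{-6})$; $|A| < 1$ enforced at $1 - 10^{-6}$.
* Intervals are half-open `[start, end)` seconds; sample indices by
  `floor(t * fs)`; labels are evaluated at step timestamps
  `(k-1) * step_s`, aligned with a trailing window ending at
  `k * step_s`.
* Annotations travel in a plain-text sidecar (`start<TAB>end` per line)
  next to the EDF; the EDF writer emits plain EDF (1-s records, 16-bit),
  and round-trip fidelity is tested at the quantization tolerance.

## Problem sizes

The test suite exercises parameter recovery at the scales a single
workstation handles comfortably: mixed-filter EM at $K = 20{,}000$ steps
× 10 seeds (median-error tolerances fixed from theory-scale pilot runs:
$\rho$ within 0.03, $\alpha$ within 0.5, $\beta$ within 0.4, variances
within 50%), combiner EM at $N = 5$, $K = 20{,}000$ × 10 seeds (A within
0.03, B within 0.1 per element, C within the scale convention — note that
near a unit root the trajectory-mean bias in B grows like
$(1+A)/(1-A)$, so the recovery harness uses $A = 0.9$), and the full
pipeline on the 90-minute reference subject. The forward filter and
smoother are implemented in C++ (Rcpp) because the per-step Newton update
is inherently sequential and sits inside the EM loop.

## Known limitations

* With few informative channel-bands, later selection iterations
  necessarily admit uninformative features; their binarizers fire at
  ~50% (the midpoint rule on a separation-free feature), which conflicts
  with the pinned base-rate $\mu$ and pushes those latent states toward a
  persistent offset carried by $\rho \to 1$. The unsupervised combiner
  can then dilute the informative tracks. The reference subject passes
  the end-to-end bound; across random subjects the bound holds for most
  but not all draws, mirroring the per-subject performance spread this
  family of methods shows on real data.
* The mixed-filter E-step is a posterior-mode Gaussian approximation;
  no exact-likelihood guarantee exists for the Bernoulli channel.
* Min/max normalization from a 60-s baseline is a high-variance
  statistic; session-level offsets in the fused state inherit that
  variance.
* The combiner assumes one global latent state; multifocal activity with
  independent foci is outside the model.
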