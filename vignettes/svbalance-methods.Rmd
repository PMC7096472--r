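---
title: "Instantaneous sympatho-vagal indices: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instantaneous sympatho-vagal indices: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
design choices made where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The heartbeat point-process model

Each RR interval is modelled as a draw from an inverse-Gaussian (IG)
density parametrized by mean and shape. The IG arises as the first-passage
time of a drifting Wiener process, a standard physiological abstraction of
the sinoatrial integrate-and-fire mechanism. The instantaneous mean is a
quadratic Volterra–Wiener autoregression on past RR *increments*,
compactly parametrized on discrete orthonormal Laguerre functions
$\phi_i(n)$ with decay parameter $\alpha$:

$$\mu_{RR}(t) = RR_{\tilde N(t)} + g_0 + \sum_{i=0}^{p} g_1(i)\, l_i
 + \sum_{i=0}^{q}\sum_{j=0}^{q} g_2(i,j)\, l_i l_j,
 \qquad l_i = \sum_{n \ge 0} \phi_i(n)\, d_n,$$

with $d_n$ the $n$-th most recent complete increment. Two conventions
deserve explanation:

* **Filtering starts at lag 0.** The most recent complete increment is
  weighted by $\phi_i(0)$. This is strictly causal, and it is what keeps
  the kernel identifiable: dropping the lag-0 term throws away most of the
  low-order basis energy and leaves the effective regressors so collinear
  that even whole-series least squares on model-generated data cannot
  recover $g_1$ usefully. The identifiability property is enforced by a
  test (parameter recovery, relative $L_2$ error of $g_1$ under 15% in the
  median over seeds).
* **The model is integrated by construction.** Because the mean is
  anchored at the previous interval, the RR level has a unit root and only
  its increments are stationary; simulations from the model drift slowly.
  Tests that need stationarity use strongly anti-persistent kernels
  (negative leading $g_1$), which keep the level in a physiological range.

**Fitting.** Parameters are tracked along a regular grid by local weighted
maximum likelihood over a trailing window $W$ with exponential per-second
forgetting $\rho$, warm-starting each step from the previous solution. The
IG shape is profiled out in closed form each Newton iteration; the Newton
step on the mean parameters uses the analytic Hessian with step-halving
whenever a step would make any in-window mean non-positive. Defaults:
$W = 90$ s, $\rho = 0.98$, at most 20 iterations, gradient tolerance
$10^{-6}$, orders $p = 8$, $q = 2$, $\alpha = 0.2$, step 5 ms. The cited
literature does not fix these; they are conventional values, exposed in
every signature, and the demo pipeline runs a coarser 250 ms step and
$p = 6$ purely for desk-scale runtime — the trajectory at a coarser step is
a subsample of the same estimate (a test asserts warm-started trajectories
at different steps agree to $10^{-4}$ relative on stationary data).

**Goodness of fit.** Observed intervals are mapped through the fitted
conditional CDF; under a correct model the transforms are uniform
(time-rescaling theorem). We report the KS distance against the 95% band
$1.36/\sqrt{n}$ and the autocorrelation of the normal-transformed
rescaled intervals.

## 2. Spectral and bispectral vagal markers

The linear kernel, mapped from Laguerre to lag domain, defines an AR-type
transfer $G(f) = 1/(1 - A(f))$ on the beat series, evaluated against the
local mean heart period as sampling interval. The spectrum is scaled as a
one-sided PSD, $Q(f) = 2\sigma^2 \Delta t\, |G(f)|^2$ with
$\sigma^2 = \mu^3/\lambda$ the IG interval variance, so that the integral
over (0, Nyquist) equals the series variance (Parseval; tested against the
closed-form AR(1) spectrum). Band powers are trapezoidal integrals over
LF and HF. The source literature quotes LF as 0.04–0.15 Hz in one place and
0.05–0.15 Hz in another, and HF variously as 0.15–0.4, 0.15–0.5 and
0.14–0.45 Hz; we default to LF = 0.04–0.15 Hz, HF = 0.15–0.4 Hz (the
field-standard edges) and expose both.

The magnitude bispectrum of the quadratic system is evaluated as
$|Bis(f_1,f_2)| = 2\sigma^4 |G(f_1) G(f_2) G^*(f_1{+}f_2) H_2(f_1,f_2)|$
with $H_2$ the two-dimensional transform of the Laguerre-expanded
quadratic kernel. The absolute normalization constant ($2\sigma^4$, ms²
scaling) is this package's fixed convention — the source literature
delegates it to an external reference — so bispectral magnitudes are
comparable within this implementation only. The structural properties
that matter are tested: a purely linear (Gaussian) system has identically
zero bispectrum; the field is symmetric under $(f_1, f_2)$ exchange; an
injected quadratic coupling at (0.1, 0.25) Hz is localized to one grid
step. LL/LH/HH are 2-D trapezoidal integrals over $(0,0.15]^2$,
$(0,0.15]\times(0.15,0.4]$ and $(0.15,0.4]^2$.

## 3. The EDA sympathetic branch

EDA is Z-scored over the whole recording (the source is silent on the
scope; whole-recording scoring keeps EDAsymp comparable across segments of
one session) and decimated to 50 Hz behind an anti-alias FIR. The
time-frequency plane uses 60 s segments hopped by 1 s (59 s overlap) with
Blackman windows; within each segment a Welch estimate with four
half-overlapped sub-windows, zero-padded to 0.0061 Hz resolution
(config-exposed — the source names both STFT and Welch without details).
Power is one-sided-PSD scaled, so EDAsymp — the 0.045–0.25 Hz band
integral — is in normalized (Z-scored) power units; the source does not
state absolute vs. normalized units, and we document normalized.

Tonic/phasic separation solves a sparse non-negative deconvolution:
$\min_{d \ge 0, b} \tfrac12\|y - Kd - Sb\|^2 + \lambda_1\|d\|_1$ with $K$
the Bateman-kernel ($\tau_0 = 0.7$ s, $\tau_1 = 3$ s, unit-peak
normalized) convolution operator and $S$ a 20 s-knot cubic B-spline basis
for the tonic level, alternating closed-form tonic updates with FISTA,
followed by a support-restricted non-negative least-squares pass that
removes lasso amplitude shrinkage. $\lambda_1 = 0.1$ was chosen once on
generator data (L-curve reasoning: small enough to recover SCR amplitudes
within 10%, large enough that pure drift yields an empty driver) and is
fixed. Significant SCRs are driver local maxima above 0.05 (normalized
units; the source says "above threshold" without a value), merged within
1 s; `nSCR` is normalized per minute (the source's table magnitudes imply
a rate, not a raw count).

## 4. Fusion, wavelet decomposition, and features

EDAsymp's native 1 Hz clock is the fusion clock; point-process series are
averaged within 1 s bins centred on each step. The four indices are
elementwise ratios with denominators below $10^{-12}$ of their median
masked as missing; the identity $S_X \cdot X_{pp} = EDA_{symp}$ holds to
floating-point rounding on every unmasked sample and is asserted in the
acceptance suite.

Tonic/phasic separation of the index series uses a 5-level db5 DWT with
symmetric-reflection boundaries, keeping slightly redundant boundary
coefficients so that full-coefficient reconstruction is exact to
$10^{-10}$. Following the source's literal prescription, the tonic
component is the reconstruction from the first-level approximation
(everything except the level-1 detail) and the phasic component from the
level-5 detail only (≈ 1/64–1/32 Hz at 1 Hz sampling); both are
config-exposed because the first-level-approximation reading is internally
odd (it contains the deeper details too) and the smoother level-5
approximation may be the intended tonic. Phasic windows are quantified by
the median and by the AUC of the *rectified* series — a signed integral of
a zero-mean oscillation would be uninformative; the signed variant remains
available.

The feature table carries the 30 columns of the study's feature families
(time-domain HRV including RMSSD and pNN50 in seconds/percent; LF, HF,
LF/HF; LL, LH, HH; EDAsymp and S_HF; the four SCR features; S_LL, S_LH,
S_HH; and the six phasic medians and AUCs), averaged in 90 s windows and,
for valence work, divided by each subject's neutral-session value.

## 5. Statistics and classification

The paired Wilcoxon test drops zero differences (Wilcoxon's original
rule), enumerates all $2^n$ sign patterns exactly for $n \le 12$ (midranks
under ties), and uses the tie-corrected normal approximation with
continuity correction above. Normality screening is a Lilliefors-type KS
test at the Dallal–Wilkinson 5% critical value. Summaries are
median ± $1.4826\,\mathrm{MAD}/\sqrt n$. No multiplicity correction by
default (raw p-values, as reported in this literature); Benjamini-Hochberg
is a flag. The CPT comparison takes the last 30 s of rest against the
first $t \in \{30, 90, 180\}$ s of CPT; the source's table caption says
"last" where its body says "first", so both are selectable
(`cpt_side`), defaulting to "first".

The classifier is a C-SVM (deterministic SMO; RBF kernel, $C = 1$,
$\gamma = 1/m$ — the source specifies "nonlinear SVM" without
hyperparameters, and describes no inner tuning loop) with recursive
feature elimination using the kernel-space criterion
$\Delta\|w\|^2_f = \|w\|^2 - \|w^{(-f)}\|^2$ at fixed multipliers, one
feature per iteration. Correlation-bias mitigation is a documented
stand-in for the unavailable reference algorithm: features with pairwise
$|r| > 0.95$ are grouped, scored jointly, and only the group's weakest
member is eliminated when the group scores worst. Leave-one-subject-out
validation standardizes on training folds only, aggregates ranks by
summation (ties broken by mean elimination round, then column order), and
reports the row-normalized confusion matrix at the best pooled subset
size. Note the best-subset accuracy maximizes over subset sizes and is
optimistically biased even under a label-permutation null; chance-level
checks therefore use the fixed full-feature classifier.

## 6. The synthetic world

The generator is the package's ground truth and deserves precision about
what it does and does not claim:

* **Heartbeats** come from integral pulse frequency modulation: a
  modulation $m(t) = [1 + a_{LF}\sin(2\pi\,0.1t) + a_{HF}\sin(2\pi\,0.25t)]/\mu_{RR}(t)$
  integrated to successive firing thresholds. Thresholds follow a
  unit-increment random walk with white jitter (`rr_noise_sd`, default
  0.03), giving resting RR variance of a few hundred ms² — the order
  reported for healthy adults — on top of the deterministic modulation;
  setting it to 0 recovers the textbook deterministic IPFM used by the
  analytic examples. Segment parameters ramp over a 10 s transition at
  boundaries, mirroring the rest-to-stress transition marked in the
  experimental protocol this design emulates; instantaneous steps would
  flood any trailing estimation window with transient power.
* **EDA** is a slow spline tonic level plus Poisson-timed,
  gamma-amplitude driver impulses convolved with the unit-peak Bateman
  kernel, plus white measurement noise. `scr_amp` is therefore the SCR
  peak amplitude in microsiemens.
* **ECG** is a minimal biphasic template at each beat plus white noise
  (SNR defined as clean-signal power over noise power); it exists to
  exercise the Pan-Tompkins-style detector, not to model P/T morphology.
* **Cohorts** apply log-normal per-subject jitter (positivity-preserving)
  around the template protocol, with subject substreams derived from one
  seed by a counter so results are independent of generation order. The
  cold-pressor effect is a parameter delta: shorter mean RR, reduced HF
  modulation, raised SCR rate and amplitude. The affective segments carry
  only the modest parameter contrasts of the template protocol.

What a green test establishes: that every pipeline stage transforms known
autonomic structure correctly, with calibrated statistics and faithful
directionality. What it does not establish: fidelity to real
physiology — no respiration coupling, no 1/f baseline drift, no motion
artifacts, no ectopy, and effect sizes chosen for testability (the source
reports no quantitative generator targets). In this world the sympathetic
surge *raises* EDAsymp during CPT; the human data showed a more complex
delayed decrease — direction-of-change tests for EDAsymp are therefore
against the configured world, while the fused S indices rise under CPT in
both.

## 7. Numerical choices and degenerate inputs

FIR filters are Hamming-windowed sincs applied zero-phase with edge
padding; decimation is filter-then-subsample. Trapezoidal quadrature
everywhere a band integral is taken, with refinement-oracle tests.
Newton steps that would produce non-positive means are step-halved (25
halvings before the step is abandoned and the previous parameters
carried); more than 5% non-converged steps abort the fit. Unstable AR
polynomials (root within $10^{-6}$ of the unit circle) flag the spectrum
with a warning rather than failing. Artifact correction flags beats
deviating more than 25% from the 11-beat running median and replaces them
by natural-spline interpolation over accepted beats; a threshold of 1 or
more disables flagging entirely (the "100% threshold is the identity"
contract). Z-scoring refuses zero-variance input; the KS test refuses
fewer than 20 intervals; empty feature windows are flagged missing rather
than silently zero.

## 8. Known limitations

Absolute bispectral (and hence LL/LH/HH and S_LL/S_LH/S_HH) magnitudes
follow this package's normalization and are not comparable across
implementations. The deconvolution is a documented simplification of the
convex-optimization reference method (quadratic tonic prior replaced by a
coarse-knot spline; no box constraints on tonic slope). The
correlation-grouped RFE is a stand-in for an unavailable reference
algorithm. The demo pipeline's coarser grids trade the 5 ms design
resolution for runtime; nothing in the method depends on the coarsening.
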