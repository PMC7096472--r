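# svbalance

Instantaneous sympatho-vagal balance from heartbeat point processes and
electrodermal activity.

## The problem

Autonomic nervous system (ANS) function is classically assessed from heart
rate variability (HRV) spectra: high-frequency (HF, 0.15–0.4 Hz) power
tracks vagal (parasympathetic) cardiac control, but no HRV quantity is a
clean marker of sympathetic outflow, which limits sympatho-vagal ratios
such as LF/HF. Electrodermal activity (EDA), by contrast, is driven purely
by sympathetic sudomotor nerves. `svbalance` implements a multimodal
alternative: a sympathetic index from the EDA spectrum is divided by
instantaneous vagal markers from a probabilistic heartbeat model, yielding
time-resolved sympatho-vagal indices whose tonic (slow) and phasic (fast)
dynamics are separated by wavelet decomposition. A statistics and
classification layer compares conditions (rest vs. cold-pressor stress)
and recognizes emotional valence from the resulting feature table.

Because the human recordings behind this line of work are not publicly
available, the package ships a first-class synthetic-signal generator
(IPFM heartbeats, Bateman-kernel skin conductance responses) with known
ground truth, and its entire validation is property-based against that
generator.

## The model

Each RR interval is a draw from an inverse-Gaussian distribution
f(t | H_t, xi(t)) with shape xi0 > 0 whose mean follows a quadratic
Volterra–Wiener autoregression on past RR increments, expanded on
orthonormal discrete Laguerre functions phi_i(n):

    mu_RR(t) = RR_N(t) + g0 + sum_i g1(i) l_i + sum_ij g2(i,j) l_i l_j,
    l_i = sum_{n>=0} phi_i(n) * (increment at lag n)

Parameters are tracked by local weighted maximum likelihood
(Newton–Raphson, exponential forgetting) along a regular time grid, with
goodness-of-fit by the time-rescaling theorem (KS test). The linear terms
give the instantaneous spectrum Q(f, t) integrated into LF/HF power; the
quadratic terms give the magnitude bispectrum |Bis(f1, f2, t)| integrated
into LL, LH, HH. From the EDA side, a Blackman-windowed Welch
time-frequency plane of the Z-scored, 50 Hz signal is integrated over
0.045–0.25 Hz to give EDAsymp(k); sparse non-negative deconvolution
separates tonic level from phasic SCRs. The fused indices are

    S_HF = EDAsymp / HF_pp,  S_LL = EDAsymp / LL_pp,
    S_LH = EDAsymp / LH_pp,  S_HH = EDAsymp / HH_pp,

each decomposed into tonic and phasic components with a 5-level db5
discrete wavelet transform. Features (30 columns: time-domain HRV,
spectral, bispectral, EDA, fused, and phasic median/AUC quantifiers) feed
robust summaries (median ± 1.4826·MAD/√n), exact paired Wilcoxon tests,
and a nonlinear SVM with recursive feature elimination validated
leave-one-subject-out.

## Worked example

```r
library(svbalance)
cfg <- run_config(n_subjects = 6, seed = 3)
res <- run_pipeline(cfg)
res
#> <pipeline_result> 42 feature rows | best valence subset: 5 features, 75.00% balanced accuracy

res$cpt_comparison$cpt90[c(1, 6, 11, 19),
    c("feature", "rest_median", "elicit_median", "p_value")]
#>    feature rest_median elicit_median p_value
#> 1    mu_rr   8.681e+02     7.869e+02 0.03125
#> 6       hf   1.771e+03     9.829e+02 0.03125
#> 11 edasymp   1.940e-01     7.757e-01 0.03125
#> 19    s_hh   1.376e-07     1.535e-06 0.03125

res$valence$report
#> Confusion matrix (% of true class):
#>              pleasant unpleasant
#>   pleasant      83.33      16.67
#>   unpleasant    33.33      66.67
#> Balanced accuracy: 75.00% | PPV 80.00% | NPV 71.43% (positive = unpleasant)
```

Reading the comparison table: during the synthetic cold-pressor segment
the mean heart period mu_RR drops (868.1 -> 786.9 ms, tachycardia), vagal
HF power falls, the sympathetic EDAsymp rises, and the fused S_HH rises by
an order of magnitude — the designed sympathetic surge read out through
every layer of the method, each with the exact paired-Wilcoxon p-value
(0.03125 = 2/2^6 is the smallest two-sided p attainable with six
subjects). The classifier report is the leave-one-subject-out confusion
matrix at the best-ranked feature subset.

A command-line interface wraps the same stages:

```sh
inst/cli/svbalance synth   --subjects 26 --seed 1 --out runs/synth
inst/cli/svbalance fit-pp  --rr runs/synth/subject01-beats.txt --out pp.csv
inst/cli/svbalance eda-symp --in runs/synth/subject01-eda.csv --band 0.045:0.25 --out eda.csv
inst/cli/svbalance run-all --subjects 26 --seed 1 --out runs/full
```

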