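---
title: "Segmentation-free heart sound screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-free heart sound screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgscreen)
```

## The problem and the modelling idea

A phonocardiogram of a healthy heart contains two events per cardiac
cycle: the first (S1) and second (S2) heart sounds. Pathology announces
itself as *extra* content — third/fourth heart sounds in diastole, or
murmur noise from turbulent flow through stenotic or regurgitant valves.
Pipelines that first segment the recording into labelled beats inherit a
hard failure mode: exactly the sounds most worth flagging (severe murmurs,
extra sounds, a vanished S1 or S2) are the ones that cannot be segmented
reliably.

`pcgscreen` therefore never labels a beat. The only temporal quantity it
estimates is the *cycle length*, obtained from the autocorrelation of an
envelope signal; everything downstream consumes a fixed amount of signal —
five cycles — so that recordings with different heart rates contribute
comparable information. Cropping five cycles also averages out local
peculiarities (an impulse artifact corrupts at most a fraction of the
segment), which is where the method's noise robustness comes from. The
working assumption, stated openly: the heart rate is constant within one
recording. Recordings with marked arrhythmia violate it and are outside
the intended scope.

## Envelope detection

The envelope is the scale-summed squared magnitude of a Complex-Morlet
continuous wavelet transform. The atom at scale $a_m$ is

$$\psi_m(k) = \pi^{-1/4} \exp\!\left(-\frac{k^2}{2a_m^2}\right)
             \exp\!\left(i\,\omega_0 k / a_m\right),$$

correlated with the signal at every shift ($Y(m,n)$), and
$E(n) = \sum_m |Y(m,n)|^2$. Because the Morlet atom looks like an FHS
burst, $E$ peaks sharply at heart-sound events and is attenuated
elsewhere — no thresholding of the raw waveform is involved.

Parameter choices:

* **Band 10–300 Hz, 8 bins per octave** (40 scales at any sampling rate).
  Fundamental heart sounds and most murmur energy live below 300 Hz; the
  octave grid is truncated at the band top rather than overshooting it
  (`scalogram_config(f_max = )` to change).
* **Carrier $\omega_0 = 5$ rad/s**, the canonical Morlet choice, with
  center frequency $F_c = \omega_0 / 2\pi$ Hz in the scale relation
  $s = F_c/(F\Delta)$. This is the only dimensionally consistent reading
  of that relation.
* **Boundaries**: zero padding. The atom is truncated at $\pm 7$
  standard deviations, where the omitted Gaussian tail mass (~3e-12) is
  far below the 1e-8 tolerance at which the FFT path is validated against
  direct evaluation of the correlation sum. The admissibility correction
  of the analytic Morlet is omitted — negligible at $\omega_0 = 5$.

Useful invariants (all tested): $E$ is quadratic in input amplitude,
shift-equivariant away from boundaries, and zero for zero input.

## Cycle length from the envelope autocorrelation

The raw positive-lag autocorrelation
$R(m) = \sum_{n} x(n+m)\,x(n)$ of a quasi-periodic envelope has a maximum
where the shift equals one period. The estimate is the argmax of $R$
inside the lag window corresponding to plausible heart rates, 48–240 BPM —
at 4 kHz, lags 1000 to 5000 samples. Design points:

* The window is expressed in BPM and mapped to lags at whatever rate the
  record has, reproducing 1000–5000 exactly at 4 kHz.
* The in-window *global* maximum is used. For clean quasi-periodic
  envelopes it coincides with the first peak after the origin; when they
  disagree (multi-peak pathologies), the global maximum is the more
  defensible choice. Exact ties resolve to the smaller lag.
* A rate outside the window cannot be represented; the estimator then
  pins to a window endpoint and sets `low_confidence = TRUE` rather than
  failing. That flag doubles as an abnormal-heart-rate indicator.
* Optional smoothing of $R$ before the search is deliberately absent by
  default: on the synthetic data it never changed an estimate, and the
  raw argmax keeps the operation exactly reproducible.

Cropping takes `n_cycles * lag` samples from any offset. Segments need
not start at a cycle boundary; the feature set below is designed to be
insensitive to crop phase.

## Features: 32 wavelet window energies + 3 envelope statistics

The sound segment is decomposed six levels with the Daubechies-2 wavelet;
the level-2 detail coefficients (d2) are split into 32 contiguous windows
and each window contributes its energy $\sum c^2$. At 4 kHz, d2 spans
roughly 500–1000 Hz — far above the FHS carriers — so for a normal heart
these energies are essentially zero while broadband murmur turbulence
raises them by orders of magnitude. When the coefficient count is not a
multiple of 32, the first `len %% 32` windows take one extra coefficient
(an arbitrary but fixed convention; energy conservation across the
partition is exact and tested).

The DWT itself is the orthogonal periodized pyramid with hard-coded
standard Daubechies filters, validated in-package by perfect
reconstruction and energy conservation; odd lengths are zero-padded one
sample per level and restored on inversion.

The envelope segment contributes three statistics:

1. **Number of peaks.** The detector keeps a running maximum and commits
   it as a peak once the signal falls `delta` below it, then re-arms only
   after the signal rises `delta` above the running minimum. A peak is
   therefore a maximum that stands above *both* flanking valleys by
   `delta`, measured from the peak's top — a murmur plateau riding above
   a fixed level does not generate spurious peaks the way simple
   thresholding does. The alternating max/valley state machine is the
   only formulation that both finds multiple peaks and never commits
   twice on one falling slope; it is validated against a brute-force
   topographic-prominence oracle.
2. **Mean peak spacing** in samples; defined as 0 with fewer than two
   peaks (a convention; the value is otherwise undefined).
3. **Segment energy**: the sum of the envelope samples. Since each
   envelope sample is already a sum of squared scalogram magnitudes, this
   sum *is* the segment's signal energy; it is quadratic in waveform
   amplitude (×4 when the waveform doubles), like the wavelet window
   energies.

`delta` defaults to 0.25 of the segment's envelope maximum. On a
normalized envelope a quarter of the S1 peak height separates FHS and
strong extra sounds from ripple; it is exposed as `delta_frac` and as an
absolute `delta` because real recordings may warrant tuning. Envelopes
are not amplitude-normalized before detection — with a relative `delta`
the detector is scale-invariant anyway.

The 35-vector is ordered `[n_peaks, mean_peak_dist, env_energy, w1..w32]`.
The ordering is a documented convention; PCA downstream is invariant to
it.

## PCA

Standard covariance PCA: center, $C = \frac{1}{n-1}\sum_i (a_i - \bar a)(a_i - \bar a)^T$,
eigendecomposition, keep the smallest leading set of eigenvectors whose
eigenvalue sum exceeds 90 % of the total. Projection centers first —
projecting uncentered data with eigenvectors of a centered covariance
would mix the mean into every component. Eigenvector signs are fixed
(largest-magnitude entry positive) so fits are bit-reproducible. The
feature dimensions mix units (counts, samples, energies); by default the
pipeline standardizes columns before PCA (`pca_standardize = TRUE` in
`pcg_config`), otherwise the energy features dominate the covariance and
the reduction collapses to one or two components. Plain covariance PCA
remains available (`standardize = FALSE` in `fit_pca`).

## Ensemble classifier

Bagging over `N = 5` single-hidden-layer networks (10 hidden units,
logistic activations, squared-error loss), each trained on a bootstrap
resample the size of the training set. Because the squared-error surface
is non-convex, each network is the best of 30 random restarts, selected
by the sum of absolute errors on a reserved stratified holdout (20 % by
default). Optimization uses `nnet`'s quasi-Newton minimizer on that same
squared-error objective: it is the established R implementation of
exactly this architecture and converges far more reliably than plain
steepest descent within a fixed iteration budget; `maxit` (default 200)
caps it. Voting: network $i$ votes abnormal when $Y_i \ge T$ with
$T = 0.15$, and the ensemble declares abnormal at $\lfloor N/2 \rfloor$
votes — two of five. Both the low threshold and the sub-majority quorum
deliberately bias toward sensitivity, the right direction for a
screening tool; `roc_curve()` reproduces the Youden-point analysis that
motivates $T = 0.15$. (With $N = 1$ the quorum is clamped to one vote so
a single-network ensemble is plain thresholding.)

## Evaluation

Ten-fold cross-validation with bagging inside each fold; folds are
stratified by class, because with a small normal class unstratified folds
can produce single-class test portions. Class balance is restored by
replicating the minority class uniformly at random ("oversampling").
By default this happens once, before folding — which means replicates of
one example can land on both sides of a fold split, an optimistic bias
that is inherent to balancing before partitioning. The leakage-safe
alternative (`oversample = "within"`) balances each fold's training
portion only. Metrics come from pooled confusion counts; the headline
index is $g = \sqrt{\text{sensitivity} \times \text{specificity}}$,
which, unlike accuracy, cannot be gamed by siding with the majority
class. `leave_one_type_out()` probes generalization to abnormal sound
types absent from training.

## The synthetic simulator: what it emulates, and what it does not

Each record is `n_cycles` identical cycles at an exactly constant rate:
S1 (unit amplitude) at the cycle start and S2 (0.8) at
`systole_fraction` of the cycle, both Gaussian-windowed tone bursts
(defaults 50 and 80 Hz carriers, 80 ms bursts; all configurable within
the constraint that the burst fits inside systole and systole is the
shorter half of the cycle). Abnormal components: S3 (0.13 s after S2) and
S4 (90 ms before the next S1) as softer, lower-pitched bursts (0.6 and
0.55 of S1, at 0.6 of the S1 carrier); murmurs as 4th-order Butterworth
band-passed white noise gated over systole or diastole with raised-cosine
edges, peak-scaled to `murmur_gain` of the S1 peak. The default murmur
band, 120–600 Hz, is an engineering choice on physiological grounds
(murmur turbulence is broadband and extends well above the FHS carriers);
nothing in the analysis chain is tuned to it. White noise is rescaled so
the *realized* SNR equals the request exactly; impulse noise replaces a
chosen window with uniform values bounded by the record's absolute
maximum. One integer seed determines every sample deterministically.

The default study cohort (`simulate_cohort`) is 60 normal + 60 abnormal
records of 8 cycles at 4 kHz, rates uniform on 55–150 BPM, per-record
variation of carriers and systole fraction, and abnormal components
cycled over systolic murmur, diastolic murmur, S3 and S4 with gains
uniform on 0.4–0.9.

What the simulator does *not* model: valve mechanics, respiration and
beat-to-beat variability, multi-source recording chains, or disease
taxonomies. Passing tests on this data demonstrates that the pipeline's
machinery is correct and noise-robust in the stated sense — not that the
classifier's synthetic-cohort performance transfers to clinical
recordings, which differ in exactly the ways the simulator idealizes
away.

## Numerical and testing choices

* Problem sizes are chosen to keep the full test suite in the low
  minutes: 8-cycle records, a 120-record cohort, 30 restarts inside
  cross-validation as in the method definition.
* Production FFT paths (envelope, autocorrelation) are validated against
  brute-force $O(N^2)$ oracles at 1e-8 / 1e-6 relative tolerance on small
  inputs; the peak detector against a prominence filter on 200 generated
  bump trains whose prominences are bounded away from the threshold
  (knife-edge prominences are an inherently unstable comparison for any
  two formulations).
* Degenerate inputs have defined behavior throughout: zero signals yield
  zero envelopes and zero features; a constant autocorrelation window or
  a single-class training set raise informative errors; metrics with zero
  denominators return `NA` rather than a number.
* All randomness flows from explicit integer seeds through one
  derivation function, so every result in the README and the acceptance
  script is reproducible from a single integer.
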