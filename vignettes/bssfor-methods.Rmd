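---
title: "Probabilistic spatio-spectral filters for motor-imagery BCI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic spatio-spectral filters for motor-imagery BCI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two-class motor-imagery brain-computer interfaces decode left- versus
right-hand imagery from the event-related desynchronization (ERD) of
sensorimotor rhythms: imagining a hand movement attenuates the mu
(~8-12 Hz) and/or beta (~16-22 Hz) rhythm over the contralateral motor
cortex. Which exact frequency band is discriminative differs strongly
between people, and a sizeable fraction of users show no usable modulation
at all ("BCI inability"). This package provides

1. a Bayesian treatment of the frequency-band choice for the standard
   band-pass / common-spatial-pattern (CSP) / log-variance / LDA decoding
   chain, where the band is a random variable with a posterior estimated by
   weighted particles (`bssfo_fit()`);
2. an unsupervised resting-state pipeline that turns two minutes of resting
   EEG into a subject-specific spectral density over candidate bands
   (`subject_spectrum()`); and
3. a cluster-distance regression that predicts a subject's future BCI
   accuracy from that resting density (`train_predictor()`).

A synthetic-EEG generator with full ground truth (`subject_spec()`,
`gen_resting()`, `gen_motor_imagery()`, `gen_cohort()`) makes every stage
testable without access to clinical recordings.

## The band posterior

A band hypothesis is $B = (b_s, b_e)$ on a 0.5 Hz grid between 4 and
40 Hz with $b_e - b_s \ge 2$ Hz. Given trials $X$ with labels $\Omega$,
the posterior $p(B \mid X, \Omega) \propto p(X, \Omega \mid B)\, p(B)$ is
represented by $n = 100$ weighted particles. The likelihood of a band is
defined operationally: the probability that trials are classified
correctly when the decoding chain is restricted to that band, estimated as
the mean accuracy of a 4-fold chronological inner cross-validation of
band-pass → CSP → log-variance → LDA.

The fitting loop is importance resampling: weight particles by
(likelihood)$^\tau$, resample systematically, perturb both endpoints with
a Gaussian kernel snapped back to the grid and reflected at the range
bounds, and re-evaluate. Numerical choices that matter:

* **Weight sharpening, $\tau = 30$.** Raw accuracies live in $[0.5, 1]$;
  without sharpening a band at chance still keeps two-thirds of the weight
  of a perfect band and the posterior barely moves. More importantly, every
  band *containing* the discriminative rhythm forms a near-plateau whose
  accuracy deficits are on the order of one percentage point; $\tau$ is set
  so such a deficit costs roughly a third of a particle's weight per
  iteration, which resolves the plateau within the iteration budget
  (with $\tau = 10$ the posterior mean settles 1-2 Hz above a planted
  band).
* **Annealed perturbation (0.85 per iteration, `perturb_decay`).** With a
  fixed kernel the population reaches a diffusion-selection equilibrium
  roughly one kernel width wide and cannot contract; shrinking the kernel
  lets late iterations refine locally. This is the usual remedy when
  particle methods estimate a static parameter.
* **Convergence.** The loop stops when the weighted mean of
  $(b_s, b_e)$ moves less than 0.25 Hz, but never before iteration 8
  (`min_iter`): early on, the mean of a still-diffuse cloud can be
  spuriously stable while the distribution is far from converged. The hard
  cap is 20 iterations.
* **Likelihood evaluation.** Band-limited filtering is zero-phase: the
  squared magnitude response of an order-5 Butterworth band-pass applied in
  the frequency domain. For CSP and log-variance features only per-trial
  covariances of the filtered signal are needed, and those are exactly a
  weighted sum of per-trial cross-spectra, so a single cached
  cross-spectrum per trial makes the likelihood of any band one matrix
  product — identical results to explicit filtering (a test asserts
  agreement), orders of magnitude faster, which is what makes 100
  particles times 10 iterations practical.
* **Degenerate inputs.** If every band scores at chance the posterior is
  left uniform and the model carries a warning flag. Ill-conditioned
  covariances are shrunk toward the scaled identity with escalating
  intensity. A decision score of exactly zero goes to the first label in
  sorted order, so classification is deterministic.

Prediction is an ensemble vote: every distinct posterior band carries its
own CSP + LDA pipeline trained on all trials, and votes are combined with
posterior weights.

For interpretation, the particle cloud is binned into a 2-D density over
$(b_s, b_e)$ and collapsed to one dimension: the value at frequency $f$
sums $p(s, e) - u(s, e)$ over all valid cells with $s \le f \le e$, where
$u$ is uniform over the same cells. The subtraction makes "no information"
exactly zero and sub-uniform evidence negative; the area under the
positive part (`auc_of_pdf()`) summarizes how much super-uniform band
evidence a subject has, optionally after weighting with a Gaussian mixture
centered on the mu and beta rhythms (defaults: 0.6 at 10 ± 4 Hz, 0.4 at
19 ± 5 Hz — deliberately broad components that prefer the canonical rhythm
regions without dragging a density's maximum toward their centers; with
widths of 2-3 Hz the weight shifts the argmax of a peak at the mu-band
edge by about 1 Hz, defeating peak localization).

## The resting-state density

Per channel, Welch power spectral densities (2 s Hann windows, 50%
overlap, so the native resolution equals the 0.5 Hz analysis grid between
2 and 34 Hz) are fitted with the noise-floor model
$g(f) = k_1 + k_2 / f^{\lambda}$ on the grid points outside the rhythm
ranges (7-14 and 15-25 Hz are excluded so the floor is fitted to the
skirts, not the peaks). For fixed $\lambda$ the model is linear in
$(k_1, k_2)$, so the fit profiles $\lambda$ out: closed-form least squares
inside, 1-D minimization of $\lambda$ over $[0.1, 3]$ outside, with
$k_2 \ge 0$ enforced. On in-family spectra this recovers parameters to
~1e-10 and never diverges; a flat spectrum is the degenerate member
$k_2 = 0$ with $\lambda$ flagged non-identifiable.

The frequency-related information (FRI) is the unclipped difference
PSD − floor. A band's likelihood is the mean positive FRI over the grid
points it covers, summed over channels; normalizing gives the 2-D density,
and the same membership-sum/uniform-subtraction rule gives the 1-D
density. Because the likelihood of a pure noise floor is exactly uniform,
its 1-D density is identically zero. With a fitted (rather than known)
floor the residual FRI is ~1e-12 of the spectrum scale, so a likelihood
whose largest positive FRI is below 1e-8 × max(PSD) is treated as zero
and mapped to the uniform density — without this guard, normalization
would amplify pure fit residue into an arbitrary density.

Normalization removes the absolute power scale, which is the one thing
known to predict BCI aptitude, so the final density is re-scaled:
$\Xi(f) = \eta \cdot w(f) \cdot p(f)$ with the subject weight
$\eta = \sum_E \max_f \mathrm{FRI}_E^+(f)$ and $w$ the mu/beta Gaussian
mixture. $\Xi$ is deliberately not a probability density. $\eta$ uses the
FRI rather than the raw PSD so a high noise floor does not masquerade as
rhythm power (`eta_source = "psd"` switches to raw maxima).

## The performance predictor

Each subject contributes the augmented vector
$[\Xi(f_1), \ldots, \Xi(f_m), \mathrm{AUC}(\Xi), \eta]$. Columns are
z-scored across the cohort (the two scalar summaries would otherwise be
swamped by 65 grid values) and reduced by PCA to the components explaining
95% of variance (capped at $n - 1$). Subjects are Ward-clustered in the
reduced space (merges minimize the increase in within-cluster squared
Euclidean distance; default $K = 5$), and each subject is re-expressed as
the vector of Euclidean distances to the $K$ cluster centers. Performance
is an ordinary least-squares function of those distances; rank-deficient
designs fall back to the minimum-norm solution. Evaluation uses
leave-one-out: the held-out subject enters neither the z-scoring, the PCA,
the clustering nor the regression — a test verifies the trained model is
bit-identical when the held-out subject's spectrum changes.

## What the generator emulates — and what it does not

`gen_resting()` synthesizes each channel as colored noise whose expected
PSD is exactly $k_1 + k_2/f^{\lambda}$ (frequency-domain amplitude shaping
of white Gaussian noise), plus per rhythm two lateralized narrow-band
sources with Gaussian spectral envelopes mixed through a geometric
source-to-channel matrix. `gen_motor_imagery()` reuses the same sources
and attenuates the power of the source contralateral to the imagined hand
by the ERD depth. `gen_cohort()` draws mu-type, beta-type and
flat-spectrum subjects and links true performance to the planted rhythm
strength through a logistic curve plus Gaussian noise, so resting spectra
and imagery performance share the structure the predictor assumes.

Deliberate simplifications: rhythm sources are stationary Gaussian
narrow-band noise rather than bursting oscillations; ERD is a constant
attenuation over the whole trial rather than a time course; volume
conduction is a fixed Gaussian mixing, with no eye/muscle artifacts, no
eyes-open/closed alpha reactivity, and no occipital alpha confound.
Passing tests therefore demonstrate correctness of the estimation
machinery under the stated generative model, not robustness to artifacts
or non-stationarity in clinical EEG.

Default study conditions mirror the usual calibration protocol: 75 trials
per class of 4 s at 100 Hz, 150 s of resting EEG (ten 15-s periods
pooled), 16 channels, 80-subject cohorts mixed 0.5/0.3/0.2
(mu/beta/flat) with performance noise sd 0.05. The standard high-SNR test
subject plants one rhythm at 12 Hz with spectral width 1 Hz — occupying
roughly 10-14 Hz — at peak amplitude 2 uV^2/Hz over a floor of
~1.7 uV^2/Hz at that frequency, i.e. a clear rhythm whose single-band CV
accuracy is about 0.93. Amplitudes much larger than this saturate the
likelihood (many distinct bands classify perfectly), at which point the
band posterior is genuinely unidentifiable, so band-recovery checks use
amplitude 2; classification-error checks, which need "high SNR" in the
sense of a single-band Bayes error below 0.05, use amplitude 3.

## Known limitations

* The band likelihood is a cross-validated accuracy: it has a plateau over
  all bands containing the discriminative rhythm, with a mild preference
  for extending toward spectrally quiet regions (extra band above the
  rhythm costs less accuracy than extra 1/f noise below it). The posterior
  mean band is therefore often somewhat wider than, and centered slightly
  above, the planted rhythm; the posterior mode localizes better than the
  mean.
* Ward clustering and PCA are refit per leave-one-out split; cluster
  labels are not stable identifiers across splits.
* The EDF reader covers the common 16-bit single-rate layout only
  (sufficient for the supported montages); EDF+ annotations are not
  parsed and event tables travel separately as TSV.
* Chronological cross-validation assumes trials are supplied in recording
  order; shuffled trial sets silently break the "conservative" property
  the contiguous blocks are meant to give.

## Problem sizes used in the test-suite

Unit tests run on reduced but structurally identical problems (10-40
trials per class, 1-16 channels, 20-150 s of resting signal); the
acceptance checks use the full study conditions above, with five seeded
fitting runs for band recovery and one 80-subject cohort for the
predictor. These sizes are the package's own choice of a thorough but
desk-scale validation.
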