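---
title: "Source-spectral analysis of thalamocortical dysrhythmia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-spectral analysis of thalamocortical dysrhythmia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Thalamocortical dysrhythmia (TCD) is an electrophysiological model in which
altered thalamic firing shifts the dominant cortical rhythm from the alpha
band toward theta, with a secondary, spatially restricted elevation of gamma
activity (the "edge effect") and an inversion of the usual relationship
between low-frequency and gamma power. Resting-state EEG signatures of this
profile — slowed peak alpha frequency (PAF), elevated theta and reduced
upper-alpha relative power, localized gamma increases, and inverse
theta–gamma power–power coupling — are candidate translatable biomarkers in
neurodevelopmental conditions such as Fragile X Syndrome.

`tcdeeg` implements the full analysis chain needed to quantify these
signatures at the cortical-source level, together with a synthetic cohort
generator that produces two-group recordings with *known* ground truth, so
that every stage — filtering, inversion, spectral estimation, parcellation,
coupling, and group inference — is verifiable end to end without access to
any clinical recording.

## Pipeline and models

### Forward model

Rather than a boundary-element model on a template head, the package uses a
single homogeneous conducting sphere with an analytic current-dipole
solution. For a monopole source at $\mathbf{b}$ inside an insulated sphere of
radius $a$ and conductivity $\sigma$, the surface potential is

$$K(\mathbf{b}) = \frac{1}{4\pi\sigma}\left[\frac{2}{d} +
\frac{1}{a}\,\ln\!\frac{2a}{a - \mathbf{b}\cdot\hat{\mathbf{r}} + d}\right],
\qquad d = \lVert \mathbf{r}-\mathbf{b}\rVert ,$$

the closed-form sum of the Legendre series $\sum_n \frac{2n+1}{n}
(b/a)^n P_n(\cos\gamma)$. The dipole potential is its directional derivative
along the moment. This choice keeps the artifact self-contained and *exactly*
testable: the unit tests compare the closed form against an independently
implemented truncated-series oracle to better than 0.1%. With positions in
mm, conductivity in S/m and moments in pA·m, potentials come out directly in
µV. The cortical mesh is an icosphere (level 3 by default: 642 vertices,
radius 70 mm inside a 90 mm scalp sphere, conductivity 0.33 S/m), electrodes
a deterministic Fibonacci lattice (32 by default), sources fixed
normal-to-mesh, and the gain average-referenced. Mesh size, channel count and
radii are all configurable up to sizes comparable to a production
lead field; the defaults are desk-scale so the complete test suite runs in
minutes.

Neither the inverse orientation constraint nor the conductivity model is
standardized across studies of this kind, so both are explicit, configurable
decisions here: fixed normal orientation (one current series per vertex) and
a homogeneous sphere.

### Preprocessing

The conditioning chain is deterministic: a 4th-order Butterworth 2 Hz
high-pass and 55–65 Hz band-stop (plus harmonic stops below Nyquist at higher
sampling rates), both applied forward–backward for zero phase; average
reference; division into 2-s epochs; rejection of any epoch containing a
sample above 100 µV (configurable); retention of the earliest 40 surviving
epochs (80 s). Filters are applied as cascaded biquad sections with
odd-reflection padding — the direct transfer-function form of a 2 Hz/500 Hz
high-pass loses about nine digits to coefficient cancellation, which would
break the package's linearity and order-invariance guarantees; the cascade
keeps filtering linear to ~1e-12 and free of edge transients. Artifact
subspace reconstruction, ICA and channel interpolation are deliberately out
of scope: synthetic inputs are generated clean, and the rejection threshold
stands in for the manual/automated cleaning applied to real data.

### Inverse model

The depth-weighted L2 minimum-norm kernel is

$$K = R L^\top (L R L^\top + \lambda^2 \bar{c}\, I)^{-1},$$

with source prior $R = \mathrm{diag}(\lVert l_i\rVert^{-2\gamma})$ normalized
to unit mean, $\gamma = 0.5$ by default (configurable in $[0,1]$; $\gamma=0$
is the classic minimum norm), noise covariance fixed to the identity, and
$\lambda^2 = 1/\mathrm{SNR}^2$ with SNR 3, scaled by the mean diagonal of
$LRL^\top$ so that SNR is dimensionless. These mirror the conventions of the
common minimum-norm toolboxes. On the default 642-vertex setup the noiseless
point-spread peak falls within the true vertex's 1-ring for >91% of sources,
and as $\lambda^2 \to 0$ on a square invertible system the kernel converges
to the matrix inverse — both asserted in the tests. Source magnitudes are
signed normal currents in pA·m; power is computed downstream.

### Spectral estimation

All spectra live on a 0.5 Hz grid (2-s windows). Scalp-level band powers use
per-epoch periodograms — linear detrend, periodic Hann taper, taper-power
normalized one-sided density — while source-level spectra use Welch averaging
(2-s Hann segments, 50% overlap) over the concatenated retained epochs. Both
feed the same band machinery: seven half-open bands, delta [2, 3.5), theta
[3.5, 7.5), alpha1 [8, 10), alpha2 [10, 12.5), beta [13, 30), gamma1
[30, 55), gamma2 [65, 90) Hz. The half-open convention makes band membership
unambiguous (10.0 Hz belongs to alpha2) and the 55–65 Hz notch region,
inter-band gaps and ≥90 Hz belong to no band. "Total power" for relative
power is the sum of the seven bands, not the full 2–90 Hz integral; the
alternative reading changes only a common denominator and is available by
summing the absolute table directly. Relative power is computed per epoch and
location, then averaged over epochs. On a flat spectrum the band shares are
exactly proportional to the bin counts (3, 8, 4, 5, 34, 50, 50).

PAF is the frequency of the largest *interior local maximum* of log power in
6–14 Hz, computed after trial averaging on the absolute (not relative)
spectrum; a strictly monotone spectrum with no peak yields a missing flag
rather than a boundary value. Natural log is used for "log relative power";
display plots use log10.

Vertex maps can be smoothed with a Gaussian kernel (FWHM 3 mm by default)
over geodesic (graph-shortest-path) distances. The symmetric kernel is
balanced to doubly-stochastic form by Sinkhorn scaling, so constant maps are
fixed points *and* total mass/mean are preserved — with one-sided row
normalization the two properties cannot hold simultaneously. At the default
mesh resolution (~9 mm edges) a 3 mm kernel is nearly the identity; it
becomes consequential on denser meshes.

### Parcellation

Vertices aggregate to atlas nodes by unweighted mean (icosphere vertex areas
are near-uniform); nodes group into 14 regions (7 lobe classes × hemisphere)
and six resting-state-network classes (DMN, DAN, SAN, AUD, VIS, Other), with
nodes kept as replicates rather than averaged away. The package ships a
68-node cortical lookup table (`dk_node_table()`) with 44 nodes in named
networks; the file is a *synthetic stand-in* assembled from standard
anatomical groupings (the original study-specific assignment is not
redistributable) and is deliberately a plain editable CSV. For the toy mesh,
`toy_atlas()` builds spatially compact nodes by seeded k-means and assigns
region/RSN labels round-robin so that every downstream code path runs at desk
scale.

### Cross-frequency coupling

Power–power CFC is the Spearman rank correlation, across 2-s epochs, between
a low band's whole-brain mean relative power (theta, alpha1 or alpha2) and
each node's gamma1 relative power, Fisher Z-transformed
($z = \mathrm{atanh}\,\rho$, clipped at $|\rho| = 1-10^{-7}$ so perfect
correlations stay finite and flagged). Average ranks break ties; gamma2
coupling is available behind an argument but off by default. Node-level
aggregation happens before the per-epoch share normalization; the opposite
order satisfies the same sum-to-one invariant and differs only in vertex
weighting.

### Group statistics

The built-in inference path is: pooled-variance two-sample t-maps;
cluster-based Monte-Carlo permutation (2000 relabelings by default, clusters
formed separately per tail at the 0.025 critical value, cluster mass = sum of
member t, max-|mass| null, exact enumeration with a notice when the design
admits fewer distinct relabelings than requested); Benjamini–Hochberg FDR at
5% applied over the locations × bands dimensions; Bonferroni 0.05/7 for
scalp-level per-band cluster summaries; and age-controlled partial Spearman
correlations (partial Pearson of ranks, t approximation on n−3 df). FDR is
applied to location-level p-values while cluster-level permutation p-values
are reported separately — mixing the two granularities in one correction is
the main ambiguity in this design space, and keeping them separate makes each
interpretable. Mixed-effects group models are intentionally not
reimplemented; `export_tidy()` emits long-format subject × band × node tables
(log relative power, PAF, CFC) ready for `nlme`/`lme4`-style fitting outside
the package.

## The synthetic cohort generator

`simulate_subject()` builds, per atlas node, a sum of band-limited Gaussian
noise components synthesized exactly on the 0.5 Hz grid: one component per
canonical band with amplitude scaled by 1/(band center) — a 1/f profile that
makes relative-power shares realistic — times a per-band gain, plus a
dominant alpha oscillation of ±1 Hz bandwidth centered on the subject's PAF
(drawn from a Normal with group mean/SD, clipped to 6–13 Hz) at `peak_gain`
(default 3) times the local 1/f level. Gamma1 on designated focus nodes is
multiplied by `gamma_focus_gain`. Node signals are copied to member vertices,
projected through the lead field, and white sensor noise is added.

Epoch-to-epoch power covariation uses a Gaussian copula: each epoch draws a
latent gamma1 driver $g_e$ and per-band latents
$u_e = r g_e + \sqrt{1-r^2}\,\varepsilon_e$, and band amplitudes are
multiplied by $\exp(s\,u_e)$ with $s = 0.6$. Because Spearman correlation is
invariant to the monotone exponential, the latent correlation that achieves a
target Spearman $\rho$ has the exact closed form $r = 2\sin(\pi\rho/6)$ — no
numeric calibration table is needed, which is why this implementation departs
from a cached-calibration design. Realized epoch-amplitude correlations are
stored in the ground truth and recomputable by brute force.

Defaults were chosen once, from first-principles scale calculations, as the
fixed study conditions: `source_scale` 600 pA·m per vertex gives ~5 µV
per-channel scalp SD (typical resting EEG, comfortably inside the 100 µV
rejection threshold so clean synthetic epochs survive epoching); sensor
`noise_sd` 0.5 µV emulates a post-artifact-cleaning noise floor — with the
1/f source profile, scalp gamma1 carries only ~0.2 µV, so a noise floor of
several µV would (as in real uncleaned EEG) bury exactly the gamma
signatures the affected preset must carry. The shipped presets mirror the
dysrhythmia profile directionally: control PAF 9.2 Hz vs affected 7.8 Hz
(SD 0.5 Hz), affected theta gain 1.5, alpha2 gain 0.6, gamma1 focus gain 1.8
on the temporal/parietal/occipital nodes, and theta–gamma1 coupling +0.2
(control) vs −0.4 (affected).

What the generator does *not* emulate: eye-blink/muscle artifacts and
ICA-removable components, bad channels, non-stationary vigilance drift,
folded cortical geometry (all icosphere vertices are equally superficial),
and sub-theta fine structure (theta is one band). Passing tests therefore
demonstrate correctness of the pipeline's computations and calibration of its
estimators under clean, stationary, spherical conditions — not robustness to
real-world artifact regimes.

## Numerical choices and degenerate inputs

* Epochs with zero total band power raise an error rather than propagate
  NaN shares; constant series in CFC produce missing-flag rows with warnings.
* Zero pooled variance in a t-map yields t = 0 with a warning; permutation
  p-values are bounded below by 1/(n_perm + 1); exact enumeration replaces
  sampling when the design allows it.
* The partial-correlation formula degenerates when the covariate
  rank-explains a variable entirely; the result is then defined as 0 with a
  warning rather than 0/0.
* All randomness flows from explicit integer seeds; per-subject seeds derive
  from a master seed via a multiplicative hash, and identical configs
  reproduce bit-identical reports.

## Problem sizes

The package's own verification runs use the desk-scale defaults: a 642-vertex
mesh, 32 electrodes, 500 Hz, 120 s per subject, 10 + 10 subjects for the
end-to-end parameter-recovery run, 50 subjects for PAF recovery, 200
replicates for estimator calibration and permutation type-I studies, and 2000
Monte-Carlo relabelings in the default group contrast. Full-scale parameters
(15k vertices, 128 channels, 1000 Hz) are accepted by every constructor; they
change memory and runtime, not code paths.

## Known limitations

The sphere forward model cannot represent skull conductivity steps or
realistic folding, so absolute localization accuracy is not meaningful here —
only the relative, fully-testable behavior of the inverse (point spread,
depth-weighting effect, regularization monotonicity). Node PAF estimates
inherit the 0.5 Hz grid resolution. The built-in group inference treats
subjects as exchangeable units and does not model sex or node random effects;
use the tidy exports for mixed-model analyses.
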