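---
title: "Methods: hyperspectral assessment of cold-water coral exposure status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral assessment of cold-water coral exposure status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cold-water corals (*Lophelia pertusa*) occur as white and orange colour
morphs whose pigmentation gives them distinct optical fingerprints. When a
coral is stressed by a toxicant, its tissue — and with it the reflectance
spectrum — changes before gross morphological damage is obvious. An
underwater hyperspectral imager (UHI) records a full spectrum per image
pixel, so a tank or seabed scan can, in principle, be turned into a map of
coral condition. `uhicoral` implements that analysis chain: radiometric
calibration of raw intensity to reflectance, extraction of labelled pixel
spectra, a dose-response model that turns toxicant concentration into
exposure categories, and a per-morph classification pipeline with
per-organism aggregation.

Because no raw imagery from the motivating experiment is publicly
deposited, the package ships a synthetic scene generator with exact ground
truth. Every stage is therefore testable end to end, and the tests state
precisely what the synthetic world does and does not establish (see
"What a green test means" below).

# Radiometric calibration

Light in water is attenuated with a strongly wavelength-dependent
coefficient $a(\lambda)$, so the apparent colour of an object depends on
its optical path length. The calibration uses two reference targets imaged
in the scene:

1. A Spectralon diffuse standard of known reflectance $R_\mathrm{spec}(\lambda)$
   at height $z_p$ gives a per-slit-column conversion factor
   $A_\mathrm{spec}(x,\lambda) = I_\mathrm{spec}(x,\lambda) / R_\mathrm{spec}(\lambda)$.
2. A larger inclined PVC plate is referenced to the Spectralon at the
   panel's height,
   $R_\mathrm{PVC}(\lambda) = \frac{1}{N}\sum_x I_\mathrm{PVC}(x, z_p, \lambda)/A_\mathrm{spec}(x,\lambda)$,
   and then provides conversion factors at every height it spans:
   $A(x, z, \lambda) = I_\mathrm{PVC}(x,z,\lambda) / R_\mathrm{PVC}(\lambda)$.

Reflectance of an object of height $z$ is then
$R(x,y,\lambda) = I(x,y,\lambda) / A(x,z,\lambda)$.

Numerical choices:

* **Averaging.** Panel statistics average over all masked frames in both
  image axes rather than a single slit frame — identical expectation,
  lower noise.
* **Height interpolation** is linear in $z$ per $(x, \lambda)$; the plate
  is planar and path length is affine in height, so linearity is exact up
  to noise. Queries at sampled heights return grid values without
  interpolation error; queries outside the spanned range fail naming the
  range.
* **Sign convention.** The synthetic forward model uses a doubled vertical
  path, $\mathrm{path}(z) = 2(H - z)$ with camera altitude $H$: higher
  objects have *shorter* paths, so $A$ *increases* with $z$ when
  $a(\lambda) > 0$. The tests assert this convention explicitly.
* **Saturation** is flagged (configurable threshold) and propagated as a
  mask; saturated pixels are excluded from calibration statistics and from
  spectra extraction, never clipped. Negative reflectance from noise at
  dark wavelengths is retained so that downstream standardisation
  statistics stay unbiased.

# The spectra database

Masked, unsaturated pixels become rows of a matrix $X$ (columns =
wavelengths). Only the closed interval 400–750 nm is analysed: outside it,
water transmits too little light for a usable signal. On the default
instrument grid — 823 channels over 381–846 nm, i.e. a spacing of
0.566 nm ("approximately every 0.5 nm") — the crop keeps exactly 619
channels. The spacing was chosen so that the crop count matches the
619-dimensional spectra of the motivating instrument; an exact 0.5 nm grid
would keep 701 channels and is still supported via
`scene_spec(wavelength_step_nm = 0.5)`.

Each row carries its sample id, morph and pixel position. Annotation adds
$Y_h$ — the beaker's mean measured toxicant concentration (arithmetic mean
of the 0/24/48/72 h water samples) and the sample's polyp mortality — and
$Y_c$, the exposure category.

# Dose-response and exposure categories

Polyp mortality (dead polyps at the end of recovery divided by live polyps
before exposure) is modelled against 2-methylnaphthalene concentration
$C$ with a binomial GLM, logit link on $\log C$:

$$\operatorname{logit} p = \beta_0 + \beta_1 \log C .$$

The log-dose parameterisation forces $p \to 0$ as $C \to 0$, which is how
we read "constrained to pass through the origin" without an improper link.
"Binarised" outcomes are polyp-level Bernoulli trials, expressed as
aggregated binomial counts per sample (identical likelihood); a
sample-level any-death binarisation is available behind
`binarize = "sample"`. Zero-concentration controls cannot enter a log-dose
likelihood; they are used as a goodness check (observed control mortality
is reported alongside the fit, and the origin-constrained curve predicts
zero there). McFadden's pseudo-$R^2$ is reported; no numerical agreement
with any published $R^2$ is claimed, since that statistic's exact
definition and data are unavailable.

Lethal concentrations invert the link in closed form,
$C_p = \exp((\operatorname{logit} p - \beta_0)/\beta_1)$. Confidence
intervals are percentile bootstrap over case resamples of coral samples
(not polyps), preserving each sample's beaker concentration; failed
resamples are counted and the run fails if fewer than 80 % succeed.
A known limitation, measured in the acceptance suite: because the 60
samples share only 20 beaker concentrations, sample-level resampling
slightly understates between-beaker concentration variance and the
nominal 95 % LC intervals cover the generating truth at roughly 89–92 %.

Exposure categories partition $[0, \infty)$ by the LC5/LC25 thresholds
(defaults 1.25 and 2.30 mg L⁻¹): *low* $C \le$ LC5, *medium*
LC5 $< C \le$ LC25, *high* $C >$ LC25, with exactly these boundary
inclusivities.

# Classification pipeline

Separate pipelines are trained per colour morph (morphs are trivially
separable and share no fitted state):

1. **Standardisation** — each wavelength column is centred and scaled to
   unit variance with *population* standard deviations computed on the
   training split; constant columns are dropped with a warning. $Y_h$ is
   standardised the same way.
2. **PLS (projection to latent structures)** — a two-block NIPALS
   regression $Y_h = XB + E$ reduces the 619 wavelengths to `n_latent`
   latent variables (default 10) chosen to maximise X–Y covariance.
   Scores are nested (the first $n$ columns are identical for any larger
   model), which makes cross-validation over the component count cheap.
   Loading/score signs are indeterminate; predictions are invariant.
   The component count can be selected by 5-fold stratified
   cross-validation of the downstream classifier (`select_n_latent`),
   with ties broken toward fewer components; in the synthetic world the
   error curve is flat between roughly 5 and 20 components, so the
   default 10 is not critical.
3. **ν-SVM** — a one-vs-one ν-support-vector classifier with RBF kernel on
   the latent scores, ν = 0.1. ν bounds the margin-error fraction from
   above and the support-vector fraction from below, and must satisfy
   $\nu \le 2\min(n_a,n_b)/(n_a+n_b)$ per class pair (violations fail with
   the bound named). The kernel width defaults to the "scale" heuristic,
   $\gamma = 1/(d \cdot \operatorname{var}(X))$. No SVM implementation was
   available in the target environment, so the solver is implemented in
   compiled code: sequential minimal optimisation with the
   two-equality-constraint working-set scheme (same-class pairs preserve
   both per-class sum constraints; first variable by steepest feasible
   descent, second by a second-order gain rule; stopping tolerance 1e-3;
   bounded kernel-row cache). Training is deterministic given data and
   parameters.

Data are split 80/20 into train/test by stratified pixel sampling within
each class (seed-reproducible, proportions preserved to ±1 row per class).
Metrics follow the precision/recall/F1 convention with
$F1 = 2PR/(P+R)$; totals rows use *pixel-count-weighted harmonic means* of
the per-class precision and recall (this is the aggregation that
reproduces the motivating study's printed totals; the unweighted harmonic
mean does not). Reports round to 2 decimals, half-up, only at
serialisation.

**Per-organism majority vote.** Each coral sample receives the category
predicted for the plurality of its pixels; ties break toward the more
severe category with a logged warning — conservative for monitoring use.
Samples with no classified pixels are reported unclassified.

# The synthetic world

`render_scene()` builds ground-truth reflectance and pushes it through the
forward model

$$I = R_\mathrm{true}(x,y,\lambda)\; E(\lambda)\; G(x)\;
  e^{-a(\lambda)\,\mathrm{path}(z)}\;(1+\varepsilon),$$

with halogen-like illumination $E$, a quadratic cross-track profile $G$,
clear-seawater-like attenuation $a$ (minimum near 480 nm, steep rise
beyond 700 nm) and multiplicative Gaussian noise $\varepsilon$
(sd 1 % by default). Scenes contain an inclined PVC plate spanning heights
0–10 cm (0.5 cm per row), a Spectralon block at 3 cm, elliptical coral
blobs of 300–700 pixels at 7 cm, and dark background — the geometry the
calibration procedure assumes, at a camera altitude of 0.35 m.

Coral endmembers are smooth morph-specific spectra: white corals rise
gently from 420 nm; orange corals have a carotenoid-like absorption below
~560 nm. Exposure adds localised features (Gaussian bumps near the pigment
bands) whose amplitude (0.05 reflectance units per severity step) and edge
position (≈5 nm per step) change monotonically with category severity —
the qualitative behaviour of pigment-loss whitening. Within-class
variation is a smooth Gaussian-process-like perturbation per sample
(sd 0.02) plus a smaller per-pixel perturbation (sd 0.01) and per-pixel
log-normal brightness jitter (sd 0.05), so standardisation has something
real to remove. None of these shapes are estimates of real corals: the
motivating study published only qualitative example spectra, so the
effect shapes are configurable package defaults, stated once and held
fixed.

The experiment design mirrors the exposure study: five groups (nominal
0/1.0/2.3/5.0/8.0 mg L⁻¹) × four beakers × three samples (one orange, two
white), 3–9 polyps per sample. Realised beaker concentrations default to
37.5 % ± 8 % of nominal — the mean and spread of the study's reported
beaker recoveries (44/47/27/32 % with replicates 26–60 %) — with 15 %
relative measurement noise per water sample; a per-beaker
`fraction_override` reproduces pathological cases such as a faulty pump
delivering 2 % of nominal. Polyp deaths are binomial draws from the true
dose-response whose LC5/LC25 equal the category thresholds.

**What a green test means.** The synthetic world shares the *structure* of
real data (geometry, attenuation, noise, class imbalance, clustered
concentrations) but not its biology: real exposure-linked spectral
features, bidirectional reflectance, spatial texture and inter-polyp
heterogeneity are absent. A green end-to-end test establishes that the
pipeline recovers known structure through the full imaging + calibration
chain at realistic noise — not that real corals are classifiable at any
particular accuracy. Published per-class metrics are used only as
arithmetic checks (F1 from printed precision/recall, totals aggregation),
never as targets for the synthetic classifier.

Determinism is part of the contract: every generator is a pure function of
its seed arguments (seeds are explicit everywhere, global RNG state is
saved and restored), renders are bit-identical under a fixed seed, and the
CLI writes byte-identical artifacts on reruns with the same configuration.

# Design choices that were genuinely open

* **Wavelength grid.** See above: the default grid realises 619 channels
  in the closed 400–750 nm crop; the crop convention is closed on both
  ends.
* **Pooled PVC spectrum.** The panel-height PVC reflectance is pooled over
  slit columns into a single spectrum (its defining equation's left side
  is column-independent); per-column variants would only add noise.
* **Group-level chemistry summaries** average the four beaker means; the
  printed-table convention of one decimal is applied at reporting time
  only. The group standard deviation pools all beaker measurements by
  default (a `beaker_means` variant exists), since the published tables do
  not state which was used.
* **Below-LOQ values** (LOQ 0.1 mg L⁻¹, LOD 0.033 mg L⁻¹) enter summaries
  at their measured value and are flagged; the alternative (imputing 0)
  would bias control summaries only.
* **One 80/20 split.** Whether the motivating analysis used one split or
  repeated splits is unstated; the default is a single seeded split, and
  repeated-split summaries can be produced by varying the seed.
* **Pixel-level splitting** means pixels of one coral can appear in both
  train and test sets — the protocol of the motivating study. Sample-level
  generalisation is checked separately with the rendered reference group
  (new, never-trained corals), which votes 100 % into the unexposed
  category in the default world.

# Known limitations

* No geometric co-registration, lens distortion or spectral-smile
  handling; scenes are assumed aligned.
* The ν-SVM solver handles the data sizes of this problem (10⁴–10⁵ pixels,
  ≤ 25 latent dimensions) comfortably but is not tuned for very large
  kernel problems.
* LC interval coverage is slightly below nominal under clustered
  concentrations (see above); a beaker-level resampling variant would
  trade that against fewer effective resampling units (20).
* The CLI stores intermediate cubes on disk in ENVI float64; a 20-beaker
  default scenario writes ~2 GB of scratch artifacts.
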