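---
title: "Models and methods for photoreceptor spectral tuning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for photoreceptor spectral tuning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodofit)
```

rhodofit analyses intracellular recordings from compound-eye
photoreceptors — the kind collected by flashing narrow-band light at an
impaled cell and reading off graded depolarizations — and the comparative
questions that follow from them: what visual pigment underlies a cell's
sensitivity, whether non-opsin mechanisms (screening pigments, opsin
co-expression) are shaping it, how many ommatidial types a retina's
R1/R2 cell classes can form, and how binary opsin characters evolved on
a species tree. This vignette documents the models, their assumptions,
the tunable parameters, and the design choices taken where the
literature leaves the design open.

## Visual-pigment templates

A rhodopsin absorbance spectrum is summarised by a single parameter, the
wavelength of peak absorbance $\lambda_{max}$, via a parametric template
("nomogram"). Two published A1-chromophore families are implemented:

* **Govardovskii et al. (2000)** (default, `family = "govardovskii_a1"`):
  the α band
  $S_\alpha(\lambda) = \left[e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D\right]^{-1}$
  with $x = \lambda_{max}/\lambda$, $A = 69.7$, $B = 28$, $C = -14.9$,
  $D = 0.674$, $b = 0.922$, $c = 1.104$ and the $\lambda_{max}$-dependent
  exponent $a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}$, plus a
  Gaussian β band of amplitude 0.26 centred at
  $189 + 0.315\,\lambda_{max}$ nm.
* **Stavenga, Smits & Hoeve (1993)** (`family = "stavenga1993"`): the
  modified log-normal
  $S_\alpha = \exp\!\big(-a_0 x^2 (1 + a_1 x + \tfrac{3}{8}a_1^2 x^2)\big)$
  with $x = \log_{10}(\lambda/\lambda_{max})$, $a_0 = 380$, $a_1 = 6.09$,
  and a fixed β band at 340 nm (amplitude 0.29, $a_0 = 247$,
  $a_1 = 3.59$).

The combined α+β curve is normalized so its maximum on a 0.1 nm grid is
exactly 1. Two consequences of the β bands are worth knowing and are
asserted in the test suite rather than hidden: for deep-UV pigments the
combined argmax sits slightly short of the nominal $\lambda_{max}$
(≤ 1.5 nm for the default family at 355 nm; up to ~5.5 nm for the 1993
family, whose β position does not scale), and the full width at half
maximum (FWHM) of the combined curve is not strictly monotone in
$\lambda_{max}$ across the 350–400 nm β-merge region, although the α
band alone is. At half maximum the template is steeper on its
long-wavelength limb (the classic sharp red cutoff) while the β band
keeps the short-wavelength tail high.

FWHM is measured by re-sampling the curve onto a ≤ 1 nm grid and
interpolating the two half-maximum crossings linearly. The default A1
template at 570 nm has FWHM 115.1 nm on a 1 nm grid; the 1993 family
gives 114.3 nm. Both families therefore agree closely with each other,
and sit a few percent above the ~110 nm that is conventionally quoted
for a 570 nm pigment.

## The intensity–response model

Graded responses follow the Naka–Rushton (hyperbolic) function
$$\frac{V}{V_{max}} = \frac{I^n}{I^n + K^n},$$
with $V_{max}$ the saturating amplitude (mV), $K$ the intensity of
half-maximal response, and $n$ the slope. Intensities are handled
throughout in *relative* photon-flux units derived from the
neutral-density wheel ($I = 10^{-OD}$, OD ∈ [0, 3.5]); no radiometric
calibration is assumed, so $K$ is in the same relative units.

`fit_naka_rushton()` uses bounded Levenberg–Marquardt least squares with
a deterministic multi-start ($n_0 \in \{0.6, 1, 1.5\}$, $K_0$ at the
intensity of the half-maximal observed response) because VlogI fits are
multi-modal in unlucky noise realisations; starts are compared by
residual sum of squares with ties broken toward the lowest $n$. A flat
curve is an error, an effectively saturated curve a warning, and a
user-supplied initial guess can only improve the reported fit. The test
suite checks the optimizer against a dense parameter-grid search.

Inversion, $I = K\,(V/(V_{max}-V))^{1/n}$, diverges as $V \to V_{max}$:
responses above 95 % of $V_{max}$ (configurable `saturation_frac`) are
excluded from inversion rather than propagated, which also covers the
practical case of a noisy peak response slightly exceeding a fitted
$V_{max}$.

## From flash responses to spectral sensitivity

For each wavelength, the response to a fixed 50 ms narrow-band flash is
inverted through the cell's fitted Naka–Rushton function to the
effective intensity that produced it; dividing by the filter set's
relative photon flux (the `flux_calibration`) and max-normalizing yields
relative spectral sensitivity. Algebraically
$S(\lambda) \propto I_{eff}(\lambda)/\phi(\lambda)$ — equivalently, the
reciprocal of the intensity that would be needed at that wavelength to
elicit a criterion response. Doubling the calibration flux at one
wavelength halves the recovered sensitivity there; a flat calibration of
any absolute level is a no-op. No real calibration table is shipped
(each rig's is measured, not modelled); a flat default and a synthetic
xenon-arc-shaped table are provided for simulation and tests.

Replicate cells are averaged per wavelength with standard error
$sd/\sqrt{n}$ computed before the mean curve is re-normalized to 1.
$\lambda_{max}$ is estimated by least squares against a template: a 1 nm
grid search over the search bounds (default the full 300–700 nm) with
0.1 nm local refinement, ties toward the lower wavelength, checked in
the tests against an exhaustive 0.1 nm grid. Template fitting can be
done per cell and the fits averaged, or on the averaged curve —
both orders are supported (`analyze_recording()` per cell;
`average_cells()` then `fit_lambda_max()` for the other order).

## Screening-pigment filtering

The yellow–orange photoreceptor class is modelled as a long-wavelength
rhodopsin screened by a photostable red (ommochrome) pigment:
$S_{filt}(\lambda) \propto S_{rh}(\lambda)\,10^{-d\,\hat A(\lambda)}$,
with $\hat A$ the max-normalized pigment absorbance and $d$ the peak
optical density. The pigment's published description is a peak
absorbance near 560 nm; no measured spectrum is available, so the shape
is a declared, replaceable model (`filter_spec()` accepts a tabulated
absorbance CSV). The default shape is an asymmetric band: Gaussian limbs
of width 150 nm below the 560 nm peak (ommochromes absorb broadly
through the blue–green and UV) and 17.7 nm above it (a steep
long-wavelength cut-off; granular ommochrome pigments transmit red
light). A symmetric rhodopsin-like band was rejected on forward-model
grounds: because it absorbs nearly as strongly at 590 nm as at 560 nm it
*broadens* the filtered curve at low density and pushes the calibrated
peak past 620 nm at high density, the opposite of the observed
phenomenology.

The limb widths are a one-time calibration of the shape against the two
published observations for this cell class: with the long limb at
17.7 nm, the smallest density that moves the 570 nm template's peak to
590 nm ($d^\ast = 0.345$, found by bisection in
`calibrate_filter()`) gives FWHM 70.5 nm — inside the observed 65–75 nm
band — and a narrowing of 44.6 nm relative to the unscreened template,
matching the reported ~40–45 nm. Density, not shape, remains the free
parameter users calibrate; both shape constants are plain arguments.

## Opsin co-expression and the broadband cell

Co-expression of two opsins in one cell is modelled as a convex mixture
of templates, optionally behind a filter
(`photoreceptor_model()`, `coexpression_sensitivity()`), and
`mixture_fit()` solves the inverse problem by nonnegative least squares
(checked against a dense simplex grid). Mixtures can only broaden or
preserve half-widths, never narrow below the narrowest member.

The packaged broadband cell model is an equal blue+LW mixture behind a
generic transmission window centred at 530 nm (Gaussian width 120 nm,
density 0.5, `shape = "bandpass"`), the hypothesised short-wavelength
bandpass mechanism. It reproduces the diagnostic features — half-width
well above 140 nm and a shape no plain two-template mixture can fit
(NNLS residual ≈ 0.7 against candidates at the species' blue and LW
peaks) — but not the measured ~530 nm peak position exactly (the model
peaks near 500 nm for the 470+570 mixture). That residual mismatch is
itself the observation that motivated the bandpass hypothesis, and the
model is intentionally minimal.

## Classification and the retinal mosaic

Cells are classified by peak wavelength and curve shape with an ordered
rule list (`default_class_rules()`): broadband first (FWHM ≥ 140 nm,
any peak), then UV (< 410 nm), blue (410–500), green (500–580 with
FWHM ≥ 90 nm), yellow–orange (580–620 with FWHM ≤ 85 nm). The windows
bracket the peaks reported for Heliconius cells and the FWHM thresholds
sit between the filtered (~70 nm), single-pigment (~95–120 nm) and
broadband (> 160 nm) regimes; all thresholds are arguments.
Classification is total: degenerate curves return `"unclassified"` with
diagnostics, never an error. Shape diagnostics are computed on the raw
interpolated curve; at 1 mV response noise single green cells are
occasionally unclassified because inversion noise near saturation
distorts the apparent FWHM — replicate averaging (`average_cells()`),
as used in practice, stabilises this, and the classifier still recovers
all five melpomene classes from ten noisy cells per class.

Ommatidial types are unordered pairs of R1/R2 cell classes:
$k$ classes give $k(k+1)/2$ types, e.g. 6 for the three-class
melpomene inventory and 10 for a four-class inventory.
`sample_retina()` draws cell classes multinomially (the reported
composition is roughly 75 % LW, 20 % blue, 5 % UV), quantifying why UV
cells are rarely hit by random electrode sampling.

## Synthetic recordings

`generate_recording()` emulates the measurement process: a white-light
VlogI series at OD 3.5…0 in 0.5 steps with responses
$V = nr(10^{-OD})$, and spectral flashes with
$V(\lambda) = nr(\phi(\lambda)\,S_{model}(\lambda))$, both plus additive
Gaussian noise (default SD 1 mV, clipped at 0 mV). Generator defaults:
$V_{max} = 60$ mV (a healthy large-amplitude cell), $n = 1$, and $K$
placed so the brightest flash sits at 90 % of $V_{max}$
($K = 1/9$ in relative flux). Species model sets
(`heliconius_models()`) encode the reported cell classes and peaks —
melpomene UV1 365 / blue 470 / green 570, ismenius blue 445, erato
UV1 355 / UV2 390 / green 555, the 590 nm filtered cell in all three —
with within-LW subdivision (green 0.53, yellow–orange 0.20, broadband
0.02 of the retina) chosen once as a plausible split of the LW-dominated
pool, since only the LW/blue/UV proportions are reported.

What the generator does *not* emulate: heteroscedastic or correlated
recording noise, adaptation and response dynamics, electrode drift, and
rhabdom waveguide optics. Passing recovery tests therefore show that the
analysis chain is consistent and unbiased under additive Gaussian noise
at realistic amplitudes, not that it is robust to every artefact of real
recordings. Under these conditions the simulate→analyze loop recovers
the generating peaks to within ~1.5 nm in the mean (50 replicates per
model, noise SD 1 mV), with replicate SDs of 2–3 nm.

## Ancestral states of binary opsin characters

Binary characters (e.g. the blue-opsin Ser116Ala substitution, or loss
of UVRh2 expression) are reconstructed on rooted trees two ways:

* **Fitch parsimony** (`fitch_parsimony()`): minimum changes, one
  most-parsimonious assignment (ties broken toward state 0), and the
  change edges identified by the tip set they subtend. Checked
  exhaustively against brute-force enumeration on all 4-tip trees and
  against an independent phylogenetics library on random trees.
* **Two-state Mk likelihood** (`mk_ml_ancestral()`): symmetric
  single-rate model, uniform root prior (the default binary likelihood
  analysis of common character-mapping tools), Felsenstein pruning plus
  an up-pass for marginal node probabilities. Missing branch lengths
  become unit lengths with a warning. The pruning likelihood is checked
  against direct summation over all internal assignments, and the
  low-rate limit against parsimony.

Species with polymorphic pseudogene evidence should be coded as having
the intact locus, following the convention of the study this package
models. The packaged Heliconiini fixture tree carries the printed
seven-taxon topology with plausible branch lengths; on it, Ala116 has a
single origin on the stem of the ismenius+numata pair. The synthetic
alignment fixture (labelled `_synthetic`) demonstrates
`map_reference_site()`: mapping an ungapped residue position of a
reference sequence (squid rhodopsin numbering) through alignment gaps to
the column holding the site, reporting each taxon's residue.

## Numerical choices and limitations

* Template evaluation: normalization constant from a 0.1 nm grid within
  ±100 nm of $\lambda_{max}$ (the combined maximum always lies there);
  evaluation outside 250–800 nm is refused.
* $\lambda_{max}$ search: 1 nm grid then 0.1 nm refinement; ties to the
  lower wavelength; boundary optima warn.
* Bisection for filter density: tolerance $10^{-4}$ on the density axis
  against the 1 nm-grid peak; densities above 10 are treated as
  unreachable.
* Problem sizes used by the packaged checks — 50 replicates per
  recovery target, 10 cells per class for classification, exhaustive
  oracles at ≤ 6 tips — were chosen to keep every Monte-Carlo standard
  error well below the tolerances being asserted.
* Real recording noise structure is unknown; additive Gaussian is a
  declared simplification. The study's measured sensitivity curves are
  not numerically deposited, so recovery is validated against the
  package's own forward models, with the published peaks as generating
  truths.
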