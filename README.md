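# rhodofit

Analysis of photoreceptor spectral sensitivities from intracellular
recordings, and of the mechanisms that tune them.

Butterfly compound eyes (the package's model system is *Heliconius*)
achieve rich colour vision with a handful of opsins by layering several
tuning mechanisms on top of opsin sequence evolution: screening-pigment
filters that red-shift and narrow a cell's sensitivity, co-expression of
two opsins in one cell, and gain or loss of whole receptor classes.
rhodofit is for physiologists and evolutionary biologists who want to go
from raw recordings — a white-light intensity series plus narrow-band
spectral flashes per cell — to fitted visual-pigment peaks, forward
models of the non-opsin mechanisms, retinal-mosaic combinatorics, and
ancestral-state reconstruction of opsin characters, with every step
testable against synthetic data from a configurable generator.

## The models at the core

* **Intensity–response:** the Naka–Rushton function
  V/V<sub>max</sub> = Iⁿ/(Iⁿ + Kⁿ), fitted per cell from its VlogI
  series (OD 3.5→0) and inverted, V ↦ K·(V/(V<sub>max</sub>−V))^(1/n),
  to convert each spectral flash response into the effective intensity
  that produced it.
* **Spectral sensitivity:** effective intensities are corrected by the
  filter set's relative photon flux and max-normalized; λ<sub>max</sub>
  is estimated by least-squares fitting of rhodopsin templates
  (Govardovskii 2000 A1 by default, Stavenga 1993 selectable) on a
  1 nm→0.1 nm search.
* **Non-opsin tuning:** screening by a photostable pigment,
  S·10^(−d·Â(λ)), with the density d calibrated by bisection to a target
  peak; opsin co-expression as convex template mixtures, decomposed by
  nonnegative least squares.
* **Mosaic and characters:** ommatidial types as unordered R1/R2 class
  pairs (k classes → k(k+1)/2 types); Fitch parsimony and two-state Mk
  marginal likelihood for binary characters on species trees; alignment
  column mapping for tuning sites numbered on a reference sequence.

## Worked example

```r
library(rhodofit)

# A long-wavelength rhodopsin template and its half-width
tpl <- pigment_template(570)
half_width(tpl)
#> [1] 115.1

# Simulate one blue-sensitive cell (1 mV noise) and analyse it back
rec <- generate_recording(heliconius_models("melpomene")$models$blue,
                          noise = noise_model(response_sd = 1, seed = 42))
ana <- analyze_recording(rec)
ana$nr
#> Naka-Rushton: Vmax = 60.1 mV, K = 0.1068, n = 1 (RSS 4.13)
ana$fit
#> lambda-max fit: 466.6 nm (govardovskii_a1, RSS 0.741)
classify_cell(ana$sensitivity)$label
#> [1] "blue"
```

The fitted V<sub>max</sub> ≈ 60 mV and K ≈ 0.11 recover the generator's
operating point (60 mV, 1/9); the template fit lands within a few nm of
the generating 470 nm pigment for a single noisy cell, and within ~1 nm
in the mean over replicates.

```r
# The yellow-orange cell: calibrate the red screening pigment so the
# 570 nm rhodopsin's peak moves to 590 nm
cal <- calibrate_filter(tpl, target_peak = 590)
cal$density
#> [1] 0.345
yo <- filtered_sensitivity(tpl, cal, seq(300, 700, 1))
c(peak_wavelength(yo), half_width(yo))
#> [1] 590.0  70.5

# Mosaic combinatorics and character history
attr(enumerate_ommatidial_types(c("UVRh1", "BRh", "BRh+LWRh")), "n_types")
#> [1] 6
tree <- ape::read.tree(system.file("extdata", "heliconiini_blue_opsin.nwk",
                                   package = "rhodofit"))
st <- read_character_table(system.file("extdata", "ser116ala_states.csv",
                                       package = "rhodofit"))
fitch_parsimony(tree, st)$changes
#>   from to                               subtends
#> 1    0  1 Heliconius_ismenius,Heliconius_numata
```

The screened 570 nm pigment peaks at 590 nm with a 70.5 nm half-width —
44.6 nm narrower than the unscreened template — and the blue-opsin
Ser116Ala substitution maps to a single origin on the stem of the
*H. ismenius* + *H. numata* pair.

A thin command-line wrapper over these functions lives at
`inst/cli/rhodofit.R` (subcommands `simulate`, `fit-cell`, `average`,
`classify`, `enumerate-mosaic`, `ancestral`, `map-site`).

## Layout

```
R/                  templates, Naka-Rushton, sensitivity pipeline,
                    tuning models, mosaic, character evolution,
                    simulation, I/O + pipeline
inst/extdata/       plain-text fixtures (Newick tree, character table,
                    synthetic alignment, synthetic calibration)
inst/cli/           command-line wrapper
tests/testthat/     unit, property and end-to-end suites
scripts/            acceptance script
vignettes/          methods vignette (models, assumptions, choices)
```
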