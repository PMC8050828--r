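---
title: "Quantifying lipid-phase partitioning of membrane-anchored constructs in GUVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid-phase partitioning of membrane-anchored constructs in GUVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvpart)
```

## The measurement

Ternary lipid mixtures containing a saturated lipid, an unsaturated lipid
and cholesterol de-mix below their miscibility temperature into coexisting
liquid-ordered (Lo) and liquid-disordered (Ld) phases.  In giant
unilamellar vesicles (GUVs) the two phases typically coalesce into two
macroscopic domains — a "Janus" vesicle — so an equatorial confocal section
shows a bright membrane ring split into two contiguous arcs.  A lipid dye
that enriches the Ld phase (channel 1) identifies which arc is which; a
fluorophore on a membrane-anchored construct (channel 2) reports where the
construct sits.

The per-vesicle statistic is the fractional Lo intensity

$$f_{p,Lo} = \frac{I_{Lo}}{I_{Lo} + I_{Ld}},$$

where $I_{Lo}$ and $I_{Ld}$ are the background-corrected mean
construct-channel intensities over the Lo and Ld arcs.  If fluorescence is
proportional to concentration, the corresponding partitioning free energy
(dimensionless, in $k_BT$; natural logarithm) is

$$\Delta G_{p,Lo} = -\ln\frac{f_{p,Lo}}{1 - f_{p,Lo}},$$

with the inverse map $f = 1/(1+e^{\Delta G})$.  The two functions
(`fraction_to_dG()`, `dG_to_fraction()`) round-trip to $10^{-12}$ and obey
the antisymmetry $\Delta G(1-f) = -\Delta G(f)$.  No temperature parameter
is exposed: all energies are in thermal units, and the logarithm must be
natural for the measured fraction/energy pairs of single- and multi-anchor
constructs to be mutually consistent (they are, to within 0.1 $k_BT$ at
their reported rounding).

For a construct carrying several hydrophobic anchors, the additive model

$$\Delta G_{pred} = \sum_i \Delta G_i$$

(`predict_additive()`) predicts the free energy from per-anchor
contributions.  `default_anchor_library()` ships the measured
single-anchor values for ternary membranes — cholesteryl-TEG
$sC = -0.4\,k_BT$, double-cholesteryl $dC = -0.8\,k_BT$, tocopherol
$sT = +1.9\,k_BT$ — as overridable defaults; for other lipid mixtures the
caller must supply its own table.  `nonadditivity()` returns
measured − predicted, negative when the construct prefers Lo more strongly
than the sum of its parts.

## The synthetic image generator

Real micrographs of this kind are rarely archived, so every image-facing
stage is validated against a generator with exact ground truth
(`sample_population()`, `render_frame()`, `simulate_frames()`).  What it
emulates:

* a population of Janus vesicles with log-normal radii (median 35 px,
  shape 0.3 by default — with the nominal 0.2 µm/px this spans the
  7–20 µm diameters typical of electroformed GUVs) placed without ring
  overlap by rejection sampling;
* a membrane ring drawn as a Gaussian radial profile (σ = 1.5 px), split
  into one Lo and one Ld arc with sharp boundaries; the Lo arc fraction is
  uniform on (0.35, 0.6) so neither phase degenerates;
* channel 1 with an Ld:Lo intensity ratio `lipid_contrast` (default 2);
  channel 2 with an Lo:Ld ratio $e^{-\Delta G_{true}}$, normalised so the
  arc amplitudes average to `membrane_amplitude` (default 1000 counts);
* then, in order: PSF blur (Gaussian, σ = 1.5 px), linear cross-talk
  mixing by a row-stochastic 2×2 leakage matrix, per-channel background
  (50 counts) and Poisson shot noise (a Gaussian model is selectable for
  low-count regimes).

The sharp pre-blur arc boundary makes the ground truth unambiguous: PSF
blur is the *only* source of boundary smearing, which is what the
segmentation's boundary-exclusion parameter compensates.  One master seed
derives per-frame streams deterministically, so a population is exactly
reproducible.  Pixel size, magnification and detector statistics are
configuration defaults (shot-noise-limited at a nominal 0.2 µm/px), not
facts asserted about any particular instrument.

What the generator does **not** emulate: photobleaching, z-drift and 3D
sectioning artifacts, vesicle deformation away from circularity,
multi-domain (non-coalesced) vesicles, and optically resolvable membrane
undulations.  Passing the recovery tests therefore shows the pipeline is
correct *given* ring-like equatorial sections with two contiguous arcs; it
does not certify performance on deformed or multi-domain vesicles.

## Detection and angular profiling

Both fluorophores label the membrane, so detection runs on the channel
sum.  Pixels above a robust threshold (median + 5·mad; on noise-free
frames, where mad collapses, 20% of the dynamic range) are grouped into
connected components, and each component of at least 80 px is fit with an
intensity-weighted algebraic (Kasa) circle fit, refined twice on the
pixels within 3 RMSE of the current circle.  This attains sub-pixel
centers and radius errors well below 2% on phantoms, which is the contract
that matters; no claim is made that any particular laboratory pipeline
used the same operators.

Numerical choices:

* **ring width** for annulus sampling defaults to 6× the fitted radial
  RMSE of the ring (≈ 3× its full width), floored at 4 px, capturing the
  full blurred membrane signal without bulk;
* **quality** is $1 - 2.5\,\mathrm{RMSE}/R$ clipped to [0, 1] — monotone
  in circularity — with a 0.5 acceptance gate;
* vesicles whose ring comes within one ring-width of the frame border are
  excluded rather than quantified (partial arcs bias the means), and of
  two overlapping circles only the higher-quality one is kept.

`extract_angular_profile()` assigns every annulus pixel to exactly one of
72 half-open angular bins (5°, at least ten bins for the smallest arcs the
generator produces) and records per-bin, per-channel means and pixel
counts.  Count-weighted bin sums conserve the total annulus intensity
exactly, and a quarter-turn of the frame shifts the profile by exactly
`n_bins/4` — both are tested properties.  Angles are radians,
counter-clockwise from +x; pixel coordinates are 0-based (x = column,
y = row) throughout.

## Phase segmentation

The lipid channel of a Janus profile is two-level.  `segment_phases()`
splits the 72 bin means at the threshold minimising intra-class variance
(an Otsu-style exhaustive search over midpoints — a dozen lines, since the
input is a short vector rather than an image), labels the brighter class
Ld, and enforces cyclic contiguity: the largest contiguous run of each
class wins (ties broken toward the run with the higher mean contrast, for
determinism) and conflicting bins are excluded.  Two boundary bins
(10°) are then dropped on each side of each of the two phase boundaries.
The default of 2 bins is a configuration parameter validated on synthetic
recovery: with PSF σ = 1.5 px on a 35 px radius the boundary smear spans
roughly 2–3°, so 10° is conservative without starving small arcs.

Guard rails: a separation score — (mean Ld − mean Lo)/pooled SD over the
retained bins — below 2 raises a "not phase-separated" error (uniform
vesicles must not be silently quantified), and arcs shorter than 4 bins
after exclusion raise a "degenerate arc" error.  On noise-free phantoms
the labels match ground truth exactly outside the exclusion zone, and the
labelling is equivariant under cyclic rotation and under swapping the two
intensity levels.

## Quantification, background and cross-talk

Background is the per-channel median over pixels farther than
ring + margin from every detected vesicle (interior included in the
exclusion).  Arc intensities are pixel-count-weighted means over each
phase's retained bins — identical to the direct per-pixel mean over the
arc, and robust to unequal bin occupancy.  After background subtraction,
negative means are clamped to zero and flagged so that $f$ stays in
[0, 1]; a vesicle whose total signal vanishes is dropped with a logged
reason, as is every other exclusion (one reason per vesicle, by
construction).

Spectral bleed-through is modelled linearly: observed = true · M with a
row-stochastic leakage matrix.  `estimate_crosstalk()` measures M from
single-fluorophore control frames as the ratio of off- to on-channel
membrane signal, normalising the diagonal to 1.  Unmixing with the
diagonal-normalised matrix recovers the true signals up to a per-channel
gain, which cancels exactly in $f$ (gain invariance is a tested
invariant).  The correction is applied to profiles *and* to the background
through the same inverse, because mixing happens before background in the
image model.  Förster transfer between the two fluorophores is not
modelled separately: any donor quench that scales one channel is absorbed
into the empirical matrix, which is all the fractional statistic needs.
Mixing biases $f$ toward 0.5 whenever the lipid channel's arc contrast is
milder than the construct channel's; the tests demonstrate both the bias
(10% leakage) and its removal to within ±0.03 of ground truth.

## Population statistics

`summarize_population()` reports n, mean, SD, median and quartiles of $f$,
plus the free energy summarised per-vesicle-then-averaged (the spread of
per-vesicle $\Delta G$ is itself informative; vesicles at the boundary
values 0/1 are excluded from the average and counted).
`compare_populations()` is the two-sided Mann–Whitney rank-sum test via
`stats::wilcox.test`: exact enumeration when the smaller sample has ≤ 8
observations and no ties, tie-corrected normal approximation otherwise;
an independent enumeration oracle in the test suite checks the exact
branch.  No multiple-testing correction is applied — partitioning studies
report single pairwise contrasts — but `run_analyze()` flags runs with
more than three comparisons.  `radius_independence()` (Spearman) encodes
the expectation that a per-molecule membrane property is independent of
vesicle size, and `density_sweep()` summarises labelling-density series
with a model-free flatness statistic.

## The responsive cargo device

A three-state machine abstracts the ligand-switchable construct: the
fluorescent cargo sits on the Ld-avid sT module (State 1), bridges sT and
dC (State 2), or sits on the Lo-avid dC module (State 3).  Fuel and
antifuel strands acting through toehold-mediated strand displacement drive
Fuel1: 1→2, Antifuel2: 2→3, Fuel2: 3→2, Antifuel1: 2→1; all other
(state, cue) pairs are no-ops, and every state is reachable from every
other within two cues.  Nucleotide-level hybridisation is out of scope —
the DNA domains are abstract transition labels.

Equilibria come from the anchor library: State 1 and State 3 use the
single-module baselines, State 2 either the additive sT+dC sum
(1.1 $k_BT$, f ≈ 0.25) or a supplied measured value (1.0 $k_BT$,
f ≈ 0.269) — configurable, with no claim that the dynamic State 2 must
equal the static construct.  Redistribution is single-exponential,
$f(t) = f_{eq} + (f_0 - f_{eq})e^{-t/\tau}$ with τ = 5 min by default
(equilibration is diffusion-limited at this scale; no rate law is
asserted).  `simulate_protocol()` changes the attractor instantaneously at
cue times while $f$ stays continuous, and an optional additive hysteresis
offset on reverse-path equilibria reproduces the observed incomplete
reversibility without claiming a mechanism.

## Problem sizes and reproducibility

The validation suite and the acceptance script run entirely on generated
data at deliberately modest sizes: populations of 20 vesicles (40 for the
radius-independence check) rendered four per 320 px frame, the scale at
which population means of $f$ are already stable to ±0.01 under default
shot noise.  All randomness flows from explicit integer seeds; rendering,
placement and the pipeline outputs are bit-reproducible for a fixed seed.

## Known limitations

* Circular contours only: deformed or budding vesicles are rejected by the
  quality gate, not fit.
* Exactly two phases: multi-domain vesicles fail contiguity enforcement
  (by design) and are excluded rather than split.
* The cross-talk model is a constant linear mixing matrix; intensity- or
  distance-dependent energy transfer is outside its reach.
* Absolute concentration calibration (counts per fluorophore) is not
  attempted; only the fractional statistic and its free-energy transform
  are reported.
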