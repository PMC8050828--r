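# guvpart

Quantifying how membrane-anchored, fluorescently labelled species —
amphiphilic DNA nanostructures in particular — distribute between the
coexisting liquid-ordered (Lo) and liquid-disordered (Ld) lipid phases of
phase-separated giant unilamellar vesicles (GUVs), starting from two-channel
equatorial confocal micrographs.

It is written for membrane biophysicists and DNA-nanotechnology groups who
image "Janus" GUVs — vesicles whose two lipid phases have coalesced into two
macroscopic domains — with one channel carrying a lipid-phase marker that
enriches the Ld phase and a second channel carrying the label on the
membrane-bound construct.

## The quantities at the core

For each vesicle the pipeline measures the mean construct-channel
intensities over the two membrane arcs, `I_Lo` and `I_Ld`, and reduces them
to the **fractional Lo intensity**

```
f_p,Lo = I_Lo / (I_Lo + I_Ld)
```

Assuming fluorescence is proportional to construct concentration, the
**partitioning free energy** (in units of kBT, natural log) is

```
ΔG_p,Lo = −ln( f_p,Lo / (1 − f_p,Lo) )
```

so `f = 0.5` means no preference (ΔG = 0) and negative ΔG means Lo
preference.  For constructs carrying several hydrophobic anchors
(cholesteryl-TEG `sC`, double-cholesteryl `dC`, tocopherol `sT`), the
additive model predicts

```
ΔG_pred = Σ_i ΔG_i
```

over the individual anchor contributions; the deviation
`ΔG_measured − ΔG_pred` quantifies nonadditive anchor coupling.

The package provides, module by module:

* **Synthetic generator** (`population_params()`, `imaging_params()`,
  `sample_population()`, `render_frame()`, `simulate_frames()`) — two-channel
  equatorial GUV phantoms with known ground truth: Gaussian-profile membrane
  rings split into two arcs, lipid-dye contrast, construct contrast set by
  `exp(−ΔG)`, PSF blur, cross-talk mixing, background and shot noise.
* **Detection** (`detect_vesicles()`, `extract_angular_profile()`) —
  robust-threshold ridge extraction, intensity-weighted sub-pixel circle
  fits, and per-angular-bin intensity profiles along the membrane annulus.
* **Segmentation** (`segment_phases()`) — Otsu-style two-class split of the
  lipid-marker profile with cyclic contiguity enforcement and boundary-bin
  exclusion.
* **Quantification** (`estimate_background()`, `compute_partition()`,
  `estimate_crosstalk()`, `apply_crosstalk_correction()`,
  `quantify_frame()`) — background-corrected per-vesicle records with
  optional linear spectral unmixing.
* **Thermodynamics** (`fraction_to_dG()`, `dG_to_fraction()`,
  `predict_additive()`, `nonadditivity()`, `default_anchor_library()`).
* **Population statistics** (`summarize_population()`,
  `compare_populations()`, `radius_independence()`, `density_sweep()`).
* **Responsive-device dynamics** (`apply_cue()`, `state_equilibrium_f()`,
  `relax_trace()`, `simulate_protocol()`) — the fuel/antifuel-driven
  three-state cargo machine with single-exponential redistribution.
* **Pipeline commands** (`run_simulate()`, `run_quantify()`,
  `run_analyze()`, `run_dynamics()`) over a YAML config, plus a thin CLI at
  `inst/scripts/guvpart-cli.R`.

## Worked example

```r
library(guvpart)

# 20 synthetic vesicles whose construct partitions at ΔG = −1.4 kBT
params <- population_params(n_vesicles = 20, dG_true = -1.4)
sim    <- simulate_frames(params, imaging_params(), seed = 11)

records <- NULL
for (fr in sim$frames) {
  records <- rbind(records, quantify_frame(fr, population_label = "dC+dC")$records)
}

summarize_population(records, "dC+dC")[, c("n", "mean_f", "sd_f", "mean_dG")]
#>    n    mean_f         sd_f   mean_dG
#> 1 20 0.8015981 0.0008986663 -1.396322

fraction_to_dG(mean(records$f_p_Lo))
#> [1] -1.396313
```

The ground truth `f = 1/(1 + exp(−1.4)) = 0.802` is recovered to three
decimals, and converting the mean fraction back through the defining
formula returns the programmed −1.4 kBT.  The same chain with
`dG_true = -0.4` (a single-cholesterol construct) yields a mean f of about
0.6.

For the responsive device:

```r
proto <- data.frame(time_min = c(30, 60, 90, 120),
                    cue = c("Fuel1", "Antifuel2", "Fuel2", "Antifuel1"))
trace <- simulate_protocol(proto, tau = 5)
```

walks the cargo through States 1 → 2 → 3 → 2 → 1, with f relaxing
exponentially (τ = 5 min) between the per-state equilibria.

## Documentation

The methods vignette (`vignettes/guv-partitioning.Rmd`) describes the image
model, the detection/segmentation contracts, the statistical machinery and
the design decisions in detail.
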