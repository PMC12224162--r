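# hilicraman

Chemometric unmixing and quantification for hyphenated
chromatography–Raman data, with a fully ground-truthed synthetic data
generator.

## The problem

Coupling liquid chromatography to Raman detection yields a
two-dimensional spectro-chromatogram: an *m* × *n* matrix **M** whose
rows are wavenumber channels (cm⁻¹) and whose columns are elution times
(min). For sugar analysis by hydrophilic interaction chromatography
(HILIC) the raw matrix is dominated by the sharp Raman bands of the
acetonitrile-rich mobile phase and the broad water background; the
analyte signal is a set of weak bands that appear only while each sugar
elutes. A spatial line-rejection mask may block the strongest solvent
bands before detection, leaving those wavenumber channels unobserved.

`hilicraman` implements the complete analysis chain for such data, for
analytical chemists who want to resolve which compounds elute when and
in what amount:

1. **Preprocessing** — block averaging of raw exposures, cropping to the
   analysis time window, per-column least-squares subtraction of a
   solvent reference spectrum, and explicit bookkeeping of masked
   (never-imputed) channels.
2. **Decomposition** — economy singular value decomposition

   **M** = **U°** **W** **V°**ᵀ

   on the observed channels, rank selection *m₁* from the singular-value
   plot, and *target rotation*: a regular *m₁* × *m₁* matrix **K** with

   **M** ≈ **U°**ₘ₁ **W**ₘ₁ **V°**ₘ₁ᵀ =
   (**U°**ₘ₁ **K**)(**K**⁻¹ **W**ₘ₁ **V°**ₘ₁ᵀ) = **U′** **V′**ᵀ

   whose columns are chosen so the rotated spectral vectors **u′**ⱼ
   match a library of model component spectra (each sugar, the solvents,
   a constant background, the derivative-shaped artifact of a drifting
   solvent band). Because **U°**ₘ₁ has orthonormal columns the
   least-squares fit of each targeted column has the closed form
   **k**ⱼ = **U°**ₘ₁ᵀ **t**ⱼ. The paired temporal vectors **v′**ⱼ are
   then the resolved *elution curves*. Targets whose fit residual shows
   they are absent from the data are screened out (classical target
   testing) rather than fitted to noise.
3. **Quantification** — Gaussian peak fitting (Levenberg–Marquardt, with
   a constant offset) and trapezoidal window integration of elution
   curves; linear calibration with limits of detection and
   quantification defined as LOD = 3·*s*ᵣ/slope and LOQ = 10·*s*ᵣ/slope
   (*s*ᵣ the residual standard error, so LOQ/LOD = 10/3); conversion
   between µg mL⁻¹ and mM; and weight-percent determination of a
   dissolved sample against single-compound standards by peak-area
   ratio, with not-detected flags for analytes below the detection
   limit or below the noise of their resolved curve.
4. **Simulation** — `simulate_hilic_run()` generates synthetic runs with
   known ground truth: per-sugar tailing elution peaks (exponentially
   modified Gaussians), fluctuating solvent levels, a baseline that dips
   during elution, band-shift artifacts, spectral masks and detector
   noise, so that every stage above is verifiable bit-for-bit without
   instrument data.

## Worked example

The bundled demonstration configuration simulates a five-sugar mixture
(fructose, glucose, sucrose, maltose, trehalose; 25 mM each, 1 mL
injected), preprocesses and decomposes it, and quantifies each sugar
against a simulated single-compound standard:

```r
library(hilicraman)
res <- run_pipeline(default_config(), out_dir = "demo_out")
print(res$summary, digits = 4)
#>   analyte center_min  area standard_area injected_mmol wt_percent detected
#> 1     Fru      36.59 617.8          4898       0.02523      9.090     TRUE
#> 2     Glu      39.48 617.5          3967       0.02490      8.973     TRUE
#> 3     Suc      42.88 472.9          1929       0.02451     16.779     TRUE
#> 4     Mal      46.59 565.1          2245       0.02518     17.235     TRUE
#> 5     Tre      48.09 580.8          2210       0.02628     17.995     TRUE
```

The five sugars are recovered in their HILIC elution order, Fru first
(36.6 min) to Tre last (48.1 min). Each `injected_mmol` is within a few
percent of the true 0.025 mmol (25 mM × 1 mL). `wt_percent` expresses
the recovered mass against the configured sample dilution (here 1 g in
20 mL with 1 mL injected, so 50 mg of sample on column — meaningful for
a real dissolved sample rather than this equimolar demo). Disaccharides
show roughly twice the weight-percent of the monosaccharides at equal
molarity because of their doubled molecular weight.

```r
print(res$decomposition)
#> decomposition: rank 8, 8 targets, cond(K) = 11.7
#>   target fit residuals:
#>       Fru       Glu       Suc       Mal       Tre       H2O  baseline ACN-shift
#>    0.0166    0.0186    0.0187    0.0179    0.0209    0.0448    0.1330    0.0439
```

Each model spectrum is reproduced by the rotated factors to within a few
percent. The acetonitrile target was screened out automatically: after
solvent subtraction (and with its main bands masked) too little of it
remains in the data to rotate onto.

All stage outputs (`svs.tsv`, `uprime.tsv`, `vprime.tsv`, `K.tsv`,
`residuals.yaml`, `summary.tsv`, `truth.yaml`) are written to
`out_dir` as plain delimited text.

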