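# mimicspec

Avian visual modelling and statistics for testing **adult plumage
aggressive mimicry** — the hypothesis that a brood-parasitic bird's females
evade host aggression by resembling a harmless, abundant model species.

The package is written for researchers in visual ecology and brood-parasite
coevolution. It provides, as tested reusable components:

- **Receptor-noise-limited discrimination.** Cone quantum catches from
  reflectance spectra or calibrated photographs (von Kries normalized,
  trapezoid quadrature on a 1-nm grid), and chromatic JNDs
  *ΔS* = √[ Σ_{i<j} (Π_{k≠i,j} e_k)² (Δf_i − Δf_j)² / Σ_i (Π_{k≠i} e_k)² ]
  with Δf_i = ln(q_i^a/q_i^b), for di- to tetrachromatic receiver models
  (UVS and VS variants included), plus achromatic JNDs |ln(q_a/q_b)|/e_D.
- **Camera-to-cone mapping.** The standard degree-2 polynomial (all
  interactions) regression from camera channels to cone catches, with
  per-receptor R² reporting.
- **Plumage and eggshell difference statistics.** The modal "abundant
  colour" of a patch (most neighbours within 2 JNDs, exhaustive O(n²)
  search under a 2000-pixel budget), the 32-bin luminance-histogram
  distance *L_diff* ∈ [0, 2], and the granularity distance *S_diff*:
  Fourier bandpass energy (SD of band-filtered pixels) at 33 geometric
  spatial scales, differenced in L1.
- **Egg quantification.** Replicate-spectra colour and luminance JNDs
  against the clutch reference, shell pattern via the same granularity
  machinery, volume/shape from outlines by solid of revolution, and
  field-rule classification of rejection outcomes from nest checks.
- **Inference.** Random-intercept linear mixed models (REML via `nlme`)
  and logistic regression with backward elimination at p > 0.05 (focal
  treatment protected) and all pairwise treatment contrasts by
  reference-category rotation.
- **A seeded synthetic-data generator** that emulates the study design
  (8 skins × 9 body regions per taxon; 15 pairs × 4 intruder models;
  rejection arms of 17/16/18 pairs at marginal rates 58.2/62.5/38.9% with
  a 0.29 log-odds effect per JND of egg colour difference), so the whole
  pipeline runs end to end with known ground truth.

## Worked example

Generate a synthetic museum-skin set with the default mimicry structure and
ask whether the focal females sit closer, in the receiver's colour space,
to the model group than to their relatives or conspecific males:

```r
library(mimicspec)

e <- weber_from_abundances(c(SWS = 0.70, MWS = 0.99, LWS = 1.00),
                           list("LWS", 0.05))
round(e, 4)
#>    SWS    MWS    LWS
#> 0.0598 0.0503 0.0500

ss  <- generate_specimens(default_taxa(), seed = 7, grid_dim = 12)
tab <- build_comparison_table(ss$focal, ss$others, e)

round(tapply(tab$colour_jnd, tab$taxon_group, mean), 2)
#> conspecific_male        Euplectes            Vidua
#>             8.20             2.90             3.96
round(tapply(tab$luminance_jnd, tab$taxon_group, mean), 2)
#> conspecific_male        Euplectes            Vidua
#>             0.72             0.73             0.78
```

The focal taxon is ~2.9 JND from the model group (barely discriminable
under good light), ~4.0 from its relatives, and ~8.2 from its own males,
while brightness is indistinguishable (< 1 JND) across all groups — the
signature of colour mimicry rather than shared ancestry. The mixed-model
stage turns the pair-level table into tested contrasts:

```r
res <- run_study_models(plumage_table = tab)
res$plumage$colour$contrasts
#>            level_a   level_b estimate     se statistic         p
#> 1 conspecific_male Euplectes    -5.30 0.0337    -157.2  0.00e+00
#> 2 conspecific_male     Vidua    -4.25 0.0337    -126.0  0.00e+00
#> 3        Euplectes     Vidua     1.05 0.0337      31.2 5.49e-170
```

(Estimates are JND differences between comparison groups; at synthetic
effect sizes the contrasts are extreme.) A single chromatic comparison is
just as direct:

```r
chromatic_jnd(c(0.18, 0.28, 0.38), c(0.20, 0.27, 0.36), e)
#> [1] 2.18213
```

The full pipeline — simulate a bundle of images, masks, spectra and trial
tables, then analyse it — is also available from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/mimicspec.R", package = "mimicspec"))')" \
  all --config config.yaml
```

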