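---
title: "Quantifying adult plumage mimicry: visual models, pattern metrics and inference"
author: "mimicspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adult plumage mimicry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicspec)
```

## The scientific question

A brood-parasitic finch whose females closely resemble the harmless,
abundant weaver females they forage among poses a classic aggressive-mimicry
question: does the resemblance hold up through the *host's* eyes, and does
it change how hosts defend their nests? Answering it takes three coupled
analyses:

1. **Perceptual similarity of museum skins.** How far apart, in units the
   receiver can actually discriminate, are the mimic's plumage colours and
   patterns from (a) its putative models, (b) its closest relatives, and
   (c) its own conspecific males?
2. **Nest defence.** Do breeding hosts treat a mounted female mimic like a
   female model species, and both differently from the males?
3. **Egg rejection.** After seeing a given intruder at the nest, how does
   the probability of rejecting a foreign egg depend on the intruder's
   identity and on how different the egg looks?

`mimicspec` implements all three stages as reusable, tested components, and
ships a seeded synthetic-data generator so the whole pipeline can be run and
validated end to end without access to the original museum photographs or
field data.

## The receptor-noise visual model

All perceptual distances are *just-noticeable differences* (JNDs) under the
receptor-noise-limited model. A stimulus is first reduced to cone quantum
catches
$$q_i = \frac{\int R(\lambda)\, I(\lambda)\, S_i(\lambda)\, d\lambda}
             {\int I(\lambda)\, S_i(\lambda)\, d\lambda},$$
where $R$ is reflectance, $I$ the illuminant and $S_i$ the receptor
sensitivity; the denominator (the catch from a perfect white reflector) is
the von Kries normalization that models chromatic adaptation. Integration is
trapezoid-rule on a 1-nm grid; spectra are linearly interpolated and never
extrapolated.

With log contrasts $\Delta f_i = \ln(q_i^a / q_i^b)$ and Weber fractions
$e_i$, the chromatic distance for any number of receptors is
$$\Delta S =
 \sqrt{\frac{\sum_{i<j}\big(\prod_{k \ne i,j} e_k\big)^2 (\Delta f_i - \Delta f_j)^2}
            {\sum_i \big(\prod_{k \ne i} e_k\big)^2}},$$
which reduces to the familiar trichromatic and tetrachromatic forms and, for
a dichromat, to $|\Delta f_1 - \Delta f_2| / \sqrt{e_1^2 + e_2^2}$. The
distance is symmetric and invariant to scaling either stimulus: intensity is
carried separately by the achromatic channel, where the double-cone JND is
$|\ln(q_a/q_b)|/e_D$.

**Parameter defaults.** Weber fractions follow the square-root-of-abundance
rule $e_i = e_\mathrm{ref}\sqrt{\eta_\mathrm{ref}/\eta_i}$ with the most
abundant cone at 0.05 — the conventional behavioural calibration. Abundance
ratios default to a small-passerine UVS retina (UVS:SWS:MWS:LWS =
0.37:0.70:0.99:1.00) and a violet-sensitive alternative is provided
(`peafowl_vs()`). Skins are analysed trichromatically (SWS, MWS, LWS) because
the source photography restricted colour data to the visible band; eggs are
analysed tetrachromatically from full-range reflectance spectra. Receptor
sensitivities are built from the Govardovskii A1 pigment nomogram at standard
peak wavelengths (371/448/503/563 nm UVS set; 432/477/537/605 nm VS set);
they are serviceable stand-ins, not measurements of any particular retina,
and any set can be replaced from CSV tables via `load_receptor_set()`. The
default illuminant is equal-energy; a daylight table can be supplied. Catches
are floored at $10^{-6}$ before logarithms so dark pixels cannot produce
infinite contrasts while perturbing realistic values negligibly.

Camera images enter the same currency through the standard polynomial
mapping: each cone catch is regressed on the camera-channel catches with all
interaction terms up to degree 2 (configurable), requiring at least three
training spectra per term. The identity case (camera sensitivities equal to
cone sensitivities) recovers an identity mapping, and held-out $R^2$ on
natural-like spectra exceeds 0.95 per receptor in the test suite.

## Plumage difference statistics

Each specimen contributes nine body-region patches (back, beak, belly,
breast, cheek, eyebrow, head, throat, wing), normalized to a 40% grey
standard and reduced to at most 2000 pixels. The reduction is seeded uniform
subsampling *of the pixel multiset*, not geometric resizing, because every
downstream statistic operates on pixel distributions and resizing would blur
them; an area-averaging alternative exists behind `method = "resize"`.

- **Abundant colour.** The modal perceived colour: the pixel with the most
  *other* pixels within 2 JNDs of it, found by exhaustive $O(n^2)$ counting
  (at 2000 pixels this is at most $4\times10^6$ JND evaluations, so no
  approximate search is needed). The comparison is strict (`< 2`), and ties
  break to the lowest pixel index so results are deterministic. The
  colour distance between two regions is the chromatic JND between their
  abundant colours.
- **L_diff.** Double-cone catches clipped to [0, 1] are binned at 32 linear
  luminance levels (half-open bins, last closed); counts are normalized to
  proportions so patches of unequal size compare, and the distance is the
  L1 distance between the proportion vectors, bounded by 0 and 2.
- **S_diff.** Granularity analysis: the patch (embedded in its bounding box,
  mean-filled outside the mask to minimize ringing without inventing
  texture) is Fourier transformed and passed through 33 annular bandpass
  filters; the "energy" at scale $s$ is the standard deviation of the
  band-filtered in-mask pixels, with the band passing wavelengths
  $[s/\sqrt2,\ s\sqrt2]$. Scales are a geometric series from 2 px to the
  shorter box dimension — the count is fixed at 33 but the spacing is a
  design choice here, made geometric to match standard granularity
  practice. S_diff is the L1 distance between energy spectra. The DC term
  belongs to no band, so S_diff ignores mean brightness and scales linearly
  with contrast.

For modelling, the pattern measure is log-transformed as
$\log(S_\mathrm{diff} + 10^{-3})$; the offset guards the self-comparison
zero and is small relative to typical values (~0.05–0.5).

## Egg metrics and outcome classification

Egg background colour is the pointwise mean of five replicate reflectance
spectra per egg (replicate CV is reported); the host reference is the mean
clutch catch, and colour/luminance JNDs to the experimental egg use the
tetrachromatic model. Shell pattern reuses the plumage granularity machinery
unchanged. Volume and shape come from the photographed outline: principal
axes are aligned, a width profile is interpolated along the long axis, and
volume is the solid of revolution $\pi \int (w(x)/2)^2\,dx$. Shape is
summarized by elongation (length over maximum width) and asymmetry (offset
of the widest section from mid-length); the pair is collapsed to one "shape
difference" as a standardized Euclidean distance. Rejection outcomes follow
the field rules: one missing egg at any check is a rejection (predators take
whole clutches), an intact incubated clutch at day 3 is an acceptance, an
empty nest is depredation, anything else is unresolved; the last two are
excluded from analysis.

## The inference stage

Plumage similarity, nest defence and egg rejection are analysed exactly as a
field researcher would: Gaussian random-intercept mixed models (fitted by
REML through `nlme`, the package this analysis tradition uses) and a
binomial logit (`stats::glm`). Three choices deserve notice:

- **Term-level tests.** Backward elimination removes, one at a time, the
  removable term with the largest term-level p above 0.05 — marginal F
  tests for mixed models, likelihood-ratio tests for the logit. The focal
  treatment (taxon group or model type) is protected and always reported.
  Both full and final models are returned with the elimination trace.
- **Degrees of freedom.** Mixed-model p-values use `nlme`'s inner-outer df
  allocation, which reproduces the paired t-test exactly on balanced
  within-pair designs (verified in the tests); no Satterthwaite machinery
  is used, and p-values for between-group terms are approximate to the
  same degree they are in standard practice.
- **Coding of covariates.** Egg-difference covariates enter the rejection
  model as absolute differences from the clutch reference, standardized to
  unit variance; pairwise treatment contrasts are read off by refitting
  with each reference level (reparameterization leaves fitted values
  untouched, so the contrasts are exactly antisymmetric and additive).
  Alarm-call counts are modelled as Gaussian responses, matching the
  tradition this analysis follows, not as Poisson counts.
- **Plumage replication.** The similarity models take one row per
  specimen-pair per body region (fixed effect: comparison group; random
  intercept: body region). Averaging specimen pairs before modelling is the
  other defensible reading of "mean difference across species"; pair-level
  rows keep the within-region replication visible to the model.
- A constant response (e.g. a no-response control dataset) cannot support
  estimation; the fit degenerates explicitly to zero contrasts with p = 1
  and a warning rather than an optimizer error.

## What the synthetic generator emulates

The generator's defaults *are* the study conditions:

- **Skins:** 8 specimens per taxon, 9 regions each. Pixel catches scatter
  lognormally (sd 0.05 in log catch) around a specimen locus, which itself
  scatters (sd 0.02) around the taxon-region locus. Taxon loci are placed
  so that locus-to-locus JNDs from the mimic are 2.86 (model group), 3.92
  (relative group) and 8.17 (conspecific male) — the separations the skin
  analysis reports. Luminance jitter (sd 0.034 in log) is calibrated to
  produce mean luminance JNDs near 0.77, i.e. essentially
  indistinguishable brightness across taxa. Texture is band-limited noise
  shaped to a per-taxon peak scale and contrast; the mimic, model and
  conspecific male share a profile while the relative group is
  finer-grained and higher-contrast, so pattern separates only the
  relative group.
- **Eggs:** arms of 17/16/18 pairs with marginal rejection rates 58.2%,
  62.5% and 38.9%; clutches of 3 host eggs plus one experimental egg; 5
  replicate spectra per egg from a polymorphic ground-colour family
  (blue-white to olive); rejection follows
  $\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\alpha_\mathrm{arm} + 0.29\cdot
  \mathrm{colour\ JND}))$ with each $\alpha_\mathrm{arm}$ calibrated by
  root-finding so the *marginal* arm rate equals its target under the
  generator's own JND distribution.
- **Aggression:** 15 pairs × 4 model types, randomized presentation order,
  replicate swapped between trials; negative-binomial alarm counts and
  censored-Gaussian mobbing seconds around per-type means (females ≫
  males), pair-level random intercepts, and zero order/replicate/stage
  effects so the elimination stage has genuine nulls to remove.

A single run seed fans out to per-component child seeds through a stable
counter scheme, so adding a generator never perturbs existing streams and
every table is byte-reproducible.

**What passing tests do and do not show.** The generator produces clean
lognormal colour clouds, stationary textures, and exactly-logistic rejection
decisions. Real museum skins add specimen preparation artefacts, uneven
illumination and UV reflectance outside the camera passband; real eggs add
correlated maculation and measurement geometry effects; real behaviour adds
overdispersion and carry-over. Passing the suite therefore certifies the
*machinery* — formulas, calibration, orderings, error control — not the
biological conclusions, which depend on data the original analysis did not
deposit.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: empty masks, zero-radius abundant-colour
searches, non-positive catches, self-intersecting outlines, increasing egg
counts and separated logits all raise targeted errors or warnings.
Replicate studies in the test suite run at reduced sizes chosen for tight
feedback loops without changing any scientific default: specimen grids of
12×12 pixels (144-pixel patches) for the 100-replicate ordering study,
2000 replicate experiments per rejection-rate calibration check, and 2000
null simulations for the type-I error check. The mimicry-ordering study
recovers *model < relative < conspecific male* in well over 95% of
replicates at these sizes; the acceptance script runs the rejection-rate
calibrations at the full 10,000 replicates.

## Known limitations

- Bundled receptor sensitivities are template-based; analyses aiming at a
  specific receiver should load measured tables.
- The shape descriptor pair (elongation, asymmetry) is minimal; curvature-
  based descriptors would discriminate more subtle shape differences.
- Visual acuity and viewing distance are not modelled; pattern energies are
  in image pixels, so cross-study comparisons require a common spatial
  calibration.
- The synthetic camera writes cone-catch-scale images; the camera-to-cone
  mapping is exercised by its own tests rather than by the default
  simulated bundle.
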