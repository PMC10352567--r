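---
title: "Isotope-ratio N-glycome quantitation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-ratio N-glycome quantitation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoratio)
library(dplyr)
```

This vignette explains the science implemented by `glycoratio`, the
assumptions behind each stage, and the design decisions taken where more
than one reasonable convention exists.

## The quantitation model

Every serum sample is spiked with a pooled glycome that was reduced with
sodium borodeuteride. Reduction converts each glycan's reducing-end
aldehyde to an alditol, adding one hydrogen (from workup) and one deuterium:

$$\Delta m = m(\mathrm{H}) + m(\mathrm{D}) = 3.021927\ \mathrm{Da},$$

nominally +3 Da, identical for every composition because the label sits on
the one reducing end all N-glycans share. Each analyte therefore appears as
a *light* peak with a *heavy* internal-standard partner 3.0219 Da above it,
and the readout per glycan is the light/heavy intensity ratio. Because each
glycan carries its own internal standard, ratios are per-glycan absolute
(relative to the fixed pool), not fractions of total spectrum signal — sum
traits are consequently sums of ratios, not percentages.

### Mass arithmetic

Neutral mass is the sum of dehydrated residue masses plus one water;
detection is as the singly sodiated cation, with the electron-corrected Na⁺
mass (22.98922 Da). Linkage-specific sialic-acid derivatization enters as
pure mass arithmetic: ethyl esterification of α2,6-linked carboxyls adds
C₂H₄ (+28.0313 Da) and lactonization of α2,3-linked ones removes H₂O
(−18.0106 Da), applied to both Neu5Ac (symbols E/L) and Neu5Gc (Ge/Gl);
O-acetylation adds C₂H₂O (+42.0106 Da) per `Ac`. Two identities tie the
table together and are enforced by tests: Ge − E = Gl − L = one oxygen
(15.9949 Da), and E − L = Ge − Gl = C₂H₄ + H₂O (46.0419 Da).

Two conventions deserved an explicit choice:

* **Adduct mass.** Published calibrant lists are rarely self-consistent at
  the 0.1–0.5 mDa level across Na⁺ conventions (atomic Na vs electron-
  corrected cation). We use the electron-corrected cation and compare at
  5 ppm, the accuracy scale of externally calibrated reflectron MALDI-TOF.
  All seven shipped calibrants agree within 2 ppm; the two lactone-
  containing ones sit ~1.5–1.9 ppm from the standard lactone arithmetic,
  which is within instrument accuracy but larger than the others — a known
  wrinkle of lactone mass bookkeeping that we document rather than absorb
  into a nonstandard lactone mass.
* **O-acetyl placement.** `Ac` is a composition-level +42.0106 Da
  modification constrained to `Ac ≤ E+L+Ge+Gl`; MS1 cannot localize it to a
  particular sialic acid, so the model does not pretend to.

### Composition-based structure classification

MS1 sees compositions, not topologies, so classification is rule-based on
counts: high mannose (N = 2, H ≥ 5, no fucose or sialic acid), hybrid
(N = 3, H ≥ 5), complex (N ≥ 4, or N = 3 with H ≤ 4), other (paucimannose
etc.). Antennarity is N − 2 for hybrid/complex glycans — bisecting GlcNAc
and antenna isomers are indistinguishable by composition and are knowingly
conflated. Galactose count is `min(max(H − 3, 0), antennae)` for complex
glycans (three core mannoses) and `min(max(H − 5, 0), antennae)` for
hybrids (plus the two untrimmed arm mannoses). "Branched sialic acid"
(a disialylated antenna) is declared when the sialic count exceeds a
positive antenna count.

## Peak processing

* **S/N filter:** peaks with S/N strictly greater than 3 are kept. When
  the acquisition software's S/N is absent from the input, noise is
  estimated as the median intensity of peaks not matching the library
  within 50 ppm, in 300 Da windows — a documented stand-in for a vendor
  quantity, not a claim about the original software.
* **Recalibration:** for each of the seven calibrant glycans the nearest
  peak within 0.3 Da is matched; mass error is regressed on m/z (affine)
  and the fit subtracted. Seven calibrants over 700–3500 m/z justify two
  parameters; higher orders would overfit. Fewer than two matches degrade
  to the identity transform with a recorded warning status. Recalibration
  is idempotent on calibrated data (tested).
* **Pair matching:** nearest peak in ppm within 10 ppm of each library
  light and heavy position. A second candidate within tolerance at
  comparable intensity (within 2×), or one observed peak claimed by two
  library entries, raises an `ambiguous` status — ambiguity is flagged,
  never silently resolved. 10 ppm and 0.3 Da are declared defaults exposed
  in `pipeline_config()`, not protocol constants.
* **Replicate aggregation:** the per-sample value is the arithmetic mean of
  the per-spot *ratios* over ok-status spots (not a ratio of summed
  intensities): ratios are the per-spot-scale-free quantity, and averaging
  them matches triplicate-spot averaging of relative signal intensity.

## Quality control

* **Reproducibility CV filter:** glycans are retained when the sample
  (n−1) CV across a reproducibility set is strictly below 25%. The
  reproducibility set is defined here as repeated spots of a pooled
  reference sample (the simulator emits one with 6 replicate spots); when
  absent, the pipeline falls back to each glycan's median technical CV
  across samples. Counts of identified/retained glycans are data outcomes,
  never hard-coded.
* **Outlier fencing:** single-pass Tukey fences at Q1 − 1.5·IQR and
  Q3 + 1.5·IQR, per glycan within (group × week) strata (sexes pooled,
  configurable), with quantiles by linear interpolation between order
  statistics (position (n−1)p+1, R type 7). Quantile conventions differ
  materially at small n, so the convention is pinned and tested; fewer
  than four values pass through unflagged. Flagged cells are masked, not
  deleted.

## Derived traits

The 18-trait registry is declarative: each trait is a predicate (and, for
weighted traits, weight expressions) over composition counts and structural
features, so alternative formula sets can be swapped without code changes.
Sum traits add ratios over qualifying glycans; the two per-antenna traits
are abundance-weighted,

$$\mathrm{gal/ant} = \frac{\sum_i \mathrm{gal}_i\, q_i}{\sum_i \mathrm{ant}_i\, q_i},$$

over antenna-carrying glycans. Whether per-antenna traits should weight by
abundance or average per-glycan fractions is not decidable from trait names
alone; abundance weighting is pinned because it is the convention that
makes the trait a property of the glycome rather than of the panel, and it
is scale-invariant (tested: multiplying all ratios by a constant leaves
weighted traits unchanged, while sum traits are homogeneous of degree 1).
Partition identities (fucosylation + afucosylation = total retained signal;
sialylation + asialylation likewise) hold exactly by construction and are
asserted on every simulated dataset. Note that under a uniform
multiplicative group effect a weighted trait is unchanged by design — group
differences in per-antenna traits arise only from *differential* per-glycan
effects.

## Group statistics

The comparison is the classical equal-variance unpaired Student's t-test
(Welch available behind a flag), two-sided, per glycan or trait, per time
point and pooled over time points. Pooling treats repeated measures of one
mouse as independent — the convention of a pooled two-group display — and a
per-mouse-mean sensitivity mode is provided for readers who prefer one
value per animal. Stars map raw p-values (\*, \*\*, \*\*\*, \*\*\*\* at
0.05, 0.01, 0.001, 0.0001); no multiple-testing correction is applied to
the headline output, but BH-adjusted p-values are always emitted as an
auxiliary column. The heatmap matrix is log10 of the ratios with
nonpositive or masked cells counted and set missing.

## What the synthetic generator emulates — and what it does not

`simulate_glycome_study()` generates, per mouse × week × glycan, a true
ratio

baseline × CR multiplier × sex-fucosylation offset × time trend ×
log-normal biological noise (× 5 with probability 2% for outliers),

and renders each sample into replicate spots: heavy peaks at unit scale
and light peaks at ratio × heavy, each with log-normal technical noise
scaled so the per-spot *ratio* CV equals `tech_cv`; peak positions get an
affine calibration drift plus Gaussian ppm jitter; ~100 decoy noise peaks
per spectrum sit away from library positions and double as the noise floor
for S/N estimation.

Defaults are the emulated study's conditions where those are stated —
2 groups × 2 sexes, 7 time points (15…60 weeks), 30 mice per group × sex,
triplicate spots, CR decreasing most glycans and increasing the
O-acetylated α2,6-only sialoglycans, females above males on fucosylated
glycans — and realistic synthetic choices where they are not: biological
CV 20%, technical CV 10%, baseline spread sdlog 0.4, CR multipliers drawn
from 0.5–0.9 (down) and 1.2–1.6 (up), sex offset 1.3, outliers 2% at 5×,
drift 0.05 Da + 10 ppm, jitter 3 ppm. Effect *magnitudes* are therefore
synthetic: passing tests show the pipeline recovers what was programmed
under a plausible noise model, not that real serum shows those sizes.

Two rendering choices to note. Jitter is specified in ppm, not Da, because
mass error scales with m/z on a time-of-flight axis; a fixed-Da jitter
would make low-mass glycans unmatchable at a ppm tolerance for reasons
unrelated to the quantitation model. And isotope-envelope bleed of the
light A+3 isotopologue into the heavy monoisotopic peak defaults to 0 —
the quantitation model applies no correction, so the default renders
none — but a positive `bleed` exists to demonstrate the bias
(measured ratio = r/(1 + bleed·r), tested in closed form). The generator
does not synthesize profile-mode spectra, isotope envelopes, or vendor
file formats.

Degenerate settings are exact: with all noise, drift and outliers at zero
the pipeline reproduces the ground-truth ratio table to below 1e−9
relative error, which is the round-trip test anchoring everything else.

## Problem sizes and numerical checks

The test suite validates parameter recovery at 20 mice per group, one time
point, five seeds (estimated CR/AL mean ratio within 3 delta-method
standard errors of the programmed multiplier for ≥95% of glycans);
direction recovery at multipliers 0.7/1.4 with n = 20 per group; and the
t-test's type-I error on 2000 null log-normal units (empirical rate within
[0.040, 0.060] at α = 0.05). These sizes were chosen as the smallest
designs at which the stochastic checks are decisive.

## Known limitations

* Composition-only classification conflates topological isomers; traits
  requiring topology (core vs antenna fucose, bisecting GlcNAc) are out of
  scope.
* Exact compositional isobars exist (e.g. swapping one fucose + Ge for one
  hexose + E); the library reports them as collisions and matching flags
  shared peaks as ambiguous rather than resolving them.
* The pooled analysis treats longitudinal samples as independent; use the
  per-mouse-mean mode when that assumption matters.
* No imputation, batch correction beyond recalibration, or
  isotope-envelope deconvolution.
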