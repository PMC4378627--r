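---
title: "Methods: targeted glycerolipidomics of P-starvation lipid remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted glycerolipidomics of P-starvation lipid remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidremodel)
```

# The analysis problem

Phosphorus starvation remodels plant membranes: phospholipids (PC, PE, PS,
PG) are degraded to salvage phosphate, glycolipids (MGDG, DGDG, SQDG) take
their place, and triacylglycerol accumulates as a carbon store. A targeted
LC-MS lipidomics platform measures this as a *detected-peak matrix* — rows
are aligned peaks with a consensus retention time and m/z, columns are
per-sample intensities — produced upstream by vendor/preprocessing software
(baseline correction, alignment, peak detection are out of scope here).
This package turns such a matrix into class-, acyl-group- and species-level
quantities with statistics, plus three satellite analyses: TAG acyl
composition from all-ion-fragmentation scans, qPCR expression of
lipid-remodeling genes, and P1BS promoter-motif scans.

# The model, step by step

## Masses and the annotation library

Each lipid species is a class plus total acyl carbons : double bonds
("DGDG 36:6"): compounds of a class sharing that pair are *isobaric* and
quantified as one unit. Neutral elemental formulas follow glycerolipid
bookkeeping: glycerol (C3H8O3) plus per-chain C~c~H~2c−2d~O~2~, minus one
water per ester bond, plus a class head-group delta. The deltas are
packaged constants validated once against external mass references
(PC 34:2 → C42H80NO8P, 757.562155 Da). Monoisotopic atomic masses are
packaged to six decimals; all mass comparisons are in ppm, never absolute
Da. Adducts are singly charged; the platform default (positive electrospray
with ammonium acetate buffer) is +NH4 for the neutral and glycolipid
classes and +H for phospholipids, overridable per library entry. The
library format is delimited text; an explicit `theoretical_mz` column wins
over the computed value.

## RT correction and matching

Markers with known reference RTs define a piecewise-linear monotone map
(observed → reference) with constant-offset extrapolation beyond the
terminal markers; marker peaks map exactly. The correction method itself is
a design choice — the transparent piecewise-linear map was chosen because
it is exact at the markers, monotone, and easily inspected; one global map
is applied per matrix because the upstream alignment already produced one
consensus RT per peak (per-sample maps would need per-sample RTs).

A peak matches a library entry when its ppm error is ≤ 10 (tolerance
inclusive, so the printed boundary is meaningful) and its RT deviation is
at most the entry's own tolerance, which must lie in 0.05–0.2 min; entries
outside that window are rejected, not clamped. A peak annotates at most one
species (smallest ppm error, ties by RT deviation, then species name) so
intensity is never double-counted; several peaks may annotate one species,
and isomer collapse sums them. Collapse conserves total matched intensity
exactly.

## TAG composition

In all-ion fragmentation no precursor is isolated, so co-elution is the
only precursor-fragment linkage: a chain c:d is *supported* for an
annotated TAG when some fragment matches the diacyl neutral-loss m/z
(neutral TAG mass − free fatty-acid mass + proton) within 10 ppm and
±0.01 min of the precursor RT. The diacyl ion of the ammoniated precursor
is the standard fragment in NH4-buffered positive mode, which is why that
ion model is fixed. Candidate triples are all multisets from a configurable
chain pool (default: plant-typical 16:0–16:3, 18:0–18:3) whose totals match
the species; triples whose every distinct chain is supported are retained.
When nothing is supported the full candidate set is kept but flagged
unconfirmed, because whether the original procedure required full support
is not decidable from the description — the result type reports both.

## Normalization

Per compound, the coefficient of variation (sd/mean) is computed from raw
intensities; the non-TAG compounds with CV at or below the median CV (ties
included) form the normalizer set; the per-sample factor is the sum of
their intensities, rescaled to mean 1; every compound is divided by its
sample's factor. Sum-rescaled-to-mean-1 was chosen over per-compound
median ratios because it leaves well-behaved data exactly unchanged and
makes fold changes invariant to the rescaling constant. TAGs are always
excluded — they respond too strongly to condition to serve as a baseline.

One subtlety matters in practice: when *most identified lipids* respond to
the condition (exactly the P-starvation situation), a normalizer drawn only
from identified species inherits condition dependence. The pipeline
therefore computes factors from the full detected-peak matrix by default
(`factor_source = "peaks"`), where abundant condition-stable background
compounds anchor the factor; `normalize_intensities()` alone implements the
species-only contract too. Compounds with zero mean are excluded from the
normalizer with a warning.

## Quantification and statistics

Class level = Σ species; acyl-group level = Σ species with the same carbon
number; the hierarchy is exact to 1e−9 by construction. Composition =
100 × group / class total per sample. Fold changes are ratios of group
medians (median bars are the field's display convention; means are
available via `stat = "mean"`). ANOVA is fixed-effects (genotype ×
treatment, organs always analysed separately); pairwise tests are Welch
two-sided *t*-tests without multiplicity correction, matching the plain
*P* < 0.05 convention (Benjamini–Hochberg available via `adjust = "BH"`).
Compact letter displays use insert-and-absorb; the processing order is
descending group mean, but the *invariant* is the contract: two groups
share a letter exactly when their pairwise p ≥ α, and the test suite
verifies that by brute force on every produced lettering.

qPCR expression is 40 − (CT~gene~ − CT~UBQ10~); 40 is the cycle cap, so a
target detected as late as the reference scores 40. Technical replicates
are averaged at the CT level before statistics (the platform's design has
two technical per biological replicate); fold induction is
2^(difference of mean 40−ΔCT).

## Motif scanning

P1BS is the degenerate 8-mer GNATATNC. Scanning is sense-strand only: the
pattern is its own reverse complement, so a second-strand scan is redundant
(the suite asserts hit-count symmetry under reverse complement).
Overlapping hits are all reported; `N` in a subject sequence never matches.
Coordinates are 0-based half-open throughout; the promoter is the 1 kb
upstream of the 5′ UTR (not the start codon). A hit is labeled by the
feature containing its start; boundary-spanning hits carry a flag.

# The synthetic stated world

The generator emulates the study design: 2 organs × {P_replete, P_starved}
× genotypes {WT, phr1, pho2, miR399d_OX} × 6 replicates. Its defaults *are*
the stated conditions, chosen once:

* `intensity_cv = 0.15` — multiplicative log-normal noise per compound and
  sample, a typical LC-MS intensity CV.
* `sample_scale_sd = 0.10` — a per-sample loading factor (log-normal). The
  configuration schema did not originally name such a term, but the
  normalization contract is only exercised meaningfully if some
  between-sample scale variation exists; 10% is a realistic injection/
  extraction spread. This is the variation normalization removes.
* `mz_ppm_sd = 2`, `rt_jitter_sd = 0.01` min — instrument-scale noise.
* `rt_drift_amplitude = 0.1` min — one smooth monotone drift (offset plus
  a long-period sinusoid) applied to consensus RTs, sized so that
  marker-based correction is both necessary (drift reaches the default RT
  tolerance) and sufficient (residual jitter ≪ tolerance).
* 150 decoy peaks, rejected within 20 ppm of every library m/z so they can
  never be annotated at the 10 ppm tolerance; 20 housekeeping compounds
  with a third of the peak noise; 8 RT markers below the lipid mass range.
* Condition effects are planted on class totals and distributed over
  species by per-condition composition weights, so both total-content and
  composition readouts have ground truth. Genotype modifiers scale the
  P-starved level relative to wild type (phr1 root TAG = 0.25).

The planted profile transcribes the reported remodeling outcome: root DGDG
×17, shoot DGDG ×4, SQDG ×10/×8 (shoot/root), TAG ×20/×13, DAG +120%,
shoot PG at 25% of replete, root PG +80%; root DGDG 36:5+36:6 at 68% (+P)
vs 21% (−P) of class; 52-C + 54-C TAG above 80% of class in both
conditions with the 52-C share rising under starvation; NPC4 induction
8.5-fold (shoot) / 2.4-fold (root). Where only a constraint is printed
(e.g. the *sum* of the 36:5 and 36:6 shares) the remaining degrees of
freedom were fixed once: the 63-entry default library spreads each class
over 6–10 species with near-uniform residual weights. That dispersion is
deliberate: the package's recovery calibration requires class folds
recovered within ±10% in ≥95% of seeded repetitions at default noise and
6 replicates, and concentrated single-species classes violate it purely
through median-of-6 sampling noise. With the packaged panel the pooled rate
is ≈99%.

What the generator does **not** emulate: continuous chromatogram profiles,
isotope envelopes, intensity-dependent (shot-noise) variance, correlated
biological replicate effects, missing peaks, or retention-time prediction
from structure. A green recovery test therefore establishes that the
pipeline's arithmetic and selection rules are correct under a realistic
noise magnitude — not that the instrument model is complete.

# Numerical choices and degenerate inputs

* Tolerances are inclusive (≤) everywhere; matching ties break by ppm,
  then RT deviation, then species name, so results are deterministic.
* All randomness flows from one seed; generators restore the caller's RNG
  state. Identical configuration ⇒ byte-identical output.
* Fold denominators must be positive; zero class totals are an error in
  composition; zero-mean compounds are excluded from the normalizer with a
  warning; all-equal responses make ANOVA report p = 1 with a degenerate
  flag instead of failing.
* The recovery estimator (ratio of 6-sample medians) is unbiased but has
  sd ≈ 3–5% per class at default noise; quantities on amplified scales
  (percentage increase, 100·(fold−1)) inherit proportionally larger spread.
  This is honest sampling noise, not bias, and is reported as measured.

# Known limitations

* One adduct per library entry; no isotope-pattern scoring, multiply
  charged species, or negative-mode-specific chemistry.
* TAG sn-positional isomers are not resolved and fragment intensities are
  not used quantitatively.
* Normalization offers the sum-of-stable-compounds factor only; alternative
  factor arithmetics (per-compound median ratio, quantile) are out of
  scope.
* No missing-value imputation and no absolute quantification (the platform
  has no internal standards).
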