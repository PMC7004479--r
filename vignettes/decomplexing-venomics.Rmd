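---
title: "Decomplexing venomics with decomplexR: models, estimators and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomplexing venomics with decomplexR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decomplexR)
```

## The problem

Snake venoms are mixtures of tens of proteins from a modest number of toxin
families (phospholipases A2, serine proteases, metalloproteinases, Kunitz
inhibitors, lectins, ...). A *decomplexing* venomics experiment apportions
the whole venom across those proteins by combining two orthogonal
measurements:

1. **Chromatography.** The crude venom is fractionated by reverse-phase
   HPLC, absorbance is recorded at 215 nm (peptide bonds absorb there, so
   area is roughly proportional to protein mass), and peaks are collected
   manually. The area share $f_i$ of fraction $i$ estimates the proportion
   of total venom protein eluting in that fraction.
2. **Mass spectrometry.** An equal amount of each fraction (not an amount
   proportional to the fraction's size) is digested and run on LC-MS/MS.
   Within fraction $i$, a protein $j$'s *mean spectral intensity*
   (MSI — the mean of its peptide PSM intensities) relative to the
   fraction's total MSI gives its within-fraction proportion $p_{ij}$.

The whole-venom abundance of protein $j$ from fraction $i$ is the
hierarchical product

$$a_{ij} = 100 \cdot f_i \cdot p_{ij} \quad (\% \text{ of total venom protein}),$$

and a toxin family's abundance is the sum of $a_{ij}$ over its member
proteins across all fractions.

**Why hierarchical, not global?** Because digestion uses a fixed protein
mass per fraction, MS intensities carry no information about how large a
fraction is — a protein that owns 90 % of a tiny fraction would swamp a
global MSI normalisation. Only the chromatogram knows the fraction sizes.
The hierarchical estimator also handles fractions that are chromatographically
real but yield no confident identifications: their $f_i$ goes into an
explicit *unidentified* bucket, so abundances plus the bucket always total
100 %. The literal global normalisation remains available as
`globalMsiAbundance()` for comparison; it cannot produce an unidentified
bucket and is not used by the pipeline.

## PSM validation

Identification quality is controlled in two stages, mirroring standard
search-engine practice:

* a fixed cascade with **strict** inequalities — protein score > 20,
  peptide score > 10, scored peak intensity (SPI) > 70 % — so a PSM at
  exactly a threshold is rejected (`FilterThresholds()` holds the
  defaults);
* **target–decoy FDR control** at PSM level on the peptide score. For a
  cutoff $c$, the raw estimate is
  $\widehat{FDR}(c) = \#\{\text{decoys} \ge c\} / \max(1, \#\{\text{targets} \ge c\})$,
  the field-default ratio estimator. Raw curves are not monotone (small
  denominators at high cutoffs), so we smooth with the q-value convention
  $\widetilde{FDR}(c) = \min_{c' \le c} \widehat{FDR}(c')$, which is
  monotone non-increasing in $c$ and guarantees a well-defined *lowest*
  cutoff with $\widetilde{FDR} < 0.01$. Ties at the cutoff are retained
  (deterministic, and consistent with keeping strictness on the cascade
  side). Decoys are removed from the output; the achieved raw ratio at the
  chosen cutoff is reported.

Whether FDR should be estimated before or after the cascade is not
settled; the default is *after* (the cascade is part of the search
engine's acceptance rule, FDR certifies what survives it), and
`filterPsms(order = "fdr_then_cascade")` flips the stages. Degenerate
inputs are defined rather than fatal: no decoys yields an all-zero curve
with a warning and flag; a pure-decoy table makes the bound unattainable
and errors.

## Chromatogram processing

Integration is trapezoidal on the sampled grid with linearly interpolated
window edges, so results do not depend on whether a sample lands exactly
on a boundary. Collection windows are half-open $[start, end)$ in minutes
— an unambiguous assignment for boundary time points — and must be sorted
and non-overlapping. Only *collected* windows enter the normalising
denominator (baseline stretches between peaks are excluded), which is what
makes the collected shares sum to exactly 1. Baseline correction defaults
to the parameter-free `linear_endpoints` (subtract the line through the
first and last points, clip at zero); `rolling_min` (centred rolling
minimum, window 15 min) handles curved baselines. `detectPeaks()` offers
prominence-based automatic windowing (default 5 mAU) for when manual
boundaries are unavailable, placing edges at the minima between retained
peaks; an empty result on a flat trace is valid output, not an error.

## ELISA immunoprofiling

Indirect ELISA readings (A492) are blank-corrected with the plate-wide
blank mean (blanks are modelled per plate, the common layout when each
antivenom occupies one plate), negatives clipped to zero, and summarised
as mean ± SEM ($s/\sqrt{n}$) over replicates — triplicates in the
emulated design. Classification uses the two empirically observed
regimes: below 0.1 is *low*, 0.2–1.5 is *reactive*, and the gap
$[0.1, 0.2)$ is reported as *indeterminate* rather than forcing an
arbitrary sharp threshold through it. Relative immunoreactivity between
two antivenoms is comparator/reference × 100 per fraction; since the
phrase "relative absorbance between two antivenoms" does not say which
is the denominator, the reference antivenom is an explicit, required
argument. Reference means below 0.02 (instrument noise scale) make the
ratio undefined and are flagged instead of reported as blow-ups. Control
antigens are a report, not a gate: `controlCheck()` verifies that
negative controls classify low and positive controls reactive.

## The synthetic generator

`venomTruth()` draws a complete experiment with known ground truth; all
stages are governed by one seed with a documented draw order (truth at
`seed`, chromatogram at `seed + 101`, PSMs at `seed + 202`, ELISA at
`seed + 303`), so the same truth always produces identical files.

Defaults emulate the study conditions the package targets:

* 9 toxin families, Dirichlet($\alpha = 3$) composition (presets
  `"thai-like"` / `"indo-like"` fix the composition to the packaged
  reference proteomes, with the Indonesian preset adding two collected
  but unidentified fractions);
* 12 identified fractions over a 0–190 min gradient, Gaussian peaks
  (width 1.5–2.5 min) with areas proportional to the true shares, linear
  drift plus 0.5 mAU white noise, sampled at 0.1 min;
* on average 3 proteins per family, each assigned to one fraction; any
  fraction falling below ~1 % of total area has proteins moved into it
  from the richest fractions — peaks smaller than that would not be
  collectable — a redistribution of elution that never alters the venom
  composition;
* Poisson(6) peptides per protein, lognormal intensities
  ($\sigma = 0.4$) whose protein-level scale is proportional to the
  protein's within-fraction proportion, then rescaled to an equal total
  intensity per fraction. This encodes the equal-mass digestion
  convention and is exactly why the hierarchical estimator is required:
  the generator makes the assumption explicit and togglable;
* peptide scores N(35, 5) for correct matches and N(15, 5) for decoys,
  with 5 % decoy PSMs and an equal number of spurious target matches
  drawn from the decoy score model — these carry a hidden ground-truth
  label so the *realized* false-discovery proportion of the filter can
  be measured, not just the estimate. SPI is Uniform(60, 100). Protein
  scores for genuinely identified proteins are N(80, 25) truncated at
  25: confident identifications sit well above the cascade's >20 gate,
  so the cascade removes junk rather than decimating true proteins;
* ELISA: saturating response $A_{max} \cdot aff/(aff + K)$ with
  $A_{max} = 1.5$, $K = 0.15$, noise sd 0.03, blank 0.02, triplicates.
  The `"dsmav-like"` antivenom preset has high affinity (0.4–0.9) for
  the later ~70 % of fractions and near-zero for the early,
  low-molecular-weight ones; `"sabu-like"` is near-zero everywhere with
  a strongly recognised control antigen (the heterologous venom the
  antivenom was actually raised against).

What the generator does *not* emulate: real peptide sequences (labels are
placeholders), retention-time structure within a fraction, shared
peptides between homologous proteins, intensity normalisation across
LC-MS runs, and matrix effects in ELISA. Passing tests on synthetic data
therefore demonstrate the correctness of the estimators under the stated
model, not robustness to those real-data complications.

## Validation problem sizes

The test-suite and acceptance checks run the full pipeline at the
generator's default scale (12 fractions, ~20–30 proteins, a few hundred
PSMs) over 20 seeds for the composition-recovery and FDR properties, use
2,000-PSM tables for the labelled false-discovery checks, and verify
chromatographic integration against closed-form Gaussian areas at 0.1-min
sampling. The packaged reference proteomes (47 + 25 proteins) exercise
aggregation, counting and comparison on real published values.

## Numerical conventions and edge cases

* Abundances are carried in percent throughout and rendered with 2
  decimals by `formatAbundance()`; writers emit full precision so files
  round-trip bit-identically.
* Conservation (abundances + unidentified = 100) is enforced at 1e-6 for
  pipeline-computed tables and at 0.5 for transcribed tables, which only
  carry two decimals per row.
* Duplicate rows for one accession within a fraction (they occur in
  real search output) are preserved by the readers; quantification pools
  their peptides by default (`mergeDuplicates = TRUE`), and grouping by
  (accession, name) is available for traceability.
* Sorting ties in family tables break by label; abundance ties in
  protein output break by accession, so outputs are deterministic.
* Unmapped accessions aggregate to `OTHER` with a warning rather than an
  error — spurious identifications surviving FDR control are expected at
  a low rate.
* A collected fraction with a share but no surviving PSMs that was not
  declared unidentified is warned into the unidentified bucket; a
  fraction with PSMs but no share is an error (the chromatogram and PSM
  tables disagree about the experiment).

## Known limitations

Quantification is relative (percent of venom protein), not molar;
proteoform inference is by accession identity only; protein-level FDR,
re-scoring and posterior error probabilities are out of scope, as are
4PL curve fits or EC50 estimation for the ELISA module. The reference
dataset is a transcription of printed, rounded values: family totals
reproduce exactly, but cross-checks against its per-fraction percentages
inherit ~0.02–0.05 rounding discrepancies from the source tables (and
the Indonesian per-fraction list carries an internal inconsistency noted
in `?referenceFractionShares`).
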