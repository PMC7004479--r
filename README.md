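# decomplexR

Decomplexing venomics quantification and antivenom immunoprofiling in R.

`decomplexR` is for venom researchers and proteomics analysts who run the
"decomplexing" workflow: a whole snake venom is fractionated by
reverse-phase HPLC, each fraction is digested and identified by LC-MS/MS,
and the venom's protein-family composition is reconstructed fraction by
fraction. The package turns a chromatogram trace plus per-fraction
peptide-spectrum match (PSM) tables into whole-venom abundances,
family-level comparisons between venoms, and indirect-ELISA
immunoreactivity profiles of antivenoms against the fractions.

## The model

Two orthogonal measurements are combined hierarchically. The chromatogram
(absorbance at 215 nm) gives each collected fraction's share of total
venom protein as its trapezoidal area proportion *f<sub>i</sub>*. Because
an equal protein mass of every fraction is digested, MS intensities only
resolve composition *within* a fraction: protein *j*'s mean spectral
intensity (MSI, the mean of its peptide intensities) over the fraction's
total MSI gives *p<sub>ij</sub>*. The whole-venom abundance is

> a<sub>ij</sub> = 100 · f<sub>i</sub> · p<sub>ij</sub>  (% of total venom protein)

and family abundances are sums of *a<sub>ij</sub>* over member proteins.
Collected fractions without confident identifications contribute their
full *f<sub>i</sub>* to an explicit *unidentified* bucket, so everything
totals 100 %. PSMs are validated with the strict cascade protein score
> 20, peptide score > 10, SPI > 70 %, followed by target–decoy FDR
control (< 1 %) on the peptide score with q-value smoothing of the
decoy/target ratio. ELISA A492 readings are blank-corrected, summarised
as triplicate mean ± SEM, and classified as low (< 0.1), indeterminate
[0.1, 0.2) or reactive (≥ 0.2).

The package also ships a curated reference dataset — the per-protein
abundances of *Daboia siamensis* venoms from Thailand and Indonesia (47
and 25 non-redundant proteins in nine toxin families each) — and a fully
seeded synthetic-experiment generator (`venomTruth()`,
`writeSyntheticExperiment()`) that produces every input file with known
ground truth.

## Worked example

Family composition and two-venom comparison on the reference proteomes:

```r
library(decomplexR)
ref <- referenceProteomes()
head(aggregateFamilies(ref$thailand), 4)
#>    family abundance n_proteins
#> 1    PLA2     37.92          6
#> 2    KSPI     22.38          8
#> 3    SVSP     18.07         10
#> 4 snaclec     10.63         13
compareVenoms(ref$thailand, ref$indonesia)
#> VenomComparison Ds-Thailand vs Ds-Indonesia: 11 families (7 shared, 2/2 unique)
```

PLA2 dominates both venoms (37.92 % vs 48.37 % of total venom protein);
KSPI (22.38 %) and svVEGF are detected only in the Thai venom, LAAO and
disintegrin only in the Indonesian one, which also carries a 16.44 %
unidentified bucket from two fractions that resisted identification.

The same numbers come out of the full pipeline on raw(-format) files.
Here a synthetic Indonesian-like experiment is generated and analysed
end to end:

```r
tr <- venomTruth(preset = "indo-like", seed = 1)
paths <- writeSyntheticExperiment(tr, "experiment/")
res <- runPipeline(list(
  venom_id = "indo-sim",
  trace = paths[["trace"]], boundaries = paths[["boundaries"]],
  psms = paths[["psms"]], family_map = paths[["family_map"]],
  unidentified = c("F6", "F7")))  # the preset's two unidentified fractions
head(res$families, 4)
#>   family abundance n_proteins
#> 1   PLA2 49.262857          2
#> 2   SVSP 22.494022          2
#> 3    DIS  6.382013          3
#> 4   SVMP  2.139520          5
res$filter$achievedFdr   # 0.0070 at peptide-score cutoff 10.72
unidentifiedShare(res$abundance)  # 14.33
```

The estimated composition tracks the generator's ground truth
(`truthComposition(tr)`); the immunoprofiling side
(`summarizePlate()`, `classifyReactivity()`,
`relativeImmunoreactivity()`) works the same way from `elisa.csv`.
`inst/scripts/decomplex.R` wraps the same functions as a shell command
(`run` / `simulate` / `compare` subcommands).

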