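---
title: "Representing and validating SRM quantitation in mzQuantML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing and validating SRM quantitation in mzQuantML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzqsrm)
```

## The representation problem

An SRM experiment quantifies *transitions*: precursor→product ion pairs
selected in Q1 and Q3 of a triple-quadrupole instrument. Each transition's
extracted ion chromatogram (XIC) yields an area (sometimes a height), and
software sums or averages the transitions of a peptide into peptide-level
values, optionally on to proteins. mzQuantML's `Feature` element was
designed for MS1 features, so the SRM dialect splits the two domains: the
precursor keeps the native `rt`, `mz` and `charge` attributes, while the
product ion is described by three controlled-vocabulary parameters —
*local retention time* (minutes), *isolation window target m/z* (Th) and
*charge state* — that every SRM feature must carry. When the software
does not track a separate precursor retention time, the attribute holds
the literal string `"null"`; the package models this as a genuinely
absent optional, never a sentinel number.

Transition measurements live in a `FeatureQuantLayer`, the one layer kind
allowed several column data types. The converter emits four fixed
columns — XIC area, XIC background, peak height, and full width at half
maximum — in that order. The exact four measurement names are this
package's documented dialect choice: the agreed report format carries
those four per-transition measurements, and the internal CV table
(`?cv_term`) assigns each a PSI-MS style accession, matching in the
validator by accession first and exact name second. Peptide- and
protein-level layers (`AssayQuantLayer`, `RatioQuantLayer`) are
single-datatype, one column per assay or ratio.

## Label modes and ratios

The compulsory `AnalysisSummary` declares the technique: the term *SRM
quantitation analysis* plus exactly one of *LC-MS label-free quantitation
analysis* or *MS1 label-based analysis*. In a labeled design each
replicate contributes two assays — its light and heavy channels —
referencing the same raw-files group; that shared group is how
`compute_peptide_ratios()` pairs channels, defining one ratio per
replicate with the light assay as numerator (a `flip` argument reverses
the orientation, which no convention fixes). Label-free documents carry
no RatioList and no RatioQuantLayer at all, and the validator treats a
violation as an error rather than noise.

One `PeptideConsensus` spans both isotope channels, with evidence keyed by
(assay, label); the alternative — duplicating the peptide per label — was
rejected because ratio rows then need two object references per peptide.
Peptide identity is (plain sequence, canonical modification descriptor,
precursor charge): the descriptor is the position-sorted `pos:name` list,
so input order cannot create duplicate consensus objects, and charge is
included because charge states are measured by different transitions.

## Conversion rules

`build_document()` converts a parsed report (`parse_report()`, which
matches headers case-insensitively after stripping spaces, and maps blank
cells and `#N/A` to missing) deterministically:

* identifiers are `<kind>_<ordinal>` in insertion order, so the same
  input always serializes to byte-identical XML;
* one feature per distinct (replicate, peptide, precursor charge,
  fragment ion, product charge, label); duplicate rows are rejected as
  ambiguous rather than silently summed;
* absent areas become 0 in the matrices — dropping them would break the
  matrix-shape rule that every row length equal the column count;
* the report's retention time describes the product trace, so it becomes
  the *local retention time* parameter and the precursor `rt` attribute is
  always `"null"`;
* the peptide layer defaults to summation of XIC areas (the conversion's
  stated behaviour); mean and weighted mean are available, with the
  weighted mean falling back to 0 (plus a recorded warning) when all
  weights in a cell are zero;
* a `DataProcessing` step records the converter and aggregation method.

## Validation

`validate_document()` applies a closed, ordered registry of ten rules.
R1–R2 check the AnalysisSummary terms; R3–R4 the three mandatory product
descriptors on every feature; R5 the matrix shape; R6 reference closure
(every assay→raw-file, layer-row→feature, peptide→feature,
protein→peptide, ratio→assay link must resolve, and a feature may belong
to at most one peptide consensus); R7–R8 the label-mode/ratio contract.
R9 (a peptide layer is expected when features exist) and R10 (a nonzero
peptide cell should be backed by feature evidence in that assay) are
warnings: the dialect does not forbid such files, but they usually
indicate a converter defect. The general CV-mapping machinery of the
other quantitation techniques is deliberately narrowed to R5/R6 — the
only general rules exercisable on SRM files without those techniques'
contexts. Reading is strict about structure (malformed XML, ragged
matrices, missing AnalysisSummary fail `read_mzq()`) but lax about
semantics, so that invalid-but-well-formed files reach the validator and
are reported as findings instead of exceptions.

## Numeric contract

Serialized numbers use fixed-decimal rendering with up to six fractional
digits and no exponent for magnitudes in [1e-4, 1e7), locale-independent
with a `.` separator. Constructors canonicalize stored values onto that
grid, which makes `write` idempotent through `read` with *zero* numeric
tolerance — at the cost that a twelfth significant digit of an aggregated
sum is not representable. Undefined ratios (zero heavy denominator)
serialize as `NaN` and must be treated as missing downstream; matrices
stay rectangular.

## The synthetic-experiment generator

`generate_srm_experiment()` emulates a small targeted panel: random
alphabet-valid peptide sequences, precursor/product m/z uniform in
[300, 1500] Th, one retention time per peptide shared by its transitions,
and per-measurement areas `base_area × label_factor × exp(N(0, σ²))`,
with `label_factor` equal to the true light/heavy ratio in the light
channel. Defaults describe a typical small study: 2 proteins × 2 peptides
× 3 transitions × 3 replicates, labeled with true ratio 2, base area 1e5,
and σ = 0.2 — roughly a 20% coefficient of variation, ordinary for SRM
peak areas. Ground truth (per-assay sums, per-replicate ratios) is
computed by direct summation inside the generator, independent of the
aggregation code it tests. R's default Mersenne-Twister generator seeded
from `spec$seed` makes output byte-reproducible.

The generator does **not** simulate chromatographic peak shapes,
interfering transitions, missing channels, retention-time drift between
replicates, or heteroscedastic detector noise. Tests passing on its
output therefore demonstrate the format, conversion, aggregation and
validation logic — not robustness to the pathologies of real
chromatography, which upstream peak-picking software is expected to
handle.

## Problem sizes and numerical checks

The test corpora use many small random documents (1–2 proteins, 1–3
peptides, 2–4 transitions, 1–3 replicates) rather than few large ones:
breadth of shapes exercises more serializer and validator paths per
second. Round-trip and validator-completeness properties run over 100
such documents; ratio recovery uses 50 seeds at σ = 0.2 with 5
transitions per peptide, where the median peptide ratio is required to
sit within 3σ/√5 of the simulated ratio — a deliberately loose
large-deviation bound, since the median of ratios of correlated
log-normal sums is only asymptotically unbiased.

## Limitations

StudyVariables and their quant layers are accepted on read (retained
verbatim and re-emitted) but never produced. Identification
cross-linking (mzIdentML), small-molecule lists, gzip containers, native
Skyline `.sky` documents, chromatogram traces, interference correction
and cross-run normalization are out of scope. Official XSD validation is
optional and only runs when a schema path is supplied; the package's own
structural checks always run.
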