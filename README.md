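# mzqsrm

Selected reaction monitoring (SRM) is the workhorse of targeted,
quantitative proteomics: a triple-quadrupole instrument monitors
precursor→product ion pairs (*transitions*), and the area of each
transition's extracted ion chromatogram (XIC) is the quantitative signal.
The mzQuantML standard (PSI, version 1.0.1) can represent the output of
SRM processing software — transition-level measurements with both MS1
(precursor) and MS2 (product) metadata, peptide- and protein-level
aggregates, and light/heavy isotope ratios — provided the file follows the
SRM-specific controlled-vocabulary conventions.

`mzqsrm` is an R toolkit for that SRM dialect, aimed at proteomics
informaticians who need to produce, check, or consume such files:

* **Data model** — S3 types mirroring the dialect: `transition_feature`
  (precursor `rt`/`mz`/`charge` attributes; the product ion described by
  the CV terms *local retention time*, *isolation window target m/z* and
  *charge state*), multi-column `feature_quant_layer` matrices,
  `peptide_consensus` objects with per-assay/per-label feature evidence,
  single-datatype assay and ratio layers, and the whole-file
  `srm_document`.
* **XML I/O** — `write_mzq()` / `read_mzq()` serialize to and from
  mzQuantML 1.0.1 with deterministic bytes, a fixed-decimal number
  contract, and the `"null"` convention for an unknown precursor retention
  time. `read(write(d))` reproduces `d` exactly.
* **Skyline-style report import** — `parse_report()` reads the agreed SRM
  report CSV (one row per transition per replicate; label-free files carry
  only `light` in IsotopeLabelType, labeled files `light`/`heavy`);
  `build_document()` applies the conversion rules: one assay per
  (replicate, label), a four-column feature quant layer (XIC area,
  background, height, peak width at half maximum), peptide consensus per
  (modified sequence, charge), sum-of-XIC-area aggregation, and — for
  labeled input only — a RatioList with light/heavy peptide ratios.
* **Quantification** — `aggregate_peptides()` (sum / mean / weighted
  mean over transitions), `compute_peptide_ratios()` (per-replicate
  light:heavy assay ratios, `NaN` on zero denominators),
  `aggregate_proteins()`.
* **Semantic validation** — `validate_document()` applies a closed
  registry of ten rules (R1–R8 errors, R9–R10 warnings): technique terms
  in the AnalysisSummary, the three mandatory product descriptors on every
  feature, matrix-shape and reference-closure rules, and the
  label-free/RatioList contract.
* **Synthetic experiments** — `generate_srm_experiment()` produces
  Skyline-style CSVs with known per-peptide ground truth (expected sums
  and ratios), so every pipeline stage is testable without external data.

## Worked example

```r
library(mzqsrm)

# a labeled 2-protein panel: 4 peptides x 3 transitions x 3 replicates,
# true light/heavy ratio 2, noise-free
exp <- generate_srm_experiment(synth_spec(noise_sigma = 0, seed = 42))
doc <- build_document(parse_report(exp$report_csv))
doc
#> SRM mzQuantML document
#>   label mode:      MS1_LABEL_BASED
#>   raw-file groups: 3
#>   assays:          6
#>   features:        72
#>   peptides:        4
#>   proteins:        2
#>   ratio defs:      3

length(validate_document(doc))        # 0 findings: a valid SRM file
#> [1] 0

doc$ratio_quant_layer$rows[[1]]       # light/heavy ratio per replicate
#> [1] 2 2 2

xml <- write_mzq(doc)
mzq_semantic_equal(read_mzq(xml), doc)
#> [1] TRUE
```

The 72 features are the 4 peptides × 3 transitions × 3 replicates × 2
isotope channels; each replicate's light and heavy channels are distinct
assays, so the three ratio definitions divide each replicate's light assay
by its heavy one, and the noise-free ratios recover the simulated value 2
exactly.

A command-line front end is installed with the package
(`system.file("cli", "mzqsrm.R", package = "mzqsrm")`) with subcommands
`convert`, `validate`, `summarize` and `synth`; exit codes are 0
(success/valid), 1 (usage or I/O error), 2 (validation errors).

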