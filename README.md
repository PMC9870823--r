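# indexclone

Single-cell analysis of clonal T cell expansion joined to flow-cytometric
immune phenotypes. The package is written for the common lymphoma /
tumor-immunology design in which T cells are FACS **index-sorted** into
96-well plates (recording a 13-marker intensity vector per deposited
cell) and then subjected to plate/well-barcoded nested RT-PCR amplicon
sequencing of TCRα, TCRβ and a cytokine/transcription-factor panel. It
answers: *which T cells are clonally expanded, and what phenotype do
expanded cells carry compared with non-expanded cells?*

Core definitions, applied throughout:

* **Clonotype** — cells of one patient with identical TCRαβ CDR3
  amino-acid sequences (default key: β CDR3 plus dominant α CDR3);
  **expanded** ⇔ at least 2 cells share the identity within one lymph
  node. Clones are never merged across patients.
* **Expressed** — a cytokine/transcription factor with strictly more than
  10 reads in that cell.
* **Positive** — marker intensity strictly above its gate (gates fixed,
  or derived as a high quantile of non-T-cell background events).
* **Differentiation** — CD45RA+CCR7+ naive, CD45RA−CCR7+ central memory,
  CD45RA−CCR7− effector memory, CD45RA+CCR7− effector.
* **Comparisons** — per-patient frequencies of positive cells in expanded
  vs non-expanded CD8 cells, Wilcoxon rank-sum test per feature (exact
  enumeration for untied groups of ≤ 10), Bonferroni correction with an
  explicit family size, significance at adjusted p < 0.05.

Because raw patient data for this assay class are typically not
deposited, the package ships a synthetic-cohort generator
(`sim_config()` / `simulate_cohort()`) whose defaults encode the
published regime — 9 patients × ~370 cells, ~50:50 CD4/CD8 sort, median
4 (range 1–18) expanded clones per patient, 89% of expanded clones CD8+,
dominant clones at 1–5% of CD8 cells, CD57 enriched on expanded cells —
with full ground truth for end-to-end validation.

## Worked example

```r
library(indexclone)

cfg   <- sim_config(rng_seed = 1)            # the default stated world
truth <- simulate_cohort(cfg, "run1")        # FASTQ + index CSVs + truth
res   <- run_pipeline("run1")                # demux -> ... -> statistics
print(res)
```

```
Cohort: 3330 cells from 9 patients (median 370 cells/patient)
Expanded clones: 54 (median 5/patient, range 1-14); 93% CD8+
Reads: 542188 total, 542188 assigned (100.0%)
Significant after Bonferroni: CCR7, CD57
```

Reading the output: all 542,188 read pairs decoded to a unique plate/well
(zero sequencing error is the default validation regime); 54 clonotypes
had ≥ 2 cells and so count as expanded, overwhelmingly CD8+; and across
the 13-marker family, expanded CD8 cells differ from non-expanded ones in
CCR7 (fewer CCR7+ cells — expanded cells are shifted away from
naive/central-memory states) and CD57 (enriched, as simulated: 0.5 vs
0.1). Component pieces are available individually: `res$clonotypes`,
`res$clone_stats$per_patient`, `res$comparisons`, `res$summary`, plus
`run_pca()` and `build_heatmap_bundle()` for the phenotype map ordered by
clone.

On a zero-error cohort the recovered clonotype partition equals the
simulated truth exactly (adjusted Rand index 1), and the expression-call
and marker-positivity matrices are identical to ground truth — this is
asserted by the test suite, along with oracle checks of the exact
Wilcoxon enumeration, barcode decoding, and CDR3 translation against
independent brute-force implementations.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates the full default cohort from the given seed, runs the complete
pipeline off the written files (FASTQ, index CSVs, references, barcode
scheme), prints the cohort/demultiplexing/comparison summary above, and
writes the JSON report to `--out`.

## Documentation

The methods vignette (`vignettes/indexclone-methods.Rmd`) describes the
model and its assumptions, every tunable threshold with its default and
rationale, what the synthetic cohort does and does not emulate, and a
documented negative result on the calibration of rank-sum comparisons
when the expanded compartment is small.
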