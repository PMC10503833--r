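# pctrace

Clonal tracing of plasma-cell precursors from paired single-cell
transcriptome and BCR repertoire data.

## The problem

In a T-cell-dependent antibody response, germinal center B cells
differentiate through a transitional plasma-cell (PC) progenitor into
distinct PC states, and some progeny migrate from the spleen to the bone
marrow. Each B-cell clone carries a unique V(D)J rearrangement, so the BCR
acts as a built-in lineage barcode: with 5'-end scRNA-seq plus V(D)J
sequencing, every cell barcode gets both a transcriptomic *genomic state*
and a *clonotype*, and clones can be traced across states, timepoints and
compartments.

`pctrace` is for immunologists and computational biologists running this
coupled analysis. It provides:

- readers for 10x `filtered_contig_annotations.csv` and AIRR Rearrangement
  TSV, MatrixMarket expression triplets, and germline FASTA;
- heavy/light chain resolution per barcode (productive light chain chosen,
  UMI tie-breaks, multi-heavy policies);
- clone calling by exact identity of heavy V/D/J + heavy CDR3 amino acids +
  light V/J;
- antigen-specificity inference from IGHV usage rank lists: NP-specific
  genes are those in the antigen-sorted reference top-25 that are shared by
  both tracked samples' top-50 lists; genes shared by the samples but absent
  from the reference are presumed carrier (KLH)-specific;
- somatic hypermutation quantification against germline V segments and
  detection of a designated high-affinity substitution (the W33L analogue
  of IGHV1-72/Vh186.2), with exact/approximate Wilcoxon group comparisons;
- centroid-correlation label transfer (Pearson r on log2-scaled counts,
  0.7 minimum), expression-matched-background signature scores,
  sorted-subset frequency decomposition, a moderated (empirical Bayes)
  t-test DEG filter (absolute fold > 1.2, BH-adjusted p < 0.05) and a
  chi-square state-frequency test;
- cross-compartment tracing: clone-by-(compartment, state) tables, spanning
  clones, spleen-state x bone-marrow-state span-frequency matrices, and
  chord-diagram adjacency export;
- a synthetic-data generator with complete per-barcode ground truth (clone,
  specificity, state, compartment, exact substitution count, affinity flag)
  that the whole test suite is validated against.

The methods vignette (`vignettes/clonal-tracing.Rmd`) documents the model,
parameter choices and limitations.

## Worked example

```r
library(pctrace)
report <- run_demo("demo_out", seed = 7)
str(report)
```

```
List of 14
 $ seed               : int 7
 $ n_cells            : int 2000
 $ n_clones           : int 150
 $ clone_ari          : num 1
 $ n_called_clones    : int 150
 $ np_precision       : num 1
 $ np_recall          : num 1
 $ n_np_cells         : int 1222
 $ n_klh_cells        : int 778
 $ shm_exact_fraction : num 1
 $ affinity_fraction  : num 0.395
 $ state_accuracy     : num 1
 $ n_spanning_clones  : int 81
 $ progenitor_bm_links: num 0
```

The demo simulates 2,000 cells in 150 clones, writes the fixture bundle
(10x CSV, AIRR TSV, MTX triplet, germline FASTA, truth table), then runs the
pipeline from the files on disk. Reading the report: clone calling
reproduced the generated partition exactly (`clone_ari = 1`, adjusted Rand
index against truth); the planted NP-specific IGHV set was recovered with
perfect precision and recall from the rank-list logic; every cell's
V-segment substitution count matched the generator's record
(`shm_exact_fraction = 1`); 39.5% of V segments carried the designated
high-affinity substitution (the generator plants it in 40% of clones);
centroid label transfer reassigned every cell to its true genomic state; 81
clones span two or more (compartment, state) nodes; and no clone links the
splenic PC-progenitor state to the bone marrow — progenitor progeny reach
the marrow only after transiting the PC states, which is the lineage
structure the generator encodes.

Stages are also exposed as file-based subcommands
(`run_subcommand("clones", config)`, ... — see `?run_subcommand`), with a
thin CLI wrapper in `inst/scripts/pctrace.R`.

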