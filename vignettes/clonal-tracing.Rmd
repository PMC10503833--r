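---
title: "Tracing plasma-cell precursors with paired transcriptome and BCR repertoire data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing plasma-cell precursors with paired transcriptome and BCR repertoire data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pctrace)
```

## The analysis problem

During a T-cell-dependent antibody response (here the classic NP-KLH
hapten-carrier immunization), germinal center (GC) B cells differentiate
through a transitional plasma-cell (PC) progenitor state into distinct PC
clusters, and some of their progeny migrate from the spleen to the bone
marrow, where long-lived plasma cells reside. Because every B-cell clone
carries a unique V(D)J rearrangement, the B-cell receptor (BCR) sequence is
a natural lineage barcode: cells captured in the same 10x channel can be
assigned simultaneously a *genomic state* (from their transcriptome) and a
*clone* (from their paired heavy/light chain rearrangement), and clones can
then be followed across states, timepoints and anatomical compartments.

`pctrace` implements this coupled analysis as composable steps:

1. **I/O and chain resolution** — read 10x `filtered_contig_annotations.csv`
   or AIRR Rearrangement TSV contig tables and resolve each barcode to one
   heavy and one light chain.
2. **Clonotyping** — partition cells into clones by exact identity of
   (heavy V, D, J, heavy CDR3 amino-acid sequence, light V, light J).
3. **Antigen-specificity inference** — rank-list logic over IGHV usage that
   classifies cells as hapten (NP)-specific, carrier (KLH)-specific or
   unassigned.
4. **Somatic hypermutation (SHM)** — per-cell substitution counts against
   germline V references and detection of a designated high-affinity
   substitution (the W33L analogue in IGHV1-72/Vh186.2).
5. **State label transfer** — centroid-correlation classification against a
   reference clustering, plus signature scores, sorted-subset frequency
   decomposition, a moderated-t DEG filter and a chi-square state-frequency
   test.
6. **Clonal tracing** — clone-by-(compartment, state) tables, spanning
   clones, span-frequency matrices and chord-diagram adjacency export.
7. **Synthetic data** — a generator producing paired repertoire + expression
   data with complete ground truth, used to validate every step.

## Chain resolution and the clone definition

A cell is analyzable when it has exactly one productive heavy chain and at
least one light chain. When a barcode carries multiple kappa and/or lambda
rearrangements, the productively rearranged light chain is used for clonal
identity; if several are productive the highest-UMI chain wins, with a
lexicographic tie-break on `v_call` so results never depend on row order.
Barcodes with more than one heavy chain are dropped by default
(`heavy_policy = "drop"`), the conservative reading that treats them as
probable doublets; `heavy_policy = "max_umi"` is available when retaining
them is preferred. Every input contig ends up either paired or excluded
with a counted reason.

Clone membership is *exact string identity* of the six key fields. We
deliberately do not use junction-similarity clustering (Hamming thresholds,
length-normalized distances) common in repertoire tools: the definition
targeted here is identity of rearrangements, including the heavy CDR3 amino
acid sequence. Light-chain CDR3 identity is not part of the default key (the
heavy CDR3 is the discriminating junction); a `strict = TRUE` mode adds it.
V/J gene granularity is configurable; the default is allele-level
(`"IGHV1-72*01"`) since references and callers report alleles.

## Specificity from IGHV rank lists

NP responses are dominated by a small set of characteristic IGHV genes, most
prominently IGHV1-72 (Vh186.2). The inference proceeds from three rank
lists: the top 25 IGHV genes of an antigen-sorted NP-specific reference
sample, and the top 50 genes of each of the two tracked CD138+ samples
(days 21 and 35 post-immunization in the emulated design).

- `np_genes` = reference genes present in both tracked samples' lists;
- `klh_genes` = genes shared by both tracked samples but absent from the
  NP reference (presumed carrier-specific);
- cells are labeled by membership of their heavy V call; the two sets are
  disjoint by construction.

"Prevalent and shared" is operationalized as membership in the truncated
top-N lists — the lists are literally top-N rank plots, and no separate
frequency threshold is imposed. `top_n` is configurable on every list.

## Somatic hypermutation and affinity maturation

`count_v_mutations()` compares gap-padded aligned strings position by
position; positions with a gap (`-`, `.`) or ambiguous base (`N`) in either
string are excluded from numerator and denominator, so the mutation
frequency is substitutions per comparable nucleotide. Counting is at the
nucleotide level over the V segment only — the convention for "SHM rate" —
and is symmetric in its arguments.

The high-affinity substitution is specified per germline gene as a 1-based
residue index plus source and target amino acids (W → L at position 33 for
the Vh186.2 analogue). Only the designated target residue counts: W33F is
not W33L. The index is a plain position into the provided germline protein;
any Kabat/IMGT renumbering must be applied upstream when real references
are used, since numbering schemes are not inferred here.

Group comparisons of mutation frequencies use the two-sided Wilcoxon
rank-sum test, exact when the combined sample is ≤ 20 without ties and a
normal approximation with continuity correction otherwise. The test suite
checks the implementation against exhaustive enumeration of all rank
assignments for every group-size combination up to 6 vs 6.

## State label transfer and expression statistics

`build_centroids()` computes per-state means of log2(1 + library-size
normalized counts) over a marker-gene panel; `classify_cells()` assigns each
query cell the state whose centroid has the highest Pearson correlation with
the cell's log2 marker vector, or `"unassigned"` when the best correlation
falls below `min_correlation = 0.7`. The 0.7 floor excludes low-quality
cells rather than forcing a label; zero-variance cells are unassigned, and
correlation ties break lexicographically by state name.

`signature_score()` controls for per-cell quality and complexity by
subtracting an expression-matched background: genes are binned into
`n_background_bins = 25` bins by dataset-wide mean expression and, for every
signature gene, `background_size_per_gene = 50` genes are drawn (seeded)
from its bin. Scores are meaningful comparatively (between cells or groups),
never as absolute values.

`subset_frequency_decomposition()` corrects the state-frequency vector of a
sorted mixed population for contamination by a pure population:
`max(f_mixed - alpha * f_pure, 0)`, renormalized. `alpha = 1` (the default)
is the literal subtraction of the unmixed subset's proportions, clipped at
zero; `alpha < 1` models partial contamination. On exact mixtures
`f_mixed = (1 - a) f_target + a f_pure` the target is recovered to machine
precision for any `a < 1`.

`differential_expression()` is a two-group moderated t-test: per-gene
variances are shrunk toward a common prior whose scale and degrees of
freedom are estimated by method of moments from the distribution of log
sample variances (the scaled-F hierarchical model), and the posterior
variance is the df-weighted combination. A gene is differentially expressed
when its absolute fold on the *linear* normalized scale exceeds 1.2 and its
Benjamini–Hochberg adjusted p falls below 0.05. Fold on linear means is the
default because the classification step — not the fold — is defined on the
log2 scale; a log2-difference fold is available via `use_log_fold = TRUE`.
The implementation is cross-checked against an independent empirical-Bayes
implementation (limma) in the test suite. State-frequency differences are
assessed with the Pearson chi-square test on the 2 × k contingency table;
states with zero total count are dropped with a warning.

## Clonal tracing across compartments

`build_clone_state_table()` aggregates cell counts per (clone, compartment,
state). A clone *spans* when it touches at least `min_nodes = 2` distinct
(compartment, state) nodes. `span_frequency_matrix()` counts, for each
(spleen state i, bone-marrow state j), the clones with at least one cell in
both — the all-pairs convention, so a clone touching k spleen states and m
marrow states contributes k × m incidences; a dominant-state alternative is
deliberately not the default because no dominant-state rule is part of the
definition being implemented. Rows can be normalized to frequencies, giving
the per-spleen-state distribution of bone-marrow destinations. Chord-diagram
rendering is out of scope; `export_chord_adjacency()` writes the long-format
adjacency (source node, target node, clone, weight) that standard tools
consume.

## What the synthetic generator emulates

The generator (`sim_config()`, `simulate_repertoire()`,
`simulate_expression()`) encodes the statistical structure the analysis
assumes, with full ground truth per barcode: clone, specificity, state,
compartment, timepoint, exact substitution count, affinity flag.

- **Repertoire**: clone heavy V genes drawn from a weight table dominated by
  an IGHV1-72-like gene, with configured NP and KLH gene sets; clone sizes
  from power-law weights (`clone_size_exponent = 1`), every clone ≥ 1 cell;
  PC-cluster clones carry a 3× size weight (`pc_size_boost`), reflecting the
  proliferative expansion of differentiating PCs relative to progenitors.
- **States and compartments** (nine states over spleen and bone marrow):
  each clone has a primary state; spleen cells keep it with probability
  `state_fidelity = 0.95`. PC-cluster clones may seed the bone marrow
  (`bm_seeding_prob`, default 1; per-state rates supported), their marrow
  cells retain the primary state, and their spleen spread is restricted to
  PC states. Progenitor clones spread into PC states within the spleen but
  never seed the marrow; B/GC clones stay put. This encodes the lineage
  structure under test: progenitor progeny appear in spleen PC states but
  not in the bone marrow, and each spleen PC state's marrow progeny
  predominantly reflect that state.
- **SHM**: per-cell substitution counts are Poisson with mean
  `mutation_rate_per_timepoint` (default 3) × timepoint index, applied
  uniformly over the V segment outside the protected affinity codon; SHM
  hotspot targeting is not modeled. Clones acquire the designated
  substitution with probability `affinity_mutation_prob = 0.4`; the codon is
  rewritten to the minimal-Hamming codon of the target residue, and the
  truth records the total Hamming distance, so the targeted rewrite is part
  of `n_v_mutations`.
- **Expression**: gamma-distributed gene abundances, Poisson library sizes
  around `library_size_mean = 2000`, negative-binomial counts
  (`dispersion = 10`); each state's `n_marker_genes_per_state = 20` marker
  genes have their abundance multiplied by `marker_fold = 8` in that state.
  `marker_fold = 1` is the degenerate null with no state structure.
- **CDR3s** are random amino-acid strings anchored C…W; only identity is
  analyzed, not biochemistry. A second, nonproductive decoy light chain is
  emitted with probability 0.1 to exercise the productive-light-chain rule.

Everything is a pure function of (config, germline, seed). What the
generator does **not** emulate: continuous differentiation trajectories,
RNA velocity, doublets and ambient RNA, SHM hotspot bias, insertions or
deletions, allelic inclusion beyond the decoy light chain, batch effects.
Passing the validation suite therefore demonstrates correctness of the
pipeline's logic under the stated model, not robustness to every artifact
of real droplet data. Rates and sizes were chosen for testability at desk
scale: no public accession accompanies the emulated study, so there is no
dataset against which to calibrate clone-size or SHM distributions, and the
suite's problem sizes (2,000 cells / 150 clones for clonotyping, 4,500
cells for label transfer, 2,000 genes × 100 cells per group over 20
replicates for DEG calibration, 20 replicates of 1,200 cells for tracing)
keep full runs in the minutes range on one CPU.

## Numerical and design choices

- Clone ids are stable integers ordered by descending clone size, then
  lexicographically by key — invariant to input row order.
- All rank lists and classifications break ties lexicographically.
- `read_contigs` parses 10x `productive` strings `"True"/"true"` as true and
  anything else (including `"None"`) as false; non-immunoglobulin loci are
  dropped with counted warnings.
- The moderated-t prior df solves `trigamma(d0/2) = var(e) − trigamma(d/2)`
  by Newton iteration; when the moment estimate is non-positive the prior is
  taken as infinite (complete pooling to the common variance).
- The "gamma chain" wording that sometimes appears in descriptions of the
  light-chain rule is treated as lambda: immunoglobulin light chains are
  kappa or lambda, and the rule is applied to both.
- Empty groups in `affinity_maturation_proportions()` report `NA`, never 0.

## A worked end-to-end run

```{r demo, eval = FALSE}
report <- run_demo("demo_out", seed = 1)
str(report)
```

`run_demo()` simulates, writes the fixture bundle, re-reads it from disk,
runs pairing → clonotyping → specificity → SHM → label transfer → tracing,
asserts the recovery invariants (clone ARI of 1, exact SHM recovery, zero
progenitor-to-marrow links) and writes `demo_report.json`. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## Limitations

- Exact-identity clonotyping will split clones whose observed CDR3 differs
  by sequencing error; no error-tolerant clustering is provided.
- Specificity is assigned from heavy V gene usage alone (no CDR3 motif or
  tetramer-binding model), as in the design being implemented.
- Mutation counting requires pre-computed gap-padded alignments (AIRR
  `sequence_alignment` / `germline_alignment`); no aligner is bundled.
- The affinity-site position is a plain index into the supplied germline
  protein; renumbering schemes are the caller's responsibility.
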