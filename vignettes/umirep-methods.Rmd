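---
title: "Methods: models, parameters and design choices in umirep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in umirep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umirep)
```

## Scope and data model

`umirep` processes AIRR-seq runs in which every read carries an inline
sample barcode and a unique molecular identifier (UMI), and evaluates the
resulting clonotype repertoires. A *clonotype* is identified throughout by
the triple (CDR3 amino-acid sequence, V gene segment, J gene segment) —
the standard T-cell definition, where clonally related cells share CDR3
amino-acid sequence and V/J usage. Clonotype tables are consumed in a
MiXCR-style tab-delimited dialect; the column mapping is configuration
(`mixcr_dialect()`), because export header names have changed across
upstream versions. Multi-hit segment fields keep the top-scoring hit only
and are stripped to gene level (`TRBV5-1*00(1200)` becomes `TRBV5-1`):
every downstream statistic operates on gene segments, so allele-level
detail would only fragment the usage vectors.

Frequencies are always recomputed from counts when a repertoire is loaded
or filtered. Stored fractions become stale the moment a cleanup stage
(cell-subset disambiguation, contamination removal) subsets the table, so
trusting them would silently corrupt all frequency-based statistics.
Duplicate clonotype rows are merged by summing counts.

## Demultiplexing and UMI consensus

Barcode patterns use the MIGEC-style alphabet: uppercase `A/C/G/T` are
*seed* positions that must match exactly, lowercase letters are *fuzzy*
positions tolerating mismatches up to a budget (default 1), and `N` marks
UMI capture positions. Patterns are searched near the 5' end of the read
(pattern start within the first 40 nt — barcodes sit next to the adapter,
so a bounded window keeps matching linear). The **earliest matching
offset wins across samples**: a later spurious hit (random UMI bases can
and do contain another sample's 5-nt seed) does not outcompete an anchored
match. Only two samples hitting at the same earliest offset make a read
ambiguous; ambiguous and unmatched reads both go to the undetermined
bucket rather than to a "best-scoring" sample — a deliberately
conservative QC stance.

Reads sharing an exact UMI string form a molecular identifier group
(MIG). No UMI error clustering is attempted — a documented simplification
relative to error-tolerant assemblers; its practical cost is that a UMI
sequencing error splits off a spurious singleton MIG, which the
`min_mig_size` floor (default 2, the common forced over-sequencing
threshold) discards. Consensus is per position over the reads of the
group's modal length: plurality vote, ties broken by summed Phred score,
then by lexicographic base order so results are permutation invariant.
Consensus quality is the summed supporting Phred capped at 93 (the
Phred+33 printable ceiling). With per-base error 1% and five reads per
MIG, a position needs two coincident same-base errors to flip, so
consensus identity exceeds 99% — the test suite checks this empirically
on 1,000 simulated MIGs.

Read-flow accounting enforces conservation at every stage (assigned +
undetermined = raw input) and emits a long-format table (source stage,
target stage, sample, count) ready for Sankey-style display.

## Quality-control stages

**Cell-subset disambiguation.** When paired cell fractions of one donor
(e.g. FACS-sorted CD4+ and CD8+) share clonotypes, sorting errors are the
usual cause. For each shared clonotype the fold change
`max(f_a, f_b) / min(f_a, f_b)` is computed on *frequencies* (robust to
unequal sequencing depth, unlike raw counts). A fold change that does not
exceed the threshold (default 2, boundary inclusive: a ratio of exactly 2
"does not exceed" two-fold) marks the clone ambiguous and removes it from
both fractions; above the threshold the clone is kept only in its
higher-frequency fraction. Removing the minor side entirely is a design
choice aimed at clean cell-fraction output; the per-clone log records
every reassignment. The operation is idempotent — a second pass finds no
shared clones.

**Cross-sample contamination.** UMIs are attached before amplification,
so the same (UMI, V, J) triple in two samples indicates shared material.
Raw UMI collisions alone would false-positive at high depth (the UMI
space saturates), which is why the V/J hits are folded into the key.
Pairwise intersections are reported for any number of samples; exact Venn
region counts only for up to three (beyond that the display becomes
unreadable and pairwise tables carry the same information). Reads whose
triple is shared are flagged for optional removal.

**Undetermined reads.** Reads no sample claims are classified by the
first matching rule in strict order: (1) mapped to a PhiX-prefixed
reference → *PhiX* (Illumina runs are PhiX-spiked, so this dominates real
undetermined files); (2) mean Phred < 30 → *Low quality*; (3) more than
10 `N`s or more than 25% `G` → *Junk* (poly-G is the no-signal artifact
of two-channel chemistry); (4) mapped to a TCR reference with mean
Phred ≥ 30 → *TCR junk*; (5) otherwise *Other*, exported as FASTQ for
external investigation. Rule (4) uses ≥ 30 rather than > 30 so no read
falls into a gap at exactly 30. The composition thresholds are applied as
total counts/fractions (the operational definition the thresholds
themselves imply), not as run lengths. With a custom reference library
the mapped groups collapse into a single *Mapped* group. Group counts
always partition the input. `naive_map()` (shared exact k-mers against a
reference FASTA, k = 21, ≥ 3 shared) is a test fallback so classification
runs without an external aligner; it is not an aligner substitute.

## Repertoire statistics

* **Shannon–Wiener** `H = -Σ p_i ln p_i` in nats; **evenness** `H / ln S`;
  **clonality** `1 - H / ln S`; **inverse Simpson** `1 / Σ p_i²`;
  **Chao1** `S + f1² / (2 f2)` with the bias-corrected
  `S + f1 (f1 - 1) / 2` when no doubletons exist. A single-clone sample is
  defined to have evenness 0. The resampled Shannon mean (multinomial
  downsampling to a common depth, 10 replicates) is re-implemented here
  rather than delegated, so no external tool is required.
* **Rarefaction curves** subsample clone *instances* (count-expanded
  reads) without replacement at sizes `step, 2·step, …, n_scaled`
  (default step 2,500) and count distinct CDR3 amino-acid sequences. The
  common depth `n_scaled` is the run-wide minimum total count, floored at
  150,000 when the minimum falls below it (each curve still capped at its
  own total). Instance-level rarefaction was chosen over clonotype-level
  subsampling because it is the interpretation under which the curve has
  a closed-form hypergeometric expectation — which the tests exploit as
  an independent oracle.
* **Curve fit** `f(x) = a·x / (b + x)`: a two-parameter saturating form
  whose asymptote `a` estimates total richness and half-saturation `b`
  measures how quickly novelty is exhausted. The model family is
  deliberately pluggable — any saturating family fits the observed curve
  shapes; this one has interpretable parameters. Initialization
  `a₀ = max(unique)`, `b₀ = median(size)`; Gauss–Newton (`nls`) with a
  Nelder–Mead fallback, `converged` reported honestly and the best
  iterate always returned. Note `b` is only constrained by curve points
  below ≈ 2·b; when the smallest subsample size is already several times
  `b`, its estimate is noise-sensitive even at 1% measurement noise.
* **Clonotype overlap**: Pearson correlation of log10 frequencies over
  the *intersection* of clonotype keys, reported as R². Log transform and
  intersection mirror the log–log regression plots this statistic feeds;
  both are configurable. Pairs sharing fewer than 3 clonotypes are
  reported missing (`NA`), never 0 — absence of evidence is not evidence
  of dissimilarity.
* **V–J pairing**: clone-frequency mass per (V, J) pair, with the minimal
  descending-mass prefix reaching 98% cumulative coverage retained for
  chord-style display and the top-5 V and J segments labeled.
* **Similarity clustering**: per-sample V and J marginal frequencies over
  the union of observed segments (absent segment → 0 so the matrix is
  rectangular), z-scored within each sample column (constant columns
  become all-zero), then agglomerative clustering (average linkage,
  Euclidean — the common clustermap defaults; both configurable). The
  tree is also exported in Newick form. Because features are usage
  *profiles*, a barcode-swapped sample clusters with its generating donor
  rather than its label — the mechanism by which swaps are caught.

## The synthetic-data generator

The generator is first-class, tested code; every pipeline stage is
validated against its truth labels. It emulates: multi-sample repertoires
with distinct clone-size laws and V/J usage profiles; barcoded, UMI-tagged
reads (barcode layout: 6-nt UMI, fuzzy spacer, 5-nt seed, fuzzy spacer,
6-nt UMI, followed by V context, CDR3 and J context, padded to 150 nt);
iid substitution errors; junk read classes (pseudo-PhiX fragments,
low-quality, poly-G/poly-N, random "other"); planted cross-sample
contamination; and planted sorting ambiguity.

Chosen defaults, and why:

* **Clone sizes**: power law by default (`P(X ≥ x) = x^(-α)`, α = 2) —
  reproduces the heavy skew of real TCRβ repertoires where a top clone
  can hold ~1% of a 10⁵-clonotype repertoire. A log-normal law is
  provided for expanded (e.g. stimulated/sorted) repertoires whose clone
  sizes span decades.
* **CDR3 length**: integer-truncated normal, mean 14.5, sd 1.5, clipped
  to 8–24 — the modal 14/15-mer lengths of human TCRβ. CDR3 nucleotide
  sequences are random non-stop codons flanked by the canonical C…F
  anchors; the amino-acid sequence is the translation.
* **Substitution-only errors**: consensus voting is positionwise, so
  indels would only complicate the truth bookkeeping without exercising
  any additional code path.
* **Pseudo-PhiX**: a deterministic 1 kb synthetic sequence named
  `phiX_synth` stands in for the control genome — classification keys on
  the name prefix only, and shipping no third-party sequence keeps the
  package self-contained. It is labeled synthetic everywhere.
* **Contaminant molecules** emit reads under the same reads-per-molecule
  law as native molecules: contaminating material is amplified and
  sequenced like everything else.
* **Planted fold changes** (sorting ambiguity) are realized on
  *frequencies* via a short fixed-point iteration on counts — planting
  changes totals, which changes frequencies — with bands (ambiguous
  ∈ [1.05, 1.9], dominant ∈ [2.6, 6]) that keep truth recovery exact
  under the boundary-inclusive two-fold rule despite count rounding.

What the generator does **not** emulate: PCR amplification bias, chimeric
reads, UMI errors correlated with quality, indels, and platform-specific
quality profiles. A green test therefore establishes that the algorithms
are correct under the stated error model, not that they are robust to
every artifact of a real instrument run.

## What the acceptance properties do and do not establish

The original quantitative observations this toolkit's design goals derive
from (e.g. replicate overlap R² > 0.75, 100% cross-validated donor
classification) were measured on a non-distributable sequencing dataset,
so validation here is property-based on synthetic worlds. Two of these
deserve explicit framing:

* **Replicate overlap.** R² between technical replicates is governed by
  per-clone sequencing depth: resampling a 10³-clone log-normal
  (expanded, MLR-like) repertoire at depth 10⁵ yields R² ≈ 0.93–0.97,
  while a 5×10³-clone power-law (naive-like) repertoire at the same depth
  yields R² ≈ 0.62–0.75 — the regime real whole-repertoire replicates
  occupy. The acceptance property uses the expanded world; the drop at
  low per-clone depth is expected behavior, not failure.
* **Classifier demonstration.** The bundled CART-style tree
  (`stump_tree`) exists only to demonstrate that the exported feature
  tables separate classes (impurity ties are broken toward the widest
  normalized margin, so a profile-exclusive V segment beats incidental
  splits). Real analyses should feed `ml.csv` / `ml_norm.csv` to a proper
  ML framework.

## Numerical and degenerate-input conventions

* Frequencies sum to 1 within 1e-6 after every normalization; usage
  vectors within 1e-9.
* Consensus ties: plurality → summed Phred → lexicographic base order.
* Top-clonotype ties: count → CDR3 AA → V → J, all lexicographic, for
  deterministic output.
* Identical samples cluster deterministically (zero distances are legal).
* Empty intersections are valid everywhere: disambiguation returns empty
  removal sets, overlap reports `NA`, contamination reports zero counts.
* Curve fitting needs ≥ 3 points; non-convergence returns the best
  iterate flagged `converged = FALSE`.
* All simulation and resampling is seeded; identical seeds give
  byte-identical FASTQ and TSV output.

## Known limitations

* No V(D)J alignment or clonotype assembly from reads: clonotype tables
  are consumed, not produced. The demultiplexer/consensus stage is a
  simplified stand-in for a dedicated UMI assembler (no quality-weighted
  UMI error correction, no overseq-threshold estimation).
* No BAM/CRAM input; SAM is read for mapped/unmapped status and reference
  name only.
* The spreadsheet summary is emitted as a directory of TSV sheets (no
  binary workbook writer is available in the supported environment); the
  information content is identical and the files mirror what a workbook's
  sheets would hold.
* Venn regions are exact only for ≤ 3 samples; larger sets fall back to
  pairwise tables.
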