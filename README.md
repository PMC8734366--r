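# umirep

Processing and quality control of barcoded, UMI-tagged immune repertoire
sequencing data, in R.

## The problem

T-cell receptor (TCR) and immunoglobulin repertoire sequencing reads the
rearranged V(D)J locus — in particular the CDR3 region, whose amino-acid
sequence together with the V and J gene segment calls defines a
*clonotype*. Library protocols for this assay tag each cDNA molecule with
a unique molecular identifier (UMI) and an inline sample barcode before
amplification. Getting from such a run to trustworthy repertoire
statistics requires a chain of steps that are usually scripted by hand:

- demultiplexing reads by inline barcode pattern (seed + fuzzy +
  UMI-capture positions) and grouping them by UMI into molecular
  identifier groups (MIGs) with positionwise consensus calling;
- accounting for every read at every stage (raw → demultiplexed →
  consensus, plus the undetermined bucket);
- classifying undetermined reads (PhiX spike-in, low quality, poly-G/N
  junk, receptor-mapped junk, other);
- disambiguating FACS-sorted cell fractions that share clonotypes
  (frequency fold-change rule, two-fold threshold);
- detecting cross-sample contamination from (UMI, V, J) triples shared
  between samples;
- computing repertoire statistics: CDR3 length spectra, top clonotypes,
  Shannon–Wiener / inverse Simpson / Chao1 / evenness / clonality,
  rarefaction curves with a saturating fit `f(x) = a·x/(b + x)`, pairwise
  clonotype overlap (Pearson R² on log10 frequencies of shared clones),
  V–J pairing usage at 98% coverage, and hierarchical sample similarity
  clustering on standardized V/J usage;
- exporting per-sample feature tables (`ml.csv`, `ml_norm.csv`) for
  machine-learning frameworks.

`umirep` implements this chain as a library plus a single-config pipeline
runner, together with a seeded, truth-labeled synthetic-data generator so
every stage is testable without any external dataset. Clonotype tables
are consumed in a configurable MiXCR-style dialect; the package does not
perform V(D)J alignment itself.

## Worked example

Two technical replicates (multinomial resamples at depth 5×10⁴) of one
simulated donor repertoire — 2,000 clones with log-normal clone sizes:

```r
library(umirep)

base <- simulate_repertoire(repertoire_profile(2000,
  clone_size_law = list(law = "lognormal", mu = 2, sigma = 1.5),
  seed = 1), "donor_BL")
set.seed(2)
resample <- function(id, depth = 5e4) {
  k <- rmultinom(1, depth, base$frequency)[, 1]
  keep <- k > 0
  repertoire_sample(data.frame(count = k[keep], cdr3_nt = base$cdr3_nt[keep],
    cdr3_aa = base$cdr3_aa[keep], v_hit = base$v_hit[keep],
    d_hit = NA_character_, j_hit = base$j_hit[keep]), id)
}
samples <- list(BL_r1 = resample("BL_r1"), BL_r2 = resample("BL_r2"))

diversity_indices(samples$BL_r1, resample_reps = 5, seed = 1)
top_clonotypes(samples$BL_r1, n = 3)
fit_diversity_curve(diversity_curve(samples$BL_r1, step = 2500, seed = 1))
overlap_matrix(samples)
```

This prints (abridged):

```
clonotypes: 1853
shannon: 6.3416          # -sum p_i ln p_i, in nats
clonality: 0.1572        # 1 - H / ln S
inv_simpson: 163.46
chao1: 1974.2
  count frequency          cdr3_aa   v_hit   j_hit
1  2329    0.0466 CHRPSTTFQYRGSERF TRBV4-1 TRBJ2-5
2  1881    0.0376 CRRAVCHRWVMNRHKF  TRBV28 TRBJ1-5
3   830    0.0166     CAQGLQTENVRF TRBV5-1 TRBJ1-1
curve fit: a = 1984, b = 4254, converged = TRUE
replicate overlap R2 = 0.835 (1744 shared clonotypes)
```

Read: the replicate sees 1,853 of the 2,000 clonotypes; the rarefaction
fit's asymptote `a = 1984` estimates the richness the library would reach
at saturating depth (close to the true 2,000, and in the same ballpark as
Chao1); the top clone holds 4.7% of the repertoire, giving the non-zero
clonality; and the two technical replicates correlate strongly over their
1,744 shared clonotypes. With deeper per-clone sampling the replicate R²
rises above 0.9 (see the methods vignette for why depth per clone governs
this number).

A full FASTQ-level walkthrough (simulate → demultiplex → consensus → QC →
stats → report) is exercised end-to-end in
`tests/testthat/test-pipeline.R`; the pipeline runner is

```r
run_pipeline(list(
  demux = TRUE, stats = TRUE, report = TRUE,
  barcode_file = "barcodes.txt", fastq_dir = "fastq/",
  clonotype_dir = "clonotypes/", output_dir = "out/",
  min_mig_size = 2, seed = 1
))
```

or, from a shell, `Rscript -e 'umirep::umirep_cli()' run --config run.cfg`.
All outputs (read-flow table, consensus FASTQ with `UMI:<seq>:<qual>`
header tokens, per-sheet TSV summary, `ml.csv` / `ml_norm.csv`, Newick
similarity tree) land under the output directory.

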