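# Fixture builders shared across test files. Everything is generated in
# code at test time; no binary fixtures.

# a tiny repertoire from explicit counts (CDR3 AAs unique by construction)
tiny_sample <- function(counts, id = "S", v = NULL, j = NULL) {
  n <- length(counts)
  aa <- vapply(seq_len(n), function(i) {
    paste0("CASS", paste(rep(LETTERS[(i %% 20) + 1], 2), collapse = ""),
      sprintf("%02d", i), "F")
  }, character(1))
  # nt backbone irrelevant for most stats; keep length = 3 * nchar(aa)
  nt <- vapply(aa, function(a) strrep("TGT", nchar(a)), character(1))
  repertoire_sample(data.frame(
    count = counts,
    cdr3_nt = unname(nt), cdr3_aa = aa,
    v_hit = if (is.null(v)) rep("TRBV5-1", n) else v,
    d_hit = NA_character_,
    j_hit = if (is.null(j)) rep("TRBJ2-7", n) else j,
    stringsAsFactors = FALSE
  ), id)
}

# barcode table for k samples: distinct 5-nt seed barcodes, 6-nt UMI on
# each side of the seed, one fuzzy t on each flank (Table-1-style layout)
make_specs <- function(ids, seeds = NULL) {
  k <- length(ids)
  if (is.null(seeds)) {
    pool <- c("CAGAT", "TTGCA", "GACCT", "ACGTC", "TGATG", "CCATA")
    seeds <- pool[seq_len(k)]
  }
  df <- data.frame(
    sample_id = ids,
    master_pattern = paste0("NNNNNNt", seeds, "tNNNNNN"),
    secondary_pattern = NA_character_,
    fastq1 = paste0(ids, "_R1.fastq.gz"),
    fastq2 = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(df, class = c("barcode_table", "data.frame"))
}

write_mixcr_fixture <- function(path, counts, aa, v, j,
                                nt = NULL, d = NULL) {
  if (is.null(nt)) nt <- vapply(aa, function(a) strrep("TGT", nchar(a)), character(1))
  if (is.null(d)) d <- rep("", length(counts))
  frac <- if (is.numeric(counts)) counts / sum(counts) else 0
  df <- data.frame(
    cloneCount = counts, cloneFraction = frac,
    nSeqCDR3 = unname(nt), aaSeqCDR3 = aa,
    allVHitsWithScore = v, allDHitsWithScore = d, allJHitsWithScore = j,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# build a read table directly
make_reads <- function(seqs, quals = NULL, ids = NULL, umi = NULL) {
  n <- length(seqs)
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (is.null(ids)) ids <- sprintf("r%03d", seq_len(n))
  df <- data.frame(
    read_id = ids, sequence = seqs, quality = quals,
    stringsAsFactors = FALSE
  )
  df$umi <- if (is.null(umi)) rep(NA_character_, n) else umi
  df
}

# error-tolerant (v, j) lookup for a read: clone whose CDR3 nt shares the
# most exact 12-mers with the read (emulates what an aligner-based
# clonotype assignment provides); NA when nothing shares any k-mer
lookup_vj <- function(seqs, clones, k = 12L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  clone_kmers <- lapply(clones$cdr3_nt, kmers)
  idx <- vapply(seqs, function(s) {
    km <- kmers(s)
    hits <- vapply(clone_kmers, function(ck) sum(ck %in% km), numeric(1))
    if (max(hits) == 0) NA_integer_ else which.max(hits)
  }, integer(1), USE.NAMES = FALSE)
  data.frame(
    v_hit = clones$v_hit[idx], j_hit = clones$j_hit[idx],
    stringsAsFactors = FALSE
  )
}

# read-level (umi, v, j) triples for one demultiplexed sample
read_triples <- function(reads, clones) {
  vj <- lookup_vj(reads$sequence, clones)
  ok <- !is.na(vj$v_hit)
  data.frame(
    read_id = reads$read_id[ok], umi = reads$umi[ok],
    v_hit = vj$v_hit[ok], j_hit = vj$j_hit[ok], stringsAsFactors = FALSE
  )
}
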