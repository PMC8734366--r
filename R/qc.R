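#' Mean Phred quality of a read
#'
#' @param qualities integer vector of Phred scores (or a single Phred+33
#'   quality string, which is converted first).
#' @return arithmetic mean.
#' @export
mean_phred <- function(qualities) {
  if (is.character(qualities)) {
    stopifnot(length(qualities) == 1L)
    qualities <- phred_ints(qualities)[[1L]]
  }
  if (length(qualities) == 0L) stop("empty quality vector")
  mean(qualities)
}

#' Disambiguate FACS-sorted cell subsets by frequency fold change
#'
#' Sorting errors leave clonotypes shared between the paired cell fractions
#' (e.g. CD4+ and CD8+ of one donor). For every clonotype key present in
#' both samples, the fold change `max(fa, fb) / min(fa, fb)` is computed on
#' frequencies. Clones that do not exceed the two-fold threshold are
#' considered ambiguously assigned and removed from both samples; clones
#' exceeding it are retained only in the higher-frequency sample and removed
#' from the other. Frequencies are renormalized afterwards. The boundary is
#' inclusive: a fold change of exactly 2 "does not exceed" two-fold and is
#' ambiguous. The operation is idempotent.
#'
#' @param sample_a,sample_b [repertoire_sample()] objects.
#' @param fold_threshold fold-change threshold (> 1, default 2).
#' @return list of class `facs_correction` with `cleaned_a`, `cleaned_b`,
#'   `removed_ambiguous` (keys), `reassigned` (data.frame key, winner),
#'   `fold_threshold` and `scatter` (plot-ready log10 fa vs log10 fb with a
#'   class label per shared clone).
#' @export
facs_correct <- function(sample_a, sample_b, fold_threshold = 2) {
  stopifnot(fold_threshold > 1)
  ka <- clonotype_key(sample_a)
  kb <- clonotype_key(sample_b)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka)
  ib <- match(shared, kb)
  fa <- sample_a$frequency[ia]
  fb <- sample_b$frequency[ib]
  fold <- pmax(fa, fb) / pmin(fa, fb)
  ambiguous <- shared[fold <= fold_threshold]
  a_wins <- fold > fold_threshold & fa > fb
  b_wins <- fold > fold_threshold & fb > fa
  win <- a_wins | b_wins
  reassigned <- data.frame(
    key = shared[win],
    winner = ifelse(a_wins[win], sample_id(sample_a), sample_id(sample_b)),
    stringsAsFactors = FALSE
  )
  drop_a <- c(ambiguous, shared[b_wins])
  drop_b <- c(ambiguous, shared[a_wins])
  cleaned_a <- if (length(drop_a) > 0L) {
    resample_from_rows(sample_a, !ka %in% drop_a)
  } else {
    sample_a
  }
  cleaned_b <- if (length(drop_b) > 0L) {
    resample_from_rows(sample_b, !kb %in% drop_b)
  } else {
    sample_b
  }
  scatter <- data.frame(
    key = shared, log10_freq_a = log10(fa), log10_freq_b = log10(fb),
    class = ifelse(fold <= fold_threshold, "ambiguous",
      ifelse(fa > fb, sample_id(sample_a), sample_id(sample_b))),
    stringsAsFactors = FALSE
  )
  structure(list(
    cleaned_a = cleaned_a, cleaned_b = cleaned_b,
    removed_ambiguous = ambiguous, reassigned = reassigned,
    fold_threshold = fold_threshold, scatter = scatter
  ), class = "facs_correction")
}

triple_key <- function(df) paste(df$umi, df$v_hit, df$j_hit, sep = "|")

#' Detect cross-sample contamination from shared UMI x V(D)J triples
#'
#' UMIs are attached before amplification, so a (UMI, V, J) combination
#' observed in two samples indicates material shared during preparation.
#' Each sample contributes the set of its (umi, v_hit, j_hit) triples;
#' pairwise intersections are reported, exact Venn region counts are
#' computed for up to three samples (pairwise tables beyond that), and
#' reads whose triple is shared with another sample are flagged.
#'
#' @param sample_triples named list (one per sample) of data.frames with
#'   columns `umi`, `v_hit`, `j_hit` and optionally `read_id`. MIG-level
#'   triples are accepted directly for table-only input.
#' @return list of class `contamination_report` with `pair_shared` (named
#'   list of shared triple keys per pair), `pair_counts` (data.frame),
#'   `venn_counts` (named vector, `NULL` for > 3 samples) and
#'   `flagged_reads` (named list of read ids per sample).
#' @export
contamination_analysis <- function(sample_triples) {
  ids <- names(sample_triples)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  for (sid in ids) {
    df <- sample_triples[[sid]]
    if (is.null(df$umi) || anyNA(df$umi)) {
      stop("sample '", sid, "' has reads without UMIs; run demultiplexing ",
        "or supply the UMI:<seq> header token")
    }
  }
  sets <- lapply(sample_triples, function(df) unique(triple_key(df)))
  pair_shared <- list()
  pair_counts <- data.frame(
    sample_a = character(), sample_b = character(), shared = integer(),
    stringsAsFactors = FALSE
  )
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq((i + 1L), length(ids))) {
        sh <- intersect(sets[[i]], sets[[j]])
        pair_shared[[paste(ids[i], ids[j], sep = "&")]] <- sh
        pair_counts[nrow(pair_counts) + 1L, ] <-
          list(ids[i], ids[j], length(sh))
      }
    }
  }
  venn <- NULL
  if (length(ids) >= 2L && length(ids) <= 3L) {
    all_triples <- unique(unlist(sets))
    membership <- vapply(sets, function(s) all_triples %in% s,
      logical(length(all_triples)))
    membership <- matrix(membership, ncol = length(ids))
    region <- apply(membership, 1L, function(m) {
      paste(ids[m], collapse = "&")
    })
    venn <- table(region)
    venn <- stats::setNames(as.integer(venn), names(venn))
  }
  shared_any <- lapply(seq_along(ids), function(i) {
    others <- unlist(sets[-i])
    intersect(sets[[i]], others)
  })
  flagged <- stats::setNames(lapply(seq_along(ids), function(i) {
    df <- sample_triples[[i]]
    if (is.null(df$read_id)) return(character(0L))
    df$read_id[triple_key(df) %in% shared_any[[i]]]
  }), ids)
  structure(list(
    pair_shared = pair_shared, pair_counts = pair_counts,
    venn_counts = venn, flagged_reads = flagged
  ), class = "contamination_report")
}

#' Classify undetermined reads into quality groups
#'
#' Reads that could not be assigned to any sample are classified by the
#' first matching rule, in strict order: (1) mapped to a PhiX reference
#' (name prefixed `phiX`) -> `PhiX`; (2) mean Phred below
#' `quality_threshold` -> `Low quality`; (3) more than `n_limit` `N`s or
#' more than `g_fraction_limit` of the bases `G` -> `Junk`; (4) mapped to a
#' TCR reference with mean Phred at or above the threshold -> `TCR junk`;
#' (5) otherwise `Other`. With `custom_library = TRUE` any mapped read goes
#' to a single `Mapped` group instead of PhiX/TCR junk. Group counts always
#' partition the input.
#'
#' @param reads read table ([read_fastq()]).
#' @param alignments data.frame from [read_sam()] or [naive_map()]; reads
#'   without a record are treated as unmapped.
#' @param custom_library collapse mapped groups into `Mapped`.
#' @param quality_threshold mean Phred threshold (default 30).
#' @param n_limit maximum tolerated `N` count (default 10).
#' @param g_fraction_limit maximum tolerated `G` fraction (default 0.25).
#' @return list of class `undetermined_breakdown` with `counts` (named
#'   vector), `groups` (per-read group labels) and `other_reads` (read
#'   table of the `Other` group, for export and external search).
#' @export
classify_undetermined <- function(reads, alignments,
                                  custom_library = FALSE,
                                  quality_threshold = 30,
                                  n_limit = 10L, g_fraction_limit = 0.25) {
  aln <- alignments[alignments$read_id %in% reads$read_id, , drop = FALSE]
  if (anyDuplicated(aln$read_id)) {
    dup <- aln$read_id[duplicated(aln$read_id)]
    conflicting <- vapply(unique(dup), function(id) {
      sub <- aln[aln$read_id == id, ]
      length(unique(paste(sub$is_mapped, sub$reference_name))) > 1L
    }, logical(1L))
    if (any(conflicting)) {
      stop("conflicting alignments for read id(s): ",
        paste(unique(dup)[conflicting], collapse = ", "))
    }
    aln <- aln[!duplicated(aln$read_id), , drop = FALSE]
  }
  idx <- match(reads$read_id, aln$read_id)
  mapped <- !is.na(idx) & aln$is_mapped[idx]
  ref <- ifelse(mapped, aln$reference_name[idx], NA_character_)
  is_phix <- mapped & grepl("^phiX", ref)
  meanq <- vapply(phred_ints(reads$quality), mean, numeric(1L))
  n_count <- nchar(gsub("[^N]", "", reads$sequence))
  g_frac <- nchar(gsub("[^G]", "", reads$sequence)) / nchar(reads$sequence)

  group <- rep("Other", nrow(reads))
  rule_mapped1 <- if (custom_library) mapped else is_phix
  lab_mapped1 <- if (custom_library) "Mapped" else "PhiX"
  group[rule_mapped1] <- lab_mapped1
  todo <- group == "Other"
  group[todo & meanq < quality_threshold] <- "Low quality"
  todo <- group == "Other"
  group[todo & (n_count > n_limit | g_frac > g_fraction_limit)] <- "Junk"
  if (!custom_library) {
    todo <- group == "Other"
    group[todo & mapped & meanq >= quality_threshold] <- "TCR junk"
  }
  levels <- if (custom_library) {
    c("Mapped", "Low quality", "Junk", "Other")
  } else {
    c("PhiX", "Low quality", "Junk", "TCR junk", "Other")
  }
  counts <- stats::setNames(
    as.integer(table(factor(group, levels = levels))), levels)
  stopifnot(sum(counts) == nrow(reads))
  structure(list(
    counts = counts, groups = group,
    other_reads = reads[group == "Other", , drop = FALSE]
  ), class = "undetermined_breakdown")
}

#' Naive exact k-mer read mapper (test fallback)
#'
#' A deliberately simple stand-in so undetermined-read classification can
#' run without an external aligner: a read is considered mapped to the
#' first reference (in file order) with which it shares at least
#' `min_shared` exact k-mers.
#'
#' @param reads read table.
#' @param reference_fasta path to a FASTA of reference sequences.
#' @param k k-mer size (default 21); must not exceed the shortest read.
#' @param min_shared minimum shared k-mers (default 3).
#' @return data.frame in the [read_sam()] layout.
#' @export
naive_map <- function(reads, reference_fasta, k = 21L, min_shared = 3L) {
  refs <- Biostrings::readDNAStringSet(reference_fasta)
  if (length(refs) == 0L) stop("reference FASTA is empty")
  ref_names <- sub("\\s.*$", "", names(refs))
  if (nrow(reads) > 0L && k > min(nchar(reads$sequence))) {
    stop("k = ", k, " exceeds the shortest read length")
  }
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0L))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  ref_kmers <- lapply(as.character(refs), kmers)
  mapped_ref <- vapply(reads$sequence, function(s) {
    km <- kmers(s)
    for (i in seq_along(ref_kmers)) {
      if (sum(km %in% ref_kmers[[i]]) >= min_shared) return(ref_names[i])
    }
    NA_character_
  }, character(1L), USE.NAMES = FALSE)
  data.frame(
    read_id = reads$read_id,
    is_mapped = !is.na(mapped_ref),
    reference_name = mapped_ref,
    stringsAsFactors = FALSE
  )
}
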