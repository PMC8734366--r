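#' Compile a barcode pattern into a positional matcher
#'
#' Uppercase A/C/G/T are seed positions (exact match required), lowercase
#' letters are fuzzy positions (mismatches tolerated up to a budget), and
#' `N` marks UMI capture positions. A master pattern must contain at least
#' one seed position.
#'
#' @param spec one row of a `barcode_table` (or a list with `sample_id`,
#'   `master_pattern`, optional `secondary_pattern`).
#' @return list of class `barcode_matcher`.
#' @export
compile_matcher <- function(spec) {
  compile_one <- function(pattern, require_seed) {
    chars <- strsplit(pattern, "")[[1L]]
    if (any(!chars %in% c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n"))) {
      stop("illegal character in barcode pattern: ", pattern)
    }
    kind <- ifelse(chars == "N", "umi",
      ifelse(chars %in% c("A", "C", "G", "T"), "seed", "fuzzy"))
    if (require_seed && !any(kind == "seed")) {
      stop("barcode pattern has no seed (uppercase) position: ", pattern)
    }
    list(
      length = length(chars),
      seed_pos = which(kind == "seed"), seed_base = toupper(chars[kind == "seed"]),
      fuzzy_pos = which(kind == "fuzzy"), fuzzy_base = toupper(chars[kind == "fuzzy"]),
      umi_pos = which(kind == "umi")
    )
  }
  secondary <- NULL
  if (!is.null(spec$secondary_pattern) && !is.na(spec$secondary_pattern)) {
    secondary <- compile_one(spec$secondary_pattern, require_seed = FALSE)
  }
  structure(
    c(list(sample_id = spec$sample_id), compile_one(spec$master_pattern, TRUE),
      list(secondary = secondary)),
    class = "barcode_matcher"
  )
}

# character matrix of the first `width` nt of each sequence, padded with "?"
seq_matrix <- function(seqs, width) {
  s <- substr(seqs, 1L, width)
  pad <- width - nchar(s)
  s[pad > 0L] <- paste0(s[pad > 0L], strrep("?", pad[pad > 0L]))
  matrix(unlist(strsplit(s, ""), use.names = FALSE), ncol = width, byrow = TRUE)
}

# first matching offset (0-based) of a compiled pattern in each row of M,
# NA where no offset matches; seed must be exact, fuzzy mismatches <= budget
match_offsets <- function(M, m, max_fuzzy, window) {
  n <- nrow(M)
  off <- rep(NA_integer_, n)
  max_off <- max(0L, min(window, ncol(M)) - m$length)
  for (o in 0L:max_off) {
    cand <- which(is.na(off))
    if (length(cand) == 0L) break
    ok <- rep(TRUE, length(cand))
    if (length(m$seed_pos) > 0L) {
      sub <- M[cand, o + m$seed_pos, drop = FALSE]
      mm <- sub != matrix(m$seed_base, nrow = length(cand),
        ncol = length(m$seed_pos), byrow = TRUE)
      ok <- ok & (rowSums(mm) == 0L)
    }
    if (length(m$fuzzy_pos) > 0L) {
      sub <- M[cand, o + m$fuzzy_pos, drop = FALSE]
      mm <- sub != matrix(m$fuzzy_base, nrow = length(cand),
        ncol = length(m$fuzzy_pos), byrow = TRUE)
      ok <- ok & (rowSums(mm) <= max_fuzzy)
    }
    off[cand[ok]] <- o
  }
  off
}

extract_umi <- function(M, off, umi_pos) {
  if (length(umi_pos) == 0L) return(rep("", length(off)))
  vapply(seq_along(off), function(i) {
    paste(M[i, off[i] + umi_pos], collapse = "")
  }, character(1L))
}

#' Demultiplex reads by inline barcode pattern
#'
#' Patterns are searched anchored near the 5' end (pattern start within the
#' first `window` nt; the first matching offset wins). A read is assigned to
#' a sample iff all seed positions match exactly and fuzzy mismatches stay
#' within `max_fuzzy_mismatch`. Reads matching two samples are routed to
#' undetermined as ambiguous — a conservative QC stance — and unmatched
#' reads are undetermined as well, so every read is routed somewhere. UMIs
#' are extracted from the `N` positions; when a mate carries a secondary
#' pattern with `N` positions, its UMI part is concatenated.
#'
#' @param reads read table from [read_fastq()].
#' @param specs `barcode_table` of samples to match.
#' @param max_fuzzy_mismatch fuzzy mismatch budget (default 1).
#' @param window search window from the 5' end in nt (default 40).
#' @return list with `assigned` (named list of read tables with `umi` set),
#'   `undetermined` (read table with a `reason` column) and `counts`
#'   (data.frame sample_id, demultiplexed; plus attribute `raw`).
#' @export
demultiplex <- function(reads, specs, max_fuzzy_mismatch = 1L, window = 40L) {
  stopifnot(nrow(specs) > 0L)
  matchers <- lapply(seq_len(nrow(specs)), function(i) compile_matcher(specs[i, ]))
  n <- nrow(reads)
  if (n == 0L) {
    empty <- reads
    counts <- data.frame(
      sample_id = specs$sample_id, demultiplexed = 0L,
      stringsAsFactors = FALSE
    )
    attr(counts, "raw") <- 0L
    return(list(
      assigned = stats::setNames(
        rep(list(empty), nrow(specs)), specs$sample_id),
      undetermined = cbind(empty, reason = character(0L)),
      counts = counts
    ))
  }
  width <- min(window + max(vapply(matchers, `[[`, integer(1L), "length")),
    max(nchar(reads$sequence)))
  M <- seq_matrix(reads$sequence, width)
  offmat <- vapply(matchers, function(m) {
    match_offsets(M, m, max_fuzzy_mismatch, window)
  }, integer(n))
  offmat <- matrix(offmat, nrow = n)

  has_mate <- !is.null(reads$mate_sequence)
  Mm <- NULL
  mate_off <- matrix(NA_integer_, n, length(matchers))
  if (has_mate) {
    widthm <- min(window + max(vapply(matchers, `[[`, integer(1L), "length")),
      max(nchar(reads$mate_sequence)))
    Mm <- seq_matrix(reads$mate_sequence, widthm)
    for (k in seq_along(matchers)) {
      sec <- matchers[[k]]$secondary
      if (!is.null(sec)) {
        mate_off[, k] <- match_offsets(Mm, sec, max_fuzzy_mismatch, window)
        # secondary barcode present and mate available: it must match too
        offmat[is.na(mate_off[, k]), k] <- NA_integer_
      }
    }
  }

  # first hit wins: the matcher whose pattern starts earliest takes the
  # read; two matchers hitting at the same earliest offset are ambiguous
  matched <- !is.na(offmat)
  nmatch <- rowSums(matched)
  minoff <- suppressWarnings(apply(offmat, 1L, min, na.rm = TRUE))
  at_min <- matched & (offmat == matrix(minoff, n, ncol(offmat)))
  at_min[!matched] <- FALSE
  n_at_min <- rowSums(at_min)
  assigned_idx <- which(nmatch >= 1L & n_at_min == 1L)
  which_matcher <- integer(n)
  which_matcher[assigned_idx] <- max.col(
    at_min[assigned_idx, , drop = FALSE], ties.method = "first")

  assigned <- stats::setNames(vector("list", length(matchers)), specs$sample_id)
  for (k in seq_along(matchers)) {
    rows <- assigned_idx[which_matcher[assigned_idx] == k]
    sub <- reads[rows, , drop = FALSE]
    if (length(rows) > 0L) {
      umi <- extract_umi(M[rows, , drop = FALSE], offmat[rows, k],
        matchers[[k]]$umi_pos)
      sec <- matchers[[k]]$secondary
      if (has_mate && !is.null(sec) && length(sec$umi_pos) > 0L) {
        umi2 <- extract_umi(Mm[rows, , drop = FALSE], mate_off[rows, k],
          sec$umi_pos)
        umi <- paste0(umi, umi2)
      }
      sub$umi <- umi
    } else if (!"umi" %in% names(sub)) {
      sub$umi <- character(0L)
    }
    rownames(sub) <- NULL
    assigned[[k]] <- sub
  }
  und_rows <- which(nmatch == 0L | n_at_min > 1L)
  undetermined <- reads[und_rows, , drop = FALSE]
  undetermined$reason <- ifelse(n_at_min[und_rows] > 1L, "ambiguous", "unmatched")
  rownames(undetermined) <- NULL
  counts <- data.frame(
    sample_id = specs$sample_id,
    demultiplexed = vapply(assigned, nrow, integer(1L)),
    stringsAsFactors = FALSE
  )
  attr(counts, "raw") <- n
  stopifnot(sum(counts$demultiplexed) + nrow(undetermined) == n)
  list(assigned = assigned, undetermined = undetermined, counts = counts)
}

#' Group reads by UMI and build consensus reads
#'
#' Reads are grouped by exact UMI string into molecular identifier groups
#' (MIGs); groups smaller than `min_mig_size` are discarded. The consensus
#' is built over the reads of the group's modal length, per position by
#' plurality vote, ties broken by the highest summed Phred score at that
#' position, then by lexicographic base order. Consensus quality per
#' position is the summed Phred of the supporting base, capped at 93.
#'
#' @param reads read table with a non-`NA` `umi` column (run
#'   [demultiplex()] first).
#' @param min_mig_size minimum reads per MIG (default 2, a common forced
#'   over-sequencing floor; use 1 to keep singletons).
#' @return list with `migs` (list of `list(umi, n_reads, consensus)`),
#'   `consensus` (read table of consensus reads with `umi` set) and
#'   `counts` (`list(input, in_migs, discarded_reads, consensus_reads)`).
#' @export
assemble_migs <- function(reads, min_mig_size = 2L) {
  stopifnot(min_mig_size >= 1L)
  if (is.null(reads$umi) || anyNA(reads$umi)) {
    stop("reads carry no UMI; demultiplex (or set the UMI header token) first")
  }
  groups <- split(seq_len(nrow(reads)), reads$umi)
  keep <- lengths(groups) >= min_mig_size
  bases <- c("A", "C", "G", "N", "T")  # lexicographic tie-break order
  migs <- vector("list", sum(keep))
  gi <- 0L
  for (umi in names(groups)[keep]) {
    idx <- groups[[umi]]
    seqs <- reads$sequence[idx]
    quals <- reads$quality[idx]
    lens <- nchar(seqs)
    tab <- table(lens)
    modal <- as.integer(names(tab)[which.max(tab)])
    sel <- lens == modal
    sm <- matrix(unlist(strsplit(seqs[sel], ""), use.names = FALSE),
      ncol = modal, byrow = TRUE)
    qm <- matrix(unlist(phred_ints(quals[sel]), use.names = FALSE),
      ncol = modal, byrow = TRUE)
    cnt <- vapply(bases, function(b) colSums(sm == b), numeric(modal))
    qs <- vapply(bases, function(b) colSums(qm * (sm == b)), numeric(modal))
    cnt <- matrix(cnt, ncol = length(bases))
    qs <- matrix(qs, ncol = length(bases))
    # plurality, then summed Phred, then base order (which.max picks first)
    score <- cnt * 1e7 + qs
    pick <- max.col(score, ties.method = "first")
    cons_seq <- paste(bases[pick], collapse = "")
    cons_q <- pmin(93, qs[cbind(seq_len(modal), pick)])
    gi <- gi + 1L
    migs[[gi]] <- list(
      umi = umi, n_reads = length(idx),
      consensus = list(
        read_id = paste0("MIG:", umi), sequence = cons_seq,
        quality = phred_string(list(as.integer(round(cons_q))))
      )
    )
  }
  consensus <- if (gi > 0L) {
    data.frame(
      read_id = vapply(migs, function(m) m$consensus$read_id, character(1L)),
      sequence = vapply(migs, function(m) m$consensus$sequence, character(1L)),
      quality = vapply(migs, function(m) m$consensus$quality, character(1L)),
      umi = vapply(migs, `[[`, character(1L), "umi"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      read_id = character(), sequence = character(), quality = character(),
      umi = character(), stringsAsFactors = FALSE
    )
  }
  in_migs <- sum(lengths(groups)[keep])
  list(
    migs = migs, consensus = consensus,
    counts = list(
      input = nrow(reads), in_migs = in_migs,
      discarded_reads = nrow(reads) - in_migs, consensus_reads = gi
    )
  )
}

#' Summarize read flow across pipeline stages
#'
#' Collects per-sample counts at the raw, demultiplexed and consensus stages
#' plus the undetermined bucket, and emits a plot-ready flow table (source
#' stage, target stage, sample, count) for Sankey-style display. Errors if
#' conservation is violated (assigned + undetermined must equal raw input).
#'
#' @param demux result of [demultiplex()].
#' @param mig_results named list (per sample) of [assemble_migs()] results;
#'   may be `NULL` for a demultiplex-only summary.
#' @return list of class `read_flow` with `per_sample` (data.frame
#'   sample_id, raw_reads, demultiplexed_reads, consensus_reads),
#'   `undetermined_reads` and `flow` (long table).
#' @export
read_flow_summary <- function(demux, mig_results = NULL) {
  counts <- demux$counts
  raw <- attr(counts, "raw")
  if (sum(counts$demultiplexed) + nrow(demux$undetermined) != raw) {
    stop("internal: read-flow conservation violated at demultiplex stage")
  }
  cons <- vapply(counts$sample_id, function(sid) {
    if (is.null(mig_results[[sid]])) NA_integer_ else
      as.integer(mig_results[[sid]]$counts$consensus_reads)
  }, integer(1L))
  per_sample <- data.frame(
    sample_id = counts$sample_id,
    raw_reads = raw,
    demultiplexed_reads = counts$demultiplexed,
    consensus_reads = cons,
    stringsAsFactors = FALSE
  )
  flow <- rbind(
    data.frame(
      source = "raw", target = "demultiplexed", sample = counts$sample_id,
      count = counts$demultiplexed, stringsAsFactors = FALSE
    ),
    data.frame(
      source = "raw", target = "undef-m", sample = "undef-m",
      count = nrow(demux$undetermined), stringsAsFactors = FALSE
    ),
    if (!is.null(mig_results)) {
      data.frame(
        source = "demultiplexed", target = "consensus",
        sample = counts$sample_id,
        count = ifelse(is.na(cons), 0L, cons), stringsAsFactors = FALSE
      )
    }
  )
  structure(list(
    per_sample = per_sample,
    undetermined_reads = nrow(demux$undetermined),
    flow = flow
  ), class = "read_flow")
}
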