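#' Default clonotype-table column dialect
#'
#' Maps the logical columns the pipeline needs onto the header names used by
#' common MiXCR-style clonotype exports. Header names changed across MiXCR
#' versions, so the mapping is configuration rather than hard-coded: pass a
#' modified list to [read_clonotype_table()] for other exports.
#'
#' @return named list mapping logical names to header names.
#' @export
mixcr_dialect <- function() {
  list(
    count     = "cloneCount",
    frequency = "cloneFraction",
    cdr3_nt   = "nSeqCDR3",
    cdr3_aa   = "aaSeqCDR3",
    v_hit     = "allVHitsWithScore",
    d_hit     = "allDHitsWithScore",
    j_hit     = "allJHitsWithScore"
  )
}

# "TRBV5-1*00(1200.5),TRBV5-4*00(900)" -> "TRBV5-1": first (top-scoring)
# hit, stripped of allele and score decorations. Downstream statistics all
# operate at gene-segment level.
strip_hit <- function(x) {
  first <- sub(",.*$", "", x)
  first <- sub("\\(.*$", "", first)
  first <- sub("\\*.*$", "", first)
  out <- trimws(first)
  out[!nzchar(out)] <- NA_character_
  out
}

#' Read a clonotype table
#'
#' Reads a tab-delimited clonotype export (MiXCR-style by default), keeps the
#' top-scoring hit of multi-hit segment fields at gene level, merges duplicate
#' (CDR3 AA, V, J) rows by summing counts, and renormalizes frequencies.
#'
#' @param path file path.
#' @param sample_id sample name; defaults to the file name without extension.
#' @param dialect named list as returned by [mixcr_dialect()].
#' @return a [repertoire_sample()].
#' @export
read_clonotype_table <- function(path, sample_id = NULL, dialect = mixcr_dialect()) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(txt|tsv|clonotypes.*)$", "", basename(path))
  }
  tab <- utils::read.delim(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    stringsAsFactors = FALSE, comment.char = "", quote = ""
  )
  required <- c("count", "cdr3_nt", "cdr3_aa", "v_hit", "j_hit")
  for (logical_col in c(required, "frequency", "d_hit")) {
    header <- dialect[[logical_col]]
    if (is.null(header) || is.na(header)) {
      if (logical_col %in% required) {
        stop("dialect does not map required column '", logical_col, "'")
      }
      next
    }
    if (!header %in% names(tab) && logical_col %in% required) {
      stop("clonotype table ", basename(path), " is missing required column '",
        header, "' (logical '", logical_col, "')")
    }
  }
  counts <- tab[[dialect$count]]
  counts_num <- suppressWarnings(as.numeric(counts))
  if (anyNA(counts_num)) {
    bad <- which(is.na(counts_num))[1L]
    stop("non-numeric clone count '", counts[bad], "' in row ", bad,
      " of ", basename(path))
  }
  d_col <- dialect$d_hit
  d <- if (!is.null(d_col) && !is.na(d_col) && d_col %in% names(tab)) {
    strip_hit(as.character(tab[[d_col]]))
  } else {
    rep(NA_character_, nrow(tab))
  }
  repertoire_sample(data.frame(
    count = counts_num,
    cdr3_nt = as.character(tab[[dialect$cdr3_nt]]),
    cdr3_aa = as.character(tab[[dialect$cdr3_aa]]),
    v_hit = strip_hit(as.character(tab[[dialect$v_hit]])),
    d_hit = d,
    j_hit = strip_hit(as.character(tab[[dialect$j_hit]])),
    stringsAsFactors = FALSE
  ), sample_id)
}

#' Write a clonotype table
#'
#' @param sample a [repertoire_sample()].
#' @param path output path (tab-delimited, MiXCR-style header).
#' @param dialect column dialect, see [mixcr_dialect()].
#' @export
write_clonotype_table <- function(sample, path, dialect = mixcr_dialect()) {
  out <- data.frame(
    a = attr(sample, "total_count") * sample$frequency,
    b = sample$frequency,
    c = sample$cdr3_nt,
    d = sample$cdr3_aa,
    e = sample$v_hit,
    f = ifelse(is.na(sample$d_hit), "", sample$d_hit),
    g = sample$j_hit,
    stringsAsFactors = FALSE
  )
  out$a <- sample$count
  names(out) <- unlist(dialect[c("count", "frequency", "cdr3_nt", "cdr3_aa",
    "v_hit", "d_hit", "j_hit")])
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read a barcode table
#'
#' Tab-delimited table in the MIGEC-style dialect: one row per sample with
#' columns sample id, master barcode pattern, additional barcode (may be
#' empty), FASTQ #1 and FASTQ #2 (may be empty). Lines starting with `#` are
#' comments/header. In patterns, uppercase A/C/G/T are exact-match seed
#' positions, lowercase letters are mismatch-tolerant fuzzy positions and `N`
#' marks UMI capture positions.
#'
#' @param path file path.
#' @return data.frame of class `barcode_table` with columns `sample_id`,
#'   `master_pattern`, `secondary_pattern`, `fastq1`, `fastq2`.
#' @export
read_barcode_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- lapply(keep, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      stop("barcode table line ", i, " has fewer than 2 columns")
    }
    length(fields) <- 5L
    fields[is.na(fields) | !nzchar(fields)] <- NA_character_
    fields
  })
  if (length(rows) == 0L) {
    return(structure(
      data.frame(
        sample_id = character(), master_pattern = character(),
        secondary_pattern = character(), fastq1 = character(),
        fastq2 = character(), stringsAsFactors = FALSE
      ),
      class = c("barcode_table", "data.frame")
    ))
  }
  m <- do.call(rbind, rows)
  df <- data.frame(
    sample_id = m[, 1L], master_pattern = m[, 2L],
    secondary_pattern = m[, 3L], fastq1 = m[, 4L], fastq2 = m[, 5L],
    stringsAsFactors = FALSE
  )
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample id(s) in barcode table: ", paste(unique(dup), collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    for (col in c("master_pattern", "secondary_pattern")) {
      pat <- df[[col]][i]
      if (is.na(pat)) next
      if (grepl("[^ACGTNacgtn]", pat)) {
        stop("illegal character in ", col, " for sample '", df$sample_id[i], "': ", pat)
      }
    }
    if (!grepl("[ACGT]", df$master_pattern[i])) {
      stop("master pattern for sample '", df$sample_id[i],
        "' has no seed (uppercase A/C/G/T) position")
    }
  }
  structure(df, class = c("barcode_table", "data.frame"))
}

#' Write a barcode table
#'
#' @param specs a `barcode_table` data.frame (see [read_barcode_table()]).
#' @param path output path.
#' @export
write_barcode_table <- function(specs, path) {
  lines <- c(
    "#SampleID\tMaster barcode sequence\tAdditional barcode sequence\tFASTQ #1\tFASTQ #2",
    vapply(seq_len(nrow(specs)), function(i) {
      f <- unlist(specs[i, c(
        "sample_id", "master_pattern", "secondary_pattern",
        "fastq1", "fastq2"
      )])
      f[is.na(f)] <- ""
      paste(f, collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-pairs file
#'
#' Two tab-delimited columns naming the sample pairs that need cell-subset
#' disambiguation (e.g. CD4+ vs CD8+ fractions of one donor).
#'
#' @param path file path.
#' @return data.frame with columns `sample_id_a`, `sample_id_b`.
#' @export
read_pairs_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  out <- data.frame(
    sample_id_a = character(), sample_id_b = character(),
    stringsAsFactors = FALSE
  )
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 2L) {
      stop("pairs file line ", i, " must have exactly 2 columns")
    }
    if (fields[1L] == fields[2L]) {
      stop("pairs file line ", i, " pairs sample '", fields[1L], "' with itself")
    }
    out[nrow(out) + 1L, ] <- fields
  }
  out
}

is_gzip <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

#' Parse the UMI token from a read header
#'
#' The pipeline convention (MIGEC-compatible) appends a whitespace-separated
#' token `UMI:<seq>` or `UMI:<seq>:<qual>` to the read id.
#'
#' @param read_id character vector of read headers (without the leading `@`).
#' @return character vector of UMI sequences, `NA` where no token is present.
#' @export
parse_umi_header <- function(read_id) {
  m <- regmatches(read_id, regexpr("(?:^|\\s)UMI:[^\\s]+", read_id, perl = TRUE))
  out <- rep(NA_character_, length(read_id))
  has <- grepl("(^|\\s)UMI:", read_id, perl = TRUE)
  if (any(has)) {
    token <- sub("^\\s*UMI:", "", m)
    seqs <- vapply(strsplit(token, ":", fixed = TRUE), `[[`, character(1L), 1L)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop("UMI token with illegal characters in read header: ", seqs[bad][1L])
    }
    out[has] <- seqs
  }
  out
}

#' Read FASTQ into a read table
#'
#' Gzip compression is detected from magic bytes, not the file extension.
#' When `path2` is given the two files are zipped into mated records. UMIs
#' are parsed from headers when the `UMI:` token is present.
#'
#' @param path FASTQ file (read 1).
#' @param path2 optional FASTQ file (read 2).
#' @return data.frame with columns `read_id`, `sequence`, `quality`, `umi`
#'   and, for paired input, `mate_sequence`, `mate_quality`.
#' @export
read_fastq <- function(path, path2 = NULL) {
  read_one <- function(p) {
    con <- if (is_gzip(p)) gzfile(p, "rt") else file(p, "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    if (length(lines) %% 4L != 0L) {
      stop("truncated FASTQ record at record ", length(lines) %/% 4L + 1L,
        " in ", basename(p))
    }
    n <- length(lines) %/% 4L
    if (n == 0L) {
      return(data.frame(
        read_id = character(), sequence = character(),
        quality = character(), stringsAsFactors = FALSE
      ))
    }
    idx <- seq_len(n)
    hdr <- lines[4L * idx - 3L]
    if (any(substr(hdr, 1L, 1L) != "@")) {
      stop("malformed FASTQ header at record ",
        which(substr(hdr, 1L, 1L) != "@")[1L], " in ", basename(p))
    }
    seqs <- lines[4L * idx - 2L]
    quals <- lines[4L * idx]
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad) > 0L) {
      stop("sequence/quality length mismatch at record ", bad[1L],
        " in ", basename(p))
    }
    data.frame(
      read_id = sub("^@", "", hdr), sequence = seqs, quality = quals,
      stringsAsFactors = FALSE
    )
  }
  r1 <- read_one(path)
  r1$umi <- parse_umi_header(r1$read_id)
  if (!is.null(path2)) {
    r2 <- read_one(path2)
    if (nrow(r1) != nrow(r2)) {
      stop("paired FASTQ files have different read counts (",
        nrow(r1), " vs ", nrow(r2), ")")
    }
    r1$mate_sequence <- r2$sequence
    r1$mate_quality <- r2$quality
  }
  r1
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`; when
#'   `add_umi_token = TRUE` and a non-`NA` `umi` column is present, a
#'   `UMI:<seq>:<qual>` token is appended to headers that lack one.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param add_umi_token append the UMI header token (default `FALSE`).
#' @export
write_fastq <- function(reads, path, add_umi_token = FALSE) {
  hdr <- reads$read_id
  if (add_umi_token && !is.null(reads$umi)) {
    need <- !is.na(reads$umi) & !grepl("(^|\\s)UMI:", hdr, perl = TRUE)
    if (any(need)) {
      uq <- if (!is.null(reads$umi_quality)) reads$umi_quality[need] else
        strrep("I", nchar(reads$umi[need]))
      hdr[need] <- paste0(hdr[need], " UMI:", reads$umi[need], ":", uq)
    }
  }
  n <- nrow(reads)
  lines <- character(4L * n)
  if (n > 0L) {
    idx <- seq_len(n)
    lines[4L * idx - 3L] <- paste0("@", hdr)
    lines[4L * idx - 2L] <- reads$sequence
    lines[4L * idx - 1L] <- "+"
    lines[4L * idx] <- reads$quality
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Convert a Phred+33 quality string to integer scores
#'
#' @param quality character vector of quality strings.
#' @return list of integer vectors (one per string).
#' @export
phred_ints <- function(quality) {
  lapply(quality, function(q) {
    if (!nzchar(q)) return(integer())
    utf8ToInt(q) - 33L
  })
}

phred_string <- function(ints) {
  vapply(ints, function(x) intToUtf8(pmin(93L, pmax(0L, x)) + 33L), character(1L))
}

#' Read alignment records from a SAM file
#'
#' Only the fields the undetermined-read classifier consumes are parsed:
#' query name, FLAG bit 0x4 (unmapped) and the reference name. Header lines
#' are skipped.
#'
#' @param path SAM file path.
#' @return data.frame with columns `read_id`, `is_mapped`, `reference_name`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(
      read_id = character(), is_mapped = logical(),
      reference_name = character(), stringsAsFactors = FALSE
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("malformed SAM line ", short[1L], ": fewer than 3 fields")
  }
  qname <- vapply(fields, `[[`, character(1L), 1L)
  flag <- as.integer(vapply(fields, `[[`, character(1L), 2L))
  rname <- vapply(fields, `[[`, character(1L), 3L)
  mapped <- bitwAnd(flag, 4L) == 0L
  data.frame(
    read_id = qname, is_mapped = mapped,
    reference_name = ifelse(mapped, rname, NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Write alignment records to a minimal SAM file
#'
#' Emits only the mandatory columns the classifier reads back (positions,
#' CIGAR and sequence are placeholders). Useful for constructing fixtures
#' and for persisting [naive_map()] results.
#'
#' @param alignments data.frame as returned by [read_sam()] / [naive_map()].
#' @param path output path.
#' @export
write_sam <- function(alignments, path) {
  lines <- vapply(seq_len(nrow(alignments)), function(i) {
    mapped <- alignments$is_mapped[i]
    paste(
      alignments$read_id[i],
      if (mapped) 0L else 4L,
      if (mapped) alignments$reference_name[i] else "*",
      if (mapped) 1L else 0L, 255L, "*", "*", 0L, 0L, "*", "*",
      sep = "\t"
    )
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
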