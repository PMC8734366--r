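#' V gene segment catalog used by the simulator defaults
#' @return character vector of TRBV gene names.
#' @export
default_v_segments <- function() {
  c(
    "TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-1", "TRBV7-2", "TRBV9",
    "TRBV11-2", "TRBV12-3", "TRBV15", "TRBV19", "TRBV20-1", "TRBV27",
    "TRBV28", "TRBV29-1", "TRBV30"
  )
}

#' J gene segment catalog used by the simulator defaults
#' @return character vector of TRBJ gene names.
#' @export
default_j_segments <- function() {
  c("TRBJ1-1", "TRBJ1-2", "TRBJ1-5", "TRBJ2-1", "TRBJ2-3", "TRBJ2-5", "TRBJ2-7")
}

rank_weights <- function(n) {
  w <- 1 / seq_len(n)
  w / sum(w)
}

#' Define a repertoire generation profile
#'
#' Describes one synthetic sample: the number of clones, the clone-size law
#' (power law by default, reproducing the heavy skew real TCR beta
#' repertoires show), V/J usage vectors and the CDR3 amino-acid length law
#' (integer-truncated normal, mean 14.5, sd 1.5, clipped to 8..24 — matching
#' the modal 14/15-mer lengths typical of TCR beta chains).
#'
#' @param n_clones number of distinct clonotypes (>= 1).
#' @param clone_size_law list: `list(law="power_law", alpha=2)`,
#'   `list(law="lognormal", mu=1, sigma=1)` or `list(law="uniform", size=k)`.
#' @param v_usage,j_usage named probability vectors over gene segments; the
#'   defaults put rank-decreasing mass on the built-in catalogs.
#' @param cdr3_length_mean,cdr3_length_sd,cdr3_length_range CDR3 AA length law.
#' @param seed integer RNG seed.
#' @return list of class `repertoire_profile`.
#' @export
repertoire_profile <- function(n_clones,
                               clone_size_law = list(law = "power_law", alpha = 2),
                               v_usage = NULL, j_usage = NULL,
                               cdr3_length_mean = 14.5, cdr3_length_sd = 1.5,
                               cdr3_length_range = c(8L, 24L),
                               seed = 1L) {
  stopifnot(n_clones >= 1L)
  if (is.null(v_usage)) {
    v <- default_v_segments()
    v_usage <- stats::setNames(rank_weights(length(v)), v)
  }
  if (is.null(j_usage)) {
    j <- default_j_segments()
    j_usage <- stats::setNames(rank_weights(length(j)), j)
  }
  for (u in list(v_usage, j_usage)) {
    if (is.null(names(u)) || abs(sum(u) - 1) > 1e-9 || any(u < 0)) {
      stop("usage vectors must be named, non-negative and sum to 1")
    }
  }
  stopifnot(clone_size_law$law %in% c("power_law", "lognormal", "uniform"))
  structure(list(
    n_clones = as.integer(n_clones), clone_size_law = clone_size_law,
    v_usage = v_usage, j_usage = j_usage,
    cdr3_length_mean = cdr3_length_mean, cdr3_length_sd = cdr3_length_sd,
    cdr3_length_range = as.integer(cdr3_length_range), seed = as.integer(seed)
  ), class = "repertoire_profile")
}

nonstop_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt)))
}

random_cdr3_nt <- function(aa_lengths) {
  codons <- nonstop_codons()
  vapply(aa_lengths, function(L) {
    # canonical CDR3: starts with C, ends with F; middle codons non-stop
    mid <- if (L > 2L) paste(sample(codons, L - 2L, replace = TRUE), collapse = "") else ""
    paste0("TGT", mid, "TTC")
  }, character(1L))
}

#' Simulate one repertoire sample
#'
#' Clone counts are drawn from the profile's clone-size law (rounded up to
#' >= 1), CDR3 nucleotide sequences are random non-stop codon strings whose
#' translation is the clone's CDR3 AA sequence, and V/J segments are drawn
#' from the usage vectors. Deterministic under the profile seed; clonotype
#' keys are guaranteed unique.
#'
#' @param profile a [repertoire_profile()].
#' @param sample_id sample name (default `"sim"`).
#' @return a [repertoire_sample()].
#' @export
simulate_repertoire <- function(profile, sample_id = "sim") {
  stopifnot(inherits(profile, "repertoire_profile"))
  set.seed(profile$seed)
  n <- profile$n_clones
  law <- profile$clone_size_law
  counts <- switch(law$law,
    power_law = pmax(1, floor(stats::runif(n)^(-1 / law$alpha))),
    lognormal = pmax(1, round(stats::rlnorm(n, law$mu, law$sigma))),
    uniform = rep(if (is.null(law$size)) 1 else law$size, n)
  )
  lens <- pmin(
    profile$cdr3_length_range[2L],
    pmax(profile$cdr3_length_range[1L],
      round(stats::rnorm(n, profile$cdr3_length_mean, profile$cdr3_length_sd)))
  )
  nt <- random_cdr3_nt(lens)
  v <- sample(names(profile$v_usage), n, replace = TRUE, prob = profile$v_usage)
  j <- sample(names(profile$j_usage), n, replace = TRUE, prob = profile$j_usage)
  aa <- translate_nt(nt)
  key <- paste(aa, v, j, sep = "|")
  tries <- 0L
  while (anyDuplicated(key) && tries < 100L) {
    dup <- which(duplicated(key))
    nt[dup] <- random_cdr3_nt(lens[dup])
    aa[dup] <- translate_nt(nt[dup])
    key <- paste(aa, v, j, sep = "|")
    tries <- tries + 1L
  }
  if (anyDuplicated(key)) stop("could not generate unique clonotypes")
  repertoire_sample(data.frame(
    count = counts, cdr3_nt = nt, cdr3_aa = aa,
    v_hit = v, d_hit = NA_character_, j_hit = j, stringsAsFactors = FALSE
  ), sample_id)
}

#' Bundled synthetic stand-in for the PhiX control genome
#'
#' A deterministic 1 kb pseudo-random sequence named with a `phiX` prefix so
#' undetermined-read classification (which keys on that prefix) can run
#' without downloading the real control genome. Clearly synthetic: it shares
#' no homology with the actual bacteriophage.
#'
#' @return named character vector of length 1 (`phiX_synth`).
#' @export
pseudo_phix_reference <- function() {
  old <- .Random.seed_exists()
  set.seed(174282L)
  s <- paste(sample(c("A", "C", "G", "T"), 1000L, replace = TRUE), collapse = "")
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  c(phiX_synth = s)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

#' Write a named character vector as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

render_pattern <- function(pattern, umi) {
  chars <- strsplit(pattern, "")[[1L]]
  is_umi <- chars == "N"
  out <- toupper(chars)
  if (any(is_umi)) {
    stopifnot(nchar(umi) == sum(is_umi))
    out[is_umi] <- strsplit(umi, "")[[1L]]
  }
  paste(out, collapse = "")
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

random_qual <- function(n, len, lo = 30L, hi = 40L) {
  vapply(seq_len(n), function(i) {
    intToUtf8(sample(lo:hi, len, replace = TRUE) + 33L)
  }, character(1L))
}

add_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1L]]
    hit <- which(stats::runif(length(chars)) < error_rate)
    for (i in hit) {
      chars[i] <- sample(setdiff(bases, chars[i]), 1L)
    }
    paste(chars, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

umi_length <- function(pattern) {
  sum(strsplit(pattern, "")[[1L]] == "N")
}

unique_umis <- function(n, len) {
  u <- random_seq(n, len)
  while (anyDuplicated(u)) {
    dup <- which(duplicated(u))
    u[dup] <- random_seq(length(dup), len)
  }
  u
}

#' Simulate a barcoded, UMI-tagged FASTQ run with truth labels
#'
#' For every sample, each clone is expanded into `count` molecules; each
#' molecule receives a unique UMI filling the `N` positions of its sample's
#' barcode pattern and emits one or more reads (per `reads_per_molecule`)
#' carrying iid substitution errors. Junk classes emulate what real
#' undetermined files contain: PhiX-like fragments (from the bundled
#' pseudo-PhiX reference), low-quality reads (mean Phred < 30 by
#' construction), poly-G / many-N junk, and unmatched random "other" reads —
#' none carry valid barcodes by construction (random sequence). Planted
#' contamination copies chosen molecules from one sample into another
#' sample's barcode context, preserving UMI and insert.
#'
#' @param samples named list of [repertoire_sample()] objects.
#' @param specs `barcode_table` with one row per sample (matched by id).
#' @param out_dir directory for the FASTQ files (created if needed).
#' @param error_rate per-base substitution probability in `[0, 0.2]`.
#' @param reads_per_molecule `list(law="constant", n=k)` or
#'   `list(law="poisson1", lambda=l)` (1 + Poisson, so every molecule emits).
#' @param junk_spec list with counts `phix`, `low_quality`, `junk`, `other`.
#' @param contamination optional data.frame with columns `from`, `to`, `n`.
#' @param read_length read length in nt (default 150).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return list with `files` (per-sample FASTQ paths), `truth` (per-read
#'   data.frame), `contamination_truth` (planted (UMI,V,J) triples per pair),
#'   `molecule_counts` (truth molecules per sample) and `specs`.
#' @export
simulate_fastq_run <- function(samples, specs, out_dir,
                               error_rate = 0,
                               reads_per_molecule = list(law = "constant", n = 1L),
                               junk_spec = list(phix = 0L, low_quality = 0L,
                                 junk = 0L, other = 0L),
                               contamination = NULL,
                               read_length = 150L, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 0.2)
  if (!all(names(samples) %in% specs$sample_id)) {
    stop("every sample needs a barcode spec")
  }
  if (!is.null(contamination)) {
    unknown <- setdiff(unique(c(contamination$from, contamination$to)), names(samples))
    if (length(unknown) > 0L) {
      stop("contamination references unknown sample(s): ", paste(unknown, collapse = ", "))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  segs <- unique(unlist(lapply(samples, function(s) c(s$v_hit, s$j_hit))))
  contexts <- stats::setNames(random_seq(length(segs), 20L), segs)

  n_reads_for <- function(n_mol) {
    switch(reads_per_molecule$law,
      constant = rep(as.integer(reads_per_molecule$n), n_mol),
      poisson1 = 1L + stats::rpois(n_mol, reads_per_molecule$lambda),
      stop("unknown reads_per_molecule law")
    )
  }

  make_read_seq <- function(pattern, umis, v, j, cdr3) {
    rendered <- vapply(seq_along(umis), function(i) {
      render_pattern(pattern, umis[i])
    }, character(1L))
    body <- paste0(rendered, contexts[v], cdr3, contexts[j])
    pad <- strrep("ACGT", ceiling(read_length / 4L))
    full <- paste0(body, pad)
    substr(full, 1L, read_length)
  }

  counter <- 0L
  next_ids <- function(n) {
    ids <- sprintf("sim%08d", counter + seq_len(n))
    counter <<- counter + n
    ids
  }

  truth_list <- list()
  files <- character(0L)
  molecule_counts <- integer(0L)
  contam_truth <- list()
  per_sample_molecules <- list()

  sample_ids <- names(samples)
  # molecules + reads per sample
  per_file_reads <- stats::setNames(vector("list", length(sample_ids)), sample_ids)
  for (sid in sample_ids) {
    smp <- samples[[sid]]
    spec <- specs[specs$sample_id == sid, ]
    ulen <- umi_length(spec$master_pattern)
    if (ulen == 0L) stop("master pattern for '", sid, "' has no UMI (N) positions")
    clone_idx <- rep(seq_len(nrow(smp)), smp$count)
    n_mol <- length(clone_idx)
    umis <- unique_umis(n_mol, ulen)
    per_sample_molecules[[sid]] <- data.frame(
      umi = umis, clone_index = clone_idx,
      v_hit = smp$v_hit[clone_idx], j_hit = smp$j_hit[clone_idx],
      cdr3_nt = smp$cdr3_nt[clone_idx], stringsAsFactors = FALSE
    )
    nr <- n_reads_for(n_mol)
    mol_of_read <- rep(seq_len(n_mol), nr)
    seqs <- make_read_seq(
      spec$master_pattern, umis[mol_of_read],
      smp$v_hit[clone_idx[mol_of_read]], smp$j_hit[clone_idx[mol_of_read]],
      smp$cdr3_nt[clone_idx[mol_of_read]]
    )
    seqs <- add_substitutions(seqs, error_rate)
    ids <- next_ids(length(seqs))
    per_file_reads[[sid]] <- data.frame(
      read_id = ids, sequence = seqs,
      quality = random_qual(length(seqs), read_length),
      stringsAsFactors = FALSE
    )
    truth_list[[length(truth_list) + 1L]] <- data.frame(
      read_id = ids, category = "sample", true_sample = sid,
      umi = umis[mol_of_read], clone_index = clone_idx[mol_of_read],
      v_hit = smp$v_hit[clone_idx[mol_of_read]],
      j_hit = smp$j_hit[clone_idx[mol_of_read]],
      stringsAsFactors = FALSE
    )
    molecule_counts[sid] <- n_mol
  }

  # planted contamination: copy molecules from -> to barcode context
  if (!is.null(contamination)) {
    for (i in seq_len(nrow(contamination))) {
      from <- contamination$from[i]
      to <- contamination$to[i]
      k <- contamination$n[i]
      mols <- per_sample_molecules[[from]]
      spec_to <- specs[specs$sample_id == to, ]
      if (umi_length(spec_to$master_pattern) != nchar(mols$umi[1L])) {
        stop("UMI lengths differ between samples '", from, "' and '", to, "'")
      }
      pick <- sample(nrow(mols), k)
      # contaminating material is amplified and sequenced like any other
      # molecule: same reads-per-molecule law
      nr <- n_reads_for(k)
      mr <- rep(pick, nr)
      seqs <- make_read_seq(
        spec_to$master_pattern, mols$umi[mr],
        mols$v_hit[mr], mols$j_hit[mr], mols$cdr3_nt[mr]
      )
      seqs <- add_substitutions(seqs, error_rate)
      ids <- next_ids(length(mr))
      per_file_reads[[to]] <- rbind(per_file_reads[[to]], data.frame(
        read_id = ids, sequence = seqs,
        quality = random_qual(length(mr), read_length), stringsAsFactors = FALSE
      ))
      truth_list[[length(truth_list) + 1L]] <- data.frame(
        read_id = ids, category = "contaminant", true_sample = from,
        umi = mols$umi[mr], clone_index = mols$clone_index[mr],
        v_hit = mols$v_hit[mr], j_hit = mols$j_hit[mr],
        stringsAsFactors = FALSE
      )
      contam_truth[[paste(from, to, sep = "->")]] <- unique(paste(
        mols$umi[pick], mols$v_hit[pick], mols$j_hit[pick], sep = "|"
      ))
    }
  }

  # junk classes, distributed round-robin over sample files
  junk_reads <- list()
  add_junk <- function(n, category, seqs, quals) {
    if (n == 0L) return()
    ids <- next_ids(n)
    junk_reads[[length(junk_reads) + 1L]] <<- data.frame(
      read_id = ids, sequence = seqs, quality = quals,
      category = category, stringsAsFactors = FALSE
    )
    truth_list[[length(truth_list) + 1L]] <<- data.frame(
      read_id = ids, category = category, true_sample = NA_character_,
      umi = NA_character_, clone_index = NA_integer_,
      v_hit = NA_character_, j_hit = NA_character_, stringsAsFactors = FALSE
    )
  }
  np <- as.integer(junk_spec$phix %||% 0L)
  if (np > 0L) {
    phix <- unname(pseudo_phix_reference())
    starts <- sample(nchar(phix) - read_length, np, replace = TRUE)
    add_junk(np, "phix", substring(phix, starts, starts + read_length - 1L),
      random_qual(np, read_length))
  }
  nl <- as.integer(junk_spec$low_quality %||% 0L)
  if (nl > 0L) {
    add_junk(nl, "low_quality", random_seq(nl, read_length),
      random_qual(nl, read_length, lo = 3L, hi = 25L))
  }
  nj <- as.integer(junk_spec$junk %||% 0L)
  if (nj > 0L) {
    half <- nj %/% 2L
    seqs <- c(
      rep(strrep("G", read_length), half),
      vapply(seq_len(nj - half), function(i) {
        s <- strsplit(random_seq(1L, read_length), "")[[1L]]
        s[sample(read_length, 15L)] <- "N"
        paste(s, collapse = "")
      }, character(1L))
    )
    add_junk(nj, "junk", seqs, random_qual(nj, read_length))
  }
  no <- as.integer(junk_spec$other %||% 0L)
  if (no > 0L) {
    add_junk(no, "other", random_seq(no, read_length),
      random_qual(no, read_length))
  }
  if (length(junk_reads) > 0L) {
    jr <- do.call(rbind, junk_reads)
    dest <- rep(sample_ids, length.out = nrow(jr))
    for (sid in sample_ids) {
      rows <- jr[dest == sid, c("read_id", "sequence", "quality")]
      per_file_reads[[sid]] <- rbind(per_file_reads[[sid]], rows)
    }
  }

  for (sid in sample_ids) {
    spec <- specs[specs$sample_id == sid, ]
    fname <- if (!is.na(spec$fastq1)) basename(spec$fastq1) else paste0(sid, "_R1.fastq.gz")
    path <- file.path(out_dir, fname)
    write_fastq(per_file_reads[[sid]], path)
    files[sid] <- path
  }

  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  list(
    files = files, truth = truth, contamination_truth = contam_truth,
    molecule_counts = molecule_counts, molecules = per_sample_molecules,
    specs = specs
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant FACS-sorting ambiguity between two samples
#'
#' Injects fresh clonotypes shared between both samples: `n_ambiguous`
#' clones whose frequency fold change lies within the two-fold band (to be
#' removed from both samples by disambiguation) and `n_dominant` clones
#' whose fold change clearly exceeds it (to be reassigned to the recorded
#' dominant side). Because planting changes sample totals — and fold change
#' is computed on frequencies — counts are adjusted by a short fixed-point
#' iteration so the realized frequency folds stay inside their bands
#' (ambiguous in [1.05, 1.9], dominant in [2.6, 6]).
#'
#' @param sample_a,sample_b [repertoire_sample()] objects.
#' @param n_ambiguous,n_dominant numbers of planted clones.
#' @param seed integer seed.
#' @return list with modified `sample_a`, `sample_b`, `ambiguous_keys`
#'   (character set) and `dominant` (data.frame key, winner).
#' @export
plant_facs_ambiguity <- function(sample_a, sample_b, n_ambiguous, n_dominant,
                                 seed = 1L) {
  stopifnot(nrow(sample_a) > 0L, nrow(sample_b) > 0L)
  set.seed(seed)
  n <- n_ambiguous + n_dominant
  if (n == 0L) {
    return(list(
      sample_a = sample_a, sample_b = sample_b,
      ambiguous_keys = character(), dominant = data.frame(
        key = character(), winner = character(), stringsAsFactors = FALSE
      )
    ))
  }
  existing <- union(clonotype_key(sample_a), clonotype_key(sample_b))
  codons <- nonstop_codons()
  make_clone <- function() {
    L <- sample(12:16, 1L)
    nt <- paste0("TGT", paste(sample(codons, L - 2L, replace = TRUE), collapse = ""), "TTC")
    list(nt = nt, aa = translate_nt(nt),
      v = sample(default_v_segments(), 1L), j = sample(default_j_segments(), 1L))
  }
  clones <- list()
  while (length(clones) < n) {
    cl <- make_clone()
    key <- paste(cl$aa, cl$v, cl$j, sep = "|")
    if (!key %in% existing) {
      existing <- c(existing, key)
      clones[[length(clones) + 1L]] <- cl
    }
  }
  folds <- c(
    if (n_ambiguous > 0L) stats::runif(n_ambiguous, 1.05, 1.9) else numeric(),
    if (n_dominant > 0L) stats::runif(n_dominant, 2.6, 6) else numeric()
  )
  winner_a <- c(
    rep(NA, n_ambiguous),
    if (n_dominant > 0L) sample(c(TRUE, FALSE), n_dominant, replace = TRUE) else logical()
  )
  # large base count keeps count-rounding granularity well inside the
  # fold-change bands realized by the fixed point below
  base_count <- max(50, round(stats::median(sample_a$count)))
  ca <- rep(base_count, n)
  cb <- rep(base_count, n)
  ta0 <- attr(sample_a, "total_count")
  tb0 <- attr(sample_b, "total_count")
  # fixed point: counts -> totals -> frequency folds
  for (iter in 1:25) {
    ta <- ta0 + sum(ca)
    tb <- tb0 + sum(cb)
    # want (ca/ta)/(cb/tb) = f on the winning side
    for (i in seq_len(n)) {
      f <- folds[i]
      if (is.na(winner_a[i]) || winner_a[i]) {
        cb[i] <- max(1, round(ca[i] * tb / (ta * f)))
      } else {
        ca[i] <- max(1, round(cb[i] * ta / (tb * f)))
      }
    }
  }
  ta <- ta0 + sum(ca)
  tb <- tb0 + sum(cb)
  realized <- pmax((ca / ta) / (cb / tb), (cb / tb) / (ca / ta))
  amb_idx <- seq_len(n_ambiguous)
  dom_idx <- setdiff(seq_len(n), amb_idx)
  if (any(realized[amb_idx] > 2) || any(realized[dom_idx] <= 2.2)) {
    stop("internal: planted fold changes left their bands")
  }
  add_rows <- function(counts) {
    data.frame(
      count = counts,
      cdr3_nt = vapply(clones, `[[`, character(1L), "nt"),
      cdr3_aa = vapply(clones, `[[`, character(1L), "aa"),
      v_hit = vapply(clones, `[[`, character(1L), "v"),
      d_hit = NA_character_,
      j_hit = vapply(clones, `[[`, character(1L), "j"),
      stringsAsFactors = FALSE
    )
  }
  cols <- c("count", "cdr3_nt", "cdr3_aa", "v_hit", "d_hit", "j_hit")
  new_a <- repertoire_sample(
    rbind(as.data.frame(sample_a)[, cols], add_rows(ca)), sample_id(sample_a)
  )
  new_b <- repertoire_sample(
    rbind(as.data.frame(sample_b)[, cols], add_rows(cb)), sample_id(sample_b)
  )
  keys <- vapply(clones, function(cl) paste(cl$aa, cl$v, cl$j, sep = "|"), character(1L))
  list(
    sample_a = new_a, sample_b = new_b,
    ambiguous_keys = keys[amb_idx],
    dominant = data.frame(
      key = keys[dom_idx],
      winner = ifelse(winner_a[dom_idx], sample_id(sample_a), sample_id(sample_b)),
      stringsAsFactors = FALSE
    )
  )
}
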