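test_that("compile_matcher partitions pattern positions", {
  m <- compile_matcher(list(sample_id = "S", master_pattern = "NNNNNNtCAGATtNNNNNN"))
  expect_length(m$umi_pos, 12L)
  expect_length(m$seed_pos, 5L)
  expect_equal(m$seed_base, c("C", "A", "G", "A", "T"))
  expect_length(m$fuzzy_pos, 2L)
  expect_equal(m$fuzzy_base, c("T", "T"))

  m2 <- compile_matcher(list(sample_id = "S", master_pattern = "ACGT"))
  expect_length(m2$seed_pos, 4L)
  expect_length(m2$umi_pos, 0L)

  expect_error(
    compile_matcher(list(sample_id = "S", master_pattern = "NNnn")),
    "no seed"
  )
})

test_that("demultiplex enforces seed exactness and fuzzy budget", {
  specs <- make_specs("S1")  # NNNNNNtCAGATtNNNNNN
  good <- paste0("AAAAAA", "T", "CAGAT", "T", "CCCCCC", strrep("G", 20))
  seed_err <- paste0("AAAAAA", "T", "CAGGT", "T", "CCCCCC", strrep("G", 20))
  fuzzy1 <- paste0("AAAAAA", "G", "CAGAT", "T", "CCCCCC", strrep("G", 20))
  fuzzy2 <- paste0("AAAAAA", "G", "CAGAT", "G", "CCCCCC", strrep("G", 20))
  reads <- make_reads(c(good, seed_err, fuzzy1, fuzzy2))
  res <- demultiplex(reads, specs)
  expect_equal(res$assigned$S1$read_id, c("r001", "r003"))
  expect_equal(res$assigned$S1$umi, c("AAAAAACCCCCC", "AAAAAACCCCCC"))
  expect_setequal(res$undetermined$read_id, c("r002", "r004"))
  expect_equal(res$undetermined$reason, c("unmatched", "unmatched"))
  expect_equal(sum(res$counts$demultiplexed) + nrow(res$undetermined), 4L)
})

test_that("reads matching two samples go to undetermined as ambiguous", {
  specs <- structure(data.frame(
    sample_id = c("X", "Y"),
    master_pattern = c("NNNNtCAGATt", "NNNNgCAGATg"),
    secondary_pattern = NA_character_, fastq1 = NA_character_,
    fastq2 = NA_character_, stringsAsFactors = FALSE
  ), class = c("barcode_table", "data.frame"))
  # fuzzy context differs; a read with 1 mismatch on each side matches both
  read <- paste0("AAAA", "T", "CAGAT", "G", strrep("C", 30))
  res <- demultiplex(make_reads(read), specs)
  expect_equal(nrow(res$undetermined), 1L)
  expect_equal(res$undetermined$reason, "ambiguous")
  # brute-force oracle: enumerate both matchers by hand
  for (m in list(compile_matcher(as.list(specs[1, ])),
                 compile_matcher(as.list(specs[2, ])))) {
    chars <- strsplit(read, "")[[1]]
    expect_true(all(chars[m$seed_pos] == m$seed_base))
    expect_lte(sum(chars[m$fuzzy_pos] != m$fuzzy_base), 1L)
  }
})

test_that("patterns are found within the search window", {
  specs <- make_specs("S1")
  shifted <- paste0("GG", "AAAAAA", "T", "CAGAT", "T", "CCCCCC", strrep("A", 30))
  res <- demultiplex(make_reads(shifted), specs)
  expect_equal(nrow(res$assigned$S1), 1L)
  expect_equal(res$assigned$S1$umi, "AAAAAACCCCCC")
  far <- paste0(strrep("C", 50), "AAAAAAT", "CAGAT", "TCCCCCC")
  res2 <- demultiplex(make_reads(far), specs)
  expect_equal(nrow(res2$undetermined), 1L)
})

test_that("consensus building follows plurality, phred, base-order rules", {
  # 5 identical reads: consensus equals the read
  reads <- make_reads(rep("ACGTACGT", 5), umi = rep("AAAA", 5))
  asm <- assemble_migs(reads, min_mig_size = 1)
  expect_length(asm$migs, 1L)
  expect_equal(asm$consensus$sequence, "ACGTACGT")

  # majority at position 7 (A,A,C -> A)
  seqs <- c("ACGTACATT", "ACGTACATT", "ACGTACCTT")
  asm <- assemble_migs(make_reads(seqs, umi = rep("GGGG", 3)), min_mig_size = 1)
  expect_equal(substr(asm$consensus$sequence, 7, 7), "A")

  # 1-1 tie broken by summed phred ('I'=40 beats '#'=2)
  reads <- make_reads(c("A", "C"), quals = c("#", "I"), umi = c("TT", "TT"))
  asm <- assemble_migs(reads, min_mig_size = 1)
  expect_equal(asm$consensus$sequence, "C")

  # full tie: lexicographic base order (A before C)
  reads <- make_reads(c("A", "C"), quals = c("I", "I"), umi = c("TT", "TT"))
  expect_equal(assemble_migs(reads, min_mig_size = 1)$consensus$sequence, "A")

  # min_mig_size threshold discards singletons
  reads <- make_reads(c("AAAA", "AAAA", "CCCC"),
    umi = c("GG", "GG", "TT"))
  asm <- assemble_migs(reads, min_mig_size = 2)
  expect_length(asm$migs, 1L)
  expect_equal(asm$counts$consensus_reads, 1L)
  expect_equal(asm$counts$discarded_reads, 1L)

  expect_error(assemble_migs(make_reads("ACGT")), "no UMI")
})

test_that("consensus is invariant to read order", {
  set.seed(31)
  seqs <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  }, character(1))
  umis <- rep(c("AAAA", "CCCC", "GGGG", "TTTT"), each = 5)
  reads <- make_reads(seqs, umi = umis)
  a1 <- assemble_migs(reads, min_mig_size = 1)
  perm <- sample(nrow(reads))
  a2 <- assemble_migs(reads[perm, ], min_mig_size = 1)
  o1 <- a1$consensus[order(a1$consensus$umi), c("umi", "sequence")]
  o2 <- a2$consensus[order(a2$consensus$umi), c("umi", "sequence")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("read flow conserves totals and handles empty input", {
  specs <- make_specs(c("S1", "S2"))
  reads <- make_reads(c(
    paste0("AAAAAA", "TCAGATT", "CCCCCC", strrep("G", 20)),
    paste0("AAAAAA", "TTTGCAT", "CCCCCC", strrep("G", 20)),
    strrep("T", 40)
  ))
  res <- demultiplex(reads, specs)
  migs <- lapply(res$assigned, assemble_migs, min_mig_size = 1)
  flow <- read_flow_summary(res, migs)
  expect_equal(sum(flow$per_sample$demultiplexed_reads) +
    flow$undetermined_reads, 3L)
  raw_rows <- flow$flow[flow$flow$source == "raw", ]
  expect_equal(sum(raw_rows$count), 3L)

  empty <- demultiplex(make_reads(character(0)), specs)
  flow0 <- read_flow_summary(empty, NULL)
  expect_equal(flow0$undetermined_reads, 0L)
  expect_equal(sum(flow0$per_sample$demultiplexed_reads), 0L)
})
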