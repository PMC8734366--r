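test_that("mean_phred is a plain arithmetic mean", {
  expect_equal(mean_phred(c(30, 30, 30, 30)), 30)
  expect_equal(mean_phred(c(20, 40)), 30)
  expect_equal(mean_phred(c(2, 2, 2, 41)), 11.75)
  expect_error(mean_phred(integer(0)), "empty")
  # quality-string form
  expect_equal(mean_phred("II"), 40)
})

test_that("facs_correct applies the two-fold rule on frequencies", {
  # construct two samples with controlled shared frequencies:
  # shared1 at fa=0.06, fb=0.04 (fold 1.5 -> ambiguous)
  # shared2 at fa=0.10, fb=0.04 (fold 2.5 -> reassigned to A)
  mk <- function(id, counts, aa) {
    repertoire_sample(data.frame(
      count = counts, cdr3_nt = strrep("TGT", nchar(aa)), cdr3_aa = aa,
      v_hit = "TRBV5-1", d_hit = NA, j_hit = "TRBJ2-7",
      stringsAsFactors = FALSE
    ), id)
  }
  a <- mk("A", c(6, 10, 84), c("CASSSHF", "CASSSDF", "CAONLYA"))
  b <- mk("B", c(4, 4, 92), c("CASSSHF", "CASSSDF", "CBONLYB"))
  fc <- facs_correct(a, b, fold_threshold = 2)
  expect_equal(fc$removed_ambiguous, "CASSSHF|TRBV5-1|TRBJ2-7")
  expect_equal(fc$reassigned$key, "CASSSDF|TRBV5-1|TRBJ2-7")
  expect_equal(fc$reassigned$winner, "A")
  expect_true("CASSSDF" %in% fc$cleaned_a$cdr3_aa)
  expect_false("CASSSDF" %in% fc$cleaned_b$cdr3_aa)
  expect_false("CASSSHF" %in% fc$cleaned_a$cdr3_aa)
  expect_false("CASSSHF" %in% fc$cleaned_b$cdr3_aa)
  # clone present only in A untouched; frequencies renormalized
  expect_true("CAONLYA" %in% fc$cleaned_a$cdr3_aa)
  expect_equal(sum(fc$cleaned_a$frequency), 1, tolerance = 1e-9)
  # boundary: fold exactly 2 is ambiguous ("does not exceed")
  a2 <- mk("A", c(20, 80), c("CASSSHF", "CAONLYA"))
  b2 <- mk("B", c(10, 90), c("CASSSHF", "CBONLYB"))
  fc2 <- facs_correct(a2, b2)
  expect_equal(fc2$removed_ambiguous, "CASSSHF|TRBV5-1|TRBJ2-7")
})

test_that("facs_correct is idempotent and recovers planted truth", {
  a <- simulate_repertoire(repertoire_profile(150, seed = 21), "CD4")
  b <- simulate_repertoire(repertoire_profile(150, seed = 22), "CD8")
  pl <- plant_facs_ambiguity(a, b, n_ambiguous = 8, n_dominant = 6, seed = 4)
  fc <- facs_correct(pl$sample_a, pl$sample_b)
  expect_setequal(fc$removed_ambiguous, pl$ambiguous_keys)
  expect_equal(
    fc$reassigned[order(fc$reassigned$key), ],
    pl$dominant[order(pl$dominant$key), ],
    ignore_attr = TRUE
  )
  fc2 <- facs_correct(fc$cleaned_a, fc$cleaned_b)
  expect_length(fc2$removed_ambiguous, 0L)
  expect_equal(nrow(fc2$reassigned), 0L)
  expect_equal(as.data.frame(fc2$cleaned_a), as.data.frame(fc$cleaned_a))
  expect_equal(as.data.frame(fc2$cleaned_b), as.data.frame(fc$cleaned_b))
})

test_that("contamination analysis computes intersections and venn regions", {
  tri <- function(umis, v = "TRBV9", j = "TRBJ1-1", ids = NULL) {
    df <- data.frame(umi = umis, v_hit = v, j_hit = j, stringsAsFactors = FALSE)
    if (!is.null(ids)) df$read_id <- ids
    df
  }
  rep_a <- tri(c("AAA", "CCC", "GGG"), ids = c("a1", "a2", "a3"))
  rep_b <- tri(c("TTT"), ids = "b1")
  rep_c <- tri(c("AAA", "CCC", "TAT"), ids = c("c1", "c2", "c3"))
  rpt <- contamination_analysis(list(A = rep_a, B = rep_b, C = rep_c))
  cnt <- rpt$pair_counts
  expect_equal(cnt$shared[cnt$sample_a == "A" & cnt$sample_b == "B"], 0L)
  expect_equal(cnt$shared[cnt$sample_a == "B" & cnt$sample_b == "C"], 0L)
  expect_equal(cnt$shared[cnt$sample_a == "A" & cnt$sample_b == "C"], 2L)
  # venn regions: brute-force set enumeration oracle
  sets <- lapply(list(rep_a, rep_b, rep_c), function(d) {
    paste(d$umi, d$v_hit, d$j_hit, sep = "|")
  })
  expect_equal(unname(rpt$venn_counts["A&C"]),
    length(setdiff(intersect(sets[[1]], sets[[3]]), sets[[2]])))
  expect_equal(unname(rpt$venn_counts["A"]),
    length(setdiff(sets[[1]], union(sets[[2]], sets[[3]]))))
  expect_equal(sum(rpt$venn_counts), length(unique(unlist(sets))))
  # flagged reads are exactly those with shared triples
  expect_setequal(rpt$flagged_reads$A, c("a1", "a2"))
  expect_setequal(rpt$flagged_reads$C, c("c1", "c2"))
  expect_length(rpt$flagged_reads$B, 0L)

  # single sample: no pairs, no flags
  solo <- contamination_analysis(list(A = rep_a))
  expect_equal(nrow(solo$pair_counts), 0L)
  expect_length(solo$flagged_reads$A, 0L)

  # reads without UMI are rejected with guidance
  bad <- data.frame(umi = NA_character_, v_hit = "V", j_hit = "J")
  expect_error(contamination_analysis(list(A = bad)), "UMI")
})

test_that("undetermined classification follows strict rule precedence", {
  reads <- make_reads(
    seqs = c(
      strrep("A", 40),                                  # phix-mapped, Q12
      strrep("A", 40),                                  # unmapped, Q20
      paste0(strrep("N", 11), strrep("A", 29)),         # 11 Ns, Q35
      strrep("A", 40),                                  # tcr-mapped, Q35
      strrep("A", 40),                                  # clean unmapped, Q35
      paste0(strrep("G", 11), strrep("A", 29))          # 27.5% G, Q35
    ),
    quals = c(
      strrep("-", 40), strrep("5", 40), strrep("D", 40),
      strrep("D", 40), strrep("D", 40), strrep("D", 40)
    ),
    ids = sprintf("u%d", 1:6)
  )
  aln <- data.frame(
    read_id = c("u1", "u4"), is_mapped = TRUE,
    reference_name = c("phiX_synth", "TRBV9"), stringsAsFactors = FALSE
  )
  bd <- classify_undetermined(reads, aln)
  expect_equal(bd$groups, c("PhiX", "Low quality", "Junk", "TCR junk",
    "Other", "Junk"))
  expect_equal(sum(bd$counts), 6L)
  expect_equal(bd$other_reads$read_id, "u5")

  # custom library: mapped reads collapse into one group
  bd2 <- classify_undetermined(reads, aln, custom_library = TRUE)
  expect_equal(unname(bd2$counts["Mapped"]), 2L)
  expect_named(bd2$counts, c("Mapped", "Low quality", "Junk", "Other"))

  # partition and permutation invariance
  perm <- c(4, 2, 6, 1, 5, 3)
  bd3 <- classify_undetermined(reads[perm, ], aln)
  expect_equal(bd3$counts, bd$counts)

  # conflicting duplicate alignments rejected
  dup <- rbind(aln, data.frame(read_id = "u1", is_mapped = TRUE,
    reference_name = "TRBV9"))
  expect_error(classify_undetermined(reads, dup), "conflicting")
})

test_that("rule order is verified against a reference rule engine", {
  # independent oracle: literal (1)-(5) rule engine over scalar features
  oracle <- function(mapped_ref, meanq, n_count, g_frac) {
    if (!is.na(mapped_ref) && startsWith(mapped_ref, "phiX")) return("PhiX")
    if (meanq < 30) return("Low quality")
    if (n_count > 10 || g_frac > 0.25) return("Junk")
    if (!is.na(mapped_ref)) return("TCR junk")
    "Other"
  }
  set.seed(77)
  cases <- expand.grid(
    ref = c(NA, "phiX_synth", "TRBV9"), q = c(12, 35),
    n = c(0, 11), g = c(0, 0.3), stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    len <- 40L
    n_g <- round(cs$g * len)
    n_n <- cs$n
    seqchars <- c(rep("G", n_g), rep("N", n_n), rep("A", len - n_g - n_n))
    reads <- make_reads(paste(seqchars, collapse = ""),
      quals = strrep(intToUtf8(cs$q + 33), len), ids = "x")
    aln <- if (is.na(cs$ref)) {
      data.frame(read_id = character(), is_mapped = logical(),
        reference_name = character())
    } else {
      data.frame(read_id = "x", is_mapped = TRUE, reference_name = cs$ref)
    }
    expect_equal(
      classify_undetermined(reads, aln)$groups,
      oracle(cs$ref, cs$q, n_n, n_g / len),
      info = paste(unlist(cs), collapse = "/")
    )
  }
})

test_that("naive_map finds containment and rejects bad input", {
  ref_path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(pseudo_phix_reference(), ref_path)
  phix <- unname(pseudo_phix_reference())
  reads <- make_reads(c(substr(phix, 101, 200), strrep("ACGT", 25)))
  set.seed(12)
  rand <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  reads <- rbind(reads, make_reads(rand, ids = "r999"))
  aln <- naive_map(reads, ref_path)
  expect_true(aln$is_mapped[1])
  expect_equal(aln$reference_name[1], "phiX_synth")
  expect_false(aln$is_mapped[3])  # random read unmapped

  expect_error(naive_map(make_reads("ACGT"), ref_path), "exceeds")
  empty_ref <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty_ref)
  expect_error(naive_map(reads, empty_ref), "empty")
})
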