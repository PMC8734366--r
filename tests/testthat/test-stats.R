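test_that("cdr3 length distribution bins frequency and clone counts", {
  s <- repertoire_sample(data.frame(
    count = c(1, 1, 1),
    cdr3_nt = strrep("TGT", c(14, 14, 15)),
    cdr3_aa = c(strrep("A", 14), strrep("C", 14), strrep("D", 15)),
    v_hit = "TRBV9", d_hit = NA, j_hit = "TRBJ1-1",
    stringsAsFactors = FALSE
  ), "S")
  h <- cdr3_length_distribution(s)
  expect_equal(h$length, c(14L, 15L))
  expect_equal(h$frequency, c(2 / 3, 1 / 3))
  expect_equal(h$clone_count, c(2L, 1L))

  one <- tiny_sample(5)
  h1 <- cdr3_length_distribution(one)
  expect_equal(sum(h1$frequency), 1)
})

test_that("top_clonotypes sorts by count with deterministic ties", {
  s <- tiny_sample(c(5, 3, 1))
  top <- top_clonotypes(s, n = 2)
  expect_equal(top$count, c(5, 3))
  # all-equal counts: lexicographically smallest CDR3 first
  s2 <- tiny_sample(c(2, 2, 2))
  top2 <- top_clonotypes(s2, n = 3)
  expect_equal(top2$cdr3_aa, sort(s2$cdr3_aa))
  # n larger than the repertoire
  expect_equal(nrow(top_clonotypes(s, n = 50)), 3L)
})

test_that("diversity indices match closed forms and hand computations", {
  # uniform closed forms: S equal clones
  u <- tiny_sample(rep(3, 4))
  d <- diversity_indices(u, resample_reps = 2)
  expect_equal(d$shannon_wiener, log(4))
  expect_equal(d$inv_simpson, 4)
  expect_equal(d$evenness, 1)
  expect_equal(d$clonality, 0)

  # hand-computed H for counts [2,1,1]
  d2 <- diversity_indices(tiny_sample(c(2, 1, 1)), resample_reps = 2)
  expect_equal(d2$shannon_wiener,
    -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)

  # chao1 for counts [1,1,2]: 3 + 2^2 / (2 * 1) = 5
  d3 <- diversity_indices(tiny_sample(c(1, 1, 2)), resample_reps = 2)
  expect_equal(d3$chao1, 5)
  # no doubletons: S + f1 (f1 - 1) / 2
  d4 <- diversity_indices(tiny_sample(c(1, 1, 3)), resample_reps = 2)
  expect_equal(d4$chao1, 3 + 2 * 1 / 2)

  # single clone: defined degenerate values
  d5 <- diversity_indices(tiny_sample(10), resample_reps = 2)
  expect_equal(d5$shannon_wiener, 0)
  expect_equal(d5$evenness, 0)
  expect_equal(d5$inv_simpson, 1)

  # resampled mean is computed at the requested depth, deterministic
  s <- tiny_sample(c(50, 30, 20))
  r1 <- diversity_indices(s, resample_depth = 50, seed = 3)
  r2 <- diversity_indices(s, resample_depth = 50, seed = 3)
  expect_equal(r1$shannon_mean_resampled, r2$shannon_mean_resampled)
  expect_lte(r1$shannon_mean_resampled, log(3))
  expect_error(diversity_indices(s, resample_depth = 1000), "exceeds")
})

test_that("rarefaction curve matches the hypergeometric oracle", {
  skip_if_not_installed("vegan")
  counts <- c(5, 3, 2)
  s <- tiny_sample(counts)
  cv <- diversity_curve(s, n_scaled = 10, step = 2, replicates = 200, seed = 9)
  for (i in seq_len(nrow(cv$points))) {
    sz <- cv$points$size[i]
    exact <- as.numeric(suppressWarnings(vegan::rarefy(matrix(counts, nrow = 1), sz)))
    se <- cv$points$sd[i] / sqrt(cv$replicates)
    tol <- max(3 * se, 1e-9)
    expect_lt(abs(cv$points$mean_unique[i] - exact), tol + 1e-9)
  }
  # exhaustive draw: exact observed richness, sd 0
  last <- nrow(cv$points)
  expect_equal(cv$points$mean_unique[last], 3)
  expect_equal(cv$points$sd[last], 0)
  # oracle-level monotonicity of the exact expectation
  exact_curve <- vapply(cv$points$size, function(sz) {
    as.numeric(suppressWarnings(vegan::rarefy(matrix(counts, nrow = 1), sz)))
  }, numeric(1))
  expect_true(all(diff(exact_curve) >= 0))
})

test_that("curve fit recovers parameters", {
  x <- seq(2500, 50000, by = 2500)
  y <- 1000 * x / (500 + x)
  fit <- fit_diversity_curve(data.frame(size = x, mean_unique = y))
  expect_true(fit$converged)
  expect_equal(fit$a, 1000, tolerance = 0.01)
  expect_equal(fit$b, 500, tolerance = 0.01)
  # rss negligible relative to the signal (y is on the 10^3 scale)
  expect_lt(fit$rss / sum(y^2), 1e-8)

  # saturated (constant) curve: a approaches the plateau, b small
  yc <- rep(800, length(x))
  fitc <- fit_diversity_curve(data.frame(size = x, mean_unique = yc))
  expect_equal(fitc$a, 800, tolerance = 0.02)
  expect_lt(fitc$b, 50)

  expect_error(
    fit_diversity_curve(data.frame(size = c(1, 2), mean_unique = c(1, 2))),
    "at least 3"
  )
})

test_that("overlap matrix is symmetric with NA for insufficient overlap", {
  a <- tiny_sample(c(50, 30, 20, 10), id = "a")
  b <- tiny_sample(c(40, 35, 15, 10), id = "b")  # same keys as a
  ov <- overlap_matrix(list(a = a, b = b))
  expect_equal(diag(ov$r_squared), c(a = 1, b = 1))
  expect_equal(ov$r_squared["a", "b"], ov$r_squared["b", "a"])
  expect_true(ov$r_squared["a", "b"] >= 0 && ov$r_squared["a", "b"] <= 1)

  # disjoint clonotypes: missing entry, not zero
  cdis <- tiny_sample(c(3, 2), id = "c",
    v = rep("TRBV2", 2), j = rep("TRBJ1-2", 2))
  ov2 <- overlap_matrix(list(a = a, c = cdis))
  expect_true(is.na(ov2$r_squared["a", "c"]))
  expect_equal(nrow(ov2$pair_tables[["a&c"]]), 0L)

  # self-overlap through duplicated sample
  ov3 <- overlap_matrix(list(x = a, y = a))
  expect_equal(ov3$r_squared["x", "y"], 1)
})

test_that("vj pairing retains the minimal coverage prefix", {
  # single pair
  s1 <- tiny_sample(5)
  vj1 <- vj_pairing(s1)
  expect_equal(nrow(vj1$pairs), 1L)
  expect_true(vj1$pairs$retained)
  expect_equal(vj1$pairs$mass, 1)

  # 100 equal pairs at coverage 0.98 -> 98 retained
  vs <- paste0("TRBV", 1:100)
  s2 <- repertoire_sample(data.frame(
    count = rep(1, 100), cdr3_nt = strrep("TGT", 10),
    cdr3_aa = sprintf("CASS%02dXYZF", 1:100),
    v_hit = vs, d_hit = NA, j_hit = "TRBJ1-1", stringsAsFactors = FALSE
  ), "S")
  vj2 <- vj_pairing(s2, coverage = 0.98)
  expect_equal(sum(vj2$pairs$retained), 98L)
  # conservation: retained + discarded mass = 1
  expect_equal(sum(vj2$pairs$mass), 1, tolerance = 1e-9)
  # top-5 labels by marginal mass
  expect_length(vj2$labeled_v, 5L)
  expect_length(vj2$labeled_j, 1L)
})

test_that("similarity clustering separates disjoint usage profiles", {
  v1 <- stats::setNames(rep(0.2, 5), paste0("TRBV", 1:5))
  v2 <- stats::setNames(rep(0.2, 5), paste0("TRBV", 6:10))
  j <- stats::setNames(rep(1 / 7, 7), default_j_segments())
  mk <- function(vu, seed, id) {
    simulate_repertoire(repertoire_profile(60, v_usage = vu, j_usage = j,
      seed = seed), id)
  }
  samples <- c(
    lapply(1:4, function(i) mk(v1, i, paste0("p1_", i))),
    lapply(5:8, function(i) mk(v2, i, paste0("p2_", i)))
  )
  names(samples) <- vapply(samples, sample_id, character(1))
  res <- similarity_clustering(samples, k = 2)
  cl <- res$clusters
  expect_length(unique(cl[1:4]), 1L)
  expect_length(unique(cl[5:8]), 1L)
  expect_false(cl[1] == cl[5])
  # standardized columns: mean 0, sd 1 (or all-zero)
  for (jcol in seq_len(ncol(res$features))) {
    col <- res$features[, jcol]
    expect_equal(mean(col), 0, tolerance = 1e-12)
    expect_true(abs(stats::sd(col) - 1) < 1e-12 || all(col == 0))
  }
  # newick export has one leaf per sample
  expect_equal(length(ape::read.tree(text = res$newick)$tip.label), 8L)

  # a sample generated from profile 1 but labeled as profile 2 clusters
  # with its generating profile (barcode-swap mechanism)
  swapped <- mk(v1, 99, "p2_swapped")
  samples2 <- c(samples, list(p2_swapped = swapped))
  res2 <- similarity_clustering(samples2, k = 2)
  expect_equal(unname(res2$clusters["p2_swapped"]),
    unname(res2$clusters["p1_1"]))
})
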