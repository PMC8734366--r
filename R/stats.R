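#' CDR3 amino-acid length distribution
#'
#' @param sample a [repertoire_sample()].
#' @return data.frame with columns `length`, `clone_count` (number of
#'   distinct clonotypes at that length) and `frequency` (summed clone
#'   frequency mass at that length).
#' @export
cdr3_length_distribution <- function(sample) {
  stopifnot(nrow(sample) > 0L)
  len <- nchar(sample$cdr3_aa)
  agg_n <- tapply(rep(1L, length(len)), len, sum)
  agg_f <- tapply(sample$frequency, len, sum)
  data.frame(
    length = as.integer(names(agg_n)),
    clone_count = as.integer(agg_n),
    frequency = as.numeric(agg_f),
    row.names = NULL
  )
}

#' Top clonotypes by count
#'
#' Clones sorted by count descending; ties broken by CDR3 AA sequence, then
#' V, then J (lexicographically) so the order is deterministic.
#'
#' @param sample a [repertoire_sample()].
#' @param n number of clonotypes to return (default 20).
#' @return the first `min(n, #clones)` rows as a data.frame.
#' @export
top_clonotypes <- function(sample, n = 20L) {
  stopifnot(n >= 1L)
  ord <- order(-sample$count, sample$cdr3_aa, sample$v_hit, sample$j_hit)
  out <- as.data.frame(sample)[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Diversity indices of a repertoire
#'
#' Shannon-Wiener index `H = -sum p_i ln p_i` (in nats) over clone
#' frequencies, inverse Simpson `1 / sum p_i^2`, Chao1 richness
#' `S + f1^2 / (2 f2)` (with `S + f1 (f1 - 1) / 2` when there are no
#' doubletons), evenness `H / ln S`, clonality `1 - H / ln S`, and the mean
#' Shannon-Wiener over repeated multinomial downsamples to a common depth
#' (the resampled mean familiar from VDJtools-style reports, re-implemented
#' here).
#'
#' @param sample a [repertoire_sample()].
#' @param resample_depth downsample depth for the resampled mean; defaults
#'   to the sample's own total count (use the run-wide minimum when
#'   comparing samples).
#' @param resample_reps number of downsampling replicates (default 10).
#' @param seed integer seed for the resampling.
#' @return list of class `diversity_result`.
#' @export
diversity_indices <- function(sample, resample_depth = NULL,
                              resample_reps = 10L, seed = 1L) {
  stopifnot(nrow(sample) > 0L)
  p <- sample$frequency
  s_obs <- nrow(sample)
  h <- -sum(p * log(p))
  inv_simpson <- 1 / sum(p^2)
  f1 <- sum(sample$count == 1)
  f2 <- sum(sample$count == 2)
  chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  evenness <- if (s_obs > 1L) h / log(s_obs) else 0
  clonality <- if (s_obs > 1L) 1 - h / log(s_obs) else 0
  total <- attr(sample, "total_count")
  if (is.null(resample_depth)) resample_depth <- total
  if (resample_depth > total) {
    stop("resample_depth exceeds the sample's total count")
  }
  set.seed(seed)
  h_res <- vapply(seq_len(resample_reps), function(r) {
    counts <- stats::rmultinom(1L, resample_depth, p)[, 1L]
    q <- counts[counts > 0] / resample_depth
    -sum(q * log(q))
  }, numeric(1L))
  structure(list(
    observed_clonotypes = s_obs,
    shannon_wiener = h,
    shannon_mean_resampled = mean(h_res),
    inv_simpson = inv_simpson,
    chao1 = chao1,
    evenness = evenness,
    clonality = clonality
  ), class = "diversity_result")
}

#' Resolve the common rarefaction depth for a run
#'
#' The common depth is the minimum total count over samples, floored at
#' 150,000 when that minimum falls below it (each sample's own curve is
#' still capped at its own total).
#'
#' @param samples list of [repertoire_sample()] objects.
#' @param floor the floor (default 150000).
#' @return integer depth.
#' @export
resolve_n_scaled <- function(samples, floor = 150000L) {
  m <- min(vapply(samples, function(s) attr(s, "total_count"), numeric(1L)))
  as.integer(max(m, floor))
}

#' Rarefaction (diversity) curve of a repertoire
#'
#' At subsample sizes `step, 2 step, ..., n_scaled`, draws that many clone
#' instances without replacement from the count-expanded clone multiset and
#' counts the distinct CDR3 AA sequences, averaged over replicates.
#' Deterministic under the seed. Sizes are capped at the sample's own total
#' count (where the draw is exhaustive and the sd is zero).
#'
#' @param sample a [repertoire_sample()].
#' @param n_scaled largest subsample size (see [resolve_n_scaled()]).
#' @param step size increment (default 2500).
#' @param replicates Monte-Carlo replicates per size (default 10).
#' @param seed integer seed.
#' @return list of class `diversity_curve` with `sample_id`, `points`
#'   (data.frame size, mean_unique, sd), `n_scaled`, `step`, `replicates`,
#'   `seed`.
#' @export
diversity_curve <- function(sample, n_scaled = NULL, step = 2500L,
                            replicates = 10L, seed = 1L) {
  stopifnot(step >= 1L)
  total <- as.integer(attr(sample, "total_count"))
  if (is.null(n_scaled)) n_scaled <- total
  n_scaled <- min(as.integer(n_scaled), total)
  sizes <- unique(c(seq(step, n_scaled, by = step), n_scaled))
  sizes <- sizes[sizes >= 1L]
  if (length(sizes) == 0L) sizes <- n_scaled
  expanded <- rep(seq_len(nrow(sample)), sample$count)
  set.seed(seed)
  pts <- t(vapply(sizes, function(sz) {
    uniq <- vapply(seq_len(replicates), function(r) {
      if (sz >= length(expanded)) {
        length(unique(sample$cdr3_aa))
      } else {
        idx <- sample(expanded, sz)
        length(unique(sample$cdr3_aa[idx]))
      }
    }, numeric(1L))
    c(mean(uniq), stats::sd(uniq))
  }, numeric(2L)))
  structure(list(
    sample_id = sample_id(sample),
    points = data.frame(size = sizes, mean_unique = pts[, 1L], sd = pts[, 2L]),
    n_scaled = n_scaled, step = step, replicates = replicates, seed = seed
  ), class = "diversity_curve")
}

#' Fit a saturating model to a diversity curve
#'
#' Least-squares fit of `f(x) = a x / (b + x)` — a two-parameter saturating
#' form whose asymptote `a` estimates richness and whose half-saturation
#' `b` measures how fast new clonotypes stop appearing. Initialization:
#' `a0` = maximum observed unique count, `b0` = median size. Falls back to
#' Nelder-Mead when `nls` does not converge; `converged` reports the
#' optimizer state and the best iterate is always returned.
#'
#' @param curve a [diversity_curve()] (or data.frame with `size`,
#'   `mean_unique`).
#' @return list of class `curve_fit` with `a`, `b`, `rss`, `converged`.
#' @export
fit_diversity_curve <- function(curve) {
  pts <- if (inherits(curve, "diversity_curve")) curve$points else curve
  if (nrow(pts) < 3L) stop("curve fit needs at least 3 points")
  x <- pts$size
  y <- pts$mean_unique
  a0 <- max(y)
  b0 <- stats::median(x)
  fit <- tryCatch({
    m <- stats::nls(y ~ a * x / (b + x),
      start = list(a = a0, b = b0),
      control = stats::nls.control(maxiter = 200L, warnOnly = FALSE)
    )
    co <- stats::coef(m)
    list(a = unname(co["a"]), b = unname(co["b"]),
      rss = sum(stats::resid(m)^2), converged = TRUE)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(par) sum((y - par[1L] * x / (par[2L] + x))^2)
    o <- stats::optim(c(a0, b0), obj, method = "Nelder-Mead",
      control = list(maxit = 2000L))
    fit <- list(a = o$par[1L], b = o$par[2L], rss = o$value,
      converged = o$convergence == 0L)
  }
  structure(fit, class = "curve_fit")
}

#' Pairwise clonotype overlap as Pearson R-squared
#'
#' For every sample pair, clonotype keys are intersected and the Pearson
#' correlation of the log10 frequencies over the shared clones is computed;
#' the reported statistic is `R^2 = r^2`. Pairs sharing fewer than
#' `min_shared` clones are reported missing (`NA`), not zero. Per-pair
#' scatter tables are emitted for linear-model plots.
#'
#' @param samples named list of [repertoire_sample()] objects (>= 2).
#' @param min_shared minimum shared clonotypes (default 3).
#' @param log_transform correlate log10 frequencies (default `TRUE`).
#' @return list of class `overlap_matrix` with `r_squared` (symmetric
#'   matrix, diagonal 1, `NA` where insufficient overlap), `shared_counts`
#'   and `pair_tables` (named list of data.frames key, freq_a, freq_b).
#' @export
overlap_matrix <- function(samples, min_shared = 3L, log_transform = TRUE) {
  ids <- names(samples)
  stopifnot(length(samples) >= 2L, !is.null(ids))
  k <- length(ids)
  r2 <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  shared_n <- matrix(0L, k, k, dimnames = list(ids, ids))
  diag(r2) <- 1
  pair_tables <- list()
  keys <- lapply(samples, clonotype_key)
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      sh <- intersect(keys[[i]], keys[[j]])
      shared_n[i, j] <- shared_n[j, i] <- length(sh)
      fa <- samples[[i]]$frequency[match(sh, keys[[i]])]
      fb <- samples[[j]]$frequency[match(sh, keys[[j]])]
      pair_tables[[paste(ids[i], ids[j], sep = "&")]] <- data.frame(
        key = sh, freq_a = fa, freq_b = fb, stringsAsFactors = FALSE
      )
      if (length(sh) >= min_shared) {
        xa <- if (log_transform) log10(fa) else fa
        xb <- if (log_transform) log10(fb) else fb
        r <- suppressWarnings(stats::cor(xa, xb))
        r2[i, j] <- r2[j, i] <- if (is.na(r)) NA_real_ else r^2
      }
    }
  }
  diag(shared_n) <- vapply(samples, nrow, integer(1L))
  structure(list(
    r_squared = r2, shared_counts = shared_n, pair_tables = pair_tables,
    min_shared = min_shared, log_transform = log_transform
  ), class = "overlap_matrix")
}

#' V-J gene segment pairing usage
#'
#' Clone-frequency mass per (V, J) pair, sorted descending; the minimal
#' prefix whose cumulative mass reaches the coverage cutoff is retained
#' (chord-diagram display set), and the top-n V and J segments by marginal
#' mass are labeled.
#'
#' @param sample a [repertoire_sample()].
#' @param coverage cumulative mass cutoff (default 0.98).
#' @param top_n segments to label per side (default 5).
#' @return list of class `vj_usage` with `pairs` (data.frame v_hit, j_hit,
#'   mass, retained), `labeled_v`, `labeled_j`, `v_marginal`, `j_marginal`.
#' @export
vj_pairing <- function(sample, coverage = 0.98, top_n = 5L) {
  stopifnot(nrow(sample) > 0L)
  key <- paste(sample$v_hit, sample$j_hit, sep = "\t")
  mass <- tapply(sample$frequency, key, sum)
  parts <- strsplit(names(mass), "\t", fixed = TRUE)
  df <- data.frame(
    v_hit = vapply(parts, `[[`, character(1L), 1L),
    j_hit = vapply(parts, `[[`, character(1L), 2L),
    mass = as.numeric(mass), stringsAsFactors = FALSE
  )
  df <- df[order(-df$mass, df$v_hit, df$j_hit), , drop = FALSE]
  rownames(df) <- NULL
  cum <- cumsum(df$mass)
  n_keep <- which(cum >= coverage - 1e-12)[1L]
  if (is.na(n_keep)) n_keep <- nrow(df)
  df$retained <- seq_len(nrow(df)) <= n_keep
  vm <- sort(tapply(sample$frequency, sample$v_hit, sum), decreasing = TRUE)
  jm <- sort(tapply(sample$frequency, sample$j_hit, sum), decreasing = TRUE)
  structure(list(
    pairs = df,
    labeled_v = names(vm)[seq_len(min(top_n, length(vm)))],
    labeled_j = names(jm)[seq_len(min(top_n, length(jm)))],
    v_marginal = vm, j_marginal = jm, coverage = coverage
  ), class = "vj_usage")
}

#' Segment-usage feature matrix over a sample set
#'
#' Rows are the union of observed V and J segments (prefixed `V:` / `J:`),
#' columns are samples, values are marginal clone-frequency mass; absent
#' segments are 0 so the matrix is rectangular.
#'
#' @param samples named list of [repertoire_sample()] objects.
#' @return numeric matrix.
#' @export
segment_usage_matrix <- function(samples) {
  ids <- names(samples)
  margs <- lapply(samples, function(s) {
    v <- tapply(s$frequency, s$v_hit, sum)
    j <- tapply(s$frequency, s$j_hit, sum)
    c(stats::setNames(as.numeric(v), paste0("V:", names(v))),
      stats::setNames(as.numeric(j), paste0("J:", names(j))))
  })
  feats <- sort(unique(unlist(lapply(margs, names))))
  m <- vapply(margs, function(x) {
    out <- stats::setNames(numeric(length(feats)), feats)
    out[names(x)] <- x
    out
  }, numeric(length(feats)))
  matrix(m, nrow = length(feats), dimnames = list(feats, ids))
}

#' Hierarchical similarity clustering of samples by V/J usage
#'
#' Each sample column of the segment-usage matrix is z-score standardized
#' (constant columns become all-zero), samples are clustered
#' agglomeratively on the standardized features, and flat labels are cut at
#' `k` when requested. The linkage tree is also exported in Newick form.
#'
#' @param samples named list of [repertoire_sample()] objects (>= 2).
#' @param linkage linkage method for [stats::hclust()] (default "average").
#' @param metric distance metric for [stats::dist()] (default "euclidean").
#' @param k optional number of flat clusters.
#' @return list of class `similarity_result` with `features` (standardized
#'   matrix), `tree` (hclust), `newick`, and `clusters` (named labels, when
#'   `k` given).
#' @export
similarity_clustering <- function(samples, linkage = "average",
                                  metric = "euclidean", k = NULL) {
  stopifnot(length(samples) >= 2L)
  m <- segment_usage_matrix(samples)
  std <- apply(m, 2L, function(col) {
    s <- stats::sd(col)
    if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  rownames(std) <- rownames(m)
  d <- stats::dist(t(std), method = metric)
  tree <- stats::hclust(d, method = linkage)
  clusters <- NULL
  if (!is.null(k)) {
    clusters <- stats::cutree(tree, k = k)
  }
  newick <- tryCatch(
    ape::write.tree(ape::as.phylo(tree)),
    error = function(e) NA_character_
  )
  structure(list(
    features = std, tree = tree, newick = newick, clusters = clusters,
    linkage = linkage, metric = metric
  ), class = "similarity_result")
}
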