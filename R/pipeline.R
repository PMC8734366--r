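#' Default run configuration
#'
#' A run configuration is a plain named list: paths, stage toggles and
#' parameters. It can also be read from a declarative file — either JSON or
#' simple `key = value` lines — via [read_run_config()].
#'
#' @return named list of defaults.
#' @export
default_run_config <- function() {
  list(
    # paths
    barcode_file = NULL, fastq_dir = NULL, clonotype_dir = NULL,
    pairs_file = NULL, reference_fasta = NULL, sam_file = NULL,
    undetermined_fastq = NULL, output_dir = "umirep_out",
    # stage toggles
    demux = FALSE, facs = FALSE, contamination = FALSE,
    undetermined = FALSE, stats = TRUE, report = TRUE,
    # parameters
    min_mig_size = 2L, max_fuzzy_mismatch = 1L, fold_threshold = 2,
    quality_threshold = 30, n_limit = 10L, g_fraction_limit = 0.25,
    n_scaled = NULL, step = 2500L, curve_replicates = 10L,
    coverage = 0.98, top_n = 5L, min_shared = 3L,
    linkage = "average", seed = 1L
  )
}

#' Read a run configuration file
#'
#' JSON (file starting with `{`) or `key = value` lines (with `#`
#' comments; values are parsed as logical/numeric where possible). Unknown
#' keys are rejected so typos fail loudly.
#'
#' @param path configuration file.
#' @return named list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  first <- substr(trimws(readLines(path, n = 1L, warn = FALSE)), 1L, 1L)
  user <- if (identical(first, "{")) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- lapply(kv, function(x) {
      v <- trimws(paste(x[-1L], collapse = "="))
      if (v %in% c("TRUE", "true")) return(TRUE)
      if (v %in% c("FALSE", "false")) return(FALSE)
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    stats::setNames(vals, vapply(kv, function(x) trimws(x[1L]), character(1L)))
  }
  config <- default_run_config()
  unknown <- setdiff(names(user), names(config))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  config[names(user)] <- user
  config
}

preflight <- function(config) {
  need <- list()
  add <- function(key) {
    if (is.null(config[[key]])) {
      need[[length(need) + 1L]] <<- paste0("<", key, "> (not set)")
    } else if (!file.exists(config[[key]])) {
      need[[length(need) + 1L]] <<- config[[key]]
    }
  }
  if (isTRUE(config$demux)) {
    add("barcode_file")
    add("fastq_dir")
  }
  if (isTRUE(config$stats) || isTRUE(config$facs)) add("clonotype_dir")
  if (isTRUE(config$facs)) add("pairs_file")
  if (isTRUE(config$undetermined)) {
    add("undetermined_fastq")
    if (is.null(config$sam_file)) add("reference_fasta") else add("sam_file")
  }
  if (length(need) > 0L) {
    stop("pre-flight check failed; missing path(s):\n  ",
      paste(unlist(need), collapse = "\n  "))
  }
}

load_clonotype_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(txt|tsv)$", full.names = TRUE))
  if (length(files) == 0L) stop("no clonotype tables (*.txt|*.tsv) in ", dir)
  samples <- lapply(files, read_clonotype_table)
  stats::setNames(samples, vapply(samples, sample_id, character(1L)))
}

#' Run the pipeline from a configuration
#'
#' Executes the enabled stages in dependency order (demultiplexing ->
#' prep/QC -> statistics -> report). Stages can start mid-pipeline when
#' their inputs exist (e.g. statistics directly from clonotype tables,
#' without any FASTQ). All required paths are validated up front and every
#' missing one is reported at once. All outputs are written under
#' `config$output_dir`; the seed is recorded in the parameter log.
#'
#' @param config named list (see [default_run_config()]); missing keys are
#'   filled with defaults.
#' @return list with `status` (0 on success), `summary` (a
#'   [build_summary()] result when the report stage ran) and per-stage
#'   results.
#' @export
run_pipeline <- function(config) {
  full <- default_run_config()
  unknown <- setdiff(names(config), names(full))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  full[names(config)] <- config
  config <- full
  preflight(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  set.seed(as.integer(config$seed))

  flow <- NULL
  if (isTRUE(config$demux)) {
    specs <- read_barcode_table(config$barcode_file)
    mig_results <- list()
    demux_all <- NULL
    reads <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
      p1 <- file.path(config$fastq_dir, basename(specs$fastq1[i]))
      read_fastq(p1)
    }))
    demux_all <- demultiplex(reads, specs,
      max_fuzzy_mismatch = config$max_fuzzy_mismatch)
    for (sid in specs$sample_id) {
      asm <- assemble_migs(demux_all$assigned[[sid]],
        min_mig_size = config$min_mig_size)
      mig_results[[sid]] <- asm
      write_fastq(asm$consensus,
        file.path(out, paste0(sid, "_consensus.fastq.gz")),
        add_umi_token = TRUE)
    }
    write_fastq(demux_all$undetermined, file.path(out, "undef-m.fastq.gz"))
    flow <- read_flow_summary(demux_all, mig_results)
    utils::write.table(flow$flow, file.path(out, "read_flow.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$demux <- demux_all
    results$migs <- mig_results
    results$read_flow <- flow
  }

  samples <- NULL
  if (isTRUE(config$stats) || isTRUE(config$facs)) {
    samples <- load_clonotype_dir(config$clonotype_dir)
  }

  if (isTRUE(config$facs)) {
    pairs <- read_pairs_file(config$pairs_file)
    facs_results <- list()
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$sample_id_a[i]
      b <- pairs$sample_id_b[i]
      if (!all(c(a, b) %in% names(samples))) {
        stop("pairs file references unloaded sample(s): ", a, ", ", b)
      }
      fc <- facs_correct(samples[[a]], samples[[b]],
        fold_threshold = config$fold_threshold)
      samples[[a]] <- fc$cleaned_a
      samples[[b]] <- fc$cleaned_b
      write_clonotype_table(fc$cleaned_a,
        file.path(out, paste0(a, "_facs_cleaned.txt")))
      write_clonotype_table(fc$cleaned_b,
        file.path(out, paste0(b, "_facs_cleaned.txt")))
      facs_results[[paste(a, b, sep = "&")]] <- fc
    }
    results$facs <- facs_results
  }

  if (isTRUE(config$contamination)) {
    if (is.null(results$migs)) {
      message("contamination stage needs demultiplexed UMI reads; skipped")
    } else {
      triples <- lapply(results$migs, function(asm) {
        data.frame(
          read_id = asm$consensus$read_id, umi = asm$consensus$umi,
          v_hit = NA_character_, j_hit = NA_character_,
          stringsAsFactors = FALSE
        )
      })
      results$contamination <- contamination_analysis(triples)
    }
  }

  und <- NULL
  if (isTRUE(config$undetermined)) {
    und_reads <- read_fastq(config$undetermined_fastq)
    aln <- if (!is.null(config$sam_file)) {
      read_sam(config$sam_file)
    } else {
      naive_map(und_reads, config$reference_fasta)
    }
    und <- classify_undetermined(und_reads, aln,
      quality_threshold = config$quality_threshold,
      n_limit = config$n_limit, g_fraction_limit = config$g_fraction_limit)
    utils::write.table(
      data.frame(group = names(und$counts), reads = as.integer(und$counts)),
      file.path(out, "undetermined_breakdown.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_fastq(und$other_reads, file.path(out, "undetermined_other.fastq"))
    results$undetermined <- und
  }

  diversity <- NULL
  fits <- NULL
  overlap <- NULL
  if (isTRUE(config$stats)) {
    depth <- min(vapply(samples, function(s) attr(s, "total_count"), numeric(1L)))
    diversity <- lapply(samples, diversity_indices,
      resample_depth = depth, seed = as.integer(config$seed))
    n_scaled <- if (!is.null(config$n_scaled)) {
      as.integer(config$n_scaled)
    } else {
      resolve_n_scaled(samples)
    }
    curves <- lapply(samples, diversity_curve, n_scaled = n_scaled,
      step = as.integer(config$step),
      replicates = as.integer(config$curve_replicates),
      seed = as.integer(config$seed))
    fits <- lapply(curves, function(cv) {
      if (nrow(cv$points) >= 3L) fit_diversity_curve(cv) else
        structure(list(a = NA_real_, b = NA_real_, rss = NA_real_,
          converged = FALSE), class = "curve_fit")
    })
    if (length(samples) >= 2L) {
      overlap <- overlap_matrix(samples, min_shared = config$min_shared)
    }
    vj <- lapply(samples, vj_pairing, coverage = config$coverage,
      top_n = config$top_n)
    for (sid in names(samples)) {
      utils::write.table(vj[[sid]]$pairs,
        file.path(out, paste0(sid, "_vj_pairs.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(samples) >= 2L) {
      sim <- similarity_clustering(samples, linkage = config$linkage)
      writeLines(sim$newick, file.path(out, "similarity_tree.nwk"))
      results$similarity <- sim
    }
    results$diversity <- diversity
    results$curves <- curves
    results$curve_fits <- fits
    results$overlap <- overlap
    results$vj <- vj
  }

  summary <- NULL
  if (isTRUE(config$report) && !is.null(samples)) {
    summary <- build_summary(
      samples,
      read_flow = flow, diversity = diversity, curve_fits = fits,
      overlap = overlap, undetermined = und,
      barcode_specs = if (isTRUE(config$demux)) {
        read_barcode_table(config$barcode_file)
      } else {
        NULL
      },
      parameters = config[c(
        "min_mig_size", "max_fuzzy_mismatch", "fold_threshold",
        "quality_threshold", "n_limit", "g_fraction_limit", "step",
        "coverage", "top_n", "min_shared", "linkage", "seed"
      )],
      out_dir = out
    )
    export_ml_features(
      samples, diversity, curve_fits = fits,
      ml_file = file.path(out, "ml.csv"),
      ml_norm_file = file.path(out, "ml_norm.csv")
    )
    results$summary <- summary
  }
  list(status = 0L, summary = summary, results = results)
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages: `run` executes whatever the
#' config enables; `demux`, `qc`, `stats`, `report` force-enable the
#' corresponding stage group. Usage:
#' `umirep <run|demux|qc|stats|report> --config PATH [--seed INT] [--outdir PATH]`.
#'
#' @param args character vector of CLI arguments (default: from the
#'   command line).
#' @return exit status, invisibly.
#' @export
umirep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    message("usage: umirep <run|demux|qc|stats|report> --config PATH ",
      "[--seed INT] [--outdir PATH]")
    return(invisible(2L))
  }
  cmd <- args[1L]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
  }
  config_path <- opt("--config")
  if (is.null(config_path)) stop("--config PATH is required")
  config <- read_run_config(config_path)
  if (!is.null(opt("--seed"))) config$seed <- as.integer(opt("--seed"))
  if (!is.null(opt("--outdir"))) config$output_dir <- opt("--outdir")
  toggles <- switch(cmd,
    run = NULL,
    demux = list(demux = TRUE, stats = FALSE, report = FALSE),
    qc = list(facs = TRUE, undetermined = TRUE, stats = FALSE, report = FALSE),
    stats = list(stats = TRUE, report = FALSE),
    report = list(stats = TRUE, report = TRUE),
    stop("unknown subcommand: ", cmd)
  )
  if (!is.null(toggles)) config[names(toggles)] <- toggles
  res <- run_pipeline(config)
  invisible(res$status)
}
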