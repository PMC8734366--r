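#' Assemble the run summary
#'
#' Collects every stage's key numbers into one structure and, when
#' `out_dir` is given, mirrors each section as a tab-delimited "sheet"
#' under `out_dir/summary/` (one TSV per sheet; no binary workbook is
#' produced — the information content is the data). Sections whose stage
#' did not run are marked skipped rather than omitted.
#'
#' @param samples named list of [repertoire_sample()] objects (required).
#' @param read_flow optional [read_flow_summary()] result.
#' @param diversity optional named list of [diversity_indices()] results.
#' @param curve_fits optional named list of [fit_diversity_curve()] results.
#' @param overlap optional [overlap_matrix()] result.
#' @param undetermined optional [classify_undetermined()] result.
#' @param barcode_specs optional `barcode_table` (sample info sheet).
#' @param parameters optional named list of run parameters to log.
#' @param out_dir optional output directory.
#' @return list of class `run_summary` with one data.frame per sheet.
#' @export
build_summary <- function(samples, read_flow = NULL, diversity = NULL,
                          curve_fits = NULL, overlap = NULL,
                          undetermined = NULL, barcode_specs = NULL,
                          parameters = NULL, out_dir = NULL) {
  stopifnot(length(samples) >= 1L)
  ids <- names(samples)
  skipped <- function(section) {
    data.frame(section = section, status = "skipped", stringsAsFactors = FALSE)
  }

  sheets <- list()
  sheets$sample_info <- if (!is.null(barcode_specs)) {
    as.data.frame(barcode_specs)
  } else {
    skipped("sample_info")
  }
  sheets$read_counts <- if (!is.null(read_flow)) {
    read_flow$per_sample
  } else {
    skipped("read_counts")
  }

  # clone stats: count plus CDR3 AA length mean/sd, both clone-unweighted
  # and frequency-weighted (the field uses either convention)
  sheets$clone_stats <- do.call(rbind, lapply(ids, function(sid) {
    s <- samples[[sid]]
    len <- nchar(s$cdr3_aa)
    wmean <- sum(len * s$frequency)
    wsd <- sqrt(sum(s$frequency * (len - wmean)^2))
    data.frame(
      sample_id = sid, clone_count = nrow(s),
      total_count = attr(s, "total_count"),
      cdr3_len_mean = mean(len), cdr3_len_sd = stats::sd(len),
      cdr3_len_mean_weighted = wmean, cdr3_len_sd_weighted = wsd,
      stringsAsFactors = FALSE
    )
  }))

  sheets$diversity <- if (!is.null(diversity)) {
    do.call(rbind, lapply(ids, function(sid) {
      d <- diversity[[sid]]
      data.frame(
        sample_id = sid, observed_clonotypes = d$observed_clonotypes,
        shannon_wiener = d$shannon_wiener,
        shannon_mean_resampled = d$shannon_mean_resampled,
        inv_simpson = d$inv_simpson, chao1 = d$chao1,
        evenness = d$evenness, clonality = d$clonality,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    skipped("diversity")
  }

  sheets$curve_fits <- if (!is.null(curve_fits)) {
    do.call(rbind, lapply(ids, function(sid) {
      f <- curve_fits[[sid]]
      data.frame(
        sample_id = sid, a = f$a, b = f$b, rss = f$rss,
        converged = f$converged, stringsAsFactors = FALSE
      )
    }))
  } else {
    skipped("curve_fits")
  }

  sheets$overlap <- if (!is.null(overlap)) {
    cbind(
      data.frame(sample_id = rownames(overlap$r_squared), stringsAsFactors = FALSE),
      as.data.frame(overlap$r_squared)
    )
  } else {
    skipped("overlap")
  }

  usage <- segment_usage_matrix(samples)
  sheets$vdj_frequencies <- cbind(
    data.frame(segment = rownames(usage), stringsAsFactors = FALSE),
    as.data.frame(usage)
  )

  sheets$undetermined <- if (!is.null(undetermined)) {
    data.frame(
      group = names(undetermined$counts),
      reads = as.integer(undetermined$counts), stringsAsFactors = FALSE
    )
  } else {
    skipped("undetermined")
  }

  sheets$parameters <- if (!is.null(parameters)) {
    data.frame(
      parameter = names(parameters),
      value = vapply(parameters, function(x) paste(format(x), collapse = ","),
        character(1L)),
      stringsAsFactors = FALSE
    )
  } else {
    skipped("parameters")
  }

  if (!is.null(out_dir)) {
    dir <- file.path(out_dir, "summary")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(sheets)) {
      utils::write.table(sheets[[nm]], file.path(dir, paste0(nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  structure(sheets, class = "run_summary")
}

#' Export machine-learning feature tables
#'
#' One row per sample. `ml` holds the diversity indices, the curve-fit
#' parameters and per-segment clone-count mass; `ml_norm` holds the same
#' with segment columns converted to frequencies normalized within each
#' segment class (V, D, J sum to 1 per row). Segment universes are unioned
#' across samples with zeros for absent segments. Files are tab-delimited
#' (despite the conventional `.csv` names).
#'
#' @param samples named list of [repertoire_sample()] objects.
#' @param diversity named list of [diversity_indices()] results.
#' @param curve_fits optional named list of [fit_diversity_curve()] results.
#' @param target optional vector (one per sample) appended as a `target`
#'   column for supervised learning.
#' @param ml_file,ml_norm_file optional output paths.
#' @return list with data.frames `ml` and `ml_norm`.
#' @export
export_ml_features <- function(samples, diversity, curve_fits = NULL,
                               target = NULL, ml_file = NULL,
                               ml_norm_file = NULL) {
  ids <- names(samples)
  stopifnot(all(ids %in% names(diversity)))

  seg_mass <- function(s, hits) {
    hits_ok <- !is.na(hits)
    if (!any(hits_ok)) return(stats::setNames(numeric(0L), character(0L)))
    m <- tapply(s$count[hits_ok], hits[hits_ok], sum)
    stats::setNames(as.numeric(m), names(m))
  }
  per_sample <- lapply(ids, function(sid) {
    s <- samples[[sid]]
    list(
      V = seg_mass(s, s$v_hit), D = seg_mass(s, s$d_hit),
      J = seg_mass(s, s$j_hit)
    )
  })
  names(per_sample) <- ids
  universe <- lapply(c(V = "V", D = "D", J = "J"), function(cls) {
    sort(unique(unlist(lapply(per_sample, function(x) names(x[[cls]])))))
  })

  base_row <- function(sid) {
    d <- diversity[[sid]]
    row <- data.frame(
      sample_id = sid,
      observed_clonotypes = d$observed_clonotypes,
      shannon_wiener = d$shannon_wiener,
      shannon_mean_resampled = d$shannon_mean_resampled,
      inv_simpson = d$inv_simpson, chao1 = d$chao1,
      evenness = d$evenness, clonality = d$clonality,
      stringsAsFactors = FALSE
    )
    if (!is.null(curve_fits)) {
      row$curve_a <- curve_fits[[sid]]$a
      row$curve_b <- curve_fits[[sid]]$b
    }
    row
  }
  seg_cols <- function(sid, normalize) {
    unlist(lapply(names(universe), function(cls) {
      segs <- universe[[cls]]
      if (length(segs) == 0L) return(NULL)
      vals <- stats::setNames(numeric(length(segs)), segs)
      have <- per_sample[[sid]][[cls]]
      vals[names(have)] <- have
      if (normalize && sum(vals) > 0) vals <- vals / sum(vals)
      stats::setNames(vals, paste0(cls, "_", segs))
    }))
  }
  assemble <- function(normalize) {
    rows <- lapply(ids, function(sid) {
      cbind(base_row(sid), as.data.frame(as.list(seg_cols(sid, normalize)),
        check.names = FALSE, optional = TRUE))
    })
    out <- do.call(rbind, rows)
    if (!is.null(target)) out$target <- target
    rownames(out) <- NULL
    out
  }
  ml <- assemble(normalize = FALSE)
  ml_norm <- assemble(normalize = TRUE)
  write_one <- function(df, path) {
    if (!is.null(path)) {
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_one(ml, ml_file)
  write_one(ml_norm, ml_norm_file)
  list(ml = ml, ml_norm = ml_norm)
}
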