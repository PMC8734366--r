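#' Construct a repertoire sample
#'
#' A repertoire sample is an ordered collection of clonotypes for one
#' biological sample. A clonotype is identified by its CDR3 amino-acid
#' sequence together with its V and J gene segment calls; rows sharing that
#' key are merged by summing counts. Frequencies are always recomputed from
#' counts, never trusted from input, because downstream subsetting stages
#' (e.g. cell-subset disambiguation) invalidate stored fractions.
#'
#' @param clonotypes data.frame with columns `count`, `cdr3_nt`, `cdr3_aa`,
#'   `v_hit`, `j_hit` and optionally `d_hit`. `frequency` is recomputed.
#' @param sample_id single non-empty string naming the sample.
#' @return A `repertoire_sample`: a data.frame with columns `count`,
#'   `frequency`, `cdr3_nt`, `cdr3_aa`, `v_hit`, `d_hit`, `j_hit` and
#'   attributes `sample_id` and `total_count`.
#' @export
repertoire_sample <- function(clonotypes, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  req <- c("count", "cdr3_nt", "cdr3_aa", "v_hit", "j_hit")
  miss <- setdiff(req, names(clonotypes))
  if (length(miss) > 0L) {
    stop("clonotype table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(clonotypes, stringsAsFactors = FALSE)
  if (is.null(df$d_hit)) df$d_hit <- NA_character_
  if (nrow(df) == 0L) stop("repertoire sample '", sample_id, "' has no clonotypes")
  if (!is.numeric(df$count) || anyNA(df$count)) {
    stop("non-numeric clone count in sample '", sample_id, "'")
  }
  if (any(df$count < 1)) stop("clonotype counts must be >= 1")
  if (any(nchar(df$cdr3_aa) < 1L)) stop("empty CDR3 amino-acid sequence")

  key <- clonotype_key(df)
  if (anyDuplicated(key)) {
    df$count <- as.numeric(ave(df$count, key, FUN = sum))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df$frequency <- df$count / sum(df$count)
  df <- df[, c("count", "frequency", "cdr3_nt", "cdr3_aa", "v_hit", "d_hit", "j_hit")]
  rownames(df) <- NULL
  structure(df,
    sample_id = sample_id,
    total_count = sum(df$count),
    class = c("repertoire_sample", "data.frame")
  )
}

#' Clonotype identity key
#'
#' @param x repertoire sample or data.frame with `cdr3_aa`, `v_hit`, `j_hit`.
#' @return character vector of `cdr3_aa|v_hit|j_hit` keys.
#' @export
clonotype_key <- function(x) {
  paste(x$cdr3_aa, x$v_hit, x$j_hit, sep = "|")
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf(
    "repertoire_sample '%s': %d clonotypes, total count %s\n",
    attr(x, "sample_id"), nrow(x), format(attr(x, "total_count"))
  ))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' @export
sample_id <- function(x) attr(x, "sample_id")

#' @export
total_count <- function(x) attr(x, "total_count")

# Rebuild a repertoire_sample after filtering rows, keeping the sample id.
resample_from_rows <- function(x, rows) {
  repertoire_sample(as.data.frame(x)[rows, , drop = FALSE], sample_id(x))
}
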