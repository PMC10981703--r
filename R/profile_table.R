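#' Construct a profile table
#'
#' Couples a sample-by-SGB relative-abundance matrix (values in percent, as
#' written by marker-gene profilers) with per-sample metadata. Invariants are
#' checked on construction: nonnegative abundances, per-sample sums at most
#' 100 (a small tolerance allows rounding; an unclassified fraction below
#' 100% is permitted), unique sample ids, and a metadata row for every sample.
#'
#' @param abundances Numeric matrix, samples in rows, SGBs in columns, percent
#'   relative abundances. Dimnames required.
#' @param metadata `data.frame` with a `sample_id` column covering every row of
#'   `abundances`; typically also `patient_id`, `material` (metallic/plastic),
#'   `procedure` (endoscopy/surgery), `patency_days`, `microbial_reads`, `age`,
#'   `sex` and optional clinical scores.
#' @return An object of class `profile_table`.
#' @export
profile_table <- function(abundances, metadata) {
  stop_unless(is.matrix(abundances) && is.numeric(abundances),
              "abundances must be a numeric matrix")
  stop_unless(!is.null(rownames(abundances)) && !is.null(colnames(abundances)),
              "abundances must carry sample (row) and SGB (column) names")
  stop_unless(!anyDuplicated(rownames(abundances)), "sample ids must be unique")
  stop_unless(!anyDuplicated(colnames(abundances)), "SGB ids must be unique")
  stop_unless(all(abundances >= 0), "abundances must be nonnegative")
  sums <- rowSums(abundances)
  stop_unless(all(sums <= 100 + 1e-6),
              "per-sample abundance sums must not exceed 100 (percent scale)")
  stop_unless(is.data.frame(metadata) && "sample_id" %in% names(metadata),
              "metadata must be a data.frame with a sample_id column")
  missing <- setdiff(rownames(abundances), metadata$sample_id)
  if (length(missing) > 0) {
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  metadata <- metadata[match(rownames(abundances), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(abundances = abundances, metadata = metadata),
            class = "profile_table")
}

#' @export
print.profile_table <- function(x, ...) {
  cat(sprintf("profile_table: %d samples x %d SGBs\n",
              nrow(x$abundances), ncol(x$abundances)))
  cat(sprintf("  mean per-sample sum: %.2f%%\n", mean(rowSums(x$abundances))))
  cat("  metadata columns: ", paste(names(x$metadata), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.profile_table <- function(x) dim(x$abundances)

#' Sample identifiers of a profile table
#' @param t A `profile_table`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(t) rownames(t$abundances)

#' SGB identifiers of a profile table
#' @param t A `profile_table`.
#' @return Character vector of SGB ids.
#' @export
sgb_ids <- function(t) colnames(t$abundances)

#' Read a merged species-abundance table plus sample metadata
#'
#' Reads a MetaPhlAn-4-style merged relative-abundance TSV (rows are clades
#' down the taxonomy, columns are samples, values are percent relative
#' abundances; the first column holds the clade name with ranks separated by
#' `|`) and keeps only the deepest-level rows: SGB-level rows (`t__` prefix)
#' where any are present, otherwise species-level rows (`s__`). Intermediate
#' clade rows (kingdom through genus) are discarded. The matrix is transposed
#' to the sample-by-SGB orientation and joined with per-sample metadata.
#'
#' Lines starting with `#` are treated as comments in both files.
#'
#' @param path Path to the merged abundance TSV.
#' @param metadata_path Path to a metadata TSV with a `sample_id` column.
#' @return A [profile_table()].
#' @export
read_profile_table <- function(path, metadata_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  stop_unless(ncol(raw) >= 2, "abundance table needs a clade column plus samples")
  clade_col <- names(raw)[1]
  samples <- names(raw)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicated sample column(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  }
  clades <- as.character(raw[[clade_col]])
  last_rank <- vapply(strsplit(clades, "|", fixed = TRUE),
                      function(p) p[length(p)], character(1))
  has_sgb <- grepl("^t__", last_rank)
  keep <- if (any(has_sgb)) has_sgb else grepl("^s__", last_rank)
  stop_unless(any(keep), "no species/SGB-level rows found in abundance table")
  mat <- t(as.matrix(raw[keep, -1, drop = FALSE]))
  mode(mat) <- "numeric"
  colnames(mat) <- last_rank[keep]
  rownames(mat) <- samples
  metadata <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                                comment.char = "#", check.names = FALSE,
                                stringsAsFactors = FALSE)
  profile_table(mat, metadata)
}

#' Write a profile table (abundances + metadata) to TSV
#'
#' Inverse of [read_profile_table()]: writes the abundance matrix in merged
#' profiler orientation (rows = SGBs, columns = samples) and the metadata as a
#' plain TSV. A read of the written pair reproduces abundances to at least six
#' decimal places and metadata exactly.
#'
#' @param t A [profile_table()].
#' @param path Output path for the abundance TSV.
#' @param metadata_path Output path for the metadata TSV.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(t, path, metadata_path) {
  out <- data.frame(clade_name = colnames(t$abundances),
                    t(t$abundances), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(t$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Drop samples below the microbial-read retention threshold
#'
#' Applies the study's sample-retention rule: a sample is kept only when its
#' microbial read count is strictly greater than `cfg$min_microbial_reads`
#' (default two million). Dropped sample ids are reported via `message()`.
#'
#' @param t A [profile_table()] whose metadata has a `microbial_reads` column.
#' @param cfg An [analysis_config()].
#' @return The filtered `profile_table`.
#' @export
filter_low_depth_samples <- function(t, cfg = analysis_config()) {
  stop_unless("microbial_reads" %in% names(t$metadata),
              "metadata must contain microbial_reads")
  stop_unless(!anyNA(t$metadata$microbial_reads),
              "microbial_reads must be present for every sample")
  keep <- t$metadata$microbial_reads > cfg$min_microbial_reads
  if (!any(keep)) {
    stop("all samples fall at or below the read threshold (",
         format(cfg$min_microbial_reads, big.mark = ","), ")", call. = FALSE)
  }
  if (any(!keep)) {
    message("dropped ", sum(!keep), " low-depth sample(s): ",
            paste(t$metadata$sample_id[!keep], collapse = ", "))
  }
  profile_table(t$abundances[keep, , drop = FALSE],
                t$metadata[keep, , drop = FALSE])
}
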