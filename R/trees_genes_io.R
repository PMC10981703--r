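#' Build a strain tree from a phylo object
#'
#' Wraps an `ape::phylo` tree with the leaf-to-sample bookkeeping the
#' strain-sharing analysis needs: which patient each leaf belongs to, whether
#' the leaf is a metagenome-derived or isolate sequence, and the total branch
#' length used to normalize patristic distances.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param patient_of Named character vector mapping leaf label to patient id.
#'   Leaves without a mapping are dropped with a warning.
#' @param source_of Optional named character vector mapping leaf label to
#'   `"metagenome"` or `"isolate"`; defaults to `"metagenome"` for all leaves.
#' @return An object of class `strain_tree`: a list with elements `tree`,
#'   `patient_of`, `source_of` and `total_branch_length`.
#' @export
as_strain_tree <- function(tree, patient_of, source_of = NULL) {
  stop_unless(inherits(tree, "phylo"), "tree must be an ape phylo object")
  stop_unless(!is.null(tree$edge.length), "tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree", call. = FALSE)
  unmapped <- setdiff(tree$tip.label, names(patient_of))
  if (length(unmapped) > 0) {
    warning("dropping ", length(unmapped), " leaf/leaves without patient mapping: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
    if (length(unmapped) >= length(tree$tip.label) - 1L) {
      stop("fewer than two mapped leaves remain", call. = FALSE)
    }
    tree <- ape::drop.tip(tree, unmapped)
  }
  leaves <- tree$tip.label
  if (is.null(source_of)) {
    source_of <- stats::setNames(rep("metagenome", length(leaves)), leaves)
  }
  total <- sum(tree$edge.length)
  stop_unless(total > 0, "total branch length must be positive")
  structure(list(tree = tree,
                 patient_of = patient_of[leaves],
                 source_of = source_of[leaves],
                 total_branch_length = total),
            class = "strain_tree")
}

#' @export
print.strain_tree <- function(x, ...) {
  cat(sprintf("strain_tree: %d leaves, %d patients, total branch length %.4g\n",
              length(x$tree$tip.label), length(unique(x$patient_of)),
              x$total_branch_length))
  invisible(x)
}

#' Read a newick strain tree with sample-named leaves
#'
#' Parses a newick file (as produced by strain-level phylogenetic profilers),
#' checks branch lengths, and resolves each leaf to a patient through the
#' sample metadata. Leaves whose label is not a known sample id are excluded
#' with a warning; a negative branch length is an error.
#'
#' @param path Newick file path.
#' @param metadata `data.frame` with `sample_id` and `patient_id` columns; may
#'   also carry a `source` column (metagenome/isolate).
#' @return A [as_strain_tree()] object.
#' @export
read_newick_tree <- function(path, metadata) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path, call. = FALSE)
  stop_unless(is.data.frame(metadata) &&
                all(c("sample_id", "patient_id") %in% names(metadata)),
              "metadata must contain sample_id and patient_id")
  patient_of <- stats::setNames(as.character(metadata$patient_id),
                                metadata$sample_id)
  source_of <- NULL
  if ("source" %in% names(metadata)) {
    source_of <- stats::setNames(as.character(metadata$source), metadata$sample_id)
  }
  as_strain_tree(tree, patient_of, source_of)
}

#' Read a gene-hit table
#'
#' Reads a TSV of candidate gene-to-cluster alignments with columns `gene_id`,
#' `cluster_id`, `identity`, `coverage` and `class`. Identities arrive on the
#' 0-100 percent scale and are normalized to fractions; coverage may be a
#' fraction in `[0,1]` or a percent (declared by naming the column
#' `coverage_pct`, or detected when values exceed 1). An identity above 100 is
#' an error. When `known_classes` is given, unknown class labels are retained
#' as `"other"` with a warning.
#'
#' @param path Gene-hit TSV path.
#' @param known_classes Optional character vector of recognized functional
#'   class labels (AMR drug classes, biofilm GO labels).
#' @return `data.frame` with columns `gene_id`, `cluster_id`, `identity`,
#'   `coverage` (both fractions in `[0,1]`) and `class`.
#' @export
read_gene_hits <- function(path, known_classes = NULL) {
  hits <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(hits) == 0) {
    warning("empty gene-hit table: ", path, call. = FALSE)
    return(data.frame(gene_id = character(), cluster_id = character(),
                      identity = numeric(), coverage = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  }
  cov_col <- if ("coverage_pct" %in% names(hits)) "coverage_pct" else "coverage"
  need <- c("gene_id", "cluster_id", "identity", cov_col, "class")
  missing <- setdiff(need, names(hits))
  stop_unless(length(missing) == 0,
              paste("gene-hit table missing column(s):",
                    paste(missing, collapse = ", ")))
  identity <- as.numeric(hits$identity)
  if (any(identity > 100)) stop("identity above 100 in gene-hit table", call. = FALSE)
  identity <- identity / 100
  coverage <- as.numeric(hits[[cov_col]])
  if (cov_col == "coverage_pct" || any(coverage > 1)) coverage <- coverage / 100
  stop_unless(all(coverage >= 0 & coverage <= 1), "coverage outside [0, 1]")
  cls <- as.character(hits$class)
  if (!is.null(known_classes)) {
    unknown <- !(cls %in% known_classes)
    if (any(unknown)) {
      warning("unknown class label(s) retained as 'other': ",
              paste(unique(cls[unknown]), collapse = ", "), call. = FALSE)
      cls[unknown] <- "other"
    }
  }
  data.frame(gene_id = as.character(hits$gene_id),
             cluster_id = as.character(hits$cluster_id),
             identity = identity, coverage = coverage, class = cls,
             stringsAsFactors = FALSE)
}
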