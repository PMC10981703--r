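#' Patristic distance matrix of a strain tree
#'
#' Pairwise leaf-to-leaf distances as the sum of branch lengths along the
#' connecting path, via [ape::cophenetic.phylo()].
#'
#' @param tree A `strain_tree` (see [as_strain_tree()]) or an `ape::phylo`.
#' @return Symmetric matrix with zero diagonal, leaves as dimnames.
#' @export
patristic_distances <- function(tree) {
  phy <- if (inherits(tree, "strain_tree")) tree$tree else tree
  stop_unless(inherits(phy, "phylo"), "tree must be a phylo or strain_tree")
  d <- ape::cophenetic.phylo(phy)
  d[order(rownames(d)), order(colnames(d)), drop = FALSE]
}

#' Detect strain sharing and within-patient persistence
#'
#' Normalizes every pairwise patristic distance by the tree's total branch
#' length and reports leaf pairs at or below the strain cutoff
#' (`cfg$strain_distance_cutoff`, default 0.01; the boundary is inclusive).
#' Pairs from different patients are strain-sharing events; pairs from the
#' same patient are reported separately as persistence of a strain within a
#' patient, not sharing. Pairs are deduplicated (each unordered pair appears
#' once).
#'
#' @param tree A `strain_tree`.
#' @param cfg An [analysis_config()].
#' @return List with two `data.frame`s, `sharing` and `persistence`, each with
#'   columns `leaf_a`, `leaf_b`, `patient_a`, `patient_b`,
#'   `normalized_distance`.
#' @export
detect_strain_sharing <- function(tree, cfg = analysis_config()) {
  stop_unless(inherits(tree, "strain_tree"), "tree must be a strain_tree")
  total <- tree$total_branch_length
  if (total <= 0) stop("total branch length must be positive", call. = FALSE)
  d <- patristic_distances(tree) / total
  leaves <- rownames(d)
  pat <- tree$patient_of[leaves]
  idx <- which(upper.tri(d) & d <= cfg$strain_distance_cutoff, arr.ind = TRUE)
  events <- data.frame(leaf_a = leaves[idx[, 1]], leaf_b = leaves[idx[, 2]],
                       patient_a = unname(pat[idx[, 1]]),
                       patient_b = unname(pat[idx[, 2]]),
                       normalized_distance = d[idx],
                       stringsAsFactors = FALSE)
  cross <- events$patient_a != events$patient_b
  list(sharing = events[cross, , drop = FALSE],
       persistence = events[!cross, , drop = FALSE])
}
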