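#' Gene-to-cluster assignment rule
#'
#' A candidate hit is assigned to its reference cluster only when the mean
#' sequence identity to the cluster centroid is strictly above
#' `cfg$identity_threshold` (default 0.90) AND the hit covers strictly more
#' than `cfg$coverage_threshold` (default 0.80) of the centroid sequence.
#' Both boundaries are exclusive: identity exactly 0.90 or coverage exactly
#' 0.80 is rejected. Vectorized over rows of a gene-hit table.
#'
#' @param hits `data.frame` with `identity` and `coverage` columns as
#'   fractions in `[0,1]` (see [read_gene_hits()]).
#' @param cfg An [analysis_config()].
#' @return Logical vector: `TRUE` where the hit is assigned.
#' @export
assign_gene_cluster <- function(hits, cfg = analysis_config()) {
  stop_unless(all(hits$identity >= 0 & hits$identity <= 1),
              "identity must be a fraction in [0, 1]")
  stop_unless(all(hits$coverage >= 0 & hits$coverage <= 1),
              "coverage must be a fraction in [0, 1]")
  hits$identity > cfg$identity_threshold & hits$coverage > cfg$coverage_threshold
}

#' Pangenome prevalence of a gene cluster
#'
#' Fraction of a species' reference genomes that carry a given cluster,
#' computed from a genome catalog mapping each genome to its set of clusters.
#'
#' @param cluster_id Cluster identifier.
#' @param genome_annotations Named list: genome id -> character vector of
#'   cluster ids carried by that genome. Must be nonempty.
#' @return Fraction in `[0,1]`.
#' @export
pangenome_prevalence <- function(cluster_id, genome_annotations) {
  stop_unless(length(genome_annotations) >= 1,
              "genome catalog must contain at least one genome")
  carriers <- vapply(genome_annotations,
                     function(cl) cluster_id %in% cl, logical(1))
  sum(carriers) / length(genome_annotations)
}

#' Specificity class of a gene cluster
#'
#' Labels a cluster by how typical it is of the species' wider pangenome:
#' `stent_specific` when its pangenome prevalence is strictly below
#' `cfg$pangenome_specific_max` (default 0.20), `shared` when strictly above
#' `cfg$pangenome_shared_min` (default 0.90), otherwise `intermediate`.
#' Vectorized over prevalences.
#'
#' @param pangenome_prevalence Numeric vector of prevalences in `[0,1]`.
#' @param cfg An [analysis_config()].
#' @return Character vector of labels.
#' @export
classify_gene_specificity <- function(pangenome_prevalence, cfg = analysis_config()) {
  stop_unless(all(pangenome_prevalence >= 0 & pangenome_prevalence <= 1),
              "prevalence must lie in [0, 1]")
  ifelse(pangenome_prevalence < cfg$pangenome_specific_max, "stent_specific",
         ifelse(pangenome_prevalence > cfg$pangenome_shared_min, "shared",
                "intermediate"))
}

#' Strain-by-class resistance/biofilm presence matrix
#'
#' Collapses assigned gene hits to a strain x functional-class presence table:
#' a strain carries a class when it has at least one assigned gene of that
#' class (duplicate hits are idempotent). Classes with no assigned gene are
#' absent from the output. Per-class prevalence across strains is reported
#' alongside.
#'
#' @param hits Gene-hit `data.frame` with a `strain_id` column plus the
#'   [read_gene_hits()] columns.
#' @param assigned Logical vector from [assign_gene_cluster()], same length as
#'   `nrow(hits)`.
#' @return List with `presence` (logical strain x class matrix) and
#'   `class_prevalence` (`data.frame` of per-class carrier fractions).
#' @export
resistance_class_matrix <- function(hits, assigned) {
  stop_unless("strain_id" %in% names(hits), "hits must have a strain_id column")
  stop_unless(length(assigned) == nrow(hits), "assigned must match hits rows")
  strains <- sort(unique(hits$strain_id))
  kept <- hits[assigned, , drop = FALSE]
  classes <- sort(unique(kept$class))
  presence <- matrix(FALSE, nrow = length(strains), ncol = length(classes),
                     dimnames = list(strains, classes))
  if (nrow(kept) > 0) {
    presence[cbind(match(kept$strain_id, strains), match(kept$class, classes))] <- TRUE
  }
  list(presence = presence,
       class_prevalence = data.frame(
         class = classes,
         n_strains = as.integer(colSums(presence)),
         prevalence = colSums(presence) / length(strains),
         stringsAsFactors = FALSE, row.names = NULL))
}
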