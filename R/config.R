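#' Analysis configuration
#'
#' Collects every numeric threshold used by the pipeline in one validated
#' object, so that each decision rule (sample retention, prevalence calls,
#' disease-association calls, strain-sharing cutoff, gene-assignment gates,
#' pangenome specificity classes) is surfaced and recorded in the run
#' manifest rather than hidden in function defaults.
#'
#' @param min_microbial_reads Samples are retained only if their microbial
#'   read count is strictly greater than this (default 2e6, the ">2 M
#'   microbial reads" retention rule).
#' @param detection_threshold An SGB counts as detected in a sample when its
#'   relative abundance is strictly greater than this (default 0: profilers
#'   report exact zeros for undetected species).
#' @param prevalence_cutoff An SGB is flagged prevalent when its stent
#'   prevalence exceeds this fraction (default 0.30).
#' @param oral_prevalence_cutoff An SGB is an oral-microbiome member when its
#'   reference prevalence in healthy oral samples exceeds this (default 0.50,
#'   strict).
#' @param fdr_threshold BH-adjusted p below which a disease association may be
#'   called (default 0.2, strict).
#' @param effect_threshold Absolute pooled standardized mean difference above
#'   which an association may be called (default 0.2, strict).
#' @param strain_distance_cutoff Normalized patristic distance at or below
#'   which two leaves carry the same strain (default 0.01, inclusive).
#' @param identity_threshold Fractional sequence identity to the cluster
#'   centroid that a gene hit must exceed to be assigned (default 0.90,
#'   strict).
#' @param coverage_threshold Fraction of the centroid sequence that must be
#'   covered, exceeded strictly (default 0.80).
#' @param pangenome_specific_max Pangenome prevalence strictly below which a
#'   gene cluster is stent-specific (default 0.20).
#' @param pangenome_shared_min Pangenome prevalence strictly above which a
#'   cluster is shared with the wider species pangenome (default 0.90).
#' @param n_permutations Number of label permutations for PERMANOVA
#'   (default 9999).
#' @param rng_seed Integer seed recorded in the manifest and used to seed
#'   every stochastic stage.
#'
#' @return An object of class `analysis_config` (a validated named list).
#' @examples
#' cfg <- analysis_config(rng_seed = 1)
#' cfg$prevalence_cutoff
#' @export
analysis_config <- function(min_microbial_reads = 2e6,
                            detection_threshold = 0,
                            prevalence_cutoff = 0.30,
                            oral_prevalence_cutoff = 0.50,
                            fdr_threshold = 0.2,
                            effect_threshold = 0.2,
                            strain_distance_cutoff = 0.01,
                            identity_threshold = 0.90,
                            coverage_threshold = 0.80,
                            pangenome_specific_max = 0.20,
                            pangenome_shared_min = 0.90,
                            n_permutations = 9999,
                            rng_seed = 42L) {
  cfg <- list(
    min_microbial_reads = min_microbial_reads,
    detection_threshold = detection_threshold,
    prevalence_cutoff = prevalence_cutoff,
    oral_prevalence_cutoff = oral_prevalence_cutoff,
    fdr_threshold = fdr_threshold,
    effect_threshold = effect_threshold,
    strain_distance_cutoff = strain_distance_cutoff,
    identity_threshold = identity_threshold,
    coverage_threshold = coverage_threshold,
    pangenome_specific_max = pangenome_specific_max,
    pangenome_shared_min = pangenome_shared_min,
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed)
  )
  validate_analysis_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_analysis_config <- function(cfg) {
  stop_unless(cfg$min_microbial_reads >= 0, "min_microbial_reads must be nonnegative")
  stop_unless(cfg$detection_threshold >= 0, "detection_threshold must be nonnegative")
  for (nm in c("prevalence_cutoff", "oral_prevalence_cutoff", "fdr_threshold",
               "strain_distance_cutoff", "identity_threshold", "coverage_threshold",
               "pangenome_specific_max", "pangenome_shared_min")) {
    v <- cfg[[nm]]
    stop_unless(is.numeric(v) && length(v) == 1L && v >= 0 && v <= 1,
                sprintf("%s must be a single value in [0, 1]", nm))
  }
  stop_unless(cfg$effect_threshold >= 0, "effect_threshold must be nonnegative")
  stop_unless(cfg$pangenome_specific_max < cfg$pangenome_shared_min,
              "pangenome_specific_max must be below pangenome_shared_min")
  stop_unless(cfg$n_permutations >= 1, "n_permutations must be at least 1")
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write a JSON run manifest
#'
#' Records the full configuration, the RNG seed and package/R versions next to
#' a set of outputs so that any reported statistic can be traced to the exact
#' thresholds and seed that produced it.
#'
#' @param cfg An [analysis_config()].
#' @param path Output JSON path.
#' @param extra Optional named list of additional entries (e.g. input paths,
#'   stage notes).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(cfg, path, extra = list()) {
  manifest <- c(
    list(
      config = unclass(cfg),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("stentmb")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

stop_unless <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
  invisible(TRUE)
}
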