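#' Prevalence, abundance summaries and per-sample dominance
#'
#' For every SGB: the fraction of samples where it is detected (abundance
#' strictly above the detection threshold), its mean and standard deviation of
#' relative abundance, and the number of samples in which it is the single
#' most abundant (dominant) species. Each sample has exactly one dominant SGB;
#' abundance ties are broken towards the lexicographically smallest SGB id and
#' reported via `message()`. SGBs whose prevalence strictly exceeds
#' `cfg$prevalence_cutoff` are flagged `prevalent`.
#'
#' @param t A [profile_table()] (typically after depth filtering).
#' @param cfg An [analysis_config()].
#' @return `data.frame` with one row per SGB: `sgb_id`, `prevalence`,
#'   `mean_abundance`, `sd_abundance`, `n_dominant`, `prevalent`. The sum of
#'   `n_dominant` over SGBs equals the number of samples.
#' @export
prevalence_and_dominance <- function(t, cfg = analysis_config()) {
  mat <- t$abundances
  stop_unless(nrow(mat) > 0, "empty profile table")
  detected <- mat > cfg$detection_threshold
  prevalence <- colMeans(detected)
  dominant <- character(nrow(mat))
  n_ties <- 0L
  for (i in seq_len(nrow(mat))) {
    top <- which(mat[i, ] == max(mat[i, ]))
    if (length(top) > 1) n_ties <- n_ties + 1L
    dominant[i] <- sort(colnames(mat)[top])[1]
  }
  if (n_ties > 0) {
    message(n_ties, " sample(s) had tied top abundances; ties broken ",
            "towards the lexicographically smallest SGB id")
  }
  n_dom <- table(factor(dominant, levels = colnames(mat)))
  data.frame(sgb_id = colnames(mat),
             prevalence = as.numeric(prevalence),
             mean_abundance = as.numeric(colMeans(mat)),
             sd_abundance = as.numeric(apply(mat, 2, stats::sd)),
             n_dominant = as.integer(n_dom),
             prevalent = as.numeric(prevalence) > cfg$prevalence_cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag oral-microbiome members from a body-site reference
#'
#' Joins a prevalence table against a reference of SGB prevalences across
#' human body sites (airways, gastrointestinal, oral, skin, vagina, bile) and
#' flags an SGB as an oral-microbiome member when its prevalence in healthy
#' oral samples is strictly above `cfg$oral_prevalence_cutoff` (0.50 by
#' default; a reference prevalence of exactly 0.50 is not oral). SGBs missing
#' from the reference get `NA` and are excluded from any oral-fraction
#' denominator.
#'
#' @param records Output of [prevalence_and_dominance()].
#' @param reference `data.frame` with `sgb_id` and one column per body site,
#'   including `oral`, holding prevalences in `[0,1]`.
#' @param cfg An [analysis_config()].
#' @return `records` with added columns `oral_reference_prevalence` and
#'   `oral_member` (logical, `NA` when the SGB is absent from the reference).
#' @export
classify_body_site <- function(records, reference, cfg = analysis_config()) {
  stop_unless(all(c("sgb_id", "oral") %in% names(reference)),
              "reference must have sgb_id and oral columns")
  idx <- match(records$sgb_id, reference$sgb_id)
  oral_prev <- reference$oral[idx]
  records$oral_reference_prevalence <- oral_prev
  records$oral_member <- oral_prev > cfg$oral_prevalence_cutoff
  records
}

#' Trait fractions among prevalent SGBs
#'
#' Fraction of prevalent SGBs positive for each predicted binary trait
#' (e.g. facultative anaerobe, gram positive, sugar fermentation), computed
#' over non-missing entries only. Traits with no non-missing entry among the
#' prevalent SGBs are excluded with a warning.
#'
#' @param records Output of [prevalence_and_dominance()] (uses the `prevalent`
#'   flag).
#' @param trait_table `data.frame` with `sgb_id` plus 0/1 (or logical) trait
#'   columns; `NA` marks missing predictions.
#' @return `data.frame` with `trait`, `n_positive`, `n_assessed`, `fraction`.
#' @export
trait_fraction <- function(records, trait_table) {
  stop_unless("sgb_id" %in% names(trait_table), "trait_table must have sgb_id")
  prev_ids <- records$sgb_id[records$prevalent]
  tt <- trait_table[trait_table$sgb_id %in% prev_ids, , drop = FALSE]
  traits <- setdiff(names(trait_table), "sgb_id")
  rows <- lapply(traits, function(tr) {
    v <- tt[[tr]]
    ok <- !is.na(v)
    if (!any(ok)) return(NULL)
    data.frame(trait = tr, n_positive = sum(v[ok] > 0),
               n_assessed = sum(ok),
               fraction = sum(v[ok] > 0) / sum(ok),
               stringsAsFactors = FALSE)
  })
  dropped <- traits[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0) {
    warning("trait(s) with no non-missing entries excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
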