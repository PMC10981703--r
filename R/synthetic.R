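# All generators draw from a locally seeded RNG stream and restore the caller's
# .Random.seed, so fixed-seed calls are byte-identical and never perturb other code.
with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic stent cohort
#'
#' Parameters of the stent-cohort generator. The defaults emulate the shape of
#' the study cohort: 56 patients, 364 SGBs observed overall, 36 SGBs with
#' elevated occurrence probability (the prevalent set), mean per-sample SGB
#' richness around 42 with a standard deviation around 25 (via a per-sample
#' gamma richness multiplier), heavy-tailed within-sample dominance, patency
#' around 70 days (log-normal), and a read-depth distribution whose low tail
#' crosses the 2 million retention threshold for roughly one sample in six.
#'
#' @param n_samples Number of stent samples.
#' @param n_sgbs Number of SGBs in the species pool.
#' @param n_prevalent Number of SGBs given elevated occurrence probability.
#' @param dominance_concentration Dirichlet concentration of within-sample
#'   abundances over detected SGBs; smaller values concentrate mass on fewer
#'   dominant species (at 0 each sample degenerates to a single species).
#' @param richness_dispersion Gamma shape of the per-sample richness
#'   multiplier; the richness standard deviation scales as
#'   `mean_richness / sqrt(richness_dispersion)`.
#' @param fraction_metallic Probability a stent is metallic (vs plastic).
#' @param fraction_endoscopy Probability a stent was retrieved at endoscopy
#'   (vs pancreatic surgery).
#' @param patency_meanlog,patency_sdlog Log-normal patency (days), truncated
#'   to 5-330 days.
#' @param depth_meanlog,depth_sdlog Log-normal microbial read depth.
#' @param seed Integer RNG seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 56,
                        n_sgbs = 364,
                        n_prevalent = 36,
                        dominance_concentration = 0.3,
                        richness_dispersion = 2.8,
                        fraction_metallic = 0.5,
                        fraction_endoscopy = 17 / 56,
                        patency_meanlog = 3.88,
                        patency_sdlog = 0.86,
                        depth_meanlog = log(2e6) + 1,
                        depth_sdlog = 1,
                        seed = 42L) {
  stop_unless(n_prevalent <= n_sgbs, "n_prevalent cannot exceed n_sgbs")
  stop_unless(dominance_concentration >= 0, "dominance_concentration must be >= 0")
  stop_unless(richness_dispersion > 0, "richness_dispersion must be positive")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic stent cohort
#'
#' Draws sparse compositional SGB profiles with the occupancy-times-intensity
#' model: each SGB has a baseline occurrence probability (elevated for the
#' prevalent subset), scaled per sample by a gamma richness multiplier to
#' produce between-sample richness overdispersion; detected SGBs receive
#' Dirichlet weights (heavy-tailed dominance) and are closed to 100 percent.
#' Per-sample metadata (patient, material, retrieval procedure, patency,
#' microbial reads, age, sex, ASA and Clavien-Dindo scores) is drawn to match
#' the cohort shape described in [cohort_spec()].
#'
#' @param spec A [cohort_spec()].
#' @return A [profile_table()]; deterministic given `spec$seed`.
#' @export
gen_stent_cohort <- function(spec = cohort_spec()) {
  stop_unless(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  with_seed(spec$seed, {
    n <- spec$n_samples
    s <- spec$n_sgbs
    sgbs <- sprintf("t__SGB%04d", seq_len(s))
    base_occ <- c(stats::runif(spec$n_prevalent, 0.30, 0.60),
                  stats::runif(s - spec$n_prevalent, 0.02, 0.14))
    mult <- stats::rgamma(n, shape = spec$richness_dispersion,
                          rate = spec$richness_dispersion)
    mat <- matrix(0, nrow = n, ncol = s,
                  dimnames = list(sprintf("STENT%02d", seq_len(n)), sgbs))
    for (i in seq_len(n)) {
      occ <- stats::runif(s) < pmin(1, base_occ * mult[i])
      if (!any(occ)) occ[sample.int(s, 1)] <- TRUE
      k <- sum(occ)
      w <- if (spec$dominance_concentration == 0) {
        wk <- numeric(k); wk[sample.int(k, 1)] <- 1; wk
      } else {
        g <- stats::rgamma(k, shape = spec$dominance_concentration)
        if (sum(g) == 0) g[sample.int(k, 1)] <- 1
        g / sum(g)
      }
      mat[i, occ] <- 100 * w
    }
    patency <- round(pmin(330, pmax(5, stats::rlnorm(n, spec$patency_meanlog,
                                                     spec$patency_sdlog))))
    metadata <- data.frame(
      sample_id = rownames(mat),
      patient_id = sprintf("PT%02d", seq_len(n)),
      material = ifelse(stats::runif(n) < spec$fraction_metallic,
                        "metallic", "plastic"),
      procedure = ifelse(stats::runif(n) < spec$fraction_endoscopy,
                         "endoscopy", "surgery"),
      patency_days = as.integer(patency),
      microbial_reads = as.integer(round(pmin(
        .Machine$integer.max / 2,
        stats::rlnorm(n, spec$depth_meanlog, spec$depth_sdlog)))),
      age = as.integer(round(pmin(89, pmax(32, stats::rnorm(n, 67.3, 15.75))))),
      sex = sample(c("female", "male"), n, replace = TRUE),
      asa_class = sample(1:4, n, replace = TRUE, prob = c(0.1, 0.45, 0.4, 0.05)),
      clavien_dindo = sample(0:4, n, replace = TRUE,
                             prob = c(0.45, 0.25, 0.2, 0.07, 0.03)),
      stringsAsFactors = FALSE
    )
    profile_table(mat, metadata)
  })
}

#' Specification of a synthetic case-control panel
#'
#' Defaults mirror the disease panel analyzed in the study: 12 diseases, of
#' which four (CRC, CD, UC, T2D) are represented by two datasets each and
#' eight by a single dataset — so the two-level synthesis pools "four
#' meta-analyses and eight coefficients" — with the published per-disease
#' sample sizes split evenly into cases and controls.
#'
#' @param diseases `data.frame` with columns `disease_id`, `n_datasets`,
#'   `n_case`, `n_control` (per dataset).
#' @param n_species Number of species in every dataset.
#' @param planted_effects Named numeric vector: species id -> true
#'   standardized mean difference on the CLR scale. Default none (global
#'   null). Effects are planted so the post-CLR SMD equals the planted value
#'   in expectation (unplanted species absorb a compensating shift keeping the
#'   mean log-shift at zero, and the plant accounts for the CLR centering of
#'   the residual noise).
#' @param sigma Residual standard deviation of log abundances.
#' @param detection_limit Relative abundance below which an entry is reported
#'   as zero (profiler detection floor); generates the sparsity the
#'   zero-replacement step downstream has to handle. Planted species are drawn
#'   with elevated baseline abundance so they stay above the floor and the
#'   planted signal is not diluted through the replacement path.
#' @param seed Integer RNG seed.
#' @return Object of class `panel_spec`.
#' @export
panel_spec <- function(diseases = default_disease_panel(),
                       n_species = 100,
                       planted_effects = numeric(0),
                       sigma = 1,
                       detection_limit = 1e-4,
                       seed = 42L) {
  need <- c("disease_id", "n_datasets", "n_case", "n_control")
  stop_unless(is.data.frame(diseases) && all(need %in% names(diseases)),
              "diseases must have disease_id, n_datasets, n_case, n_control")
  stop_unless(all(diseases$n_case >= 10 & diseases$n_control >= 10),
              "each dataset needs at least 10 cases and 10 controls")
  stop_unless(detection_limit >= 0 && detection_limit < 0.5,
              "detection_limit must be a small fraction")
  structure(as.list(environment())[c("diseases", "n_species", "planted_effects",
                                     "sigma", "detection_limit", "seed")],
            class = "panel_spec")
}

#' Default disease panel layout
#'
#' The 12-disease layout of the study panel with its published total sample
#' sizes; the four multi-dataset diseases are split into two equal datasets.
#'
#' @return `data.frame` with `disease_id`, `n_datasets`, `n_case`, `n_control`
#'   (per dataset).
#' @export
default_disease_panel <- function() {
  totals <- c(CRC = 1300, CD = 309, UC = 346, T2D = 477, ACVD = 305,
              schizophrenia = 171, asthma = 200, behcet = 65, cirrhosis = 237,
              STH = 159, ME_CFS = 100, migraine = 226)
  multi <- c("CRC", "CD", "UC", "T2D")
  n_datasets <- ifelse(names(totals) %in% multi, 2L, 1L)
  per_dataset <- floor(totals / n_datasets)
  data.frame(disease_id = names(totals),
             n_datasets = n_datasets,
             n_case = pmax(10L, as.integer(floor(per_dataset / 2))),
             n_control = pmax(10L, as.integer(ceiling(per_dataset / 2))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a synthetic case-control panel
#'
#' For every dataset, log abundances are drawn as
#' `y = mu_species + shift * status + covariate effects + noise` and
#' exponentiated; entries whose within-sample relative abundance falls below
#' the detection limit are reported as zero (profiler-style sparsity); closure
#' to composition happens downstream in the analysis. Planted species receive
#' a shift of `d * sigma * sqrt(1 - 1/S)` (the factor undoes the variance
#' shrinkage the CLR centering applies to the residual noise), and unplanted
#' species share a compensating shift so the per-sample mean log-shift is
#' zero — making the post-CLR disease contrast of a planted species `d`
#' standard deviations in expectation. Covariate effects vary by species and
#' sequencing depth is correlated with age and status, so the covariate
#' adjustment in the downstream model is genuinely exercised.
#'
#' @param spec A [panel_spec()].
#' @return Object of class `case_control_panel`: list with `datasets` (each a
#'   list with `dataset_id`, `disease_id`, `abundances`, `status`,
#'   `covariates`), `planted_effects`, and `spec`. Deterministic given
#'   `spec$seed`.
#' @export
gen_case_control_panel <- function(spec = panel_spec()) {
  stop_unless(inherits(spec, "panel_spec"), "spec must be a panel_spec")
  species <- sprintf("t__SGB%04d", seq_len(spec$n_species))
  planted <- spec$planted_effects
  if (length(planted) > 0) {
    stop_unless(!is.null(names(planted)) && all(names(planted) %in% species),
                "planted species must be members of the species list")
  }
  s <- spec$n_species
  shift <- stats::setNames(numeric(s), species)
  if (length(planted) > 0) {
    shift[names(planted)] <- planted * spec$sigma * sqrt(1 - 1 / s)
    others <- setdiff(species, names(planted))
    shift[others] <- -sum(shift[names(planted)]) / length(others)
  }
  with_seed(spec$seed, {
    mu <- stats::rnorm(s, 0, 1.5)
    names(mu) <- species
    # planted species sit well above the detection floor
    if (length(planted) > 0) {
      mu[names(planted)] <- stats::runif(length(planted), 0.5, 1.5)
    }
    datasets <- list()
    for (r in seq_len(nrow(spec$diseases))) {
      dis <- spec$diseases[r, ]
      for (ds in seq_len(dis$n_datasets)) {
        n_case <- dis$n_case
        n_control <- dis$n_control
        n <- n_case + n_control
        status <- c(rep(1, n_case), rep(0, n_control))
        age <- stats::rnorm(n, 55, 12)
        sex <- stats::rbinom(n, 1, 0.5)
        bmi <- stats::rnorm(n, 25, 4)
        depth <- round(exp(log(2e7) + 0.10 * status + 0.01 * (age - 55) +
                             stats::rnorm(n, 0, 0.5)))
        beta_cov <- matrix(stats::rnorm(4 * s, 0, 0.1), nrow = 4)
        covs <- rbind(age - 55, sex, bmi - 25, log10(depth) - log10(2e7))
        y <- matrix(mu, n, s, byrow = TRUE) +
          outer(status, shift) +
          crossprod(covs, beta_cov) +
          matrix(stats::rnorm(n * s, 0, spec$sigma), n, s)
        x <- exp(y)
        x[x / rowSums(x) < spec$detection_limit] <- 0
        dimnames(x) <- list(sprintf("%s_D%d_S%03d", dis$disease_id, ds, seq_len(n)),
                            species)
        datasets[[length(datasets) + 1L]] <- list(
          dataset_id = sprintf("%s_ds%d", dis$disease_id, ds),
          disease_id = dis$disease_id,
          abundances = x,
          status = status,
          covariates = data.frame(age = age, sex = sex, bmi = bmi, depth = depth)
        )
      }
    }
    structure(list(datasets = datasets, planted_effects = planted, spec = spec),
              class = "case_control_panel")
  })
}

#' Generate a strain tree with planted identical-strain pairs
#'
#' Builds a rooted tree whose leaves hang off a central backbone with pendant
#' lengths of order 1, plus `n_shared_pairs` cherries whose two leaves are
#' placed at a patristic distance of one quarter of `cutoff` times the total
#' branch length (safely inside the strain cutoff), each leaf of a cherry
#' assigned to a different patient. All other leaf pairs sit at normalized
#' distances above twice the cutoff, so the planted pairs are exactly the
#' strain-sharing events a correct detector reports. Construction fails when
#' the margins are infeasible (too many leaves for the cutoff).
#'
#' @param n_leaves Total number of leaves.
#' @param n_shared_pairs Number of planted cross-patient identical-strain
#'   pairs (at most `n_leaves / 2`).
#' @param cutoff Normalized strain distance cutoff the margins are built
#'   around (default 0.01).
#' @param seed Integer RNG seed.
#' @return List with `tree` (a `strain_tree`), `newick` (the exact string),
#'   and `planted_pairs` (`data.frame` of leaf pairs). Deterministic given
#'   `seed`.
#' @export
gen_strain_tree <- function(n_leaves = 26, n_shared_pairs = 2, cutoff = 0.01,
                            seed = 42L) {
  stop_unless(n_shared_pairs >= 0 && n_shared_pairs <= n_leaves / 2,
              "n_shared_pairs must be at most n_leaves / 2")
  stop_unless(n_leaves >= 3, "need at least 3 leaves")
  n_units <- n_leaves - n_shared_pairs
  if (2 * 0.8 <= 2 * cutoff * 1.2 * (n_units + 1)) {
    stop("infeasible margins: too many leaves for this cutoff", call. = FALSE)
  }
  with_seed(seed, {
    leaves <- sprintf("S%03d", seq_len(n_leaves))
    patients <- sprintf("P%03d", seq_len(n_leaves))
    pend <- stats::runif(n_units, 0.8, 1.2)
    t0 <- sum(pend)
    leg <- cutoff * t0 / 8  # pair distance 2*leg = cutoff * total / 4
    pair_leaf_a <- leaves[seq_len(n_shared_pairs) * 2 - 1]
    pair_leaf_b <- leaves[seq_len(n_shared_pairs) * 2]
    singletons <- leaves[setdiff(seq_len(n_leaves), seq_len(2 * n_shared_pairs))]
    units <- character(n_units)
    if (n_shared_pairs > 0) {
      units[seq_len(n_shared_pairs)] <- sprintf(
        "(%s:%.10f,%s:%.10f):%.10f", pair_leaf_a, leg, pair_leaf_b, leg,
        pend[seq_len(n_shared_pairs)])
    }
    if (length(singletons) > 0) {
      units[n_shared_pairs + seq_along(singletons)] <- sprintf(
        "%s:%.10f", singletons, pend[n_shared_pairs + seq_along(singletons)])
    }
    newick <- paste0("(", paste(sample(units), collapse = ","), ");")
    phy <- ape::read.tree(text = newick)
    st <- as_strain_tree(phy, stats::setNames(patients, leaves))
    dn <- patristic_distances(st) / st$total_branch_length
    planted <- data.frame(leaf_a = pair_leaf_a, leaf_b = pair_leaf_b,
                          stringsAsFactors = FALSE)
    if (n_shared_pairs > 0) {
      planted_d <- dn[cbind(planted$leaf_a, planted$leaf_b)]
      stop_unless(all(planted_d < cutoff / 2),
                  "internal error: planted pair outside margin")
    }
    off <- dn[upper.tri(dn)]
    non_planted <- off[off > cutoff / 2 + 1e-12]
    if (any(non_planted <= 2 * cutoff)) {
      stop("infeasible margins: background pair within 2x cutoff", call. = FALSE)
    }
    list(tree = st, newick = newick, planted_pairs = planted)
  })
}

#' Generate a gene-hit table straddling the assignment gates
#'
#' Samples candidate gene hits whose identities and coverages straddle the
#' strict identity/coverage gates (over 0.90 and over 0.80), appends exact
#' boundary rows (identity exactly 0.90, coverage exactly 0.80), and records
#' for each row the truth label of the strict assignment rule.
#'
#' @param n_genes Number of sampled hits (boundary rows are added on top).
#' @param fraction_passing Fraction of sampled hits drawn from the passing
#'   region.
#' @param n_strains Number of strains hits are spread over.
#' @param seed Integer RNG seed.
#' @return `data.frame` with `gene_id`, `cluster_id`, `strain_id`, `identity`,
#'   `coverage`, `class` and the logical `truth_assigned`. Deterministic given
#'   `seed`.
#' @export
gen_gene_hits <- function(n_genes = 200, fraction_passing = 0.4, n_strains = 26,
                          seed = 42L) {
  stop_unless(fraction_passing >= 0 && fraction_passing <= 1,
              "fraction_passing must lie in [0, 1]")
  classes <- c("penem", "sulfonamide", "nitrofuran", "diaminopyrimidine",
               "streptogramin", "sulfone", "glycylcycline", "nitroimidazole",
               "biofilm_formation")
  with_seed(seed, {
    pass <- stats::runif(n_genes) < fraction_passing
    identity <- ifelse(pass, stats::runif(n_genes, 0.901, 1.0),
                       ifelse(stats::runif(n_genes) < 0.5,
                              stats::runif(n_genes, 0.5, 0.9),
                              stats::runif(n_genes, 0.901, 1.0)))
    coverage <- ifelse(pass, stats::runif(n_genes, 0.801, 1.0),
                       ifelse(identity > 0.9,
                              stats::runif(n_genes, 0.2, 0.8),
                              stats::runif(n_genes, 0.2, 1.0)))
    boundary <- data.frame(identity = c(0.90, 0.95, 0.90, 0.95),
                           coverage = c(0.85, 0.80, 0.80, 0.85))
    identity <- c(identity, boundary$identity)
    coverage <- c(coverage, boundary$coverage)
    m <- length(identity)
    hits <- data.frame(
      gene_id = sprintf("gene_%04d", seq_len(m)),
      cluster_id = sprintf("UniRef90_Q%04d", sample.int(max(10, m %/% 3), m,
                                                        replace = TRUE)),
      strain_id = sprintf("strain_%02d", sample.int(n_strains, m, replace = TRUE)),
      identity = identity,
      coverage = coverage,
      class = sample(classes, m, replace = TRUE),
      stringsAsFactors = FALSE
    )
    hits$truth_assigned <- hits$identity > 0.90 & hits$coverage > 0.80
    hits
  })
}

#' Generate a body-site reference prevalence table
#'
#' Reference prevalences of SGBs across human body sites, with a chosen
#' fraction of the SGBs made oral-microbiome members (oral prevalence above
#' 0.5) and the rest kept below.
#'
#' @param sgb_ids SGB identifiers to cover.
#' @param fraction_oral Fraction of SGBs drawn as oral members.
#' @param seed Integer RNG seed.
#' @return `data.frame` with `sgb_id` and prevalence columns `airways`,
#'   `gastrointestinal`, `oral`, `skin`, `vagina`, `bile`.
#' @export
gen_body_site_reference <- function(sgb_ids, fraction_oral = 17 / 36, seed = 42L) {
  with_seed(seed, {
    n <- length(sgb_ids)
    oral_member <- stats::runif(n) < fraction_oral
    data.frame(
      sgb_id = sgb_ids,
      airways = stats::runif(n, 0, 0.6),
      gastrointestinal = stats::runif(n, 0, 0.9),
      oral = ifelse(oral_member, stats::runif(n, 0.55, 0.95),
                    stats::runif(n, 0, 0.45)),
      skin = stats::runif(n, 0, 0.5),
      vagina = stats::runif(n, 0, 0.3),
      bile = stats::runif(n, 0, 0.7),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a binary microbial trait table
#'
#' Predicted binary traits per SGB (facultative anaerobe, gram positive,
#' fermentation of simple sugars) with a small missingness rate, at the
#' marginal frequencies reported for prevalent stent species.
#'
#' @param sgb_ids SGB identifiers to cover.
#' @param missing_rate Probability an entry is `NA`.
#' @param seed Integer RNG seed.
#' @return `data.frame` with `sgb_id` plus 0/1 trait columns.
#' @export
gen_trait_table <- function(sgb_ids, missing_rate = 0.05, seed = 42L) {
  probs <- c(facultative_anaerobe = 0.50, gram_positive = 0.583,
             ferments_dmannose = 0.611, ferments_glucose = 0.833,
             ferments_maltose = 0.694, ferments_sucrose = 0.611,
             ferments_trehalose = 0.611)
  with_seed(seed, {
    n <- length(sgb_ids)
    out <- data.frame(sgb_id = sgb_ids, stringsAsFactors = FALSE)
    for (tr in names(probs)) {
      v <- stats::rbinom(n, 1, probs[[tr]])
      v[stats::runif(n) < missing_rate] <- NA
      out[[tr]] <- v
    }
    out
  })
}

#' Generate a genome catalog with target cluster prevalences
#'
#' Draws a genome-to-cluster catalog in which each cluster is carried by each
#' genome independently with its target pangenome prevalence.
#'
#' @param cluster_prevalence Named numeric vector: cluster id -> target
#'   prevalence in `[0,1]`.
#' @param n_genomes Number of reference genomes.
#' @param seed Integer RNG seed.
#' @return Named list: genome id -> character vector of carried cluster ids.
#' @export
gen_genome_catalog <- function(cluster_prevalence, n_genomes = 40, seed = 42L) {
  stop_unless(n_genomes >= 1, "need at least one genome")
  stop_unless(all(cluster_prevalence >= 0 & cluster_prevalence <= 1),
              "prevalences must lie in [0, 1]")
  with_seed(seed, {
    genomes <- sprintf("genome_%03d", seq_len(n_genomes))
    out <- lapply(genomes, function(g) {
      names(cluster_prevalence)[stats::runif(length(cluster_prevalence)) <
                                  cluster_prevalence]
    })
    stats::setNames(out, genomes)
  })
}
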