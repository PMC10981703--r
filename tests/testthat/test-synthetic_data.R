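test_that("all generators are deterministic under a fixed seed", {
  c1 <- gen_stent_cohort(cohort_spec(seed = 3))
  c2 <- gen_stent_cohort(cohort_spec(seed = 3))
  expect_identical(c1$abundances, c2$abundances)
  expect_identical(c1$metadata, c2$metadata)

  t1 <- gen_strain_tree(20, 2, seed = 3)
  t2 <- gen_strain_tree(20, 2, seed = 3)
  expect_identical(t1$newick, t2$newick)

  g1 <- gen_gene_hits(seed = 3)
  expect_identical(g1, gen_gene_hits(seed = 3))

  p1 <- gen_case_control_panel(
    panel_spec(diseases = small_panel_layout(12), n_species = 10, seed = 3))
  p2 <- gen_case_control_panel(
    panel_spec(diseases = small_panel_layout(12), n_species = 10, seed = 3))
  expect_identical(p1$datasets[[1]]$abundances, p2$datasets[[1]]$abundances)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_stent_cohort(cohort_spec(seed = 1)))
  invisible(gen_gene_hits(seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("cohort compositions are valid and calibrated to the study shape", {
  co <- gen_stent_cohort(cohort_spec(seed = 1))
  expect_equal(dim(co$abundances), c(56, 364))
  expect_true(all(co$abundances >= 0))
  expect_true(all(abs(rowSums(co$abundances) - 100) < 1e-6))
  expect_true(all(co$metadata$patency_days >= 5 &
                    co$metadata$patency_days <= 330))
  expect_true(all(co$metadata$material %in% c("metallic", "plastic")))
  expect_true(all(co$metadata$procedure %in% c("endoscopy", "surgery")))

  mean_rich <- vapply(1:20, function(s) {
    mean(alpha_diversity(gen_stent_cohort(cohort_spec(seed = s)))$richness)
  }, numeric(1))
  expect_gt(mean(mean_rich), 37)
  expect_lt(mean(mean_rich), 47)
})

test_that("vanishing dominance concentration collapses samples to one species", {
  co <- gen_stent_cohort(cohort_spec(n_samples = 10, n_sgbs = 50,
                                     n_prevalent = 5,
                                     dominance_concentration = 0, seed = 2))
  expect_true(all(rowSums(co$abundances > 0) == 1))
  expect_error(cohort_spec(n_sgbs = 10, n_prevalent = 20), "n_prevalent")
})

test_that("default panel layout has four multi-dataset and eight single-dataset diseases", {
  lay <- default_disease_panel()
  expect_equal(nrow(lay), 12)
  expect_equal(sum(lay$n_datasets == 2), 4)
  expect_equal(sum(lay$n_datasets == 1), 8)
  expect_true(all(lay$n_case >= 10 & lay$n_control >= 10))

  panel <- gen_case_control_panel(
    panel_spec(diseases = small_panel_layout(10), n_species = 5, seed = 1))
  expect_equal(length(panel$datasets), 16)
  res <- meta_disease_association(panel)$results
  expect_equal(res$k[res$scope == "overall"][1], 12L)
  expect_error(
    panel_spec(diseases = small_panel_layout(9)), "at least 10")
  expect_error(
    gen_case_control_panel(panel_spec(diseases = small_panel_layout(10),
                                      n_species = 5,
                                      planted_effects = c(nope = 0.5))),
    "members of the species list")
})

test_that("gene-hit generator truth labels agree with the assignment rule", {
  hits <- gen_gene_hits(n_genes = 300, seed = 4)
  expect_identical(unname(assign_gene_cluster(hits)), hits$truth_assigned)
  # exact-boundary rows are present and rejected
  expect_true(any(hits$identity == 0.90 & !hits$truth_assigned))
  expect_true(any(hits$coverage == 0.80 & !hits$truth_assigned))
  expect_true(all(hits$identity >= 0 & hits$identity <= 1))
})

test_that("strain-tree generator plants detectable pairs with clean margins", {
  out <- gen_strain_tree(n_leaves = 26, n_shared_pairs = 2, seed = 6)
  dn <- patristic_distances(out$tree) / out$tree$total_branch_length
  planted <- dn[cbind(out$planted_pairs$leaf_a, out$planted_pairs$leaf_b)]
  expect_true(all(planted < 0.005))
  off <- dn[upper.tri(dn)]
  expect_true(all(off[off > 0.005] > 0.02))

  out0 <- gen_strain_tree(n_leaves = 10, n_shared_pairs = 0, seed = 6)
  expect_equal(nrow(detect_strain_sharing(out0$tree)$sharing), 0)
  expect_error(gen_strain_tree(10, 6, seed = 1), "n_shared_pairs")
  expect_error(gen_strain_tree(500, 2, seed = 1), "infeasible")
})

test_that("body-site and trait generators produce valid reference tables", {
  ids <- sprintf("t__SGB%03d", 1:40)
  ref <- gen_body_site_reference(ids, seed = 5)
  expect_equal(ref$sgb_id, ids)
  expect_true(all(ref$oral >= 0 & ref$oral <= 1))
  expect_true(any(ref$oral > 0.5) && any(ref$oral <= 0.5))

  tt <- gen_trait_table(ids, seed = 5)
  vals <- unlist(tt[-1])
  expect_true(all(vals %in% c(0, 1) | is.na(vals)))

  cat <- gen_genome_catalog(c(U1 = 1, U2 = 0), n_genomes = 15, seed = 5)
  expect_equal(pangenome_prevalence("U1", cat), 1)
  expect_equal(pangenome_prevalence("U2", cat), 0)
})
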