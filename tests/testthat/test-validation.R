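test_that("overlap permutation test handles disjoint references and bad sizes", {
  pri <- list(tA = c("g1", "g2"))
  cand <- list(tA = c("g1", "g2", "g3", "g4"))
  res <- permutation_overlap_test(pri, cand, c("x1", "x2"),
                                  n_iter = 50, seed = 3)
  expect_equal(res$observed_overlap, 0L)
  expect_equal(res$p_empirical, 1)
  expect_error(
    permutation_overlap_test(list(tA = c("g1", "g2")), list(tA = "g1"),
                             "g1", n_iter = 10, seed = 1),
    "larger than candidate")
})

test_that("empirical overlap p matches exhaustive enumeration", {
  # candidates {g1..g4}, draw 2, reference {g1}: 3 of the C(4,2)=6
  # subsets contain g1, exact p = 0.5
  res <- permutation_overlap_test(list(tA = c("g1", "g2")),
                                  list(tA = paste0("g", 1:4)), "g1",
                                  n_iter = 4000, seed = 17)
  expect_equal(res$observed_overlap, 1L)
  se <- sqrt(0.5 * 0.5 / 4000)
  expect_lt(abs(res$p_empirical - 0.5), 3 * se)
  # pure function of (inputs, seed)
  res2 <- permutation_overlap_test(list(tA = c("g1", "g2")),
                                   list(tA = paste0("g", 1:4)), "g1",
                                   n_iter = 4000, seed = 17)
  expect_identical(res, res2)
  # add-one estimator
  res3 <- permutation_overlap_test(list(tA = c("g1", "g2")),
                                   list(tA = paste0("g", 1:4)), "g1",
                                   n_iter = 100, seed = 1,
                                   p_estimator = "add_one")
  expect_equal(res3$p_empirical, (res3$n_at_least + 1) / 101)
})

test_that("annotation randomization preserves both incidence marginals", {
  sim <- simulate_qtl_study(simulation_config(seed = 5))
  rnd <- randomize_annotations(sim$annotation, sim$genome, seed = 42)
  expect_identical(rnd$term_counts[names(sim$annotation$term_counts)],
                   sim$annotation$term_counts)
  sizes_before <- sort(table(sim$annotation$pairs$gene_id))
  sizes_after <- sort(table(rnd$pairs$gene_id))
  expect_identical(as.integer(sizes_before), as.integer(sizes_after))
  expect_identical(randomize_annotations(sim$annotation, sim$genome, 42),
                   rnd)
  expect_false(identical(rnd$pairs, sim$annotation$pairs))
})

test_that("nearest-gene distances use span edges with deterministic ties", {
  genome <- genome_gene_set(data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(100, 300, 900), end = c(200, 400, 1000)))
  near <- nearest_genes_to_snp(genome, "chr1", 350, k = 3)
  expect_equal(near$gene_id, c("g2", "g1", "g3"))
  expect_equal(near$distance, c(0L, 150L, 550L))
  # SNP inside a gene comes first at distance zero
  expect_equal(nearest_genes_to_snp(genome, "chr1", 150, 1)$gene_id, "g1")
  # fewer genes than k
  two <- genome_gene_set(genome[genome$gene_id != "g3", ])
  expect_equal(nrow(nearest_genes_to_snp(two, "chr1", 350, 3)), 2L)
  expect_warning(res <- nearest_genes_to_snp(genome, "chrX", 10),
                 "chrX")
  expect_equal(nrow(res), 0L)
})

test_that("GWAS neighborhood test counts per-trait hits and is seeded", {
  sim <- simulate_qtl_study(simulation_config(seed = 2))
  run <- suppressMessages(run_prioritization(sim$genome, sim$compendium,
                                             sim$annotation))
  g <- gwas_overlap_test(run$prioritized_by_trait, run$candidates_by_trait,
                         sim$snp_hits, sim$genome, n_iter = 200, seed = 9)
  # SNPs sit inside planted causal genes: observed equals the direct
  # per-trait intersection with the 3-nearest neighborhoods
  direct <- 0L
  for (tr in intersect(names(run$prioritized_by_trait),
                       unique(sim$snp_hits$trait))) {
    snps <- sim$snp_hits[sim$snp_hits$trait == tr, ]
    nb <- unique(unlist(lapply(seq_len(nrow(snps)), function(i) {
      nearest_genes_to_snp(sim$genome, snps$chrom[i], snps$pos[i])$gene_id
    })))
    direct <- direct + length(intersect(run$prioritized_by_trait[[tr]], nb))
  }
  expect_equal(g$result$observed_overlap, direct)
  expect_gte(g$result$observed_overlap, 1L)
  expect_identical(
    g$result,
    gwas_overlap_test(run$prioritized_by_trait, run$candidates_by_trait,
                      sim$snp_hits, sim$genome, n_iter = 200,
                      seed = 9)$result)
  # no shared trait is an error
  bad_snps <- data.frame(trait = "no-such-trait", chrom = "chr1",
                         pos = 100L)
  expect_error(
    gwas_overlap_test(run$prioritized_by_trait, run$candidates_by_trait,
                      bad_snps, sim$genome, n_iter = 10, seed = 1),
    "no trait shared")
})

test_that("a neighborhood that hits nothing gives observed 0 and p 1", {
  genome <- make_tiled_genome(10)
  pri <- list(tA = c("g1", "g2"))
  cand <- list(tA = sprintf("g%d", 1:6))
  snps <- data.frame(trait = "tA", chrom = "chr1", pos = 1950L)
  # nearest genes to 1950 are g8,g9,g10: disjoint from the candidates
  g <- gwas_overlap_test(pri, cand, snps, genome, n_iter = 100, seed = 1)
  expect_equal(g$result$observed_overlap, 0L)
  expect_equal(g$result$p_empirical, 1)
  expect_equal(nrow(g$matches), 0L)
})

test_that("TF profile percentages and the family panel follow the rules", {
  genome <- genome_gene_set(data.frame(
    gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
    start = (1:100) * 10, end = (1:100) * 10 + 5))
  tf <- data.frame(gene_id = sprintf("g%03d", 1:10),
                   family = c(rep("MYB", 4), rep("WRKY", 6)),
                   stringsAsFactors = FALSE)
  sets <- list(candidates = data.frame(
    trait = "tA", gene_id = sprintf("g%03d", 1:50)),
    summary = data.frame(trait = "tA", n_regions_retained = 1L,
                         n_candidate_genes = 50L))
  # 12 prioritized TFs for tA (4 MYB = 33%), 9 for tB (below threshold)
  pri <- data.frame(
    trait = c(rep("tA", 20), rep("tB", 9)),
    region_id = "r",
    gene_id = c(sprintf("g%03d", 1:12), sprintf("g%03d", 90:97),
                sprintf("g%03d", 1:9)),
    supporting_terms = "T1", stringsAsFactors = FALSE)
  prof <- tf_profile(pri, sets, genome, tf)
  expect_equal(prof$pct_tf_genome, 10)
  expect_equal(prof$pct_tf_candidates, 100 * 10 / 50)
  expect_equal(prof$pct_tf_prioritized, 100 * 10 / 20)
  expect_equal(unname(prof$strata["k>=2"]), 100 * 9 / 9)
  expect_equal(prof$family_by_trait$trait, "tA")
  expect_true("MYB" %in% names(prof$family_by_trait))   # 4/12 = 33% > 25%
  expect_true("WRKY" %in% names(prof$family_by_trait))  # 8/12 = 67% > 25%
})

test_that("the parameter sweep reproduces direct runs and scales the grid", {
  sim <- simulate_qtl_study(simulation_config(seed = 6))
  ref <- sim$reference_genes$gene_id
  params <- analysis_parameters()
  one <- suppressMessages(parameter_sweep(
    sim$genome, sim$compendium, sim$annotation,
    data.frame(fdr_threshold = 0.1, min_region_fraction = 0.5,
               max_generality = 0.01),
    ref, base_params = params, n_iter = 200, seed = 4))
  run <- suppressMessages(run_prioritization(sim$genome, sim$compendium,
                                             sim$annotation, params))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_associations, sum(run$associations$associated))
  expect_equal(one$n_prioritized, length(unique(run$prioritized$gene_id)))
  expect_equal(one$prioritized_fraction, run$reduction$global$mean_fraction)

  grid <- expand.grid(fdr_threshold = c(0.05, 0.1),
                      min_region_fraction = 0.5, max_generality = 0.01)
  two <- suppressMessages(parameter_sweep(
    sim$genome, sim$compendium, sim$annotation, grid, ref,
    base_params = params, n_iter = 100, seed = 4))
  expect_equal(nrow(two), 2L)

  # relaxing the generality cap cannot shrink the prioritized fraction here
  relax <- suppressMessages(parameter_sweep(
    sim$genome, sim$compendium, sim$annotation,
    data.frame(fdr_threshold = 0.1, min_region_fraction = 0.5,
               max_generality = c(0.01, 0.05, 0.2)),
    ref, base_params = params, n_iter = 100, seed = 4))
  expect_true(all(diff(relax$prioritized_fraction) >= -1e-12))
})
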