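make_annotated_universe <- function(n_genes, term_sizes, seed = 7L) {
  genome <- genome_gene_set(data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)), chrom = "chr1",
    start = seq_len(n_genes) * 10L, end = seq_len(n_genes) * 10L + 5L))
  pairs <- withr::with_seed(seed, do.call(rbind, lapply(
    names(term_sizes), function(tm) {
      data.frame(gene_id = sample(genome$gene_id, term_sizes[[tm]]),
                 term_id = tm, stringsAsFactors = FALSE)
    })))
  list(genome = genome,
       annotation = function_annotation(pairs, genome))
}

test_that("generality eligibility is strict-by-default and configurable", {
  u <- make_annotated_universe(1000L, c(T_small = 9L, T_edge = 10L,
                                        T_big = 200L))
  elig <- eligible_terms(u$annotation, u$genome, analysis_parameters())
  expect_true("T_small" %in% elig)    # 0.009 < 0.01
  expect_false("T_edge" %in% elig)    # 0.010 not < 0.01
  expect_false("T_big" %in% elig)
  elig_le <- eligible_terms(u$annotation, u$genome,
                            analysis_parameters(generality_cmp = "le"))
  expect_true("T_edge" %in% elig_le)
  # 20% cap admits a 15%-generality term (the sensitivity setting)
  u2 <- make_annotated_universe(1000L, c(T15 = 150L))
  expect_equal(eligible_terms(u2$annotation, u2$genome,
                              analysis_parameters(max_generality = 0.2)),
               "T15")
  expect_error(eligible_terms(u2$annotation, u2$genome,
                              analysis_parameters(max_generality = 0.01)),
               "generality filter")
})

test_that("the one-sided Fisher tail validates its 2x2 counts", {
  expect_error(fisher_one_sided(5, 4, 10, 20), "invalid")
  expect_error(fisher_one_sided(1, 2, 3, 2), "invalid")
  expect_silent(fisher_one_sided(0, 0, 0, 0))
})

test_that("one- and two-sided p-values agree with fisher.test", {
  set.seed(11)
  for (i in 1:30) {
    G <- sample(10:200, 1)
    n <- sample.int(G, 1)
    K <- sample.int(G, 1)
    a <- sample(max(0, n + K - G):min(n, K), 1)
    tab <- matrix(c(a, K - a, n - a, G - K - n + a), 2)
    expect_equal(fisher_one_sided(a, n, K, G),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
    expect_equal(fisher_two_sided(a, n, K, G),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("BH adjustment handles singletons, ties and bad input", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("region-occurrence fractions count regions, not genes", {
  genome <- make_tiled_genome(16)
  comp <- qtl_compendium(data.frame(
    trait = "tA", chrom = "chr1",
    start = c(100, 900, 1700, 2500), end = c(800, 1600, 2400, 3200)))
  map <- suppressMessages(filter_regions_by_size(
    assign_genes_to_regions(genome, comp)))
  # T1 in two regions (twice in the first: still one region each)
  pairs <- data.frame(gene_id = c("g1", "g2", "g5", "g9"),
                      term_id = c("T1", "T1", "T1", "T2"))
  ann <- function_annotation(pairs, genome)
  expect_equal(region_occurrence_fraction("tA", "T1", map, ann), 0.5)
  expect_equal(region_occurrence_fraction("tA", "T2", map, ann), 0.25)
  expect_equal(region_occurrence_fraction("tA", "T3", map, ann), 0)
  comp1 <- qtl_compendium(data.frame(trait = "tB", chrom = "chr1",
                                     start = 100, end = 800))
  map1 <- suppressMessages(filter_regions_by_size(
    assign_genes_to_regions(genome, comp1)))
  expect_equal(region_occurrence_fraction("tB", "T1", map1, ann), 1)
})

test_that("a single test passes BH unchanged and respects the region filter", {
  genome <- make_tiled_genome(40)
  comp <- qtl_compendium(data.frame(
    trait = "tA", chrom = "chr1",
    start = c(100, 2100), end = c(2000, 4000)))
  map <- suppressMessages(filter_regions_by_size(
    assign_genes_to_regions(genome, comp)))
  sets <- build_trait_candidate_sets(map, comp)
  pairs <- data.frame(gene_id = c("g1", "g2", "g12"), term_id = "T1")
  ann <- function_annotation(pairs, genome)
  params <- analysis_parameters(max_generality = 0.2)
  tab <- test_associations(sets, map, ann, genome, params)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$q_bh, tab$p_raw)  # m = 1
  expect_equal(tab$region_fraction, 1)
  expect_equal(tab$a, 3L)
  expect_equal(tab$n, 20L)
  expect_equal(tab$K, 3L)
  expect_equal(tab$G, 40L)
  expect_equal(tab$associated, tab$q_bh <= 0.1)
})

test_that("planted causal terms are recovered and false associations are rare", {
  sim <- simulate_qtl_study(simulation_config(seed = 1))
  run <- suppressMessages(run_prioritization(sim$genome, sim$compendium,
                                             sim$annotation))
  tab <- run$associations
  causal <- vapply(sim$ground_truth, `[[`, character(1), "causal_term")
  for (tr in names(sim$ground_truth)) {
    expect_true(causal[[tr]] %in% tab$term[tab$trait == tr & tab$associated])
  }
  noncausal <- tab[!tab$term %in% causal, , drop = FALSE]
  expect_lte(mean(noncausal$associated), 0.1)
  # filter screening: every tested term passed the generality filter
  elig <- eligible_terms(sim$annotation, sim$genome, run$params)
  expect_true(all(tab$term %in% elig))
  # count invariants of every row
  expect_true(all(tab$a >= 1 & tab$a <= pmin(tab$n, tab$K)))
  expect_true(all(tab$q_bh >= tab$p_raw))
  expect_true(all(tab$region_fraction >= 0 & tab$region_fraction <= 1))
})

test_that("false associations under the annotation-permutation null are rare", {
  n_assoc <- vapply(1:20, function(s) {
    sim <- simulate_qtl_study(simulation_config(seed = 100L + s))
    run <- suppressMessages(run_prioritization(
      sim$genome, sim$compendium, sim$annotation,
      null_run = TRUE, seed = s))
    sum(run$associations$associated)
  }, numeric(1))
  expect_lt(mean(n_assoc), 1)
})

test_that("pooling the correction over traits uses one BH family", {
  sim <- simulate_qtl_study(simulation_config(seed = 3))
  run <- suppressMessages(run_prioritization(sim$genome, sim$compendium,
                                             sim$annotation))
  tab <- run$associations
  expect_equal(tab$q_bh, bh_adjust(tab$p_raw))
  # appending strictly larger p-values never lowers an existing q-value
  p <- tab$p_raw
  grown <- bh_adjust(c(p, rep(max(p) + (1 - max(p)) / 2, 10)))
  expect_true(all(grown[seq_along(p)] >= bh_adjust(p) - 1e-12))
})

test_that("zero-count tests can be included on request", {
  sim <- simulate_qtl_study(simulation_config(seed = 4))
  params0 <- analysis_parameters()
  params1 <- analysis_parameters(include_zero_counts = TRUE)
  run0 <- suppressMessages(run_prioritization(sim$genome, sim$compendium,
                                              sim$annotation, params0))
  run1 <- suppressMessages(run_prioritization(sim$genome, sim$compendium,
                                              sim$annotation, params1))
  expect_gt(nrow(run1$associations), nrow(run0$associations))
  expect_true(all(run1$associations$p_raw[run1$associations$a == 0] == 1))
  expect_true(all(run0$associations$a >= 1))
})
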