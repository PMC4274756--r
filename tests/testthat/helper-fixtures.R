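# Fixtures are built in code; the independent oracles live here so the
# tests never re-use the implementation path they check.

# Genes tiled at (100-200), (300-400), (500-600), ... on one chromosome.
make_tiled_genome <- function(n, chrom = "chr1", len = 101L, pitch = 200L) {
  start <- 100L + (seq_len(n) - 1L) * pitch
  genome_gene_set(data.frame(
    gene_id = sprintf("g%d", seq_len(n)),
    chrom = chrom, start = start, end = start + len - 1L,
    stringsAsFactors = FALSE
  ))
}

random_small_instance <- function(seed, max_genes = 50L, max_regions = 10L,
                                  n_chroms = 2L, span = 5000L) {
  withr::with_seed(seed, {
    n_genes <- sample.int(max_genes, 1)
    s <- sample.int(span, n_genes, replace = TRUE)
    genome <- genome_gene_set(data.frame(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      chrom = paste0("chr", sample.int(n_chroms, n_genes, replace = TRUE)),
      start = s, end = s + sample.int(400, n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    ))
    n_reg <- sample.int(max_regions, 1)
    rs <- sample.int(span, n_reg, replace = TRUE)
    compendium <- qtl_compendium(data.frame(
      trait = paste0("t", sample.int(3, n_reg, replace = TRUE)),
      chrom = paste0("chr", sample.int(n_chroms, n_reg, replace = TRUE)),
      start = rs, end = rs + sample.int(1500, n_reg, replace = TRUE),
      stringsAsFactors = FALSE
    ))
    list(genome = genome, compendium = compendium)
  })
}

# All-pairs closed-interval overlap check.
oracle_region_assignments <- function(genome, compendium, rule = "any") {
  rows <- list()
  for (i in seq_len(nrow(genome))) {
    for (j in seq_len(nrow(compendium))) {
      if (genome$chrom[i] != compendium$chrom[j]) next
      hit <- if (rule == "contained") {
        genome$start[i] >= compendium$start[j] &&
          genome$end[i] <= compendium$end[j]
      } else {
        genome$start[i] <= compendium$end[j] &&
          genome$end[i] >= compendium$start[j]
      }
      if (hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = compendium$region_id[j],
          gene_id = genome$gene_id[i], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = character(0), gene_id = character(0))
  out[order(out$region_id, out$gene_id), , drop = FALSE]
}

# Direct step-up formula: q_(i) = min over j >= i of p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, ps[i] * m / i)
    q[i] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Minimal constructed study: one trait, configurable regions/terms.
make_micro_study <- function() {
  genome <- make_tiled_genome(12)
  compendium <- qtl_compendium(data.frame(
    trait = "traitA",
    chrom = "chr1",
    start = c(100, 500, 900, 1300),
    end = c(400, 800, 1200, 1600),
    stringsAsFactors = FALSE
  ))
  list(genome = genome, compendium = compendium)
}

write_mini_gff3 <- function(path, genome) {
  write_gene_models_gff3(genome, path)
  path
}
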