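#' Configuration for the synthetic QTL study generator
#'
#' Defines a desk-scale genome, annotation set and QTL compendium with
#' known planted trait-BP signal. Defaults describe the standard study
#' conditions used throughout the test suite: a 1,000-gene genome on two
#' chromosomes, 50 biological-process terms whose background sizes follow a
#' truncated power law (mirroring the long-tailed size distribution of real
#' GO term usage), and five traits with four 20-gene QTL regions each. Each
#' trait has one causal term; every planted region receives two genes
#' annotated with it, and the causal term is additionally carried by
#' `causal_background_genes` random genes, so its genome-wide count stays
#' strictly below 1% of the genome and the term is eligible under the
#' default generality filter. Raising `causal_background_genes` past the
#' cap makes the planted term ineligible on purpose.
#'
#' @param n_chroms,genes_per_chrom Genome layout; genes are tiled
#'   deterministically along each chromosome.
#' @param gene_length,intergenic_gap Span and spacing of tiled genes (bp).
#' @param n_terms Total number of BP terms; the first `n_traits` of them
#'   are the causal terms.
#' @param generality_alpha Power-law exponent of background term sizes.
#' @param generality_min Minimum background term size (genes).
#' @param generality_cap_fraction Maximum background term size as a
#'   fraction of the genome.
#' @param terms_per_gene_mean Target mean number of annotations per gene;
#'   background sizes are rescaled towards this total.
#' @param n_traits,regions_per_trait QTL compendium layout.
#' @param region_gene_span Number of consecutive genes spanned by a region.
#' @param f_regions Fraction of each trait's regions that carry planted
#'   causal genes (1.0 plants all of them; 0 disables planting).
#' @param n_causal_per_region Causal genes planted per planted region.
#' @param causal_background_genes Random off-region genes also annotated
#'   with each causal term.
#' @param tf_fraction Fraction of genes listed as transcription factors.
#' @param n_tf_families Number of TF family labels.
#' @param snp_fraction Fraction of planted genes receiving a GWAS SNP at
#'   their midpoint.
#' @param reference_fraction Fraction of planted genes used as the
#'   fine-mapped reference set.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_chroms = 2L, genes_per_chrom = 500L,
                              gene_length = 1000L, intergenic_gap = 1000L,
                              n_terms = 50L,
                              generality_alpha = 1.5,
                              generality_min = 2L,
                              generality_cap_fraction = 0.05,
                              terms_per_gene_mean = 1.0,
                              n_traits = 5L, regions_per_trait = 4L,
                              region_gene_span = 20L,
                              f_regions = 1.0,
                              n_causal_per_region = 2L,
                              causal_background_genes = 1L,
                              tf_fraction = 0.05, n_tf_families = 5L,
                              snp_fraction = 0.5,
                              reference_fraction = 0.5,
                              seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              genes_per_chrom = as.integer(genes_per_chrom),
              gene_length = as.integer(gene_length),
              intergenic_gap = as.integer(intergenic_gap),
              n_terms = as.integer(n_terms),
              generality_alpha = generality_alpha,
              generality_min = as.integer(generality_min),
              generality_cap_fraction = generality_cap_fraction,
              terms_per_gene_mean = terms_per_gene_mean,
              n_traits = as.integer(n_traits),
              regions_per_trait = as.integer(regions_per_trait),
              region_gene_span = as.integer(region_gene_span),
              f_regions = f_regions,
              n_causal_per_region = as.integer(n_causal_per_region),
              causal_background_genes = as.integer(causal_background_genes),
              tf_fraction = tf_fraction,
              n_tf_families = as.integer(n_tf_families),
              snp_fraction = snp_fraction,
              reference_fraction = reference_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$n_chroms >= 1, cfg$genes_per_chrom >= 1,
            cfg$gene_length >= 1, cfg$intergenic_gap >= 0,
            cfg$n_terms > cfg$n_traits, cfg$generality_min >= 1,
            cfg$f_regions >= 0, cfg$f_regions <= 1,
            cfg$n_causal_per_region >= 0,
            cfg$n_traits >= 1, cfg$regions_per_trait >= 1)
  if (cfg$region_gene_span > cfg$genes_per_chrom) {
    stop("region_gene_span exceeds genes_per_chrom: region cannot fit")
  }
  if (cfg$n_causal_per_region > cfg$region_gene_span) {
    stop("cannot plant more causal genes than a region holds")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a QTL study with planted trait-BP signal
#'
#' Generates every input the pipeline consumes — genome, annotations, QTL
#' compendium, TF catalog, GWAS SNP hits and a fine-mapped reference set —
#' together with the planted ground truth. Background annotations are
#' assigned independently of genomic position, so any positional enrichment
#' is attributable solely to the planted signal; SNPs sit at the midpoints
#' of a random subset of planted genes and the reference set is a random
#' subset of planted genes.
#'
#' @param config A [simulation_config].
#' @return list with genome, annotation, compendium, tf_catalog (data.frame
#'   gene_id, family), snp_hits, reference_genes (data.frame gene_id,
#'   trait), ground_truth (per trait: causal_term, causal_genes,
#'   planted_regions) and the config.
#' @export
simulate_qtl_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_qtl_study_impl(config))
}

simulate_qtl_study_impl <- function(cfg) {
  G <- cfg$n_chroms * cfg$genes_per_chrom
  pitch <- cfg$gene_length + cfg$intergenic_gap
  idx <- seq_len(G)
  chrom_i <- (idx - 1L) %/% cfg$genes_per_chrom + 1L
  within <- (idx - 1L) %% cfg$genes_per_chrom
  genome <- genome_gene_set(data.frame(
    gene_id = sprintf("g%04d", idx),
    chrom = paste0("chr", chrom_i),
    start = within * pitch + 1L,
    end = within * pitch + cfg$gene_length,
    strand = rep_len(c("+", "-"), G),
    stringsAsFactors = FALSE
  ))
  gene_ids <- sprintf("g%04d", idx)  # ordered by genomic position

  terms <- sprintf("T%03d", seq_len(cfg$n_terms))
  causal_terms <- terms[seq_len(cfg$n_traits)]
  bg_terms <- setdiff(terms, causal_terms)

  # background term sizes: truncated power law, rescaled to the target
  # annotation density
  cap <- max(cfg$generality_min,
             floor(cfg$generality_cap_fraction * G))
  support <- cfg$generality_min:cap
  sizes <- sample(support, length(bg_terms), replace = TRUE,
                  prob = support^(-cfg$generality_alpha))
  target_total <- round(cfg$terms_per_gene_mean * G)
  sizes <- pmax(cfg$generality_min,
                pmin(cap, round(sizes * target_total / sum(sizes))))
  # capping biases the rescaled total; spread the remainder one gene at a
  # time over terms that still have slack
  for (pass in 1:200) {
    deficit <- target_total - sum(sizes)
    if (deficit == 0) break
    free <- if (deficit > 0) which(sizes < cap) else
      which(sizes > cfg$generality_min)
    if (length(free) == 0) break
    bump <- if (length(free) == 1) free else
      sample(free, min(abs(deficit), length(free)))
    sizes[bump] <- sizes[bump] + sign(deficit)
  }
  bg_pairs <- do.call(rbind, lapply(seq_along(bg_terms), function(i) {
    data.frame(gene_id = sample(gene_ids, sizes[i]),
               term_id = bg_terms[i], stringsAsFactors = FALSE)
  }))

  traits <- sprintf("trait%02d", seq_len(cfg$n_traits))
  regions <- do.call(rbind, lapply(seq_along(traits), function(t) {
    # a trait's regions are distinct loci: placed uniformly but without
    # overlapping each other, so region-level occurrence counts are exact
    placed <- matrix(integer(0), ncol = 2)
    do.call(rbind, lapply(seq_len(cfg$regions_per_trait), function(r) {
      for (attempt in 1:200) {
        ch <- sample.int(cfg$n_chroms, 1)
        first <- sample.int(
          cfg$genes_per_chrom - cfg$region_gene_span + 1L, 1)
        g_first <- (ch - 1L) * cfg$genes_per_chrom + first
        g_last <- g_first + cfg$region_gene_span - 1L
        clash <- nrow(placed) > 0 &&
          any(g_first <= placed[, 2] & g_last >= placed[, 1])
        if (!clash || attempt == 200L) break
      }
      placed <<- rbind(placed, c(g_first, g_last))
      data.frame(
        region_id = sprintf("%s_r%d", traits[t], r),
        trait = traits[t],
        chrom = paste0("chr", ch),
        start = genome$start[match(gene_ids[g_first], genome$gene_id)],
        end = genome$end[match(gene_ids[g_last], genome$gene_id)],
        first_gene = g_first, last_gene = g_last,
        stringsAsFactors = FALSE
      )
    }))
  }))

  n_planted_regions <- round(cfg$f_regions * cfg$regions_per_trait)
  causal_pairs <- NULL
  ground_truth <- list()
  for (t in seq_along(traits)) {
    tr <- traits[t]
    reg_t <- regions[regions$trait == tr, , drop = FALSE]
    planted_idx <- if (n_planted_regions > 0) {
      sort(sample.int(nrow(reg_t), n_planted_regions))
    } else integer(0)
    planted_genes <- character(0)
    for (ri in planted_idx) {
      pool <- gene_ids[reg_t$first_gene[ri]:reg_t$last_gene[ri]]
      picked <- sample(pool, min(cfg$n_causal_per_region, length(pool)))
      planted_genes <- union(planted_genes, picked)
    }
    region_pool <- unique(unlist(lapply(seq_len(nrow(reg_t)), function(ri) {
      gene_ids[reg_t$first_gene[ri]:reg_t$last_gene[ri]]
    })))
    # background carriers stay outside the trait's own regions so the
    # region-occurrence fraction of a causal term is exactly f_regions
    extra <- if (cfg$causal_background_genes > 0) {
      sample(setdiff(gene_ids, region_pool), cfg$causal_background_genes)
    } else character(0)
    carriers <- c(planted_genes, extra)
    if (length(carriers) > 0) {
      causal_pairs <- rbind(causal_pairs, data.frame(
        gene_id = carriers, term_id = causal_terms[t],
        stringsAsFactors = FALSE))
    }
    ground_truth[[tr]] <- list(
      causal_term = causal_terms[t],
      causal_genes = sort(planted_genes),
      planted_regions = reg_t$region_id[planted_idx]
    )
  }

  annotation <- function_annotation(rbind(bg_pairs, causal_pairs), genome)
  compendium <- qtl_compendium(
    regions[, c("region_id", "trait", "chrom", "start", "end")])

  n_tf <- round(cfg$tf_fraction * G)
  tf_catalog <- data.frame(
    gene_id = sort(sample(gene_ids, n_tf)),
    stringsAsFactors = FALSE)
  tf_catalog$family <- sample(sprintf("F%d", seq_len(cfg$n_tf_families)),
                              n_tf, replace = TRUE)

  planted_all <- sort(unique(unlist(lapply(ground_truth, `[[`,
                                           "causal_genes"))))
  snp_genes <- if (length(planted_all) > 0 && cfg$snp_fraction > 0) {
    # per trait so every trait with planted genes can contribute SNPs
    unlist(lapply(ground_truth, function(gt) {
      g <- gt$causal_genes
      if (length(g) == 0) return(character(0))
      sort(sample(g, max(1, round(cfg$snp_fraction * length(g)))))
    }))
  } else character(0)
  snp_hits <- if (length(snp_genes) > 0) {
    tr_of <- rep(names(ground_truth),
                 vapply(ground_truth, function(gt) {
                   g <- gt$causal_genes
                   if (length(g) == 0) 0L else
                     max(1L, as.integer(round(cfg$snp_fraction * length(g))))
                 }, integer(1)))
    gi <- match(snp_genes, genome$gene_id)
    data.frame(trait = tr_of, chrom = genome$chrom[gi],
               pos = as.integer((genome$start[gi] + genome$end[gi]) %/% 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(trait = character(0), chrom = character(0),
               pos = integer(0), stringsAsFactors = FALSE)
  }

  reference_genes <- do.call(rbind, lapply(names(ground_truth),
                                           function(tr) {
    g <- ground_truth[[tr]]$causal_genes
    if (length(g) == 0 || cfg$reference_fraction <= 0) return(NULL)
    data.frame(gene_id = sort(sample(g, max(1, round(
      cfg$reference_fraction * length(g))))),
      trait = tr, stringsAsFactors = FALSE)
  }))
  if (is.null(reference_genes)) {
    reference_genes <- data.frame(gene_id = character(0),
                                  trait = character(0))
  }

  list(genome = genome, annotation = annotation, compendium = compendium,
       tf_catalog = tf_catalog, snp_hits = snp_hits,
       reference_genes = reference_genes, ground_truth = ground_truth,
       config = cfg)
}

#' Write a simulated study to disk in the standard input formats
#'
#' Emits genes.gff3, qtl_regions.tsv, annotations.tsv, tf_list.tsv,
#' snp_hits.tsv, reference_genes.tsv and ground_truth.json. Re-reading the
#' files through the package readers reproduces the in-memory objects.
#'
#' @param sim Result of [simulate_qtl_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  paths <- c(
    genes = file.path(dir, "genes.gff3"),
    qtl = file.path(dir, "qtl_regions.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    tf = file.path(dir, "tf_list.tsv"),
    snps = file.path(dir, "snp_hits.tsv"),
    reference = file.path(dir, "reference_genes.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_gene_models_gff3(sim$genome, paths["genes"])
  write_tsv(as.data.frame(sim$compendium), paths["qtl"])
  ann <- sim$annotation$pairs
  write_tsv(ann[order(ann$gene_id, ann$term_id), ], paths["annotations"])
  write_tsv(sim$tf_catalog, paths["tf"])
  write_tsv(sim$snp_hits, paths["snps"])
  write_tsv(sim$reference_genes, paths["reference"])
  jsonlite::write_json(sim$ground_truth, paths["truth"],
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read a fixture directory back into pipeline inputs
#'
#' @param dir Directory written by [write_fixture()].
#' @return list(genome, annotation, compendium, tf_catalog, snp_hits,
#'   reference_genes, ground_truth).
#' @export
read_fixture <- function(dir) {
  genome <- read_gene_models(file.path(dir, "genes.gff3"), "gff3")
  annotation <- suppressMessages(
    read_annotations(file.path(dir, "annotations.tsv"), genome, "tsv2col"))
  compendium <- read_qtl_regions(file.path(dir, "qtl_regions.tsv"))
  list(
    genome = genome,
    annotation = annotation,
    compendium = compendium,
    tf_catalog = read_gene_list(file.path(dir, "tf_list.tsv")),
    snp_hits = read_snp_hits(file.path(dir, "snp_hits.tsv")),
    reference_genes = utils::read.delim(
      file.path(dir, "reference_genes.tsv"), stringsAsFactors = FALSE),
    ground_truth = jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                       simplifyVector = TRUE)
  )
}
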