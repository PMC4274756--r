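#' Permutation test of overlap with a reference gene set
#'
#' Assesses whether the prioritized genes retain more reference genes (e.g.
#' fine-mapped causal genes) than random selections of the same size. Per
#' iteration, one random gene set is drawn without replacement from each
#' trait's candidate set, with the same size as that trait's prioritized
#' set; the draws are pooled (union) and the number of distinct reference
#' genes they contain is counted. The empirical p-value is the fraction of
#' iterations whose overlap is at least the observed one.
#'
#' @param prioritized_by_trait Named list: per trait, character vector of
#'   prioritized gene ids.
#' @param candidates_by_trait Named list: per trait, character vector of
#'   candidate gene ids (must cover the prioritized genes and share names
#'   with `prioritized_by_trait`).
#' @param reference_genes Character vector of reference gene ids.
#' @param n_iter Number of iterations (the published analyses used 1,000).
#' @param seed Integer seed; the test is a pure function of (inputs, seed).
#' @param p_estimator `"count"` (count/n_iter; a zero count is reported as
#'   `< 1/n_iter`) or `"add_one"` ((count+1)/(n_iter+1)).
#' @return Object of class `permutation_result`: list(observed_overlap,
#'   n_iter, n_at_least, p_empirical, p_label, seed).
#' @export
permutation_overlap_test <- function(prioritized_by_trait,
                                     candidates_by_trait,
                                     reference_genes,
                                     n_iter = 1000L, seed = 1L,
                                     p_estimator = c("count", "add_one")) {
  p_estimator <- match.arg(p_estimator)
  traits <- names(prioritized_by_trait)
  stopifnot(!is.null(traits), all(traits %in% names(candidates_by_trait)))
  sizes <- vapply(prioritized_by_trait, length, integer(1))
  cand_sizes <- vapply(candidates_by_trait[traits], length, integer(1))
  if (any(sizes > cand_sizes)) {
    stop("prioritized set larger than candidate set for trait(s): ",
         paste(traits[sizes > cand_sizes], collapse = ", "))
  }
  reference_genes <- unique(reference_genes)
  observed <- length(intersect(
    unique(unlist(prioritized_by_trait, use.names = FALSE)),
    reference_genes))
  active <- traits[sizes > 0]
  overlaps <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      drawn <- unlist(lapply(active, function(tr) {
        sample(candidates_by_trait[[tr]], sizes[[tr]])
      }), use.names = FALSE)
      length(intersect(unique(drawn), reference_genes))
    }, integer(1))
  })
  n_at_least <- sum(overlaps >= observed)
  p <- if (p_estimator == "add_one") {
    (n_at_least + 1) / (n_iter + 1)
  } else {
    n_at_least / n_iter
  }
  label <- if (p_estimator == "count" && n_at_least == 0) {
    sprintf("< %g", 1 / n_iter)
  } else {
    sprintf("%g", p)
  }
  structure(list(observed_overlap = observed, n_iter = as.integer(n_iter),
                 n_at_least = n_at_least, p_empirical = p, p_label = label,
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test: observed overlap %d; p %s (%d/%d iterations >= observed; seed %d)\n",
    x$observed_overlap, x$p_label, x$n_at_least, x$n_iter, x$seed))
  invisible(x)
}

#' Randomly reassign gene functions
#'
#' Permutes gene identities over whole annotation bundles: gene i receives
#' the complete term set of gene pi(i), with pi a uniform random permutation
#' of the gene universe (unannotated genes carry empty bundles). Per-term
#' genome counts and the multiset of per-gene annotation counts are both
#' preserved exactly. This is the null model behind the "null run" mode.
#'
#' @param annotation A [function_annotation].
#' @param genome The [genome_gene_set] universe to permute over.
#' @param seed Integer seed.
#' @return A new [function_annotation] with permuted gene assignments.
#' @export
randomize_annotations <- function(annotation, genome, seed = 1L) {
  stopifnot(inherits(annotation, "function_annotation"),
            inherits(genome, "genome_gene_set"))
  genes <- genome$gene_id
  perm <- withr::with_seed(seed, sample(genes))
  # gene that currently holds bundle j hands it to perm[j]
  new_gene <- perm[match(annotation$pairs$gene_id, genes)]
  pairs <- data.frame(gene_id = new_gene,
                      term_id = annotation$pairs$term_id,
                      stringsAsFactors = FALSE)
  function_annotation(pairs, genome)
}

#' k nearest genes to a SNP
#'
#' Distance is 0 when the position falls inside the gene span, otherwise
#' the distance to the nearest span edge. Only same-chromosome genes are
#' considered; ties are broken by (distance, gene_id). Fewer than `k` genes
#' on the chromosome returns all of them; an unknown chromosome returns an
#' empty result with a warning.
#'
#' @param genome A [genome_gene_set].
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param k Number of genes to return (default 3, the GWAS neighborhood).
#' @return data.frame(gene_id, distance), ordered nearest-first.
#' @export
nearest_genes_to_snp <- function(genome, chrom, pos, k = 3L) {
  stopifnot(inherits(genome, "genome_gene_set"), k >= 1)
  g <- genome[genome$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) {
    warning("no genes on chromosome '", chrom, "'")
    return(data.frame(gene_id = character(0), distance = integer(0)))
  }
  inside <- pos >= g$start & pos <= g$end
  dist <- ifelse(inside, 0L, pmin(abs(pos - g$start), abs(pos - g$end)))
  ord <- order(dist, g$gene_id)
  take <- ord[seq_len(min(k, nrow(g)))]
  data.frame(gene_id = g$gene_id[take], distance = as.integer(dist[take]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' GWAS neighborhood overlap test
#'
#' For each trait shared between the prioritization results and the SNP
#' table, the neighborhood is the union of the `k` genes nearest to each of
#' the trait's SNPs. The observed statistic is the number of prioritized
#' genes falling in their trait's neighborhood, summed over traits. The
#' null draws random gene sets from each trait's candidates (same sizes as
#' the prioritized sets) and recomputes the same statistic.
#'
#' @inheritParams permutation_overlap_test
#' @param snp_hits data.frame(trait, chrom, pos) as from [read_snp_hits()].
#' @param genome A [genome_gene_set].
#' @param k Neighborhood size per SNP (default 3).
#' @return list with `result` (a `permutation_result`) and `matches`
#'   (data.frame trait, gene_id of observed neighborhood hits).
#' @export
gwas_overlap_test <- function(prioritized_by_trait, candidates_by_trait,
                              snp_hits, genome, k = 3L,
                              n_iter = 1000L, seed = 1L,
                              p_estimator = c("count", "add_one")) {
  p_estimator <- match.arg(p_estimator)
  shared <- intersect(names(prioritized_by_trait), unique(snp_hits$trait))
  if (length(shared) == 0) {
    stop("no trait shared between prioritization results and SNP hits")
  }
  neighborhoods <- lapply(shared, function(tr) {
    snps <- snp_hits[snp_hits$trait == tr, , drop = FALSE]
    unique(unlist(lapply(seq_len(nrow(snps)), function(i) {
      nearest_genes_to_snp(genome, snps$chrom[i], snps$pos[i], k)$gene_id
    }), use.names = FALSE))
  })
  names(neighborhoods) <- shared
  match_rows <- do.call(rbind, lapply(shared, function(tr) {
    hits <- intersect(unique(prioritized_by_trait[[tr]]),
                      neighborhoods[[tr]])
    if (length(hits) == 0) return(NULL)
    data.frame(trait = tr, gene_id = sort(hits), stringsAsFactors = FALSE)
  }))
  if (is.null(match_rows)) {
    match_rows <- data.frame(trait = character(0), gene_id = character(0))
  }
  observed <- nrow(match_rows)
  sizes <- vapply(prioritized_by_trait[shared], function(x)
    length(unique(x)), integer(1))
  cand_sizes <- vapply(candidates_by_trait[shared], length, integer(1))
  if (any(sizes > cand_sizes)) {
    stop("prioritized set larger than candidate set for trait(s): ",
         paste(shared[sizes > cand_sizes], collapse = ", "))
  }
  active <- shared[sizes > 0]
  stat <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      sum(vapply(active, function(tr) {
        length(intersect(sample(candidates_by_trait[[tr]], sizes[[tr]]),
                         neighborhoods[[tr]]))
      }, integer(1)))
    }, integer(1))
  })
  n_at_least <- sum(stat >= observed)
  p <- if (p_estimator == "add_one") {
    (n_at_least + 1) / (n_iter + 1)
  } else {
    n_at_least / n_iter
  }
  label <- if (p_estimator == "count" && n_at_least == 0) {
    sprintf("< %g", 1 / n_iter)
  } else {
    sprintf("%g", p)
  }
  res <- structure(list(observed_overlap = observed,
                        n_iter = as.integer(n_iter),
                        n_at_least = n_at_least, p_empirical = p,
                        p_label = label, seed = as.integer(seed)),
                   class = "permutation_result")
  list(result = res, matches = match_rows)
}

#' Transcription-factor profile of the prioritization
#'
#' Computes the percentage of transcription factors in the genome, among
#' all candidate genes, and among prioritized genes; TF percentages among
#' genes prioritized for at least k traits (default k = 1, 2, 4); and a
#' per-trait TF-family breakdown restricted, as in the published figure, to
#' traits with at least `min_tfs` prioritized TFs and at least one family
#' exceeding `family_pct` percent of them (only families exceeding that
#' share for some included trait are shown).
#'
#' @param prioritized Result of [prioritize_genes()].
#' @param candidate_sets Result of [build_trait_candidate_sets()].
#' @param genome A [genome_gene_set].
#' @param tf_catalog data.frame(gene_id\[, family\]) as from
#'   [read_gene_list()].
#' @param ks Integer vector of minimum-trait-count strata.
#' @param min_tfs Minimum prioritized TFs for a trait to enter the family
#'   breakdown (default 10).
#' @param family_pct Family share threshold in percent (default 25,
#'   exclusive).
#' @return Object of class `tf_profile`: list(pct_tf_genome,
#'   pct_tf_candidates, pct_tf_prioritized, strata, family_by_trait).
#' @export
tf_profile <- function(prioritized, candidate_sets, genome, tf_catalog,
                       ks = c(1L, 2L, 4L), min_tfs = 10L, family_pct = 25) {
  tf_genes <- intersect(unique(tf_catalog$gene_id), genome$gene_id)
  pct <- function(genes) {
    if (length(genes) == 0) return(NA_real_)
    100 * length(intersect(genes, tf_genes)) / length(genes)
  }
  all_cand <- unique(candidate_sets$candidates$gene_id)
  all_prio <- unique(prioritized$gene_id)
  traits_per_gene <- tapply(prioritized$trait, prioritized$gene_id,
                            function(x) length(unique(x)))
  strata <- vapply(ks, function(k) {
    pct(names(traits_per_gene)[traits_per_gene >= k])
  }, numeric(1))
  names(strata) <- paste0("k>=", ks)

  family_by_trait <- NULL
  if ("family" %in% names(tf_catalog)) {
    fam_of <- stats::setNames(tf_catalog$family, tf_catalog$gene_id)
    per_trait <- lapply(split(prioritized$gene_id, prioritized$trait),
                        function(g) intersect(unique(g), tf_genes))
    kept <- list()
    for (tr in names(per_trait)) {
      tfs <- per_trait[[tr]]
      if (length(tfs) < min_tfs) next
      fam_pct <- 100 * table(fam_of[tfs]) / length(tfs)
      if (any(fam_pct > family_pct)) {
        kept[[tr]] <- fam_pct
      }
    }
    if (length(kept) > 0) {
      fams <- sort(unique(unlist(lapply(kept, function(fp) {
        names(fp)[fp > family_pct]
      }))))
      family_by_trait <- do.call(rbind, lapply(names(kept), function(tr) {
        v <- as.numeric(kept[[tr]][fams])
        v[is.na(v)] <- 0
        stats::setNames(data.frame(trait = tr, t(v),
                                   stringsAsFactors = FALSE),
                        c("trait", fams))
      }))
      rownames(family_by_trait) <- NULL
    }
  }
  structure(list(
    pct_tf_genome = pct(genome$gene_id),
    pct_tf_candidates = pct(all_cand),
    pct_tf_prioritized = pct(all_prio),
    strata = strata,
    family_by_trait = family_by_trait
  ), class = "tf_profile")
}

#' @export
print.tf_profile <- function(x, ...) {
  cat(sprintf("TF share: genome %.1f%%, candidates %.1f%%, prioritized %.1f%%\n",
              x$pct_tf_genome, x$pct_tf_candidates, x$pct_tf_prioritized))
  for (nm in names(x$strata)) {
    cat(sprintf("  prioritized for %s traits: %.1f%%\n", nm, x$strata[nm]))
  }
  invisible(x)
}

#' Sweep the three prioritization parameters
#'
#' Re-runs the full pipeline (association testing, prioritization and the
#' reference-gene permutation test) at every grid point of
#' (fdr_threshold, min_region_fraction, max_generality), the procedure used
#' to pick the published operating point.
#'
#' @param genome A [genome_gene_set].
#' @param compendium A [qtl_compendium].
#' @param annotation A [function_annotation].
#' @param grid data.frame with columns fdr_threshold, min_region_fraction,
#'   max_generality (one row per configuration).
#' @param reference_genes Character vector of known causal genes.
#' @param base_params [analysis_parameters] supplying all non-swept
#'   settings.
#' @param n_iter Permutation iterations per grid point.
#' @param seed Integer seed (each grid point uses `seed`).
#' @return data.frame: the grid plus n_associations, n_prioritized, recall
#'   (fraction of attainable reference genes prioritized),
#'   prioritized_fraction (mean over traits) and permutation_p.
#' @export
parameter_sweep <- function(genome, compendium, annotation, grid,
                            reference_genes,
                            base_params = analysis_parameters(),
                            n_iter = 1000L, seed = 1L) {
  stopifnot(nrow(grid) > 0,
            all(c("fdr_threshold", "min_region_fraction",
                  "max_generality") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    params <- base_params
    params$fdr_threshold <- grid$fdr_threshold[i]
    params$min_region_fraction <- grid$min_region_fraction[i]
    params$max_generality <- grid$max_generality[i]
    run <- run_prioritization(genome, compendium, annotation, params)
    perm <- permutation_overlap_test(
      run$prioritized_by_trait, run$candidates_by_trait, reference_genes,
      n_iter = n_iter, seed = seed, p_estimator = base_params$p_estimator)
    attainable <- intersect(reference_genes,
                            unique(run$candidate_sets$candidates$gene_id))
    recall <- if (length(attainable) == 0) NA_real_ else {
      length(intersect(attainable, unique(run$prioritized$gene_id))) /
        length(attainable)
    }
    data.frame(
      fdr_threshold = params$fdr_threshold,
      min_region_fraction = params$min_region_fraction,
      max_generality = params$max_generality,
      n_associations = sum(run$associations$associated),
      n_prioritized = length(unique(run$prioritized$gene_id)),
      recall = recall,
      prioritized_fraction = run$reduction$global$mean_fraction,
      permutation_p = perm$p_empirical,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
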