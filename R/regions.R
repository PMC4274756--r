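#' Assign genes to QTL regions
#'
#' A gene belongs to a region when both are on the same chromosome and their
#' closed intervals intersect. Under the default `"any"` overlap rule one
#' shared base suffices; under `"contained"` the gene span must lie fully
#' inside the region. Strand is ignored.
#'
#' @param genome A [genome_gene_set].
#' @param compendium A [qtl_compendium].
#' @param overlap_rule `"any"` (default) or `"contained"`.
#' @return An object of class `region_gene_map`: list with `assignments`
#'   (data.frame region_id, trait, gene_id) and `regions` (the compendium
#'   plus `n_genes` and a `retained` flag, initially all `TRUE`).
#' @export
assign_genes_to_regions <- function(genome, compendium,
                                    overlap_rule = c("any", "contained")) {
  stopifnot(inherits(genome, "genome_gene_set"),
            inherits(compendium, "qtl_compendium"))
  overlap_rule <- match.arg(overlap_rule)
  if (nrow(genome) == 0) stop("genome gene set is empty")
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genome$chrom,
    ranges = IRanges::IRanges(genome$start, genome$end)
  )
  region_gr <- GenomicRanges::GRanges(
    seqnames = compendium$chrom,
    ranges = IRanges::IRanges(compendium$start, compendium$end)
  )
  type <- if (overlap_rule == "contained") "within" else "any"
  hits <- GenomicRanges::findOverlaps(gene_gr, region_gr, type = type)
  assignments <- data.frame(
    region_id = compendium$region_id[S4Vectors::subjectHits(hits)],
    trait = compendium$trait[S4Vectors::subjectHits(hits)],
    gene_id = genome$gene_id[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE
  )
  assignments <- assignments[order(assignments$region_id,
                                   assignments$gene_id), ]
  rownames(assignments) <- NULL
  regions <- as.data.frame(compendium, stringsAsFactors = FALSE)
  counts <- table(assignments$region_id)
  regions$n_genes <- as.integer(counts[regions$region_id])
  regions$n_genes[is.na(regions$n_genes)] <- 0L
  regions$retained <- TRUE
  structure(list(assignments = assignments, regions = regions),
            class = "region_gene_map")
}

#' Exclude over-large QTL regions
#'
#' Regions containing more than `max_region_genes` genes are flagged as not
#' retained (a region with exactly the threshold count is kept; an empty
#' region is vacuously kept). Everything downstream — candidate sets and the
#' region-occurrence denominator — sees only retained regions.
#'
#' @param map A `region_gene_map` from [assign_genes_to_regions()].
#' @param params An [analysis_parameters] (uses `max_region_genes`).
#' @return The map with the `retained` flag updated.
#' @export
filter_regions_by_size <- function(map, params = analysis_parameters()) {
  stopifnot(inherits(map, "region_gene_map"),
            inherits(params, "analysis_parameters"))
  map$regions$retained <- map$regions$n_genes <= params$max_region_genes
  n_excl <- sum(!map$regions$retained)
  if (n_excl > 0) {
    message(n_excl, " region(s) excluded by the ", params$max_region_genes,
            "-gene size cap")
  }
  map
}

#' Build per-trait candidate gene sets
#'
#' For each trait, the candidate set is the union of gene sets of its
#' retained regions (a gene occurring in several regions counts once).
#' Traits whose regions were all excluded by the size filter are dropped
#' and reported.
#'
#' @param map A size-filtered `region_gene_map`.
#' @param compendium The [qtl_compendium] (supplies the full trait list so
#'   dropped traits can be reported).
#' @return list with `candidates` (data.frame trait, gene_id), `summary`
#'   (data.frame trait, n_regions_retained, n_candidate_genes) and
#'   `dropped_traits` (character vector).
#' @export
build_trait_candidate_sets <- function(map, compendium) {
  stopifnot(inherits(map, "region_gene_map"),
            inherits(compendium, "qtl_compendium"))
  retained_ids <- map$regions$region_id[map$regions$retained]
  asg <- map$assignments[map$assignments$region_id %in% retained_ids, ,
                         drop = FALSE]
  candidates <- unique(asg[, c("trait", "gene_id")])
  candidates <- candidates[order(candidates$trait, candidates$gene_id), ]
  rownames(candidates) <- NULL

  retained_per_trait <- table(map$regions$trait[map$regions$retained])
  traits_kept <- names(retained_per_trait)[retained_per_trait > 0]
  all_traits <- sort(unique(compendium$trait))
  dropped <- setdiff(all_traits, traits_kept)
  if (length(dropped) > 0) {
    message(length(dropped),
            " trait(s) dropped: no QTL region passed the size filter (",
            paste(dropped, collapse = ", "), ")")
  }
  n_cand <- table(candidates$trait)
  summary <- data.frame(
    trait = sort(traits_kept),
    stringsAsFactors = FALSE
  )
  summary$n_regions_retained <-
    as.integer(retained_per_trait[summary$trait])
  summary$n_candidate_genes <- as.integer(n_cand[summary$trait])
  summary$n_candidate_genes[is.na(summary$n_candidate_genes)] <- 0L
  rownames(summary) <- NULL
  list(candidates = candidates, summary = summary, dropped_traits = dropped)
}

#' Candidate gene ids for one trait
#' @param candidate_sets Result of [build_trait_candidate_sets()].
#' @param trait Trait name.
#' @return Character vector of gene ids.
#' @export
trait_candidates <- function(candidate_sets, trait) {
  candidate_sets$candidates$gene_id[candidate_sets$candidates$trait == trait]
}
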