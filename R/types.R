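#' Construct a genome gene set
#'
#' The gene universe used as the Fisher background. Coordinates are 1-based
#' inclusive (GFF3 convention). Genes without any functional annotation stay
#' in the universe; the published background of 38,998 genes includes them.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (`+`, `-` or `*` for unknown).
#' @return An object of class `genome_gene_set`: the gene table sorted by
#'   (chrom, start, gene_id), with attribute-free access via `$`.
#' @export
genome_gene_set <- function(genes) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"strand" %in% names(genes)) genes$strand <- "*"
  genes$strand[is.na(genes$strand) | !genes$strand %in% c("+", "-")] <- "*"
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyNA(genes$start) || anyNA(genes$end)) {
    stop("gene coordinates must be integers")
  }
  bad <- which(genes$start > genes$end)
  if (length(bad) > 0) {
    stop("gene with start > end: ", genes$gene_id[bad[1]])
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  }
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id),
                 c("gene_id", "chrom", "start", "end", "strand")]
  rownames(genes) <- NULL
  structure(genes, class = c("genome_gene_set", "data.frame"))
}

#' Number of genes in a genome gene set
#' @param genome A `genome_gene_set`.
#' @return Integer count of distinct genes.
#' @export
genome_size <- function(genome) {
  stopifnot(inherits(genome, "genome_gene_set"))
  nrow(genome)
}

#' Construct a QTL compendium
#'
#' @param regions data.frame with columns `trait`, `chrom`, `start`, `end`
#'   and optionally `region_id`. When `region_id` is absent it is generated
#'   as `<trait>_r<ordinal>` within each trait.
#' @return An object of class `qtl_compendium`.
#' @export
qtl_compendium <- function(regions) {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  required <- c("trait", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    stop("QTL table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(regions) == 0) stop("QTL compendium is empty")
  regions$trait <- as.character(regions$trait)
  regions$chrom <- as.character(regions$chrom)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (anyNA(regions$start) || anyNA(regions$end)) {
    stop("region coordinates must be integers")
  }
  bad <- which(regions$start > regions$end)
  if (length(bad) > 0) {
    stop("region with start > end at row ", bad[1])
  }
  if (!"region_id" %in% names(regions) || all(is.na(regions$region_id))) {
    ord <- stats::ave(seq_len(nrow(regions)), regions$trait, FUN = seq_along)
    regions$region_id <- paste0(regions$trait, "_r", ord)
  }
  regions$region_id <- as.character(regions$region_id)
  dup <- regions$region_id[duplicated(regions$region_id)]
  if (length(dup) > 0) {
    stop("duplicate region_id: ", paste(unique(dup), collapse = ", "))
  }
  regions <- regions[, c("region_id", "trait", "chrom", "start", "end")]
  rownames(regions) <- NULL
  structure(regions, class = c("qtl_compendium", "data.frame"))
}

#' Trait names of a QTL compendium
#' @param compendium A `qtl_compendium`.
#' @return Character vector of distinct trait names, sorted.
#' @export
compendium_traits <- function(compendium) {
  stopifnot(inherits(compendium, "qtl_compendium"))
  sort(unique(compendium$trait))
}

#' Construct a gene-to-term functional annotation
#'
#' Stores the bipartite gene/BP-term map restricted to a gene universe, with
#' per-term genome-wide counts (the term's "generality" numerator).
#'
#' @param pairs data.frame with columns `gene_id`, `term_id`; duplicate
#'   pairs are collapsed.
#' @param universe A `genome_gene_set`; pairs whose gene is not in the
#'   universe are discarded (and counted in `n_discarded`).
#' @return An object of class `function_annotation`: list with `pairs`
#'   (sorted data.frame), `term_counts` (named integer vector of genome-wide
#'   gene counts per term), `universe_size`, `n_annotated_genes`,
#'   `n_discarded`.
#' @export
function_annotation <- function(pairs, universe) {
  stopifnot(inherits(universe, "genome_gene_set"))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("gene_id", "term_id"), names(pairs))
  if (length(missing_cols) > 0) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pairs$gene_id <- as.character(pairs$gene_id)
  pairs$term_id <- as.character(pairs$term_id)
  pairs <- unique(pairs[, c("gene_id", "term_id")])
  keep <- pairs$gene_id %in% universe$gene_id
  n_discarded <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) {
    stop("no annotations survive restriction to the gene universe")
  }
  pairs <- pairs[order(pairs$gene_id, pairs$term_id), ]
  rownames(pairs) <- NULL
  counts <- table(pairs$term_id)
  term_counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(
      pairs = pairs,
      term_counts = term_counts,
      universe_size = nrow(universe),
      n_annotated_genes = length(unique(pairs$gene_id)),
      n_discarded = n_discarded
    ),
    class = "function_annotation"
  )
}

#' Genes annotated with a term
#' @param annotation A `function_annotation`.
#' @param term_id Term identifier.
#' @return Character vector of gene ids (possibly empty).
#' @export
genes_of_term <- function(annotation, term_id) {
  stopifnot(inherits(annotation, "function_annotation"))
  annotation$pairs$gene_id[annotation$pairs$term_id == term_id]
}

#' Terms annotated to a gene
#' @param annotation A `function_annotation`.
#' @param gene_id Gene identifier.
#' @return Character vector of term ids (possibly empty).
#' @export
terms_of_gene <- function(annotation, gene_id) {
  stopifnot(inherits(annotation, "function_annotation"))
  annotation$pairs$term_id[annotation$pairs$gene_id == gene_id]
}

#' @export
print.function_annotation <- function(x, ...) {
  cat(sprintf(
    "function_annotation: %d gene-term pairs, %d terms, %d/%d genes annotated (%d pairs discarded)\n",
    nrow(x$pairs), length(x$term_counts), x$n_annotated_genes,
    x$universe_size, x$n_discarded
  ))
  invisible(x)
}
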