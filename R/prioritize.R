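#' Prioritize candidate genes
#'
#' Within each retained QTL region of a trait, the genes annotated with at
#' least one of the trait's associated biological-process terms are the
#' prioritized candidates — the most likely causal genes. A gene is emitted
#' once per (trait, region) in which it occurs; a gene lying in regions of
#' several traits can be prioritized for each trait independently. Traits
#' without associated terms contribute no rows.
#'
#' @param associations An `association_table` from [test_associations()].
#' @param map The size-filtered `region_gene_map`.
#' @param annotation A [function_annotation].
#' @return data.frame with columns trait, region_id, gene_id,
#'   supporting_terms (semicolon-joined associated terms annotated to the
#'   gene), sorted by (trait, region_id, gene_id).
#' @export
prioritize_genes <- function(associations, map, annotation) {
  stopifnot(inherits(map, "region_gene_map"),
            inherits(annotation, "function_annotation"))
  assoc <- associations[associations$associated, c("trait", "term"),
                        drop = FALSE]
  empty <- data.frame(trait = character(0), region_id = character(0),
                      gene_id = character(0),
                      supporting_terms = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(assoc) == 0) return(empty)
  reg_ok <- map$regions$region_id[map$regions$retained]
  asg <- map$assignments[map$assignments$region_id %in% reg_ok, ,
                         drop = FALSE]
  m <- merge(asg, annotation$pairs, by = "gene_id")
  names(m)[names(m) == "term_id"] <- "term"
  m <- merge(m, assoc, by = c("trait", "term"))
  if (nrow(m) == 0) return(empty)
  m <- m[order(m$trait, m$region_id, m$gene_id, m$term), ]
  key <- paste(m$trait, m$region_id, m$gene_id, sep = "\r")
  terms_by_row <- vapply(split(m$term, factor(key, levels = unique(key))),
                         function(x) paste(sort(unique(x)), collapse = ";"),
                         character(1))
  first <- m[!duplicated(key), c("trait", "region_id", "gene_id")]
  first$supporting_terms <- unname(terms_by_row)
  first <- first[order(first$trait, first$region_id, first$gene_id), ]
  rownames(first) <- NULL
  first
}

#' Prioritized gene ids for one trait (union over regions)
#' @param prioritized Result of [prioritize_genes()].
#' @param trait Trait name.
#' @return Character vector of distinct gene ids.
#' @export
trait_prioritized <- function(prioritized, trait) {
  sort(unique(prioritized$gene_id[prioritized$trait == trait]))
}

#' Regions where a gene is the only one annotated with a term
#'
#' The "prime candidate" refinement: among prioritized genes supported by
#' `term`, return those that are the unique term-annotated gene within
#' their region.
#'
#' @param prioritized Result of [prioritize_genes()].
#' @param map The size-filtered `region_gene_map`.
#' @param annotation A [function_annotation].
#' @param term Term id; must exist in the annotation.
#' @return data.frame(trait, region_id, gene_id).
#' @export
single_annotated_gene_regions <- function(prioritized, map, annotation,
                                          term) {
  stopifnot(inherits(annotation, "function_annotation"))
  if (!term %in% names(annotation$term_counts)) {
    stop("unknown term: ", term)
  }
  term_genes <- genes_of_term(annotation, term)
  asg <- map$assignments
  n_term_in_region <- table(asg$region_id[asg$gene_id %in% term_genes])
  supported <- prioritized[
    vapply(strsplit(prioritized$supporting_terms, ";", fixed = TRUE),
           function(ts) term %in% ts, logical(1)), , drop = FALSE]
  unique_regions <- names(n_term_in_region)[n_term_in_region == 1]
  out <- supported[supported$region_id %in% unique_regions,
                   c("trait", "region_id", "gene_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the candidate-set reduction achieved by prioritization
#'
#' @param prioritized Result of [prioritize_genes()].
#' @param candidate_sets Result of [build_trait_candidate_sets()].
#' @param map Optional size-filtered `region_gene_map`; when given, a
#'   per-region table (n_genes, n_selected) is included.
#' @return list with `per_trait` (trait, n_candidates, n_prioritized,
#'   fraction), `per_region` (or NULL), and `global`: unweighted mean and
#'   standard deviation of the per-trait fraction, plus mean/sd of genes
#'   selected per region when `map` is given.
#' @export
reduction_summary <- function(prioritized, candidate_sets, map = NULL) {
  summ <- candidate_sets$summary
  pr_by_trait <- lapply(summ$trait, function(tr) {
    unique(prioritized$gene_id[prioritized$trait == tr])
  })
  per_trait <- data.frame(
    trait = summ$trait,
    n_candidates = summ$n_candidate_genes,
    n_prioritized = vapply(pr_by_trait, length, integer(1)),
    stringsAsFactors = FALSE
  )
  per_trait$fraction <- ifelse(per_trait$n_candidates > 0,
                               per_trait$n_prioritized /
                                 per_trait$n_candidates, 0)
  per_region <- NULL
  region_stats <- NULL
  if (!is.null(map)) {
    reg <- map$regions[map$regions$retained, , drop = FALSE]
    key_pr <- paste(prioritized$trait, prioritized$region_id, sep = "\r")
    sel <- table(key_pr)
    key_reg <- paste(reg$trait, reg$region_id, sep = "\r")
    per_region <- data.frame(
      trait = reg$trait, region_id = reg$region_id, n_genes = reg$n_genes,
      n_selected = as.integer(sel[key_reg]), stringsAsFactors = FALSE
    )
    per_region$n_selected[is.na(per_region$n_selected)] <- 0L
    rownames(per_region) <- NULL
    region_stats <- list(
      mean_selected_per_region = mean(per_region$n_selected),
      sd_selected_per_region = stats::sd(per_region$n_selected)
    )
  }
  list(
    per_trait = per_trait,
    per_region = per_region,
    global = c(list(
      mean_fraction = mean(per_trait$fraction),
      sd_fraction = stats::sd(per_trait$fraction),
      n_traits = nrow(per_trait),
      n_traits_with_prioritized = sum(per_trait$n_prioritized > 0),
      n_prioritized_total = length(unique(prioritized$gene_id))
    ), region_stats)
  )
}
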