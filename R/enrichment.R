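#' Terms eligible for testing under the generality filter
#'
#' A term's generality is the fraction of genome genes annotated with it.
#' Only low-generality terms are informative for prioritization, so terms
#' above the cap are removed before any testing — they never enter the
#' multiple-testing burden. The default comparison is strict
#' (`generality < max_generality`, i.e. "less than 1%").
#'
#' @param annotation A [function_annotation].
#' @param genome A [genome_gene_set] (supplies the genome size `G`).
#' @param params An [analysis_parameters] (uses `max_generality`,
#'   `generality_cmp`, `annotated_only_background`).
#' @return Character vector of eligible term ids, sorted.
#' @export
eligible_terms <- function(annotation, genome,
                           params = analysis_parameters()) {
  stopifnot(inherits(annotation, "function_annotation"),
            inherits(genome, "genome_gene_set"))
  G <- enrichment_background_size(annotation, genome, params)
  gen <- annotation$term_counts / G
  ok <- if (params$generality_cmp == "lt") {
    gen < params$max_generality
  } else {
    gen <= params$max_generality
  }
  out <- sort(names(annotation$term_counts)[ok])
  if (length(out) == 0) {
    stop("no term passes the generality filter (max_generality = ",
         params$max_generality, "); review the threshold")
  }
  out
}

enrichment_background_size <- function(annotation, genome, params) {
  if (isTRUE(params$annotated_only_background)) {
    annotation$n_annotated_genes
  } else {
    nrow(genome)
  }
}

#' One-sided Fisher exact test for overrepresentation
#'
#' Exact upper-tail hypergeometric probability
#' P(X >= a) for X ~ Hypergeometric(K successes in a universe of G, n
#' draws): the probability of seeing at least `a` term-annotated genes among
#' `n` candidates when `K` of the `G` genome genes carry the term. Computed
#' with [stats::phyper()]; no normal approximation. Vectorized over the
#' count arguments.
#'
#' @param a Count of candidate genes annotated with the term.
#' @param n Candidate-set size.
#' @param K Genome-wide count of genes with the term.
#' @param G Genome size.
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' fisher_one_sided(4, 6, 5, 20)  # 540/38760
fisher_one_sided <- function(a, n, K, G) {
  check_fisher_counts(a, n, K, G)
  stats::phyper(a - 1, K, G - K, n, lower.tail = FALSE)
}

check_fisher_counts <- function(a, n, K, G) {
  if (any(a < 0) || any(n < 0) || any(K < 0) || any(G < 0) ||
      any(a > n) || any(a > K) || any(n > G) || any(K > G) ||
      any(a < pmax(0, n + K - G))) {
    stop("invalid 2x2 counts: need max(0, n+K-G) <= a <= min(n, K), ",
         "n <= G, K <= G")
  }
  invisible(TRUE)
}

#' Two-sided Fisher exact p-value
#'
#' Sum of all hypergeometric point probabilities not exceeding that of the
#' observed table (the convention of [stats::fisher.test()]). Offered as an
#' alternative to the default one-sided overrepresentation tail.
#'
#' @inheritParams fisher_one_sided
#' @return Numeric vector of p-values.
#' @export
fisher_two_sided <- function(a, n, K, G) {
  check_fisher_counts(a, n, K, G)
  mapply(function(a, n, K, G) {
    support <- max(0, n + K - G):min(n, K)
    d <- stats::dhyper(support, K, G - K, n)
    # relative tolerance on the density comparison, as in fisher.test
    sum(d[d <= d[support == a] * (1 + 1e-7)])
  }, a, n, K, G)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: with p-values sorted ascending,
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1 and mapped back to
#' the input order. Delegates to [stats::p.adjust()] after validating the
#' input range.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04, 0.8))
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Region-occurrence fraction of a term for a trait
#'
#' Fraction of the trait's retained QTL regions that contain at least one
#' gene annotated with the term (several annotated genes in one region
#' count once). This filter removes terms that are statistically enriched
#' but present in only a few of the trait's regions.
#'
#' @param trait Trait name.
#' @param term Term id.
#' @param map A size-filtered `region_gene_map`.
#' @param annotation A [function_annotation].
#' @return Fraction in \[0, 1\].
#' @export
region_occurrence_fraction <- function(trait, term, map, annotation) {
  stopifnot(inherits(map, "region_gene_map"),
            inherits(annotation, "function_annotation"))
  reg <- map$regions[map$regions$trait == trait & map$regions$retained, ,
                     drop = FALSE]
  if (nrow(reg) == 0) {
    stop("trait '", trait, "' has no retained regions; it should have been ",
         "dropped before testing")
  }
  term_genes <- genes_of_term(annotation, term)
  asg <- map$assignments
  hit <- asg$region_id %in% reg$region_id & asg$gene_id %in% term_genes
  length(unique(asg$region_id[hit])) / nrow(reg)
}

#' Test all trait/term combinations for overrepresentation
#'
#' For every trait with a nonempty candidate set and every eligible term
#' present in that set (at least one annotated candidate gene, unless
#' `include_zero_counts`), builds the 2x2 table, computes the Fisher
#' p-value, and applies a single Benjamini-Hochberg correction pooled over
#' all rows of the table — all traits and all terms jointly. A row is
#' `associated` when `q_bh <= fdr_threshold` and its region-occurrence
#' fraction is at least `min_region_fraction`.
#'
#' @param candidate_sets Result of [build_trait_candidate_sets()].
#' @param map The size-filtered `region_gene_map` used to build them.
#' @param annotation A [function_annotation].
#' @param genome A [genome_gene_set].
#' @param params An [analysis_parameters].
#' @return data.frame of class `association_table` with columns trait,
#'   term, a, n, K, G, p_raw, q_bh, region_fraction, associated.
#' @export
test_associations <- function(candidate_sets, map, annotation, genome,
                              params = analysis_parameters()) {
  stopifnot(inherits(annotation, "function_annotation"),
            inherits(genome, "genome_gene_set"),
            inherits(params, "analysis_parameters"))
  eligible <- eligible_terms(annotation, genome, params)
  G <- enrichment_background_size(annotation, genome, params)
  pairs <- annotation$pairs[annotation$pairs$term_id %in% eligible, ,
                            drop = FALSE]

  cand <- candidate_sets$candidates
  summ <- candidate_sets$summary
  rows <- lapply(summ$trait, function(tr) {
    genes <- cand$gene_id[cand$trait == tr]
    n <- length(genes)
    if (n == 0) return(NULL)
    sub <- pairs[pairs$gene_id %in% genes, , drop = FALSE]
    a_tab <- table(sub$term_id)
    if (params$include_zero_counts) {
      terms <- eligible
      a <- as.integer(a_tab[terms])
      a[is.na(a)] <- 0L
    } else {
      terms <- sort(names(a_tab))
      if (length(terms) == 0) return(NULL)
      a <- as.integer(a_tab[terms])
    }
    data.frame(trait = tr, term = terms, a = a, n = n,
               K = as.integer(annotation$term_counts[terms]),
               G = G, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) {
    tab <- data.frame(trait = character(0), term = character(0),
                      a = integer(0), n = integer(0), K = integer(0),
                      G = integer(0), p_raw = numeric(0), q_bh = numeric(0),
                      region_fraction = numeric(0), associated = logical(0))
    class(tab) <- c("association_table", "data.frame")
    return(tab)
  }
  tab$p_raw <- if (params$two_sided) {
    fisher_two_sided(tab$a, tab$n, tab$K, tab$G)
  } else {
    fisher_one_sided(tab$a, tab$n, tab$K, tab$G)
  }
  tab$q_bh <- bh_adjust(tab$p_raw)
  tab$region_fraction <- region_fraction_table(tab, map, annotation)
  tab$associated <- tab$q_bh <= params$fdr_threshold &
    tab$region_fraction >= params$min_region_fraction
  tab <- tab[order(tab$trait, tab$term), ]
  rownames(tab) <- NULL
  class(tab) <- c("association_table", "data.frame")
  tab
}

# Vectorized region-occurrence fractions for every (trait, term) row.
region_fraction_table <- function(tab, map, annotation) {
  reg <- map$regions[map$regions$retained, , drop = FALSE]
  asg <- map$assignments[map$assignments$region_id %in% reg$region_id, ,
                         drop = FALSE]
  # distinct (trait, region, term) occurrences via a pairs join
  m <- merge(asg, annotation$pairs, by = "gene_id")
  m <- unique(m[, c("trait", "region_id", "term_id")])
  occ <- stats::aggregate(region_id ~ trait + term_id, data = m,
                          FUN = function(x) length(unique(x)))
  names(occ)[names(occ) == "region_id"] <- "n_occ"
  denom <- table(reg$trait)
  key_tab <- paste(tab$trait, tab$term, sep = "\r")
  key_occ <- paste(occ$trait, occ$term_id, sep = "\r")
  n_occ <- occ$n_occ[match(key_tab, key_occ)]
  n_occ[is.na(n_occ)] <- 0L
  n_occ / as.integer(denom[tab$trait])
}

#' Associated terms per trait
#' @param associations An `association_table`.
#' @return Named list: for each trait with at least one association, the
#'   character vector of associated term ids.
#' @export
associated_terms <- function(associations) {
  assoc <- associations[associations$associated, , drop = FALSE]
  split(assoc$term, assoc$trait)
}
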