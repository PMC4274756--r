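#' Analysis parameters
#'
#' Bundles the thresholds of the prioritization method. The defaults are the
#' published optimized values: FDR 0.1, a biological-process term must occur
#' in at least 50% of a trait's QTL regions, term generality below 1% of the
#' genome, and QTL regions with more than 450 genes are excluded.
#'
#' @param fdr_threshold Benjamini-Hochberg FDR cutoff on adjusted p-values
#'   (inclusive: a term is associated when `q <= fdr_threshold`).
#' @param min_region_fraction Minimum fraction of a trait's retained QTL
#'   regions in which an associated term must occur (inclusive `>=`).
#' @param max_generality Maximum allowed term generality, as a fraction of
#'   genome genes annotated with the term.
#' @param max_region_genes Maximum number of genes a QTL region may contain;
#'   regions with more genes are excluded (a region with exactly this many
#'   genes is retained).
#' @param permutation_iters Number of iterations for permutation tests.
#' @param rng_seed Integer seed used by stochastic operations.
#' @param generality_cmp `"lt"` (strict `<`, default) or `"le"` (`<=`) for
#'   the generality eligibility comparison.
#' @param overlap_rule `"any"` (default; a gene belongs to a region when it
#'   shares at least one base) or `"contained"` (gene span fully inside the
#'   region).
#' @param include_zero_counts If `TRUE`, (trait, term) pairs with zero
#'   annotated candidate genes are also tested (p = 1 rows enter the
#'   multiple-testing burden). Default `FALSE`.
#' @param two_sided If `TRUE`, use the two-sided Fisher exact p-value
#'   instead of the one-sided overrepresentation tail. Default `FALSE`.
#' @param annotated_only_background If `TRUE`, the Fisher background `G` is
#'   the number of annotated genes rather than all genes in the gene-model
#'   file. Default `FALSE`.
#' @param p_estimator `"count"` (default; empirical p = count/n_iter) or
#'   `"add_one"` ((count + 1)/(n_iter + 1)).
#'
#' @return An object of class `analysis_parameters`.
#' @export
#' @examples
#' analysis_parameters()
#' analysis_parameters(fdr_threshold = 0.05, max_generality = 0.2)
analysis_parameters <- function(fdr_threshold = 0.1,
                                min_region_fraction = 0.5,
                                max_generality = 0.01,
                                max_region_genes = 450L,
                                permutation_iters = 1000L,
                                rng_seed = 1L,
                                generality_cmp = c("lt", "le"),
                                overlap_rule = c("any", "contained"),
                                include_zero_counts = FALSE,
                                two_sided = FALSE,
                                annotated_only_background = FALSE,
                                p_estimator = c("count", "add_one")) {
  generality_cmp <- match.arg(generality_cmp)
  overlap_rule <- match.arg(overlap_rule)
  p_estimator <- match.arg(p_estimator)
  stopifnot(
    is.numeric(fdr_threshold), length(fdr_threshold) == 1L,
    fdr_threshold >= 0, fdr_threshold <= 1,
    is.numeric(min_region_fraction), length(min_region_fraction) == 1L,
    min_region_fraction >= 0, min_region_fraction <= 1,
    is.numeric(max_generality), length(max_generality) == 1L,
    max_generality > 0, max_generality <= 1,
    is.numeric(max_region_genes), length(max_region_genes) == 1L,
    max_region_genes >= 0,
    is.numeric(permutation_iters), permutation_iters >= 1,
    is.numeric(rng_seed), length(rng_seed) == 1L
  )
  structure(
    list(
      fdr_threshold = as.numeric(fdr_threshold),
      min_region_fraction = as.numeric(min_region_fraction),
      max_generality = as.numeric(max_generality),
      max_region_genes = as.integer(max_region_genes),
      permutation_iters = as.integer(permutation_iters),
      rng_seed = as.integer(rng_seed),
      generality_cmp = generality_cmp,
      overlap_rule = overlap_rule,
      include_zero_counts = isTRUE(include_zero_counts),
      two_sided = isTRUE(two_sided),
      annotated_only_background = isTRUE(annotated_only_background),
      p_estimator = p_estimator
    ),
    class = "analysis_parameters"
  )
}

#' @export
print.analysis_parameters <- function(x, ...) {
  cat("Analysis parameters:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, as.character(x[[nm]])))
  }
  invisible(x)
}
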