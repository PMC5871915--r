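#' Select highly mutated genes
#'
#' Genes whose cohort mutation frequency is at least `min_freq`. The default
#' 5% reflects the observation that most altered genes in a tumor type fall
#' below that frequency, which is exactly why threshold-based selection can
#' miss dispersed pathway drivers. `top_n` offers an alternative selection of
#' the `top_n` most frequently mutated genes (ties broken by gene name).
#'
#' @param cohort a [mutation_cohort].
#' @param min_freq frequency threshold in (0, 1].
#' @param top_n if non-`NULL`, overrides `min_freq`.
#' @return Character vector of gene symbols.
#' @export
select_highly_mutated <- function(cohort, min_freq = 0.05, top_n = NULL) {
  stopifnot(inherits(cohort, "mutation_cohort"))
  freq <- colMeans(cohort$M)
  if (!is.null(top_n)) {
    ord <- order(-freq, names(freq))
    return(sort(names(freq)[ord[seq_len(min(top_n, length(freq)))]]))
  }
  stopifnot(min_freq > 0, min_freq <= 1)
  sort(names(freq)[freq >= min_freq])
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` that contains `K` pathway genes, the probability of an
#' overlap of at least `k`.
#'
#' @param k observed overlap.
#' @param K pathway size within the universe.
#' @param n number of selected genes.
#' @param N universe size.
#' @return p-value in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop(sprintf("inconsistent counts: k=%d K=%d n=%d N=%d", k, K, n, N))
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric pathway enrichment (no-network baseline)
#'
#' Overlaps a selected gene set (e.g. highly mutated genes, or a patient's
#' mutated genes) with each pathway and assigns upper-tail hypergeometric
#' p-values. Pathway genes are intersected with the universe first.
#'
#' @param selected character vector of selected genes, must be a subset of
#'   `universe`.
#' @param pathways a [pathway_collection].
#' @param universe character vector defining the gene universe (default
#'   should be the cohort's gene set; switch to the network's genes for
#'   symmetry with the propagation arm).
#' @return A `data.frame` (class `enrichment_table`) with columns `pathway`,
#'   `N`, `K`, `n`, `k`, `p_hypergeom`, ordered by p then pathway name.
#' @export
enrich <- function(selected, pathways, universe) {
  stopifnot(inherits(pathways, "pathway_collection"))
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, universe)
  if (length(outside) > 0) {
    stop("selected genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(pathways$pathways), function(nm) {
    pw <- intersect(pathways$pathways[[nm]], universe)
    K <- length(pw)
    k <- length(intersect(selected, pw))
    data.frame(pathway = nm, N = N, K = K, n = n, k = k,
               p_hypergeom = hypergeom_pvalue(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_hypergeom, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write an enrichment table as TSV
#'
#' @param tab an `enrichment_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(tab, path) {
  out <- as.data.frame(tab)
  out$p_hypergeom <- format_full(out$p_hypergeom)
  write_tsv(out, path)
}
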