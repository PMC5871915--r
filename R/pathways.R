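#' Pathway collection
#'
#' Named gene sets (KEGG-style). Every set must be non-empty and names
#' unique.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param source free-text provenance string.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(sets, source = "") {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("all pathways must be named")
  }
  if (anyDuplicated(names(sets))) stop("duplicate pathway names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("empty pathway gene set")
  structure(list(pathways = sets, source = source),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways, median size %g\n",
              length(x$pathways), stats::median(lengths(x$pathways))))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One pathway per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return A [pathway_collection].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    stop(sprintf("malformed GMT line %d (need name, description, >=1 gene)",
                 short[1]))
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  pathway_collection(sets, source = path)
}

#' Write gene sets in GMT format
#'
#' @param pathways a [pathway_collection].
#' @param path output path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path, description = "na") {
  stopifnot(inherits(pathways, "pathway_collection"))
  lines <- vapply(names(pathways$pathways), function(nm) {
    paste(c(nm, description, pathways$pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Pathway score: summed stationary scores
#'
#' Sum of stationary propagation scores over the pathway genes present in
#' the network; absent genes contribute 0.
#'
#' @param scores a `stationary_scores` object or named numeric vector.
#' @param genes character vector of pathway gene symbols.
#' @return The summed score (numeric scalar).
#' @export
pathway_score <- function(scores, genes) {
  vals <- seed_values(scores)
  sum(vals[intersect(unique(genes), names(vals))])
}

#' Empirical null distribution of size-matched random gene sets
#'
#' Scores of `n_null` gene sets of `set_size` genes drawn uniformly without
#' replacement from the gene universe of `scores`, each scored as the sum of
#' stationary scores. Reproducible given `rng_seed`.
#'
#' @inheritParams pathway_score
#' @param set_size number of genes per random set.
#' @param n_null number of random sets; 10,000 by default.
#' @param rng_seed integer seed.
#' @return Numeric vector of `n_null` null scores.
#' @export
empirical_null <- function(scores, set_size, n_null = 10000L, rng_seed = 1L) {
  vals <- seed_values(scores)
  nuniv <- length(vals)
  if (set_size > nuniv) {
    stop(sprintf("set_size (%d) exceeds gene universe (%d)", set_size, nuniv))
  }
  stopifnot(set_size >= 1, n_null >= 1)
  withr::with_seed(rng_seed, {
    idx <- replicate(n_null, sample.int(nuniv, set_size))
    colSums(matrix(vals[idx], nrow = set_size))
  })
}

#' Empirical p-value with the add-one convention
#'
#' `p = (#\{null >= observed\} + 1) / (length(null) + 1)`; one-sided, large
#' scores significant. The minimum attainable p is `1 / (n_null + 1)`, so
#' finite resampling never yields p = 0.
#'
#' @param observed observed score.
#' @param null numeric vector of null scores.
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null) {
  stopifnot(length(null) >= 1)
  (sum(null >= observed) + 1) / (length(null) + 1)
}

#' Score all pathways against size-matched empirical nulls
#'
#' For each pathway: map its genes onto the gene universe of `scores`, sum
#' the stationary scores, and compare against `n_null` random gene sets of
#' the same network-mapped size ("same size" = mapped gene count, since
#' unmapped genes contribute 0 to both the observed and the null sums; set
#' `size_from = "annotated"` for the alternative). Null draws are cached per
#' set size, so equally sized pathways share one null sample: the per-size
#' RNG seed is `rng_seed + size`.
#'
#' @inheritParams empirical_null
#' @param pathways a [pathway_collection].
#' @param min_size pathways with fewer network-mapped genes are dropped
#'   (default 5).
#' @param null_universe optional character vector restricting the gene
#'   universe the random sets are drawn from; defaults to all network genes
#'   carried by `scores`.
#' @param size_from `"mapped"` (default) or `"annotated"`.
#' @param adjust if `TRUE`, append a Benjamini-Hochberg `q_value` column
#'   (off by default; raw empirical p-values are the primary output).
#' @return A `data.frame` (class `pathway_score_table`) with columns
#'   `pathway`, `n_genes`, `n_in_network`, `score`, `p_empirical`, `n_null`
#'   (plus `q_value` when `adjust = TRUE`).
#' @export
score_pathways <- function(scores, pathways, n_null = 10000L, rng_seed = 1L,
                           min_size = 5L, null_universe = NULL,
                           size_from = c("mapped", "annotated"),
                           adjust = FALSE) {
  size_from <- match.arg(size_from)
  stopifnot(inherits(pathways, "pathway_collection"))
  vals <- seed_values(scores)
  if (!is.null(null_universe)) {
    keep <- intersect(names(vals), null_universe)
    vals <- vals[keep]
  }
  mapped <- lapply(pathways$pathways, function(g) {
    intersect(unique(g), names(vals))
  })
  n_total <- lengths(pathways$pathways)
  n_mapped <- lengths(mapped)
  keep <- n_mapped >= min_size
  nulls <- new.env(parent = emptyenv())
  rows <- lapply(which(keep), function(i) {
    obs <- sum(vals[mapped[[i]]])
    s <- if (size_from == "mapped") n_mapped[i] else n_total[i]
    s <- min(s, length(vals))
    key <- as.character(s)
    if (is.null(nulls[[key]])) {
      nulls[[key]] <- empirical_null(vals, s, n_null = n_null,
                                     rng_seed = rng_seed + s)
    }
    data.frame(pathway = names(pathways$pathways)[i],
               n_genes = as.integer(n_total[i]),
               n_in_network = as.integer(n_mapped[i]),
               score = obs,
               p_empirical = empirical_pvalue(obs, nulls[[key]]),
               n_null = as.integer(n_null),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(pathway = character(), n_genes = integer(),
               n_in_network = integer(), score = numeric(),
               p_empirical = numeric(), n_null = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (adjust) out$q_value <- stats::p.adjust(out$p_empirical, method = "BH")
  class(out) <- c("pathway_score_table", "data.frame")
  out
}

#' Cohort-mode pathway analysis
#'
#' Propagates gene mutation frequencies over the network
#' (`lambda = 0.5` by default) and scores every pathway against
#' size-matched random gene-set nulls.
#'
#' @param cohort a [mutation_cohort].
#' @param op a `propagation_operator`.
#' @param pathways a [pathway_collection].
#' @param lambda propagation weight; cohort-mode default 0.5.
#' @inheritParams score_pathways
#' @param ... passed to [score_pathways()].
#' @return A `pathway_score_table`.
#' @export
score_cohort <- function(cohort, op, pathways, lambda = 0.5,
                         n_null = 10000L, rng_seed = 1L, ...) {
  seed <- cohort_seed(cohort)
  scores <- propagate(op, seed, lambda = lambda)
  score_pathways(scores, pathways, n_null = n_null, rng_seed = rng_seed, ...)
}

#' Patient-mode pathway analysis
#'
#' For every patient: build the normalized mutation-indicator seed,
#' propagate it over the network (`lambda = 0.1` by default) and score all
#' pathways against size-matched empirical nulls computed under that
#' patient's stationary scores. Patients with no network-mapped mutation
#' are skipped with a warning and reported in `skipped`.
#'
#' @inheritParams score_cohort
#' @param lambda propagation weight; patient-mode default 0.1.
#' @return List with `tables` (named list of `pathway_score_table`, one per
#'   retained patient) and `skipped` (character vector of sample IDs).
#' @export
score_patients <- function(cohort, op, pathways, lambda = 0.1,
                           n_null = 10000L, rng_seed = 1L, ...) {
  tables <- list()
  skipped <- character()
  for (s in cohort$samples) {
    seed <- withCallingHandlers(
      patient_seed(cohort, s, genes = op$genes),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(seed)) {
      skipped <- c(skipped, s)
      next
    }
    scores <- propagate(op, seed, lambda = lambda)
    tables[[s]] <- score_pathways(scores, pathways, n_null = n_null,
                                  rng_seed = rng_seed, ...)
  }
  if (length(skipped) > 0) {
    warning(sprintf("%d patient(s) skipped (no network-mapped mutation)",
                    length(skipped)))
  }
  list(tables = tables, skipped = skipped)
}

#' Write a pathway score table as TSV
#'
#' @param tab a `pathway_score_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path) {
  out <- as.data.frame(tab)
  out$score <- format_full(out$score)
  out$p_empirical <- format_full(out$p_empirical)
  write_tsv(out, path)
}
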