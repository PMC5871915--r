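#' Somatic mutation cohort
#'
#' A binary patients-by-genes somatic-mutation matrix with unique sample and
#' gene identifiers.
#'
#' @param M numeric/integer matrix with entries in {0, 1}; rownames are
#'   sample IDs, colnames gene symbols.
#' @return An object of class `mutation_cohort` with elements `M`, `samples`
#'   and `genes`.
#' @export
mutation_cohort <- function(M) {
  M <- as.matrix(M)
  if ((is.null(rownames(M)) && nrow(M) > 0) ||
      (is.null(colnames(M)) && ncol(M) > 0)) {
    stop("mutation matrix must carry sample rownames and gene colnames")
  }
  if (is.null(rownames(M))) rownames(M) <- character(0)
  if (is.null(colnames(M))) colnames(M) <- character(0)
  if (anyDuplicated(rownames(M))) stop("duplicate sample IDs")
  if (anyDuplicated(colnames(M))) stop("duplicate gene symbols")
  bad <- which(!(M %in% c(0, 1)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(M))
    stop(sprintf("non-binary mutation entry at sample '%s', gene '%s': %s",
                 rownames(M)[rc[1]], colnames(M)[rc[2]], M[bad[1]]))
  }
  storage.mode(M) <- "integer"
  if (nrow(M) == 0) warning("mutation cohort has 0 samples")
  structure(list(M = M, samples = rownames(M), genes = colnames(M)),
            class = "mutation_cohort")
}

#' @export
print.mutation_cohort <- function(x, ...) {
  cat(sprintf("mutation_cohort: %d samples x %d genes, %d mutations\n",
              nrow(x$M), ncol(x$M), sum(x$M)))
  invisible(x)
}

#' Read somatic mutations from disk
#'
#' `matrix_tsv` expects samples in rows and genes in columns with 0/1 cells
#' (first column = sample ID). `maf_lite` expects a TSV with at least the
#' columns `Hugo_Symbol` and `Tumor_Sample_Barcode`; rows are aggregated to
#' binary presence per (sample, gene) and both axes sorted lexicographically.
#'
#' @param path input path.
#' @param fmt `"matrix_tsv"` or `"maf_lite"`.
#' @return A [mutation_cohort].
#' @export
load_mutations <- function(path, fmt = c("matrix_tsv", "maf_lite")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("mutation file not found: ", path)
  if (fmt == "matrix_tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 1) stop("empty mutation matrix file")
    M <- as.matrix(tab[, -1, drop = FALSE])
    rownames(M) <- as.character(tab[[1]])
    mutation_cohort(M)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    need <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
    miss <- setdiff(need, colnames(tab))
    if (length(miss) > 0) {
      stop("MAF file missing required column(s): ",
           paste(miss, collapse = ", "))
    }
    samples <- sort(unique(as.character(tab$Tumor_Sample_Barcode)))
    genes <- sort(unique(as.character(tab$Hugo_Symbol)))
    M <- matrix(0L, length(samples), length(genes),
                dimnames = list(samples, genes))
    if (nrow(tab) > 0) {
      M[cbind(match(tab$Tumor_Sample_Barcode, samples),
              match(tab$Hugo_Symbol, genes))] <- 1L
    }
    mutation_cohort(M)
  }
}

#' Write a mutation cohort as a matrix TSV
#'
#' @param cohort a [mutation_cohort].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(cohort, path) {
  stopifnot(inherits(cohort, "mutation_cohort"))
  df <- data.frame(sample = cohort$samples, cohort$M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Cohort-level seed vector: gene mutation frequencies
#'
#' The seed for cohort-mode propagation is each gene's mutation frequency
#' among the patients.
#'
#' @param cohort a [mutation_cohort] with at least one sample.
#' @return Named numeric vector in `[0, 1]` with attribute
#'   `mode = "cohort_frequency"`.
#' @export
cohort_seed <- function(cohort) {
  stopifnot(inherits(cohort, "mutation_cohort"))
  if (nrow(cohort$M) < 1) stop("cohort has no samples")
  v <- colMeans(cohort$M)
  attr(v, "mode") <- "cohort_frequency"
  v
}

#' Patient-level seed vector: normalized mutation indicator
#'
#' The seed for patient-mode propagation is 1 for the patient's mutated
#' genes and 0 elsewhere, normalized to sum to 1. When `genes` (typically
#' the network gene universe) is supplied, the indicator is restricted to it
#' first; a patient with no mutated gene mapping to `genes` cannot be
#' propagated and yields `NULL` with a warning (the skip sentinel used by
#' [score_patients()]).
#'
#' @param cohort a [mutation_cohort].
#' @param sample_id a sample identifier present in the cohort.
#' @param genes optional gene universe to restrict to.
#' @return Named numeric vector summing to 1 with attribute
#'   `mode = "patient_indicator"`, or `NULL` if no mutation maps.
#' @export
patient_seed <- function(cohort, sample_id, genes = NULL) {
  stopifnot(inherits(cohort, "mutation_cohort"))
  if (!sample_id %in% cohort$samples) {
    stop("unknown sample ID: ", sample_id)
  }
  mut <- cohort$genes[cohort$M[sample_id, ] == 1L]
  if (!is.null(genes)) mut <- intersect(mut, genes)
  if (length(mut) == 0) {
    warning(sprintf("sample '%s' has no network-mapped mutation; skipped",
                    sample_id))
    return(NULL)
  }
  v <- stats::setNames(rep(1 / length(mut), length(mut)), mut)
  attr(v, "mode") <- "patient_indicator"
  v
}
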