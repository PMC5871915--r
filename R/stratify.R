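#' Assemble the patients x pathways feature matrix
#'
#' Stacks per-patient pathway score tables into a matrix of
#' `-log10(p_empirical)` features. All tables must cover the same pathway
#' list. Entries lie in `[0, log10(n_null + 1)]`: the add-one p-value floor
#' caps the features naturally, so no extra winsorization is applied.
#'
#' @param tables named list of `pathway_score_table`s (sample ID -> table),
#'   e.g. `score_patients(...)$tables`.
#' @return Numeric matrix, rownames = sample IDs, colnames = pathway names.
#' @export
build_feature_matrix <- function(tables) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  ref <- tables[[1]]$pathway
  for (s in names(tables)) {
    if (!identical(tables[[s]]$pathway, ref)) {
      diff <- union(setdiff(tables[[s]]$pathway, ref),
                    setdiff(ref, tables[[s]]$pathway))
      stop(sprintf("pathway set mismatch for sample '%s': %s", s,
                   paste(utils::head(diff, 5), collapse = ", ")))
    }
  }
  F <- t(vapply(tables, function(tab) -log10(tab$p_empirical),
                numeric(length(ref))))
  dimnames(F) <- list(names(tables), ref)
  F
}

#' Hierarchical clustering of patients
#'
#' Clusters the rows of the feature matrix with agglomerative hierarchical
#' clustering and cuts the tree into `k` groups. Labels are stabilized: the
#' cluster whose centroid has the largest mean feature gets label 1, and so
#' on in decreasing order, so cluster numbering is comparable across reruns.
#' Ties are broken by sample order via `stats::hclust`'s deterministic
#' agglomeration.
#'
#' @param F numeric samples x features matrix (rownames = sample IDs).
#' @param k number of clusters (must be <= number of samples).
#' @param linkage `"ward"` (mapped to `hclust`'s `"ward.D2"`), `"average"`
#'   or `"complete"`.
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson on rows).
#' @return Named integer vector of group labels in `1..k`.
#' @export
hierarchical_cluster <- function(F, k = 3L,
                                 linkage = c("ward", "average", "complete"),
                                 metric = c("euclidean", "correlation")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  F <- as.matrix(F)
  if (k > nrow(F)) stop(sprintf("k = %d exceeds n = %d samples", k, nrow(F)))
  d <- switch(metric,
              euclidean = stats::dist(F),
              correlation = stats::as.dist(1 - stats::cor(t(F))))
  method <- switch(linkage, ward = "ward.D2", linkage)
  labels <- stats::cutree(stats::hclust(d, method = method), k = k)
  centroid_mean <- vapply(seq_len(k), function(g) {
    mean(F[labels == g, , drop = FALSE])
  }, numeric(1))
  remap <- integer(k)
  remap[order(-centroid_mean)] <- seq_len(k)
  stats::setNames(remap[labels], rownames(F))
}

#' Read a clinical survival table
#'
#' TSV with columns `sample`, `time`, `event` (1 = event observed,
#' 0 = censored).
#'
#' @param path input path.
#' @return `data.frame` with validated columns.
#' @export
load_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, colnames(tab))
  if (length(miss) > 0) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(tab$time < 0)) stop("negative survival time")
  if (!all(tab$event %in% c(0, 1))) stop("event indicator must be 0/1")
  tab
}

#' Two-sample log-rank test with group pooling
#'
#' Standard log-rank statistic computed from first principles: at each
#' distinct event time, the observed minus expected number of events in the
#' pooled group A under the hypergeometric variance of the at-risk table;
#' `chi_square = (sum(O - E))^2 / sum(Var)` with 1 degree of freedom.
#' Pooling (`group_a`/`group_b` may contain several labels) makes
#' comparisons such as "group 1 + group 2 vs group 3" expressible.
#'
#' @param time non-negative survival/censoring times.
#' @param event 0/1 event indicators (1 = event observed).
#' @param group group label per sample.
#' @param group_a,group_b label sets defining the two pooled arms.
#' @return An object of class `logrank_result`: list with `chi_square`,
#'   `df` (1), `p_value`, `groups_compared`, and the summed observed and
#'   expected event counts in arm A.
#' @export
logrank_test <- function(time, event, group, group_a, group_b) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  in_a <- group %in% group_a
  in_b <- group %in% group_b
  if (!any(in_a) || !any(in_b)) stop("both pooled groups must be non-empty")
  keep <- in_a | in_b
  time <- time[keep]; event <- event[keep]; a <- in_a[keep]
  if (sum(event) == 0) stop("no events observed in either group")
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & a)
    dj <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & a)
    O <- O + d1j
    E <- E + dj * n1j / nj
    if (nj > 1) {
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  structure(list(chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 groups_compared = list(a = group_a, b = group_b),
                 observed_a = O, expected_a = E, variance = V),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: {%s} vs {%s}  chi^2 = %.4g (df=%d), p = %.4g\n",
              paste(x$groups_compared$a, collapse = ","),
              paste(x$groups_compared$b, collapse = ","),
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Kaplan-Meier step-function coordinates per group
#'
#' Product-limit survival estimates, returned as diffable plot data rather
#' than images. Each group's curve starts at `(0, 1)` and is non-increasing.
#'
#' @inheritParams logrank_test
#' @return `data.frame` with columns `group`, `time`, `survival`.
#' @export
km_curves <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  out <- lapply(sort(unique(group)), function(g) {
    tt <- time[group == g]; ee <- event[group == g]
    ev_times <- sort(unique(tt[ee == 1]))
    surv <- numeric(length(ev_times))
    s <- 1
    for (i in seq_along(ev_times)) {
      t <- ev_times[i]
      nj <- sum(tt >= t)
      dj <- sum(tt == t & ee == 1)
      s <- s * (1 - dj / nj)
      surv[i] <- s
    }
    data.frame(group = g, time = c(0, ev_times), survival = c(1, surv))
  })
  do.call(rbind, out)
}

#' End-to-end patient stratification case study
#'
#' Runs the full patient-level workflow: per-patient label propagation
#' (`lambda = 0.1`), pathway p-values against size-matched random gene-set
#' nulls, hierarchical clustering of the `-log10(p)` feature matrix into
#' `k` groups, pairwise and pooled (each group vs all others) log-rank
#' comparisons, and Kaplan-Meier curve coordinates per group.
#'
#' @param cohort a [mutation_cohort].
#' @param network a [gene_network] (or a precomputed
#'   `propagation_operator`).
#' @param pathways a [pathway_collection].
#' @param clinical `data.frame` with columns `sample`, `time`, `event`
#'   (see [load_clinical()]).
#' @param k number of patient groups.
#' @param lambda patient-mode propagation weight (default 0.1).
#' @param n_null random gene sets per null (default 10,000).
#' @param rng_seed integer seed for the null draws.
#' @param linkage,metric passed to [hierarchical_cluster()].
#' @param min_size minimum network-mapped pathway size.
#' @return An object of class `case_study`: list with `feature_matrix`,
#'   `labels`, `logrank_pairwise`, `logrank_pooled` (each group vs the
#'   rest), `km`, `skipped` and the call parameters.
#' @export
run_case_study <- function(cohort, network, pathways, clinical, k = 3L,
                           lambda = 0.1, n_null = 10000L, rng_seed = 1L,
                           linkage = "ward", metric = "euclidean",
                           min_size = 5L) {
  op <- if (inherits(network, "propagation_operator")) network else
    normalize_adjacency(network)
  res <- score_patients(cohort, op, pathways, lambda = lambda,
                        n_null = n_null, rng_seed = rng_seed,
                        min_size = min_size)
  F <- build_feature_matrix(res$tables)
  labels <- hierarchical_cluster(F, k = k, linkage = linkage, metric = metric)
  cl <- clinical[match(names(labels), clinical$sample), , drop = FALSE]
  ok <- !is.na(cl$sample)
  time <- cl$time[ok]; event <- cl$event[ok]; grp <- labels[ok]
  pairs <- utils::combn(seq_len(k), 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(p) {
    logrank_test(time, event, grp, p[1], p[2])
  })
  names(pairwise) <- vapply(pairs, function(p) {
    sprintf("%d_vs_%d", p[1], p[2])
  }, "")
  pooled <- lapply(seq_len(k), function(g) {
    logrank_test(time, event, grp, setdiff(seq_len(k), g), g)
  })
  names(pooled) <- vapply(seq_len(k), function(g) {
    sprintf("%s_vs_%d", paste(setdiff(seq_len(k), g), collapse = "+"), g)
  }, "")
  structure(list(feature_matrix = F, labels = labels,
                 logrank_pairwise = pairwise, logrank_pooled = pooled,
                 km = km_curves(time, event, grp), skipped = res$skipped,
                 params = list(k = k, lambda = lambda, n_null = n_null,
                               rng_seed = rng_seed, linkage = linkage,
                               metric = metric, min_size = min_size)),
            class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("case_study: %d patients x %d pathways, k = %d groups\n",
              nrow(x$feature_matrix), ncol(x$feature_matrix), x$params$k))
  for (nm in names(x$logrank_pooled)) {
    cat(sprintf("  pooled %s: p = %.4g\n", nm, x$logrank_pooled[[nm]]$p_value))
  }
  invisible(x)
}
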