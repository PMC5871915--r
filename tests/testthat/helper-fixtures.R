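# fixtures and independent oracles shared across test files

# Erdos-Renyi gene network with lexicographic node names, possibly with
# isolated nodes
rand_net <- function(n, p, seed) {
  withr::with_seed(seed, {
    ut <- which(upper.tri(matrix(FALSE, n, n)))
    ij <- arrayInd(ut, c(n, n))
    keep <- stats::rbinom(length(ut), 1, p) == 1
    genes <- sprintf("N%03d", seq_len(n))
    gene_network(genes[ij[keep, 1]], genes[ij[keep, 2]], 1, nodes = genes)
  })
}

rand_seed_vec <- function(genes, seed) {
  withr::with_seed(seed, stats::setNames(stats::runif(length(genes)), genes))
}

# brute-force upper-tail hypergeometric by enumerating all n-subsets of a
# universe 1..N whose first K elements are the "pathway"
hyper_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

# log-rank chi-square for every relabeling of a 2-group design (exact
# permutation distribution of the statistic)
logrank_perm_stats <- function(time, event, n_a) {
  n <- length(time)
  idx <- utils::combn(n, n_a)
  apply(idx, 2, function(a) {
    grp <- rep("B", n)
    grp[a] <- "A"
    logrank_test(time, event, grp, "A", "B")$chi_square
  })
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# tiny scenario used by pipeline tests
mini_cfg <- function(seed = 11L) {
  scenario_config(n_modules = 2L, module_size = 8L, p_in = 0.6, p_out = 0.05,
                  n_pathways = 4L, pathway_size = 6L, n_patients = 20L,
                  n_subgroups = 2L, hazard_per_subgroup = c(1, 3),
                  passenger_rate = 0.05, seed = seed)
}
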