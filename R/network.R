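#' Gene interaction network
#'
#' An undirected, weighted gene graph. Nodes are gene symbols, edges are
#' interactions with non-negative weights (default 1). Self-loops are never
#' stored; duplicate edges are collapsed keeping the maximum weight; nodes are
#' kept in lexicographic order so that matrix representations are
#' bit-reproducible.
#'
#' @param from,to character vectors of gene symbols (one edge per element).
#' @param weight numeric vector of non-negative edge weights, recycled to the
#'   number of edges; defaults to 1.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes to retain.
#'
#' @return An object of class `gene_network` with elements `nodes` (sorted
#'   character vector) and `edges` (data.frame with columns `from`, `to`,
#'   `weight`, canonicalized so `from < to`).
#' @export
gene_network <- function(from = character(), to = character(), weight = 1,
                         nodes = character()) {
  stopifnot(length(from) == length(to))
  weight <- rep_len(as.numeric(weight), length(from))
  if (anyNA(weight) || any(weight < 0)) {
    stop("edge weights must be numeric and >= 0")
  }
  all_nodes <- unique(c(from, to, nodes))
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loops)))
    to <- to[!loops]; weight <- weight[!loops]; from <- from[!loops]
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  edges <- data.frame(from = a, to = b, weight = weight,
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    key <- paste(edges$from, edges$to, sep = "\r")
    # duplicate edges keep the maximum weight
    w <- tapply(edges$weight, key, max)
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$weight <- as.numeric(w[paste(edges$from, edges$to, sep = "\r")])
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = sort(all_nodes), edges = edges),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a gene interaction network from disk
#'
#' Supported formats: tab/whitespace-separated edge list
#' (`gene_a gene_b [weight]`, `#` comment lines ignored) and SIF
#' (`gene_a relation gene_b`; the relation is ignored and weight 1 used).
#'
#' @param path path to the network file.
#' @param fmt `"edge_list_tsv"` (default) or `"sif"`.
#' @return A [gene_network]. An empty file yields an empty network.
#' @export
load_network <- function(path, fmt = c("edge_list_tsv", "sif")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) return(gene_network())
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(parts)
  if (fmt == "edge_list_tsv") {
    bad <- which(nf < 2 | nf > 3)
    if (length(bad) > 0) {
      stop(sprintf("malformed network line %d: %s", idx[bad[1]],
                   lines[idx[bad[1]]]))
    }
    from <- vapply(parts, `[`, "", 1)
    to <- vapply(parts, `[`, "", 2)
    weight <- vapply(parts, function(p) {
      if (length(p) >= 3) p[3] else "1"
    }, "")
    wnum <- suppressWarnings(as.numeric(weight))
    if (anyNA(wnum)) {
      bad <- which(is.na(wnum))[1]
      stop(sprintf("non-numeric weight on line %d: %s", idx[bad],
                   lines[idx[bad]]))
    }
    if (any(wnum < 0)) {
      bad <- which(wnum < 0)[1]
      stop(sprintf("negative weight on line %d: %s", idx[bad],
                   lines[idx[bad]]))
    }
  } else {
    bad <- which(nf != 3)
    if (length(bad) > 0) {
      stop(sprintf("malformed SIF line %d: %s", idx[bad[1]],
                   lines[idx[bad[1]]]))
    }
    from <- vapply(parts, `[`, "", 1)
    to <- vapply(parts, `[`, "", 3)
    wnum <- rep(1, length(from))
  }
  gene_network(from, to, wnum)
}

#' Write a network as an edge-list TSV
#'
#' @param net a [gene_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gene_a\tgene_b\tweight", con)
  if (nrow(net$edges) > 0) {
    writeLines(sprintf("%s\t%s\t%s", net$edges$from, net$edges$to,
                       format_full(net$edges$weight)), con)
  }
  iso <- setdiff(net$nodes, unique(c(net$edges$from, net$edges$to)))
  if (length(iso) > 0) {
    # isolated nodes recorded as degenerate weight-0 self entries are not
    # representable in an edge list; emit them as comments for round-trips
    writeLines(sprintf("#node\t%s", iso), con)
  }
  invisible(path)
}

#' Symmetric normalization of the adjacency matrix
#'
#' Computes `S = D^(-1/2) W D^(-1/2)` where `W` is the weighted adjacency
#' matrix and `D` the diagonal matrix of row sums (weighted degrees). Rows and
#' columns of zero-degree nodes are identically zero: isolated genes are kept
#' in the operator so that their seed mass remains visible after propagation.
#' The spectral radius of `S` is at most 1.
#'
#' @param net a [gene_network] with at least one node.
#' @return An object of class `propagation_operator` with elements `S`
#'   (sparse symmetric matrix), `genes` (row/column names), `degree`
#'   (weighted degrees) and `zero_degree` (genes with degree 0).
#' @export
normalize_adjacency <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$nodes)
  if (n < 1) stop("network must have at least one node")
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(net$edges$weight, 2L),
                            dims = c(n, n),
                            dimnames = list(net$nodes, net$nodes))
  w <- Matrix::rowSums(W)
  dinv <- ifelse(w > 0, 1 / sqrt(w), 0)
  Dinv <- Matrix::Diagonal(n, x = dinv)
  S <- Dinv %*% W %*% Dinv
  dimnames(S) <- list(net$nodes, net$nodes)
  structure(list(S = S, genes = net$nodes, degree = w,
                 zero_degree = net$nodes[w == 0]),
            class = "propagation_operator")
}

#' @export
print.propagation_operator <- function(x, ...) {
  cat(sprintf("propagation_operator: %d genes, %d zero-degree\n",
              length(x$genes), length(x$zero_degree)))
  invisible(x)
}
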