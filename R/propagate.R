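#' Label propagation to stationary scores
#'
#' Iterates `f <- lambda * S %*% f + (1 - lambda) * f0` to its fixed point,
#' which equals the closed form `(1 - lambda) (I - lambda S)^(-1) f0`. With
#' the spectral radius of `S` at most 1 and `lambda < 1` the iteration is a
#' contraction, so convergence is guaranteed; non-convergence within
#' `max_iter` signals numerical misuse and raises an error carrying the last
#' residual.
#'
#' `lambda` weights the network term and `1 - lambda` the seed under the
#' default convention (`lambda_convention = "network"`). Some propagation
#' write-ups use the complement; set `lambda_convention = "seed"` to have
#' `lambda` weight the seed instead.
#'
#' Seed genes absent from the network are dropped with a message reporting
#' the count; network genes absent from the seed start at 0. A zero-degree
#' gene `g` ends at `(1 - lambda) * seed[g]`.
#'
#' @param op a `propagation_operator` from [normalize_adjacency()].
#' @param seed named non-negative numeric vector of initial scores
#'   (see [cohort_seed()] and [patient_seed()]).
#' @param lambda propagation weight in (0, 1); 0.5 is the cohort-mode
#'   default, 0.1 the patient-mode default.
#' @param tol convergence tolerance, max-norm on successive iterates.
#' @param max_iter maximum number of iterations.
#' @param lambda_convention `"network"` (default) or `"seed"`.
#' @return An object of class `stationary_scores`: list with `values` (named
#'   numeric over the network genes), `lambda`, `iterations` (0 for the
#'   closed-form solver) and `residual`.
#' @seealso [propagate_exact()] for the direct linear solve.
#' @export
propagate <- function(op, seed, lambda = 0.5, tol = 1e-9, max_iter = 1000L,
                      lambda_convention = c("network", "seed")) {
  lambda_convention <- match.arg(lambda_convention)
  lam <- effective_lambda(lambda, lambda_convention)
  f0 <- align_seed(op, seed)
  f <- f0
  it <- 0L
  res <- Inf
  repeat {
    fn <- lam * as.numeric(op$S %*% f) + (1 - lam) * f0
    it <- it + 1L
    res <- max(abs(fn - f))
    f <- fn
    if (res <= tol) break
    if (it >= max_iter) {
      stop(sprintf("propagation did not converge in %d iterations (residual %g)",
                   max_iter, res))
    }
  }
  new_stationary_scores(f, op$genes, lambda, it, res)
}

#' Closed-form propagation (direct linear solve)
#'
#' Solves `(I - lambda S) f = (1 - lambda) f0` directly. Used as the internal
#' oracle for [propagate()]; guarded to networks of at most 20,000 nodes.
#'
#' @inheritParams propagate
#' @return A `stationary_scores` object with `iterations = 0`.
#' @export
propagate_exact <- function(op, seed, lambda = 0.5,
                            lambda_convention = c("network", "seed")) {
  lambda_convention <- match.arg(lambda_convention)
  lam <- effective_lambda(lambda, lambda_convention)
  n <- length(op$genes)
  if (n > 20000L) stop("direct solve guarded to networks of <= 20,000 nodes")
  f0 <- align_seed(op, seed)
  A <- Matrix::Diagonal(n) - lam * op$S
  f <- tryCatch(as.numeric(Matrix::solve(A, (1 - lam) * f0)),
                error = function(e) {
                  stop("singular propagation system (corrupted operator?): ",
                       conditionMessage(e))
                })
  new_stationary_scores(f, op$genes, lambda, 0L, 0)
}

new_stationary_scores <- function(values, genes, lambda, iterations, residual) {
  structure(list(values = stats::setNames(as.numeric(values), genes),
                 lambda = lambda, iterations = iterations,
                 residual = residual),
            class = "stationary_scores")
}

#' @export
print.stationary_scores <- function(x, ...) {
  cat(sprintf("stationary_scores: %d genes, lambda=%g, %d iterations\n",
              length(x$values), x$lambda, x$iterations))
  invisible(x)
}

effective_lambda <- function(lambda, convention) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda > 0, lambda < 1)
  if (convention == "network") lambda else 1 - lambda
}

align_seed <- function(op, seed) {
  vals <- seed_values(seed)
  if (is.null(names(vals))) stop("seed must be a named numeric vector")
  if (anyNA(vals) || any(vals < 0)) stop("seed values must be >= 0")
  missing <- setdiff(names(vals), op$genes)
  if (length(missing) > 0) {
    message(sprintf("dropping %d seed gene(s) absent from the network",
                    length(missing)))
  }
  f0 <- numeric(length(op$genes))
  m <- match(names(vals), op$genes)
  ok <- !is.na(m)
  f0[m[ok]] <- vals[ok]
  f0
}

seed_values <- function(seed) {
  if (inherits(seed, "stationary_scores")) return(seed$values)
  seed
}

#' Write stationary scores as a two-column TSV
#'
#' Full-precision output (`gene<TAB>score`) that round-trips through
#' `as.numeric`.
#'
#' @param scores a `stationary_scores` object or named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  vals <- seed_values(scores)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("gene\tscore", con)
  writeLines(sprintf("%s\t%s", names(vals), format_full(vals)), con)
  invisible(path)
}
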