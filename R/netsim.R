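#' Simulate a random weighted directed graph
#'
#' Each of the `p*(p-1)` ordered off-diagonal entries of the adjacency
#' matrix is nonzero independently with probability `edge_prob`; nonzero
#' entries receive standard-normal weights and the diagonal is set to 1.
#' The matrix is returned sparse, since at the default density `1/p` only
#' about `p` off-diagonal entries are nonzero.
#'
#' @param p number of nodes (at least 2).
#' @param edge_prob probability of each ordered directed edge.
#' @param seed integer seed.
#' @return a `p x p` sparse [Matrix::sparseMatrix()] adjacency.
#' @export
sample_weighted_graph <- function(p, edge_prob, seed) {
  if (!is.numeric(p) || length(p) != 1L || p < 2 || p != round(p))
    stop("'p' must be a single integer >= 2")
  if (!is.numeric(edge_prob) || edge_prob < 0 || edge_prob > 1)
    stop("'edge_prob' must be a probability in [0, 1]")
  with_seed(seed, {
    n_pairs <- p * (p - 1)
    n_edges <- rbinom(1L, n_pairs, edge_prob)
    # sample ordered off-diagonal slots uniformly without replacement
    slot <- sample.int(n_pairs, n_edges)
    i <- (slot - 1L) %% p + 1L
    joff <- (slot - 1L) %/% p + 1L
    j <- ifelse(joff >= i, joff + 1L, joff)  # skip the diagonal
    w <- rnorm(n_edges)
    Matrix::sparseMatrix(i = c(seq_len(p), i), j = c(seq_len(p), j),
                         x = c(rep(1, p), w), dims = c(p, p))
  })
}

#' Moralized precision matrix of a weighted directed graph
#'
#' Converting the directed adjacency `A` into the precision matrix
#' `Theta = A %*% t(A)` induces edges between nodes that share a child
#' (moralization), inflating the undirected connectivity relative to the
#' directed graph.
#'
#' @param A square weighted adjacency matrix (dense or sparse).
#' @return symmetric positive-semidefinite precision matrix `A %*% t(A)`.
#' @export
moralized_precision <- function(A) {
  d <- dim(A)
  if (is.null(d) || d[1L] != d[2L]) stop("'A' must be a square matrix")
  Matrix::tcrossprod(A)
}

#' Sample multivariate normal data with a given precision matrix
#'
#' Draws `n` independent rows from `N(0, solve(Theta))` using the Cholesky
#' factor of `Theta`, so the precision is never explicitly inverted.
#'
#' @param Theta symmetric positive-definite precision matrix.
#' @param n number of samples.
#' @param seed integer seed.
#' @return `n x p` numeric matrix.
#' @export
sample_mvn_data <- function(Theta, n, seed) {
  if (!isTRUE(n >= 1)) stop("'n' must be a positive integer")
  Theta <- as.matrix(Theta)
  p <- ncol(Theta)
  if (nrow(Theta) != p) stop("'Theta' must be square")
  if (max(abs(Theta - t(Theta))) > 1e-8 * max(abs(Theta)))
    stop("'Theta' must be symmetric")
  R <- tryCatch(chol(Theta), error = function(e) {
    ev <- min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(
      "'Theta' is numerically singular (smallest eigenvalue %.3e)", ev))
  })
  with_seed(seed, {
    Z <- matrix(rnorm(n * p), n, p)
    # rows y = R^{-1} z  =>  cov(y) = R^{-1} R^{-T} = Theta^{-1}
    t(backsolve(R, t(Z)))
  })
}

#' Undirected edge set of a precision matrix
#'
#' Zeros of the precision matrix encode conditional independence; the true
#' undirected edge set is therefore the support of the off-diagonal
#' entries.  Exact cancellation has measure zero under continuous weights,
#' so the tolerance only guards floating-point noise.
#'
#' @param Theta symmetric precision matrix.
#' @param tol entries with absolute value above `tol` count as edges;
#'   defaults to `1e-12 * max(abs(Theta))`.
#' @return two-column integer matrix of unordered pairs `i < j`.
#' @export
true_edges <- function(Theta, tol = NULL) {
  if (is.null(tol)) tol <- 1e-12 * max(abs(Theta))
  Th <- methods::as(methods::as(Matrix::Matrix(Theta, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  keep <- Th@i < Th@j & abs(Th@x) > tol
  e <- cbind(i = Th@i[keep] + 1L, j = Th@j[keep] + 1L)
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Simulate a replicate network and its data
#'
#' Bundles the generator stages: random weighted directed graph, moralized
#' precision `Theta = A A'`, and (optionally) `n` multivariate normal
#' samples with covariance `solve(Theta)`.
#'
#' @param p number of nodes.
#' @param n number of samples (`sample_data = FALSE` skips `Y`).
#' @param edge_prob directed edge probability, default `1/p`.
#' @param seed master seed for this replicate.
#' @param sample_data if `FALSE`, `Y` is `NULL` (graph-only studies).
#' @return object of class `simulated_network` with elements `A`, `Theta`,
#'   `Y`, `edges` (true undirected edge set), `p`, `n`, `edge_prob`,
#'   `seed`.
#' @export
simulate_network <- function(p, n, edge_prob = 1 / p, seed,
                             sample_data = TRUE) {
  seeds <- spawn_seeds(seed, 2L)
  A <- sample_weighted_graph(p, edge_prob, seeds[1L])
  Theta <- moralized_precision(A)
  Y <- if (sample_data) sample_mvn_data(Theta, n, seeds[2L]) else NULL
  structure(list(A = A, Theta = Theta, Y = Y, edges = true_edges(Theta),
                 p = p, n = n, edge_prob = edge_prob, seed = seed),
            class = "simulated_network")
}

#' @export
print.simulated_network <- function(x, ...) {
  cat(sprintf(
    "simulated_network: p=%d nodes, %d true undirected edges (%.2f per node), n=%s samples\n",
    x$p, nrow(x$edges), nrow(x$edges) / x$p,
    if (is.null(x$Y)) "0" else x$n))
  invisible(x)
}

#' Write a simulated network to disk as plain text
#'
#' The edge list is written as a tab-separated table `(i, j, weight)` with
#' `weight` the precision-matrix entry, and the data as a sample-by-node
#' table with a header row.
#'
#' @param net a `simulated_network`.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, dir, prefix = "net") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ef <- file.path(dir, paste0(prefix, "_edges.tsv"))
  Th <- as.matrix(net$Theta)
  e <- net$edges
  edf <- data.frame(i = e[, 1L], j = e[, 2L],
                    weight = Th[e, drop = FALSE])
  write.table(edf, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- ef
  if (!is.null(net$Y)) {
    yf <- file.path(dir, paste0(prefix, "_data.tsv"))
    Y <- as.data.frame(net$Y)
    names(Y) <- paste0("v", seq_len(ncol(Y)))
    Y <- cbind(sample_id = paste0("s", seq_len(nrow(Y))), Y)
    write.table(Y, yf, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, yf)
  }
  invisible(paths)
}
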