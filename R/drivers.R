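#' Minimum driver nodes from the PBH test
#'
#' For an undirected (symmetric-adjacency) network, the
#' Popov-Belevitch-Hautus controllability test reduces to a spectral
#' condition: the minimum number of independent control inputs equals the
#' maximum geometric multiplicity of the eigenvalues of the adjacency matrix
#' `A` -- and for symmetric matrices geometric and algebraic multiplicities
#' coincide. Eigenvalues are sorted and clustered with a gap tolerance; the
#' largest cluster size is the driver-node count `n_D`.
#'
#' @param graph An undirected simple igraph graph with at least one node.
#' @param tol Clustering tolerance for eigenvalue gaps; default
#'   `1e-8 * n * max(|lambda|)`. Integer-entried symmetric matrices have well
#'   separated distinct eigenvalues at the sizes studied here, so the default
#'   is far below any true gap.
#' @return An object of class `driver_result`: a list with `n_driver`,
#'   `clusters` (tibble of eigenvalue cluster means and multiplicities), and
#'   `tol_used`.
#' @examples
#' min_driver_nodes(igraph::make_star(6, mode = "undirected"))$n_driver  # 4
#' @export
min_driver_nodes <- function(graph, tol = NULL) {
  n <- igraph::vcount(graph)
  stopifnot(n >= 1)
  lam <- sort(eigen(as_adjacency_dense(graph), symmetric = TRUE,
                    only.values = TRUE)$values)
  if (is.null(tol)) tol <- 1e-8 * n * max(abs(lam))
  cluster_id <- cumsum(c(1, diff(lam) > tol))
  mult <- as.integer(table(cluster_id))
  vals <- as.numeric(tapply(lam, cluster_id, mean))
  structure(list(
    n_driver = max(mult),
    clusters = tibble::tibble(value = vals, multiplicity = mult),
    tol_used = tol,
    n_nodes = n
  ), class = "driver_result")
}

#' @export
print.driver_result <- function(x, ...) {
  cat(sprintf("<driver_result> n_D = %d of %d nodes (%d distinct eigenvalues, tol = %.3g)\n",
              x$n_driver, x$n_nodes, nrow(x$clusters), x$tol_used))
  invisible(x)
}
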