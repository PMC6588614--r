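#' Uniform random graph with a fixed number of edges
#'
#' Draws a simple undirected graph with exactly `n_edges` distinct edges chosen
#' uniformly without replacement from all unordered node pairs (an
#' Erdos-Renyi G(n, m) draw). This is the starting configuration for adaptive
#' rewiring.
#'
#' @param n_nodes Number of nodes (positive integer).
#' @param n_edges Number of edges; must not exceed `n_nodes * (n_nodes - 1) / 2`.
#' @return An undirected simple [igraph::igraph] graph.
#' @examples
#' set.seed(1)
#' g <- net_random_graph(100, 300)
#' igraph::ecount(g)
#' @export
net_random_graph <- function(n_nodes, n_edges) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1L, n_nodes >= 1,
            is.numeric(n_edges), length(n_edges) == 1L, n_edges >= 0)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) {
    rlang::abort(
      sprintf("n_edges = %d exceeds the maximum %d for %d nodes",
              n_edges, max_edges, n_nodes),
      class = "sparselap_invalid_argument")
  }
  igraph::sample_gnm(n_nodes, n_edges, directed = FALSE)
}

#' Heat kernel of a graph
#'
#' Computes the graph diffusion operator `h = expm(-tau * Lhat)`, where `Lhat`
#' is the symmetric degree-normalized Laplacian
#' `I - D^{-1/2} A D^{-1/2}` (rows and columns of isolated nodes are set to
#' zero, so an isolated node keeps `h[i, i] = 1`). Entry `h[i, j]` measures how
#' much heat injected at node `i` has diffused to node `j` after time `tau`;
#' the adaptive rewiring rule cuts a pivot's coldest neighbor and connects its
#' hottest non-neighbor.
#'
#' @param graph An undirected simple igraph graph.
#' @param tau Nonnegative diffusion time; `tau = 0` gives the identity.
#' @return A symmetric `n x n` numeric matrix.
#' @export
heat_kernel <- function(graph, tau) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0)
  n <- igraph::vcount(graph)
  if (tau == 0) return(diag(n))
  A <- as_adjacency_dense(graph)
  d <- colSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- A * tcrossprod(inv_sqrt)          # D^{-1/2} A D^{-1/2}
  Lhat <- diag(as.numeric(d > 0), nrow = n) - S
  e <- eigen(Lhat, symmetric = TRUE)
  h <- e$vectors %*% (exp(-tau * e$values) * t(e$vectors))
  (h + t(h)) / 2
}

# Dense 0/1 adjacency matrix of a simple undirected graph.
as_adjacency_dense <- function(graph) {
  A <- igraph::as_adjacency_matrix(graph, type = "both", sparse = FALSE)
  storage.mode(A) <- "double"
  A
}

#' One adaptive rewiring step
#'
#' Picks a pivot node with at least one neighbor and one non-neighbor, then
#' removes one edge and adds one edge, both incident to the pivot, so the edge
#' count is conserved. With probability `p_random` the cut neighbor and new
#' non-neighbor are chosen uniformly; otherwise the neighbor minimizing the
#' heat-kernel entry `h[pivot, .]` is cut and the non-neighbor maximizing it is
#' connected (ties broken uniformly at random).
#'
#' @param graph An undirected simple igraph graph.
#' @param kernel Heat kernel matrix of `graph` (see [heat_kernel()]); ignored
#'   on the random branch.
#' @param p_random Probability of a purely random rewiring, default 0.1.
#' @param max_redraws Cap on pivot redraws before declaring the graph
#'   degenerate (default `10 * n`).
#' @return The rewired graph.
#' @export
rewire_step <- function(graph, kernel, p_random = 0.1,
                        max_redraws = 10 * igraph::vcount(graph)) {
  stopifnot(p_random >= 0, p_random <= 1)
  n <- igraph::vcount(graph)
  A <- as_adjacency_dense(graph)
  for (draw in seq_len(max_redraws)) {
    i <- sample.int(n, 1L)
    nbr <- which(A[i, ] > 0)
    non <- setdiff(which(A[i, ] == 0), i)
    if (length(nbr) == 0L || length(non) == 0L) next  # ineligible pivot, redraw
    if (stats::runif(1) < p_random) {
      j <- sample_one(nbr)
      k <- sample_one(non)
    } else {
      hrow <- kernel[i, ]
      j <- sample_one(nbr[hrow[nbr] == min(hrow[nbr])])
      k <- sample_one(non[hrow[non] == max(hrow[non])])
    }
    g2 <- igraph::delete_edges(graph, igraph::get_edge_ids(graph, c(i, j)))
    g2 <- igraph::add_edges(g2, c(i, k))
    return(g2)
  }
  rlang::abort("no eligible pivot node found; graph is degenerate",
               class = "sparselap_degenerate_graph")
}

# Uniform draw from a vector of candidate ids (length-1 safe, unlike sample()).
sample_one <- function(x) {
  if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
}

#' Generate a heat-kernel adaptive rewiring ensemble
#'
#' Runs `n_steps` adaptive rewiring steps from an Erdos-Renyi start and
#' snapshots the graph at a constant rate (after steps `n_steps / n_samples`,
#' `2 n_steps / n_samples`, ..., `n_steps`). The diffusion parameter `tau`
#' sets the emerging topology: `tau = 0` stays random (Erdos-Renyi-like),
#' `tau` near 1 grows modular community structure, and large `tau` (around 10)
#' concentrates edges on hubs into a centralized, star-like network. The heat
#' kernel is recomputed from the current graph every `kernel_refresh` accepted
#' steps (default every step).
#'
#' @param tau Nonnegative diffusion parameter.
#' @param n_steps Number of rewiring steps (default 600).
#' @param p_random Random-rewiring probability (default 0.1).
#' @param n_samples Number of snapshots (default 100; must be <= `n_steps`).
#' @param n_nodes,n_edges Graph size (defaults 100 nodes, 300 edges).
#' @param seed Optional integer seed; when given the run is reproducible.
#' @param kernel_refresh Recompute the kernel every this many steps.
#' @return A tibble with one row per snapshot: `tau`, `sample` (1-based
#'   snapshot index), `step` (rewiring step at which it was taken), and a
#'   `graph` list-column of igraph objects.
#' @examples
#' ens <- rewire_ensemble(tau = 1, n_steps = 60, n_samples = 10,
#'                        n_nodes = 30, n_edges = 90, seed = 1)
#' ens
#' @export
rewire_ensemble <- function(tau, n_steps = 600, p_random = 0.1,
                            n_samples = 100, n_nodes = 100, n_edges = 300,
                            seed = NULL, kernel_refresh = 1) {
  stopifnot(n_steps >= 1, n_samples >= 1, n_samples <= n_steps,
            kernel_refresh >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- net_random_graph(n_nodes, n_edges)
  snap_steps <- unique(round(seq_len(n_samples) * n_steps / n_samples))
  kernel <- heat_kernel(g, tau)
  out <- vector("list", length(snap_steps))
  s <- 1L
  for (step in seq_len(n_steps)) {
    g <- rewire_step(g, kernel, p_random = p_random)
    if (step %% kernel_refresh == 0L && step < n_steps) {
      kernel <- heat_kernel(g, tau)
    }
    if (s <= length(snap_steps) && step == snap_steps[s]) {
      out[[s]] <- g
      s <- s + 1L
    }
  }
  tibble::tibble(tau = tau, sample = seq_along(snap_steps),
                 step = snap_steps, graph = out)
}

#' Degree-preserving null model
#'
#' Randomizes a graph by repeated double-edge swaps, keeping the degree of
#' every node while shuffling which nodes are connected. Swaps that would
#' create a self-loop or a duplicate edge are skipped, so the result is always
#' simple. Used to normalize topology metrics against what the degree sequence
#' alone produces.
#'
#' @param graph An undirected simple igraph graph with at least 2 edges.
#' @param n_swap_attempts Number of attempted swaps (default `10 * ecount`).
#' @return A randomized graph with the identical degree sequence.
#' @export
degree_preserving_null <- function(graph,
                                   n_swap_attempts = 10 * igraph::ecount(graph)) {
  stopifnot(igraph::ecount(graph) >= 2)
  igraph::rewire(graph, with = igraph::keeping_degseq(niter = n_swap_attempts))
}

#' Read / write graphs as plain-text edge lists
#'
#' The on-disk format is a two-column tab-separated edge list with 0-based
#' node ids, one undirected edge per line with the smaller id first. The
#' writer/reader pair round-trips exactly.
#'
#' @param graph An undirected simple igraph graph.
#' @param path File path.
#' @param n_nodes Number of nodes; needed on read when trailing nodes are
#'   isolated (defaults to max id + 1).
#' @return `read_edgelist_tsv()` returns an igraph graph;
#'   `write_edgelist_tsv()` returns `path` invisibly.
#' @export
write_edgelist_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = FALSE) - 1L
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  utils::write.table(el, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edgelist_tsv
#' @export
read_edgelist_tsv <- function(path, n_nodes = NULL) {
  el <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                    colClasses = "integer"))
  if (is.null(n_nodes)) n_nodes <- max(el) + 1L
  igraph::graph_from_edgelist(el + 1L, directed = FALSE) |>
    igraph::add_vertices(max(0L, n_nodes - max(el) - 1L))
}
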