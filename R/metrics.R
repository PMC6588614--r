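#' Degree statistics of a graph
#'
#' Summarizes the degree distribution by its mean `2E/N`, its sample standard
#' deviation (denominator `N - 1`), and the edge density
#' `rho = 2E / (N^2 - N)`. The standard deviation serves as a centralization
#' measure: near zero for regular or homogeneous random graphs, large for
#' hub-dominated star-like topologies.
#'
#' @param graph An undirected simple igraph graph with at least 2 nodes.
#' @return A one-row tibble with columns `n_nodes`, `n_edges`, `mean_degree`,
#'   `degree_std`, `density`.
#' @examples
#' degree_stats(net_random_graph(100, 300))
#' @export
degree_stats <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n >= 2)
  m <- igraph::ecount(graph)
  deg <- igraph::degree(graph)
  tibble::tibble(
    n_nodes = n,
    n_edges = m,
    mean_degree = 2 * m / n,
    degree_std = stats::sd(deg),
    density = 2 * m / (n^2 - n)
  )
}

#' Newman-Girvan modularity of a partition
#'
#' Computes `Q = sum_c [ e_c / E - (d_c / 2E)^2 ]`, where `e_c` is the number
#' of intra-community edges and `d_c` the total degree of community `c`:
#' the fraction of edges inside communities minus the fraction expected from
#' the degree sequence alone. `Q` lies in `[-1/2, 1)`; the single-community
#' partition always scores exactly 0.
#'
#' @param graph An undirected simple igraph graph with at least one edge.
#' @param membership Integer vector assigning each node a community label.
#' @return The modularity `Q` (a single number).
#' @examples
#' g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
#' modularity_q(g, c(1, 1, 1, 2, 2, 2))  # 0.5
#' @export
modularity_q <- function(graph, membership) {
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  if (m < 1) {
    rlang::abort("modularity is undefined for a graph with no edges",
                 class = "sparselap_undefined_metric")
  }
  stopifnot(length(membership) == n, !anyNA(membership))
  el <- igraph::as_edgelist(graph, names = FALSE)
  n_intra <- sum(membership[el[, 1]] == membership[el[, 2]])
  deg <- igraph::degree(graph)
  d_c <- tapply(deg, factor(membership), sum)
  n_intra / m - sum((as.numeric(d_c) / (2 * m))^2)
}

#' Detect communities by modularity maximization
#'
#' Finds a node partition that (locally) maximizes Newman-Girvan modularity.
#' Several greedy/multilevel candidates are computed -- the agglomerative
#' fast-greedy method and seeded multilevel (Louvain) restarts -- and the
#' partition with the largest `Q` under [modularity_q()] is kept, so results
#' are reproducible for a given seed.
#'
#' @param graph An undirected simple igraph graph.
#' @param n_restarts Number of seeded multilevel restarts (default 5).
#' @param seed Optional integer seed for the restarts.
#' @return An integer membership vector (communities labeled contiguously
#'   from 1 in order of first appearance) with attribute `"Q"` holding its
#'   modularity.
#' @export
find_communities <- function(graph, n_restarts = 5, seed = NULL) {
  n <- igraph::vcount(graph)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (igraph::ecount(graph) == 0) {
    out <- rep(1L, n)
    attr(out, "Q") <- NA_real_
    return(out)
  }
  candidates <- list(igraph::membership(igraph::cluster_fast_greedy(graph)))
  for (r in seq_len(n_restarts)) {
    candidates[[length(candidates) + 1L]] <-
      igraph::membership(igraph::cluster_louvain(graph))
  }
  qs <- vapply(candidates, function(mb) modularity_q(graph, mb), numeric(1))
  best <- relabel_contiguous(as.integer(candidates[[which.max(qs)]]))
  attr(best, "Q") <- max(qs)
  best
}

# Relabel community ids contiguously from 1 in order of first appearance.
relabel_contiguous <- function(membership) {
  match(membership, unique(membership))
}

#' Null-normalized modularity
#'
#' Divides the modularity of a graph by the mean modularity of an ensemble of
#' degree-preserving null graphs (each null scored under its own best detected
#' partition). A ratio above 1 means more community structure than the degree
#' sequence alone produces. A z-score against the null distribution is
#' reported alongside.
#'
#' @param graph An undirected simple igraph graph.
#' @param membership Optional partition of `graph`; found by
#'   [find_communities()] when missing.
#' @param null_graphs A list of at least 10 degree-preserving null graphs
#'   (see [degree_preserving_null()]).
#' @param seed Optional seed for the community detection on the nulls.
#' @return A one-row tibble with columns `Q`, `Q_null_mean`, `Q_null_sd`,
#'   `Q_norm` (the ratio, the primary normalization) and `Q_z`.
#' @export
normalized_modularity <- function(graph, membership = NULL, null_graphs,
                                  seed = NULL) {
  if (length(null_graphs) < 10) {
    rlang::abort("at least 10 null graphs are required",
                 class = "sparselap_invalid_argument")
  }
  if (is.null(membership)) membership <- find_communities(graph, seed = seed)
  q <- modularity_q(graph, membership)
  q_null <- vapply(null_graphs, function(g0) {
    mb <- find_communities(g0, seed = seed)
    modularity_q(g0, mb)
  }, numeric(1))
  mu <- mean(q_null)
  if (mu <= 0) {
    rlang::abort("mean null modularity is not positive; ratio undefined",
                 class = "sparselap_undefined_metric")
  }
  tibble::tibble(Q = q, Q_null_mean = mu, Q_null_sd = stats::sd(q_null),
                 Q_norm = q / mu,
                 Q_z = if (stats::sd(q_null) > 0) (q - mu) / stats::sd(q_null)
                       else NA_real_)
}
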