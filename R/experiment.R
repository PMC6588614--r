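#' Configuration for a tau-by-gamma sweep
#'
#' Bundles the parameters of the full computational study: for every
#' diffusion parameter `tau`, network ensembles are generated by adaptive
#' rewiring, topology metrics and driver-node counts are computed once per
#' network, and the sparsity-promoting controller is designed for every
#' channel price `gamma` by warm-started homotopy.
#'
#' The defaults are desk-scale: 10 networks per tau (independent seeded
#' rewiring runs, final snapshot each) and 100 nulls per network, instead of
#' the 100-network / 1,000-null production scale, which remains a
#' configuration change.
#'
#' @param tau_grid Diffusion parameters (default `0:10`).
#' @param gamma_grid Channel prices (default `c(1e-4, 1e-2, 1e-1)`).
#' @param networks_per_tau Networks generated per tau (default 10).
#' @param nulls_per_network Degree-preserving nulls per network used for
#'   modularity normalization (default 100, scaled down from the production
#'   1,000); 0 skips normalization.
#' @param n_nodes,n_edges Graph size (defaults 100, 300).
#' @param n_steps Rewiring steps per network (default 600).
#' @param p_random Random-rewiring probability (default 0.1).
#' @param sampling `"replicates"` (default): each network is the final
#'   snapshot of an independent seeded rewiring run, giving well-separated
#'   topology classes per tau. `"trajectory"`: the networks are
#'   `networks_per_tau` snapshots of a single run, so each tau contributes a
#'   trajectory from random towards its limiting topology (the production
#'   sampling scheme).
#' @param seed Top-level integer seed; per-network streams are derived
#'   deterministically from `(tau, replicate)`.
#' @param homotopy_grid Price grid actually solved (warm-started, increasing);
#'   the union of [default_gamma_grid()] and `gamma_grid` by default. Rows are
#'   emitted only at `gamma_grid`, but the intermediate solves keep each
#'   nonconvex solution in the basin of its predecessor.
#' @param admm An [admm_options()] list for the control solves.
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(tau_grid = 0:10,
                         gamma_grid = c(1e-4, 1e-2, 1e-1),
                         networks_per_tau = 10,
                         nulls_per_network = 100,
                         n_nodes = 100, n_edges = 300,
                         n_steps = 600, p_random = 0.1,
                         sampling = c("replicates", "trajectory"),
                         seed = 1,
                         homotopy_grid = sort(union(default_gamma_grid(),
                                                    gamma_grid)),
                         admm = admm_options()) {
  stopifnot(length(tau_grid) >= 1, length(gamma_grid) >= 1,
            all(gamma_grid > 0), networks_per_tau >= 1,
            nulls_per_network >= 0, all(gamma_grid %in% homotopy_grid))
  structure(list(tau_grid = tau_grid, gamma_grid = sort(gamma_grid),
                 homotopy_grid = sort(homotopy_grid),
                 networks_per_tau = networks_per_tau,
                 nulls_per_network = nulls_per_network,
                 n_nodes = n_nodes, n_edges = n_edges, n_steps = n_steps,
                 p_random = p_random, sampling = match.arg(sampling),
                 seed = seed, admm = admm),
            class = "sweep_config")
}

# Deterministic per-(tau, replicate) seed stream below 2^31 (double
# arithmetic stays exact here: products are far below 2^53).
derive_seed <- function(seed, tau_index, replicate) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(tau_index) * 104729 +
                as.numeric(replicate) * 1299709) %% 2147483647)
}

# Networks for one tau under a config: list of igraph graphs.
networks_for_tau <- function(config, tau, tau_index) {
  if (config$sampling == "replicates") {
    lapply(seq_len(config$networks_per_tau), function(r) {
      ens <- rewire_ensemble(
        tau, n_steps = config$n_steps, p_random = config$p_random,
        n_samples = 1, n_nodes = config$n_nodes, n_edges = config$n_edges,
        seed = derive_seed(config$seed, tau_index, r))
      ens$graph[[nrow(ens)]]
    })
  } else {
    ens <- rewire_ensemble(
      tau, n_steps = config$n_steps, p_random = config$p_random,
      n_samples = config$networks_per_tau, n_nodes = config$n_nodes,
      n_edges = config$n_edges,
      seed = derive_seed(config$seed, tau_index, 0L))
    ens$graph
  }
}

#' Run the tau-by-gamma sweep
#'
#' Executes the full study under a [sweep_config()]: generate networks per
#' tau, measure modularity (with optional null normalization), degree spread,
#' and driver-node count once per network, then solve the
#' sparsity-promoting design along the `gamma` grid by warm-started homotopy
#' ([sparse_gain_path()]). Solver failures are recorded as flagged rows
#' (`converged = NA`, costs `NA`) rather than aborting the sweep.
#'
#' @param config A [sweep_config()].
#' @param verbose Print per-network progress (default `FALSE`).
#' @return A tibble with one row per `(tau, network, gamma)`:
#'   `tau`, `network_id`, `gamma`, `Q`, `Q_norm`, `degree_std`,
#'   `mean_degree`, `n_driver`, `J`, `card`, `total`, `converged`. The
#'   accounting identity `total = J + gamma * card` holds in every row.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  rows <- list()
  for (ti in seq_along(config$tau_grid)) {
    tau <- config$tau_grid[ti]
    graphs <- networks_for_tau(config, tau, ti)
    for (ni in seq_along(graphs)) {
      g <- graphs[[ni]]
      set.seed(derive_seed(config$seed, ti, 100000L + ni))
      mb <- find_communities(g)
      q <- modularity_q(g, mb)
      q_norm <- NA_real_
      if (config$nulls_per_network >= 10) {
        nulls <- lapply(seq_len(config$nulls_per_network),
                        function(k) degree_preserving_null(g))
        q_norm <- normalized_modularity(g, mb, nulls)$Q_norm
      }
      ds <- degree_stats(g)
      nd <- min_driver_nodes(g)$n_driver
      sys <- laplacian_system(g)
      sols <- tryCatch(
        sparse_gain_path(sys, config$homotopy_grid, opts = config$admm),
        error = function(e) NULL)
      for (gi in seq_along(config$gamma_grid)) {
        gamma <- config$gamma_grid[gi]
        sol <- if (is.null(sols)) NULL
               else sols[[which(config$homotopy_grid == gamma)]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          tau = tau, network_id = ni, gamma = gamma,
          Q = q, Q_norm = q_norm,
          degree_std = ds$degree_std, mean_degree = ds$mean_degree,
          n_driver = nd,
          J = if (is.null(sol)) NA_real_ else sol$costs$J,
          card = if (is.null(sol)) NA_integer_ else sol$costs$card,
          total = if (is.null(sol)) NA_real_ else sol$costs$total,
          converged = if (is.null(sol)) NA else sol$converged)
      }
      if (verbose) {
        message(sprintf("tau = %g, network %d/%d done (Q = %.2f, sigma = %.2f, n_D = %d)",
                        tau, ni, length(graphs), q, ds$degree_std, nd))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Which topology wins at each channel price
#'
#' For every `gamma` in a sweep table, averages the total control cost per
#' `tau` and flags the tau with the minimal mean: the topology class that is
#' cheapest to control at that price.
#'
#' @param table A results tibble from [run_sweep()].
#' @param tau_set Optional subset of tau values to compare (default: all
#'   present). Requesting absent values is an error.
#' @return A tibble with columns `gamma`, `tau`, `mean_total`, `is_min`,
#'   sorted by `gamma` then `tau`.
#' @export
regime_ordering <- function(table, tau_set = NULL) {
  if (is.null(tau_set)) tau_set <- sort(unique(table$tau))
  missing_tau <- setdiff(tau_set, table$tau)
  if (length(missing_tau) > 0) {
    rlang::abort(sprintf("tau value(s) %s not present in the table",
                         paste(missing_tau, collapse = ", ")),
                 class = "sparselap_invalid_argument")
  }
  table |>
    dplyr::filter(.data$tau %in% tau_set, !is.na(.data$total)) |>
    dplyr::group_by(.data$gamma, .data$tau) |>
    dplyr::summarise(mean_total = mean(.data$total), .groups = "drop_last") |>
    dplyr::mutate(is_min = .data$mean_total == min(.data$mean_total)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gamma, .data$tau)
}

#' Rank correlations between topology metrics and control costs
#'
#' Spearman correlations of the degree-distribution spread (`degree_std`) and
#' modularity (`Q`) against the performance cost `J`, channel count `card`,
#' and total cost, stratified by `gamma`; plus the gamma-independent
#' correlations of the driver-node count `n_driver` with `degree_std` and
#' `Q`. Constant columns give an undefined correlation, flagged with
#' `defined = FALSE` and `rho = NA`.
#'
#' @param table A results tibble from [run_sweep()] with at least 10 rows per
#'   gamma.
#' @return A tibble with columns `gamma` (`NA` for the driver-node rows),
#'   `metric`, `response`, `rho`, `n`, `defined`.
#' @export
correlate_metrics <- function(table) {
  spearman <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(rho = NA_real_, n = sum(ok), defined = FALSE))
    }
    tibble::tibble(rho = stats::cor(x[ok], y[ok], method = "spearman"),
                   n = sum(ok), defined = TRUE)
  }
  pairs <- tidyr::expand_grid(metric = c("degree_std", "Q"),
                              response = c("J", "card", "total"))
  by_gamma <- table |>
    dplyr::group_by(.data$gamma) |>
    dplyr::group_modify(function(d, key) {
      pairs |>
        dplyr::mutate(res = purrr::map2(.data$metric, .data$response,
                                        function(m, r) spearman(d[[m]], d[[r]]))) |>
        tidyr::unnest("res")
    }) |>
    dplyr::ungroup()
  per_net <- table |>
    dplyr::distinct(.data$tau, .data$network_id, .data$Q, .data$degree_std,
                    .data$n_driver)
  nd <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(gamma = NA_real_, metric = "degree_std",
                                    response = "n_driver"),
                     spearman(per_net$degree_std, per_net$n_driver)),
    dplyr::bind_cols(tibble::tibble(gamma = NA_real_, metric = "Q",
                                    response = "n_driver"),
                     spearman(per_net$Q, per_net$n_driver)))
  dplyr::bind_rows(by_gamma, nd)
}
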