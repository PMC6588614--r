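#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sparse feedback design
#'
#' `tidy()` returns the nonzero feedback channels, one row per entry of the
#' gain; `glance()` returns the one-row cost and convergence summary.
#'
#' @param x A `sparse_gain` object from [sparse_gain_admm()].
#' @param ... Unused.
#' @return A tibble. For `tidy()`: columns `row`, `col`, `value`,
#'   `self` (diagonal channel or not). For `glance()`: `gamma`, `J`, `card`,
#'   `total`, `iterations`, `converged`.
#' @export
tidy.sparse_gain <- function(x, ...) {
  idx <- which(x$pattern & abs(x$F) > 0, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1], col = idx[, 2],
                 value = x$F[idx], self = idx[, 1] == idx[, 2]) |>
    dplyr::arrange(.data$row, .data$col)
}

#' @rdname tidy.sparse_gain
#' @export
glance.sparse_gain <- function(x, ...) {
  dplyr::bind_cols(x$costs,
                   tibble::tibble(iterations = x$iterations,
                                  converged = x$converged))
}

#' Tidy a driver-node result
#'
#' `tidy()` returns the adjacency eigenvalue clusters (value, multiplicity);
#' `glance()` the one-row summary.
#'
#' @param x A `driver_result` from [min_driver_nodes()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.driver_result <- function(x, ...) {
  x$clusters
}

#' @rdname tidy.driver_result
#' @export
glance.driver_result <- function(x, ...) {
  tibble::tibble(n_driver = x$n_driver, n_nodes = x$n_nodes,
                 n_distinct_eigenvalues = nrow(x$clusters),
                 tol_used = x$tol_used)
}
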