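#' Laplacian state-space system of a graph
#'
#' Builds the control model `dx/dt = -L x + B1 d + B2 u` with `L = D - A` the
#' combinatorial graph Laplacian, disturbance input `B1`, control input `B2`,
#' and quadratic performance weights `Qw` (state) and `Rw` (input), all set to
#' the identity: every node can be disturbed, actuated, and penalized equally.
#' Under state feedback `u = -F x` the closed loop is `dx/dt = -(L + F) x`.
#'
#' @param graph An undirected simple igraph graph.
#' @return An object of class `laplacian_system`: a list with fields `L`
#'   (dense symmetric matrix), `n`, and the identity matrices `B1`, `B2`,
#'   `Qw`, `Rw`.
#' @examples
#' sys <- laplacian_system(net_random_graph(10, 20))
#' range(rowSums(sys$L))  # every row sums to zero
#' @export
laplacian_system <- function(graph) {
  A <- as_adjacency_dense(graph)
  n <- nrow(A)
  L <- diag(colSums(A), nrow = n) - A
  structure(list(L = L, n = n, B1 = diag(n), B2 = diag(n),
                 Qw = diag(n), Rw = diag(n)),
            class = "laplacian_system")
}

#' @export
print.laplacian_system <- function(x, ...) {
  cat(sprintf("<laplacian_system> %d nodes, %d edges\n",
              x$n, sum(x$L[upper.tri(x$L)] != 0)))
  invisible(x)
}

# ---- Lyapunov machinery -----------------------------------------------------
#
# The closed-loop matrix M = L + F is diagonalized once (complex, in general,
# since F need not be symmetric); both Gramians are then solved in the
# eigenbasis, where the Lyapunov operator is diagonal with entries d_i + d_j.

closed_loop_decomposition <- function(system, F_gain) {
  M <- system$L + F_gain
  e <- eigen(M)
  list(M = M, values = e$values, V = e$vectors)
}

is_hurwitz <- function(dec, margin = 0) {
  all(Re(dec$values) > margin)
}

abort_unstable <- function() {
  rlang::abort("closed loop -(L + F) is not Hurwitz; H2 cost is infinite",
               class = "sparselap_unstable")
}

# Solve M^T P + P M = Qm (M stable, i.e. all eigenvalues in the open right
# half plane here because the closed loop is -M). Diagonalization route with a
# residual check; falls back to the Kronecker linear system for small n.
lyap_obsv <- function(dec, Qm) {
  V <- dec$V
  d <- dec$values
  Qt <- t(V) %*% Qm %*% V
  Pt <- Qt / outer(d, d, `+`)
  P <- Re(solve(t(V), t(solve(t(V), t(Pt)))))
  P <- (P + t(P)) / 2
  res <- norm(t(dec$M) %*% P + P %*% dec$M - Qm, "F")
  if (res > 1e-8 * max(1, norm(Qm, "F"))) {
    P <- lyap_kron(t(dec$M), Qm)
  }
  P
}

# Solve M W + W M^T = Qm.
lyap_ctrb <- function(dec, Qm) {
  V <- dec$V
  d <- dec$values
  Ct <- solve(V, t(solve(V, t(Qm))))
  Wt <- Ct / outer(d, d, `+`)
  W <- Re(V %*% Wt %*% t(V))
  W <- (W + t(W)) / 2
  res <- norm(dec$M %*% W + W %*% t(dec$M) - Qm, "F")
  if (res > 1e-8 * max(1, norm(Qm, "F"))) {
    W <- lyap_kron(dec$M, Qm)
  }
  W
}

# Dense Kronecker fallback: solves A X + X A^T = Q. O(n^6); guard rail for
# (near-)defective closed loops at small n.
lyap_kron <- function(A, Q) {
  n <- nrow(A)
  if (n > 60) {
    rlang::abort("Lyapunov solve failed and system too large for dense fallback",
                 class = "sparselap_numerical")
  }
  K <- kronecker(diag(n), A) + kronecker(A, diag(n))
  X <- matrix(solve(K, as.numeric(Q)), n, n)
  (X + t(X)) / 2
}

#' Closed-loop observability Gramian
#'
#' Solves the Lyapunov equation
#' `-(L+F)^T P - P (L+F) + (I + F^T F) = 0` for the unique symmetric
#' positive-semidefinite `P`. The H2 performance cost of the closed loop is
#' `trace(B1^T P B1)`.
#'
#' @param system A [laplacian_system()].
#' @param gain An `n x n` feedback gain matrix `F` such that `-(L+F)` is
#'   Hurwitz; otherwise an error of class `sparselap_unstable` is thrown.
#' @return A symmetric PSD matrix `P`.
#' @export
observability_gramian <- function(system, gain) {
  dec <- closed_loop_decomposition(system, gain)
  if (!is_hurwitz(dec)) abort_unstable()
  lyap_obsv(dec, diag(system$n) + crossprod(gain))
}

#' Closed-loop controllability Gramian
#'
#' Solves `(L+F) W + W (L+F)^T = B1 B1^T`. `W` is the adjoint Gramian used in
#' the gradient of the H2 cost.
#'
#' @inheritParams observability_gramian
#' @return A symmetric PSD matrix `W`.
#' @export
controllability_gramian <- function(system, gain) {
  dec <- closed_loop_decomposition(system, gain)
  if (!is_hurwitz(dec)) abort_unstable()
  lyap_ctrb(dec, tcrossprod(system$B1))
}

# Both Gramians from one decomposition (the solver hot path).
gramians <- function(system, gain, dec = NULL) {
  if (is.null(dec)) dec <- closed_loop_decomposition(system, gain)
  if (!is_hurwitz(dec)) return(NULL)
  list(P = lyap_obsv(dec, diag(system$n) + crossprod(gain)),
       W = lyap_ctrb(dec, diag(system$n)))
}

#' H2 performance cost of a feedback gain
#'
#' `J(F) = trace(B1^T P(F) B1)` with `P` the closed-loop observability
#' Gramian: the energy of the disturbance-to-`[x; u]` response, i.e. how much
#' white-noise disturbance shows up in the states and the control effort.
#'
#' @inheritParams observability_gramian
#' @return The cost `J` (a nonnegative number).
#' @export
h2_cost <- function(system, gain) {
  P <- observability_gramian(system, gain)
  sum(diag(crossprod(system$B1, P %*% system$B1)))
}

#' Gradient of the H2 cost
#'
#' `grad J(F) = 2 (Rw F - B2^T P) W`, which reduces to `2 (F - P) W` for the
#' identity-weight model used here.
#'
#' @inheritParams observability_gramian
#' @return An `n x n` gradient matrix.
#' @export
h2_gradient <- function(system, gain) {
  gr <- gramians(system, gain)
  if (is.null(gr)) abort_unstable()
  2 * (system$Rw %*% gain - crossprod(system$B2, gr$P)) %*% gr$W
}

#' Centralized (dense) H2-optimal gain
#'
#' The unconstrained optimum of `J(F)`. Because `L` is symmetric and all
#' weights are identity, the Riccati equation diagonalizes in the eigenbasis
#' of `L`: `F* = -L + (L^2 + I)^{1/2}` and
#' `J* = sum_i ( sqrt(lambda_i^2 + 1) - lambda_i )` over the eigenvalues
#' `lambda_i` of `L`. The closed loop `-(L + F*) = -(L^2 + I)^{1/2}` is always
#' Hurwitz, even for disconnected graphs.
#'
#' @param system A [laplacian_system()].
#' @return A list with `F` (the gain matrix) and `J` (the optimal cost).
#' @export
centralized_gain <- function(system) {
  e <- eigen(system$L, symmetric = TRUE)
  lam <- e$values
  Fstar <- e$vectors %*% ((sqrt(lam^2 + 1) - lam) * t(e$vectors))
  Fstar <- (Fstar + t(Fstar)) / 2
  list(F = Fstar, J = sum(sqrt(lam^2 + 1) - lam))
}

#' Total control cost with priced feedback channels
#'
#' `total = J(F) + gamma * card(F)`, where `card(F)` counts the nonzero
#' entries of the gain (the feedback channels, diagonal entries included) and
#' `gamma` is the price per channel.
#'
#' @inheritParams observability_gramian
#' @param gamma Nonnegative channel price.
#' @param card_tol Magnitude below which an entry counts as zero
#'   (default 1e-10; hard thresholding produces exact zeros, the tolerance
#'   only guards polishing round-off).
#' @return A one-row tibble with columns `gamma`, `J`, `card`, `total`.
#' @export
total_cost <- function(system, gain, gamma, card_tol = 1e-10) {
  stopifnot(gamma >= 0)
  J <- h2_cost(system, gain)
  card <- sum(abs(gain) > card_tol)
  tibble::tibble(gamma = gamma, J = J, card = card, total = J + gamma * card)
}

#' Solver options for the sparsity-promoting design
#'
#' @param rho ADMM quadratic penalty (default 100).
#' @param eps_abs Absolute stopping tolerance: iteration ends when the primal
#'   residual `||F - G||_F` drops below `eps_abs * n` (default 1e-4).
#' @param max_iter Maximum ADMM iterations (default 100).
#' @param fstep_tol Gradient tolerance of the inner F-minimization
#'   (default 1e-6).
#' @param fstep_max_iter Cap on inner Anderson-Moore iterations per F-step.
#' @param polish_tol,polish_max_iter Projected-gradient settings for the
#'   structured polishing stage.
#' @param card_tol Nonzero-counting tolerance, see [total_cost()].
#' @return A list of class `admm_options`.
#' @export
admm_options <- function(rho = 100, eps_abs = 1e-4, max_iter = 100,
                         fstep_tol = 1e-6, fstep_max_iter = 20,
                         polish_tol = 1e-6, polish_max_iter = 500,
                         card_tol = 1e-10) {
  structure(list(rho = rho, eps_abs = eps_abs, max_iter = max_iter,
                 fstep_tol = fstep_tol, fstep_max_iter = fstep_max_iter,
                 polish_tol = polish_tol, polish_max_iter = polish_max_iter,
                 card_tol = card_tol),
            class = "admm_options")
}

# Augmented F-step objective phi(F) = J(F) + rho/2 ||F - U||_F^2 (U = G -
# Lambda/rho). Anderson-Moore: at the current Gramians the stationarity
# condition is linear in F, F (2 W + rho I) = 2 P W + rho U; a backtracking
# step toward that solve keeps the closed loop stable and phi decreasing.
fstep_minimize <- function(system, F0, U, rho, tol, max_iter) {
  F_cur <- F0
  gr <- gramians(system, F_cur)
  if (is.null(gr)) return(NULL)
  phi <- function(J, Fm) J + rho / 2 * norm(Fm - U, "F")^2
  J_cur <- sum(diag(gr$P))
  phi_cur <- phi(J_cur, F_cur)
  for (it in seq_len(max_iter)) {
    grad <- 2 * (F_cur - gr$P) %*% gr$W + rho * (F_cur - U)
    gnorm <- norm(grad, "F")
    if (gnorm <= tol * max(1, abs(phi_cur))) break
    F_am <- t(solve(2 * gr$W + rho * diag(system$n), t(2 * gr$P %*% gr$W + rho * U)))
    dirn <- F_am - F_cur
    slope <- sum(grad * dirn)
    if (slope > 0) { dirn <- -grad; slope <- -gnorm^2 }
    step <- 1
    improved <- FALSE
    for (bt in 1:30) {
      F_try <- F_cur + step * dirn
      gr_try <- gramians(system, F_try)
      if (!is.null(gr_try)) {
        J_try <- sum(diag(gr_try$P))
        if (phi(J_try, F_try) <= phi_cur + 1e-4 * step * slope) {
          F_cur <- F_try; gr <- gr_try
          J_cur <- J_try; phi_cur <- phi(J_try, F_try)
          improved <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!improved) break
  }
  list(F = F_cur, J = J_cur, P = gr$P, W = gr$W)
}

#' Refine a gain on a fixed sparsity pattern
#'
#' Minimizes the H2 cost `J(F)` over gains supported on a given boolean
#' pattern by projected gradient descent (Barzilai-Borwein steps with Armijo
#' backtracking, the gradient masked to the pattern), starting from a supplied
#' iterate or from the centralized gain masked to the pattern.
#'
#' @param system A [laplacian_system()].
#' @param pattern Logical `n x n` matrix of allowed nonzeros.
#' @param init Optional starting gain (entries off the pattern are zeroed).
#'   It, or the masked centralized gain, must stabilize the loop; otherwise an
#'   error of class `sparselap_infeasible` is thrown.
#' @param tol Gradient-norm stopping tolerance (relative to `1 + |J|`).
#' @param max_iter Iteration cap.
#' @return A list with `F` (the polished gain) and `J` (its cost).
#' @export
polish_gain <- function(system, pattern, init = NULL, tol = 1e-6,
                        max_iter = 500) {
  pattern <- pattern != 0
  starts <- list()
  if (!is.null(init)) starts <- c(starts, list(init * pattern))
  starts <- c(starts, list(centralized_gain(system)$F * pattern))
  F_cur <- NULL
  for (s in starts) {
    if (!is.null(gramians(system, s))) { F_cur <- s; break }
  }
  if (is.null(F_cur)) {
    rlang::abort("no stabilizing gain found on the requested sparsity pattern",
                 class = "sparselap_infeasible")
  }
  gr <- gramians(system, F_cur)
  J_cur <- sum(diag(gr$P))
  g_cur <- (2 * (F_cur - gr$P) %*% gr$W) * pattern
  step <- 1 / max(1, norm(g_cur, "F"))
  g_prev <- NULL; F_prev <- NULL
  for (it in seq_len(max_iter)) {
    if (norm(g_cur, "F") <= tol * (1 + abs(J_cur))) break
    if (!is.null(g_prev)) {
      sF <- F_cur - F_prev; sg <- g_cur - g_prev
      denom <- sum(sF * sg)
      step <- if (denom > 0) sum(sF * sF) / denom else 1 / max(1, norm(g_cur, "F"))
      step <- min(max(step, 1e-8), 1e4)
    }
    accepted <- FALSE
    st <- step
    for (bt in 1:40) {
      F_try <- F_cur - st * g_cur
      gr_try <- gramians(system, F_try)
      if (!is.null(gr_try)) {
        J_try <- sum(diag(gr_try$P))
        if (J_try <= J_cur - 1e-4 * st * norm(g_cur, "F")^2) {
          F_prev <- F_cur; g_prev <- g_cur
          F_cur <- F_try; J_cur <- J_try
          g_cur <- (2 * (F_cur - gr_try$P) %*% gr_try$W) * pattern
          accepted <- TRUE
          break
        }
      }
      st <- st / 2
    }
    if (!accepted) break
  }
  list(F = F_cur, J = J_cur)
}

#' Sparsity-promoting H2 feedback design by ADMM
#'
#' Minimizes `J(F) + gamma * card(F)` over state-feedback gains by the
#' alternating direction method of multipliers on the split
#' `J(F) + gamma * card(G)` subject to `F = G`. The F-step approximately
#' minimizes the smooth augmented term by Anderson-Moore iterations; the
#' G-step is the proximal operator of the cardinality penalty, elementwise
#' hard thresholding that keeps an entry `v` iff `|v| > sqrt(2 gamma / rho)`;
#' dual variables are updated and iteration stops once
#' `||F - G||_F <= eps_abs * n`. The gain is finally polished on the
#' identified pattern ([polish_gain()]).
#'
#' @param system A [laplacian_system()].
#' @param gamma Nonnegative feedback-channel price.
#' @param opts An [admm_options()] list.
#' @param init Optional warm-start gain (defaults to the centralized optimum,
#'   the `gamma = 0` solution).
#' @return An object of class `sparse_gain`: a list with `F` (polished gain),
#'   `pattern` (logical mask), `costs` (one-row tibble from [total_cost()]),
#'   `history` (per-iteration tibble of objective and primal residual),
#'   `iterations`, `converged`, `gamma`.
#' @examples
#' sys <- laplacian_system(net_random_graph(8, 14))
#' sol <- sparse_gain_admm(sys, gamma = 0.01)
#' glance(sol)
#' @export
sparse_gain_admm <- function(system, gamma, opts = admm_options(),
                             init = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0) {
    rlang::abort("gamma must be a single nonnegative number",
                 class = "sparselap_invalid_argument")
  }
  n <- system$n
  F_cur <- if (is.null(init)) centralized_gain(system)$F else init
  G <- F_cur
  Lam <- matrix(0, n, n)
  thr <- sqrt(2 * gamma / opts$rho)
  hist <- vector("list", opts$max_iter)
  converged <- FALSE
  it <- 0L
  while (it < opts$max_iter) {
    it <- it + 1L
    fs <- fstep_minimize(system, F_cur, G - Lam / opts$rho, opts$rho,
                         opts$fstep_tol, opts$fstep_max_iter)
    if (is.null(fs)) {
      rlang::abort("F-step lost closed-loop stability",
                   class = "sparselap_infeasible")
    }
    F_cur <- fs$F
    V <- F_cur + Lam / opts$rho
    G <- V * (abs(V) > thr)
    Lam <- Lam + opts$rho * (F_cur - G)
    r_primal <- norm(F_cur - G, "F")
    hist[[it]] <- tibble::tibble(
      iter = it, J = fs$J, card = sum(G != 0),
      objective = fs$J + gamma * sum(G != 0), primal_residual = r_primal)
    if (r_primal <= opts$eps_abs * n) { converged <- TRUE; break }
  }
  pattern <- G != 0
  if (gamma == 0) pattern[] <- TRUE  # channels are free: keep the full pattern
  pol <- polish_gain(system, pattern, init = G,
                     tol = opts$polish_tol, max_iter = opts$polish_max_iter)
  costs <- total_cost(system, pol$F, gamma, card_tol = opts$card_tol)
  structure(list(F = pol$F, pattern = pattern, costs = costs,
                 history = dplyr::bind_rows(hist[seq_len(it)]),
                 iterations = it, converged = converged, gamma = gamma,
                 n = n),
            class = "sparse_gain")
}

#' @export
print.sparse_gain <- function(x, ...) {
  cat(sprintf(
    "<sparse_gain> n = %d, gamma = %g\n  J = %.6g, card = %d (%.1f%% dense), total = %.6g\n  ADMM: %d iteration(s), %s\n",
    x$n, x$gamma, x$costs$J, x$costs$card,
    100 * x$costs$card / x$n^2, x$costs$total, x$iterations,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Warm-started homotopy over a grid of channel prices
#'
#' Solves [sparse_gain_admm()] along an increasing `gamma` grid, warm-starting
#' each solve from the previous solution (the first from the centralized
#' gain). The nonconvex cardinality objective needs good starts, and the
#' homotopy yields the expected monotone trade-off: `card` non-increasing and
#' `J` non-decreasing along the grid.
#'
#' Because the objective is nonconvex, the solution at each price is a local
#' optimum shaped by the path taken: a sufficiently fine grid (the default,
#' seven log-spaced points per three decades) keeps each solve in the basin
#' of its predecessor, which is how the underlying solver family is meant to
#' be run.
#'
#' @param system A [laplacian_system()].
#' @param gammas Vector of nonnegative prices (sorted internally); default
#'   [default_gamma_grid()].
#' @param opts An [admm_options()] list.
#' @return A list of `sparse_gain` objects, one per `gamma`, in increasing
#'   `gamma` order.
#' @export
sparse_gain_path <- function(system, gammas = default_gamma_grid(),
                             opts = admm_options()) {
  gammas <- sort(gammas)
  out <- vector("list", length(gammas))
  warm <- NULL
  for (i in seq_along(gammas)) {
    out[[i]] <- sparse_gain_admm(system, gammas[i], opts = opts, init = warm)
    warm <- out[[i]]$F
  }
  names(out) <- as.character(gammas)
  out
}

#' Default channel-price grid for the homotopy
#'
#' Seven log-spaced prices spanning `1e-4` to `1e-1`, the range over which
#' the control regime shifts from dense/random-favoring to sparse/
#' centralization-favoring.
#'
#' @return A numeric vector.
#' @export
default_gamma_grid <- function() 10^seq(-4, -1, by = 0.5)
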