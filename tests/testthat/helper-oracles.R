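# Independent oracles used across the suite. These deliberately avoid the
# package's diagonalization-based Lyapunov path: the Kronecker route solves
# the same equations through base solve() on the vectorized system.

# Solve M^T P + P M = Qm by vectorization.
lyap_oracle <- function(M, Qm) {
  n <- nrow(M)
  K <- kronecker(diag(n), t(M)) + kronecker(t(M), diag(n))
  matrix(solve(K, as.numeric(Qm)), n, n)
}

# H2 cost trace(P) by the oracle route; Inf if the closed loop -(L+F) is not
# Hurwitz.
j_oracle <- function(L, F) {
  M <- L + F
  if (any(Re(eigen(M, only.values = TRUE)$values) <= 1e-12)) return(Inf)
  P <- lyap_oracle(M, diag(nrow(L)) + crossprod(F))
  sum(diag(P))
}

# Best achievable J on a fixed support mask, by derivative-free optimization
# of the oracle cost over the supported entries.
pattern_oracle <- function(L, mask, v0 = NULL) {
  k <- sum(mask)
  if (k == 0) return(Inf)
  fn <- function(v) {
    F <- matrix(0, nrow(L), ncol(L))
    F[mask == 1] <- v
    j_oracle(L, F)
  }
  if (is.null(v0)) {
    e <- eigen(L, symmetric = TRUE)
    Fc <- e$vectors %*% ((sqrt(e$values^2 + 1) - e$values) * t(e$vectors))
    v0 <- Fc[mask == 1]
  }
  if (k == 1) {
    # unstabilizable supports give Inf everywhere; Brent warns and returns it
    o <- suppressWarnings(
      stats::optim(v0, fn, method = "Brent", lower = -10, upper = 10))
  } else {
    o <- suppressWarnings(
      stats::optim(v0, fn, control = list(maxit = 5000, reltol = 1e-13)))
  }
  o$value
}

# All partitions of 1..n as membership vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recur <- function(prefix, max_label) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(max_label + 1L)) {
      recur(c(prefix, lab), max(max_label, lab))
    }
  }
  recur(integer(0), 0L)
  out
}

# Small named fixtures.
two_triangles <- function() {
  igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
    directed = FALSE)
}

path_graph <- function(n) {
  igraph::graph_from_edgelist(cbind(seq_len(n - 1), seq_len(n - 1) + 1),
                              directed = FALSE)
}

ring_graph <- function(n) igraph::make_ring(n)

star_graph <- function(n) igraph::make_star(n, mode = "undirected")

# A random graph whose centralized closed loop is perturbed into a random
# feasible (stabilizing) gain.
random_feasible_gain <- function(system, sd = 0.05) {
  repeat {
    F0 <- centralized_gain(system)$F +
      matrix(stats::rnorm(system$n^2, sd = sd), system$n, system$n)
    ok <- tryCatch({
      observability_gramian(system, F0)
      TRUE
    }, sparselap_unstable = function(e) FALSE)
    if (ok) return(F0)
  }
}
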