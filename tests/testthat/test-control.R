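test_that("the Laplacian system has the defining structure", {
  k2 <- igraph::make_full_graph(2)
  sys <- laplacian_system(k2)
  expect_equal(sys$L, matrix(c(1, -1, -1, 1), 2, 2))

  set.seed(1)
  g <- net_random_graph(20, 45)
  sys <- laplacian_system(g)
  expect_equal(rowSums(sys$L), rep(0, 20))
  expect_equal(sys$L, t(sys$L))
  # zero-eigenvalue multiplicity = number of connected components
  lam <- eigen(sys$L, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(lam) < 1e-8),
               igraph::count_components(g))
})

test_that("Gramians solve their Lyapunov equations and detect instability", {
  # scalar: L = [0], F = [1] gives P = 1
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  s1 <- laplacian_system(g1)
  expect_equal(observability_gramian(s1, matrix(1)), matrix(1))
  expect_equal(controllability_gramian(s1, matrix(2)), matrix(1 / 4))
  expect_error(observability_gramian(s1, matrix(0)),
               class = "sparselap_unstable")

  set.seed(2)
  g <- net_random_graph(8, 16)
  sys <- laplacian_system(g)
  F0 <- random_feasible_gain(sys)
  P <- observability_gramian(sys, F0)
  W <- controllability_gramian(sys, F0)
  M <- sys$L + F0
  Qm <- diag(8) + crossprod(F0)
  expect_lt(norm(t(M) %*% P + P %*% M - Qm, "F"), 1e-8 * norm(Qm, "F"))
  expect_lt(norm(M %*% W + W %*% t(M) - diag(8), "F"), 1e-8)
  expect_true(all(eigen(P, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  # against the independent vectorized solver
  expect_equal(P, lyap_oracle(M, Qm), tolerance = 1e-9)
})

test_that("H2 cost matches scalar closed forms and the trace identity", {
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  s1 <- laplacian_system(g1)
  expect_equal(h2_cost(s1, matrix(2)), 1.25)
  expect_equal(h2_cost(s1, matrix(1)), 1)

  # K2 with the centralized optimal gain
  s2 <- laplacian_system(igraph::make_full_graph(2))
  cg <- centralized_gain(s2)
  expect_equal(h2_cost(s2, cg$F), sqrt(5) - 1, tolerance = 1e-9)

  # trace(B1' P B1) = trace((I + F'F) W) on random feasible solves
  for (s in 1:5) {
    set.seed(s)
    g <- net_random_graph(7, 14)
    sys <- laplacian_system(g)
    F0 <- random_feasible_gain(sys)
    J <- h2_cost(sys, F0)
    W <- controllability_gramian(sys, F0)
    expect_equal(J, sum(diag((diag(7) + crossprod(F0)) %*% W)),
                 tolerance = 1e-6 * J)
  }
})

test_that("the analytic H2 gradient matches finite differences", {
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  s1 <- laplacian_system(g1)
  f <- 1.7
  expect_equal(h2_gradient(s1, matrix(f))[1, 1], (f^2 - 1) / (2 * f^2),
               tolerance = 1e-10)
  expect_equal(h2_gradient(s1, matrix(1))[1, 1], 0, tolerance = 1e-12)

  for (s in 1:3) {
    set.seed(10 + s)
    n <- sample(4:8, 1)
    g <- net_random_graph(n, min(2 * n, n * (n - 1) / 2))
    sys <- laplacian_system(g)
    F0 <- random_feasible_gain(sys)
    gr <- h2_gradient(sys, F0)
    fd <- matrix(0, n, n)
    h <- 1e-6
    for (i in seq_len(n)) for (j in seq_len(n)) {
      Ep <- F0; Ep[i, j] <- Ep[i, j] + h
      Em <- F0; Em[i, j] <- Em[i, j] - h
      fd[i, j] <- (h2_cost(sys, Ep) - h2_cost(sys, Em)) / (2 * h)
    }
    expect_lt(max(abs(gr - fd) / (abs(fd) + 1e-6)), 1e-4)
    # stationarity at the centralized optimum
    expect_lt(norm(h2_gradient(sys, centralized_gain(sys)$F), "F"), 1e-6)
  }
})

test_that("the centralized gain matches spectral closed forms", {
  # empty graph: N decoupled scalar problems
  s <- laplacian_system(igraph::make_empty_graph(5, directed = FALSE))
  cg <- centralized_gain(s)
  expect_equal(cg$F, diag(5))
  expect_equal(cg$J, 5)

  # K2 and K3 from the eigenvalue formula
  expect_equal(centralized_gain(laplacian_system(igraph::make_full_graph(2)))$J,
               sqrt(5) - 1, tolerance = 1e-12)
  expect_equal(centralized_gain(laplacian_system(igraph::make_full_graph(3)))$J,
               1 + 2 * (sqrt(10) - 3), tolerance = 1e-12)

  # disconnected graphs are stabilized too
  g <- igraph::disjoint_union(igraph::make_full_graph(3),
                              igraph::make_full_graph(4))
  sys <- laplacian_system(g)
  cg <- centralized_gain(sys)
  expect_true(all(Re(eigen(sys$L + cg$F, only.values = TRUE)$values) > 0))
})

test_that("polishing refines gains on fixed patterns and flags infeasible ones", {
  s2 <- laplacian_system(igraph::make_full_graph(2))

  # full pattern reproduces the centralized optimum
  pol <- polish_gain(s2, matrix(TRUE, 2, 2))
  expect_equal(pol$J, sqrt(5) - 1, tolerance = 1e-8)

  # diagonal pattern against the derivative-free oracle
  pol <- polish_gain(s2, diag(2) == 1)
  expect_equal(pol$J, pattern_oracle(s2$L, diag(2)), tolerance = 1e-4)
  expect_equal(pol$F[1, 2], 0)
  expect_equal(pol$F[2, 1], 0)

  # no gain supported on the empty pattern stabilizes a connected graph
  expect_error(polish_gain(s2, matrix(FALSE, 2, 2)),
               class = "sparselap_infeasible")
})

test_that("ADMM at zero channel price recovers the centralized solution", {
  for (s in 1:5) {
    set.seed(20 + s)
    n <- sample(5:12, 1)
    g <- net_random_graph(n, min(round(1.8 * n), n * (n - 1) / 2))
    sys <- laplacian_system(g)
    sol <- sparse_gain_admm(sys, 0)
    Jstar <- centralized_gain(sys)$J
    expect_lt(abs(sol$costs$J - Jstar) / Jstar, 1e-5)
    expect_equal(sol$costs$card, n^2)
  }
  expect_error(sparse_gain_admm(laplacian_system(igraph::make_full_graph(2)),
                                -1),
               class = "sparselap_invalid_argument")
})

test_that("scalar ADMM keeps the single forced channel", {
  s1 <- laplacian_system(igraph::make_empty_graph(1, directed = FALSE))
  sol <- sparse_gain_admm(s1, 0.01)
  expect_equal(sol$F[1, 1], 1, tolerance = 1e-6)
  expect_equal(sol$costs$card, 1L)
  expect_equal(sol$costs$total, 1.01, tolerance = 1e-6)
})

test_that("the K2 price sweep is monotone and near the 16-pattern oracle", {
  s2 <- laplacian_system(igraph::make_full_graph(2))
  gammas <- c(1e-4, 1e-2, 1e-1)
  sols <- sparse_gain_path(s2, gammas)
  cards <- vapply(sols, function(s) s$costs$card, numeric(1))
  js <- vapply(sols, function(s) s$costs$J, numeric(1))
  expect_true(all(diff(cards) <= 0))
  expect_true(all(diff(js) >= -1e-9))

  # global optimum over all 16 supports, each polished by the oracle
  oracle_best <- function(gamma) {
    best <- Inf
    for (mask_id in 1:15) {
      mask <- matrix(as.integer(intToBits(mask_id))[1:4], 2, 2)
      tot <- pattern_oracle(s2$L, mask) + gamma * sum(mask)
      best <- min(best, tot)
    }
    best
  }
  for (i in seq_along(gammas)) {
    opt <- oracle_best(gammas[i])
    # never better than the global optimum...
    expect_gte(sols[[i]]$costs$total, opt - 1e-6)
    # ...and attains it while the dense support remains globally optimal
    if (gammas[i] <= 1e-2) {
      expect_equal(sols[[i]]$costs$total, opt, tolerance = 1e-4)
    }
  }
})

test_that("homotopy solutions are stabilizing with tight Lyapunov residuals", {
  set.seed(30)
  g <- net_random_graph(15, 35)
  sys <- laplacian_system(g)
  sols <- sparse_gain_path(sys, c(1e-3, 1e-2, 1e-1))
  cards <- vapply(sols, function(s) s$costs$card, numeric(1))
  js <- vapply(sols, function(s) s$costs$J, numeric(1))
  expect_true(all(diff(cards) <= 0))
  expect_true(all(diff(js) >= -1e-9))
  for (sol in sols) {
    M <- sys$L + sol$F
    expect_true(all(Re(eigen(M, only.values = TRUE)$values) > 0))
    expect_true(all(sol$F[!sol$pattern] == 0))
    P <- observability_gramian(sys, sol$F)
    Qm <- diag(15) + crossprod(sol$F)
    expect_lt(norm(t(M) %*% P + P %*% M - Qm, "F"), 1e-8 * norm(Qm, "F"))
    # accounting identity
    expect_equal(sol$costs$total,
                 sol$costs$J + sol$gamma * sol$costs$card)
    # iterates settle: the final consensus objective is within solver
    # tolerance of the best seen, and polishing never worsens it
    obj <- sol$history$objective
    expect_lte(obj[length(obj)], min(obj) + 1e-2 * max(1, min(obj)))
    expect_lte(sol$costs$total, obj[length(obj)] + 1e-6)
  }
})

test_that("total_cost prices channels and tidiers summarize solutions", {
  s1 <- laplacian_system(igraph::make_empty_graph(1, directed = FALSE))
  tc <- total_cost(s1, matrix(1), gamma = 0.01)
  expect_equal(tc$total, 1.01)
  tc0 <- total_cost(s1, matrix(1), gamma = 0)
  expect_equal(tc0$total, tc0$J)

  set.seed(31)
  g <- net_random_graph(10, 20)
  sys <- laplacian_system(g)
  sol <- sparse_gain_admm(sys, 0.05)
  # sparse never beats the unconstrained optimum
  expect_gte(sol$costs$J, centralized_gain(sys)$J - 1e-9)
  td <- tidy(sol)
  expect_equal(nrow(td), sol$costs$card)
  gl <- glance(sol)
  expect_named(gl, c("gamma", "J", "card", "total", "iterations", "converged"))
  expect_s3_class(autoplot(sol), "ggplot")
})
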