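# Independent oracles and generators shared across tests. Everything here
# is deliberately written by a different route than the package code
# (explicit loops, igraph, generic optimizers).

random_weight_matrix <- function(n, density = 0.4, wmin = 0.2, wmax = 1.5) {
  W <- matrix(0, n, n, dimnames = list(paste0("V", seq_len(n)),
                                       paste0("V", seq_len(n))))
  ut <- which(upper.tri(W))
  on <- runif(length(ut)) < density
  W[ut[on]] <- runif(sum(on), wmin, wmax)
  W + t(W)
}

# weight matrix -> igraph object with lengths as edge weights
as_igraph_lengths <- function(W) {
  igraph::graph_from_adjacency_matrix(ifelse(W > 0, 1 / W, 0),
                                      mode = "undirected", weighted = TRUE)
}

oracle_strength <- function(W) {
  out <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) out[i] <- sum(abs(W[i, ]))
  out
}

# Onnela weighted clustering by explicit triple loop
oracle_clustering <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  if (max(W) == 0) return(out)
  Wh <- W / max(W)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (l in seq_len(n)) {
      if (j == i || l == i || j == l) next
      acc <- acc + (Wh[i, j] * Wh[j, l] * Wh[i, l])^(1 / 3)
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

oracle_distances <- function(W) {
  igraph::distances(as_igraph_lengths(W))
}

oracle_betweenness <- function(W) {
  g <- as_igraph_lengths(W)
  as.numeric(igraph::betweenness(g, directed = FALSE))
}

oracle_closeness <- function(W) {
  D <- oracle_distances(W)
  n <- nrow(D)
  out <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    r <- length(reach)
    if (r > 0) out[v] <- (r / (n - 1)) * (r / sum(D[v, reach]))
  }
  out
}

# Map equation via the four-term algebraic form
# L = PL(sum q) - 2 sum_m PL(q_m) - sum_i PL(p_i) + sum_m PL(q_m + p_m)
oracle_map_equation <- function(W, modules) {
  PL <- function(x) sum(ifelse(x > 0, x * log2(x), 0))
  s <- rowSums(W)
  tot <- sum(s)
  if (tot == 0) return(0)
  p <- s / tot
  ids <- unique(modules)
  q <- vapply(ids, function(m)
    sum(W[modules == m, modules != m, drop = FALSE]), 0) / tot
  pm <- vapply(ids, function(m) sum(p[modules == m]), 0)
  PL(sum(q)) - 2 * PL(q) - PL(p) + PL(q + pm)
}

# penalized logistic objective (average negative log-likelihood + l1)
penalized_objective <- function(a, b, y, X, lambda) {
  eta <- a + as.numeric(X %*% b)
  mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + lambda * sum(abs(b))
}

# independent solver: L-BFGS-B on the positive/negative part split
oracle_lasso_fit <- function(y, X, lambda) {
  q <- ncol(X)
  fn <- function(par) {
    a <- par[1]; bp <- par[2:(q + 1)]; bn <- par[(q + 2):(2 * q + 1)]
    b <- bp - bn
    eta <- a + as.numeric(X %*% b)
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda * sum(bp + bn)
  }
  best <- NULL
  for (start in list(rep(0, 2 * q + 1), c(qlogis(mean(y)), rep(0.1, 2 * q)))) {
    o <- optim(start, fn, method = "L-BFGS-B",
               lower = c(-Inf, rep(0, 2 * q)),
               control = list(maxit = 2000, factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(a = best$par[1],
       b = best$par[2:(q + 1)] - best$par[(q + 2):(2 * q + 1)],
       objective = best$value)
}

# 6-node chain ground truth used by several recovery tests
chain_model <- function(beta = 1, tau = -0.5, p = 6) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) W[i, i + 1] <- W[i + 1, i] <- beta
  ising_network(W, rep(tau, p))
}

# ground truth with a strong triangle at V1 plus a chain tail; removing
# V1's edges post drops its true clustering to zero
planted_triangle_model <- function() {
  W <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3)))
    W[e[1], e[2]] <- W[e[2], e[1]] <- 2
  for (e in list(c(3, 4), c(4, 5), c(5, 6)))
    W[e[1], e[2]] <- W[e[2], e[1]] <- 1.2
  ising_network(W, c(-2, -2, -2.5, -1, -1, -0.6))
}

# two disconnected unit-weight triangles (closed-form map equation example)
two_triangles <- function() {
  W <- matrix(0, 6, 6, dimnames = list(paste0("V", 1:6), paste0("V", 1:6)))
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    W[e[1], e[2]] <- W[e[2], e[1]] <- 1
  W
}

# null model for the permutation-test calibration: complete 5-node graph,
# moderate couplings, marginals 1/2
calibration_null_model <- function() {
  W <- matrix(0.6, 5, 5)
  diag(W) <- 0
  ising_network(W, rep(-1.2, 5))
}

expect_equal_upto_tol <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
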