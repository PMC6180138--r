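# Two-level map-equation community detection on the absolute-weight
# undirected network, with a Louvain-style optimizer and an exhaustive
# enumeration oracle for small graphs.

# -sum x log2 x over the positive entries of an (already normalized) vector
entropy_bits <- function(x) {
  x <- x[x > 0]
  if (!length(x)) return(0)
  -sum(x * log2(x))
}

normalize_modules <- function(modules, labels) {
  m <- as.integer(factor(modules, levels = unique(modules)))
  stats::setNames(m, labels)
}

#' Two-level map equation
#'
#' Codelength (bits per step) of a random walk on the undirected weighted
#' network under a two-level code given a module partition. With node
#' strengths \eqn{s_i}, total weight \eqn{2W = \sum_i s_i}, stationary
#' visit rates \eqn{p_i = s_i / 2W} and module exit rates
#' \eqn{q_m = \mathrm{cut}(m) / 2W} (cut = total weight of edges with
#' exactly one endpoint in \eqn{m}):
#' \deqn{L(M) = \Big(\sum_m q_m\Big) H(Q) +
#'   \sum_m p_m^\circlearrowright H(P^m),}
#' where \eqn{H(Q)} is the entropy of the normalized exit rates,
#' \eqn{p_m^\circlearrowright = q_m + \sum_{i \in m} p_i}, and
#' \eqn{H(P^m)} the entropy of
#' \eqn{\{q_m / p_m^\circlearrowright\} \cup \{p_i / p_m^\circlearrowright\}}.
#' All logarithms are base 2 and \eqn{0 \log 0 = 0}. On a disconnected
#' network the same expression applies (per-component contributions add);
#' a message notes the disconnection.
#'
#' @param net An [ising_network()] (absolute weights taken) or weight
#'   matrix.
#' @param modules Integer module id per node (named by node label or in
#'   node order), or a `network_partition`.
#' @param warn_disconnected Emit the disconnection message (default `TRUE`;
#'   the optimizer suppresses it).
#' @return Codelength in bits.
#' @export
map_equation <- function(net, modules, warn_disconnected = TRUE) {
  W <- as_weight_matrix(net)
  n <- nrow(W)
  if (inherits(modules, "network_partition")) modules <- modules$modules
  if (!is.null(names(modules))) modules <- modules[colnames(W)]
  modules <- as.integer(factor(modules))
  stopifnot(length(modules) == n, !anyNA(modules))
  s <- rowSums(W)
  tot <- sum(s)
  if (tot == 0) return(0)
  if (warn_disconnected && n > 1) {
    D <- shortest_paths(edge_lengths(W))$distances
    if (any(!is.finite(D)))
      message("network is disconnected; map equation adds per-component contributions")
  }
  p <- s / tot
  k <- max(modules)
  memb <- outer(modules, seq_len(k), `==`) * 1  # n x k indicator
  within <- t(memb) %*% W %*% memb  # within[a, b]: weight between modules a, b
  pm_node <- as.numeric(t(memb) %*% p)
  q <- (rowSums(within) - diag(within)) / tot
  qsum <- sum(q)
  term1 <- if (qsum > 0) qsum * entropy_bits(q / qsum) else 0
  term2 <- 0
  for (a in seq_len(k)) {
    pm <- q[a] + pm_node[a]
    if (pm <= 0) next
    inner <- c(q[a], p[modules == a]) / pm
    term2 <- term2 + pm * entropy_bits(inner)
  }
  term1 + term2
}

make_partition <- function(modules, labels, codelength, extra = list()) {
  structure(c(list(modules = normalize_modules(modules, labels),
                   codelength = codelength), extra),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d nodes in %d modules, codelength %.4f bits\n",
              length(x$modules), length(unique(x$modules)), x$codelength))
  invisible(x)
}

#' Two-level map-equation optimization
#'
#' Minimizes [map_equation()] by seeded local search in the spirit of the
#' Louvain procedure: starting from singleton modules, repeated sweeps move
#' single nodes to the neighboring module giving the largest codelength
#' decrease; when no move helps, whole-module merges are attempted, and the
#' two phases alternate until no change improves the codelength by more
#' than `tol`. The best partition over `n_restarts` random sweep orders is
#' returned; the result never exceeds the single-module codelength.
#'
#' @inheritParams map_equation
#' @param seed Integer seed making restarts reproducible.
#' @param n_restarts Number of random restarts (default 10).
#' @param tol Minimum accepted improvement (default 1e-10).
#' @return A `network_partition`: `modules` (named, ids contiguous from 1),
#'   `codelength`, `n_restarts`, `seed`.
#' @export
optimize_partition <- function(net, seed = NULL, n_restarts = 10, tol = 1e-10) {
  W <- as_weight_matrix(net)
  n <- nrow(W)
  labels <- colnames(W)
  if (n == 1L)
    return(make_partition(1L, labels, map_equation(W, 1L),
                          list(n_restarts = n_restarts, seed = seed)))
  if (any(!is.finite(shortest_paths(edge_lengths(W))$distances)))
    message("network is disconnected; map equation adds per-component contributions")

  Lof <- function(mod) map_equation(W, mod, warn_disconnected = FALSE)
  neighbors <- lapply(seq_len(n), function(i) which(W[i, ] > 0))

  one_restart <- function() {
    mod <- seq_len(n)
    L <- Lof(mod)
    repeat {
      improved <- FALSE
      # single-node moves
      repeat {
        moved <- FALSE
        for (v in sample.int(n)) {
          cand <- unique(mod[neighbors[[v]]])
          cand <- setdiff(cand, mod[v])
          if (!length(cand)) next
          best_L <- L; best_m <- mod[v]
          for (m2 in cand) {
            trial <- mod; trial[v] <- m2
            L2 <- Lof(trial)
            if (L2 < best_L - tol) { best_L <- L2; best_m <- m2 }
          }
          if (best_m != mod[v]) {
            mod[v] <- best_m; L <- best_L; moved <- TRUE; improved <- TRUE
          }
        }
        if (!moved) break
      }
      # whole-module merges
      merged <- TRUE
      while (merged) {
        merged <- FALSE
        ids <- unique(mod)
        if (length(ids) < 2L) break
        best_L <- L; best_pair <- NULL
        for (a_i in seq_along(ids)[-length(ids)]) for (b_i in seq.int(a_i + 1L, length(ids))) {
          a <- ids[a_i]; b <- ids[b_i]
          trial <- mod; trial[trial == b] <- a
          L2 <- Lof(trial)
          if (L2 < best_L - tol) { best_L <- L2; best_pair <- c(a, b) }
        }
        if (!is.null(best_pair)) {
          mod[mod == best_pair[2L]] <- best_pair[1L]
          L <- best_L; merged <- TRUE; improved <- TRUE
        }
      }
      if (!improved) break
    }
    list(mod = mod, L = L)
  }

  best <- with_seed(seed, {
    res <- lapply(seq_len(max(1L, n_restarts)), function(r) one_restart())
    res[[which.min(vapply(res, `[[`, 0, "L"))]]
  })
  single_L <- Lof(rep(1L, n))
  if (single_L < best$L - tol) best <- list(mod = rep(1L, n), L = single_L)
  make_partition(best$mod, labels, best$L,
                 list(n_restarts = n_restarts, seed = seed))
}

# Iterate over all set partitions of n items as restricted growth strings.
next_rgs <- function(a, b) {
  # a: current string (1-based), b[i] = max(a[1..i-1]); returns NULL at end
  n <- length(a)
  for (i in n:2) {
    if (a[i] <= b[i]) {
      a[i] <- a[i] + 1L
      if (i < n) {
        for (j in (i + 1L):n) {
          a[j] <- 1L
          b[j] <- max(b[i], a[i])
        }
      }
      return(list(a = a, b = b))
    }
  }
  NULL
}

#' Exhaustive map-equation minimizer (oracle)
#'
#' Evaluates [map_equation()] on every set partition of the nodes (Bell
#' number enumeration, so limited to 10 nodes) and returns the exact
#' minimizer. Intended as a test oracle for [optimize_partition()].
#'
#' @inheritParams map_equation
#' @return A `network_partition` with the globally minimal codelength.
#' @export
enumerate_optimal_partition <- function(net) {
  W <- as_weight_matrix(net)
  n <- nrow(W)
  stopifnot(n <= 10L)
  if (n == 1L) return(make_partition(1L, colnames(W), map_equation(W, 1L)))
  a <- rep(1L, n)
  b <- rep(1L, n)
  best_mod <- a
  best_L <- map_equation(W, a, warn_disconnected = FALSE)
  repeat {
    nx <- next_rgs(a, b)
    if (is.null(nx)) break
    a <- nx$a; b <- nx$b
    L <- map_equation(W, a, warn_disconnected = FALSE)
    if (L < best_L - 1e-12) { best_L <- L; best_mod <- a }
  }
  make_partition(best_mod, colnames(W), best_L)
}
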