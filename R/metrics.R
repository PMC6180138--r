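# Regional measures on the absolute-weight undirected network: strength,
# connection-length transform, Floyd-Warshall shortest paths, betweenness,
# component-scaled closeness, Onnela weighted clustering, and rank-based
# hub detection.

as_weight_matrix <- function(net) {
  if (inherits(net, "ising_network")) abs(net$weights) else {
    W <- as.matrix(net)
    stopifnot(nrow(W) == ncol(W))
    if (is.null(colnames(W))) dimnames(W) <- list(paste0("V", seq_len(ncol(W))),
                                                  paste0("V", seq_len(ncol(W))))
    abs(W)
  }
}

#' Node strength
#'
#' Sum of the absolute weights of the edges incident to each node.
#'
#' @param net An [ising_network()] (absolute weights taken) or a weight
#'   matrix.
#' @return Named numeric vector.
#' @export
node_strength <- function(net) {
  W <- as_weight_matrix(net)
  rowSums(W)
}

#' Weight-to-length transform
#'
#' Converts connection weights to connection lengths for the distance-based
#' measures: \eqn{L_{ij} = 1 / w_{ij}} for \eqn{w_{ij} > 0}, `Inf` for
#' absent edges, 0 on the diagonal. Stronger connections are thus shorter.
#'
#' @inheritParams node_strength
#' @return Length matrix.
#' @export
edge_lengths <- function(net) {
  W <- as_weight_matrix(net)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  L
}

#' All-pairs shortest paths (Floyd-Warshall)
#'
#' Computes the full matrix of shortest-path lengths over the connection
#' lengths. Path reconstruction (see [extract_path()]) is done greedily on
#' the distance matrix and, among equal-length geodesics, returns the
#' lexicographically smallest node sequence (by node order), so reported
#' paths are canonical.
#'
#' @param lengths Length matrix from [edge_lengths()] (non-negative, `Inf`
#'   for absent edges).
#' @return Object of class `shortest_paths`: `distances` matrix and the
#'   input `lengths`.
#' @export
shortest_paths <- function(lengths) {
  L <- as.matrix(lengths)
  n <- nrow(L)
  stopifnot(ncol(L) == n)
  if (any(L < 0)) stop("negative connection lengths are not allowed")
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    dk <- outer(D[, k], D[k, ], `+`)
    upd <- dk < D
    D[upd] <- dk[upd]
  }
  structure(list(distances = D, lengths = L), class = "shortest_paths")
}

#' Reconstruct one canonical shortest path
#'
#' @param sp A `shortest_paths` object.
#' @param from,to Node labels or indices.
#' @return Character (or integer, for an unnamed matrix) vector of the node
#'   sequence from `from` to `to`; `NULL` when `to` is unreachable.
#' @export
extract_path <- function(sp, from, to) {
  D <- sp$distances; L <- sp$lengths
  labels <- colnames(D)
  idx <- function(x) if (is.character(x)) match(x, labels) else as.integer(x)
  i <- idx(from); j <- idx(to)
  stopifnot(!is.na(i), !is.na(j))
  if (!is.finite(D[i, j])) return(NULL)
  path <- i
  cur <- i
  steps <- 0L
  while (cur != j) {
    steps <- steps + 1L
    if (steps > nrow(D)) stop("path reconstruction failed (inconsistent distances)")
    cand <- which(is.finite(L[cur, ]) &
                    abs(L[cur, ] + D[, j] - D[cur, j]) <=
                      1e-9 * (1 + abs(D[cur, j])))
    cand <- setdiff(cand, cur)
    nxt <- cand[1L]  # smallest index: lexicographically smallest sequence
    path <- c(path, nxt)
    cur <- nxt
  }
  if (!is.null(labels)) labels[path] else path
}

# Dijkstra from one source over a length matrix; returns distances, geodesic
# counts sigma, and predecessor lists. Equal lengths are compared with a
# relative tolerance so tied geodesics are counted.
dijkstra_sigma <- function(L, s, eps = 1e-10) {
  n <- nrow(L)
  dist <- rep(Inf, n); dist[s] <- 0
  sigma <- numeric(n); sigma[s] <- 1
  preds <- vector("list", n)
  done <- rep(FALSE, n)
  order_out <- integer(0)
  for (iter in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1L]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    order_out <- c(order_out, u)
    nb <- which(is.finite(L[u, ]) & !done)
    for (v in nb) {
      alt <- dist[u] + L[u, v]
      tol <- eps * (1 + abs(alt))
      if (alt < dist[v] - tol) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        preds[[v]] <- u
      } else if (abs(alt - dist[v]) <= tol) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_out)
}

#' Betweenness centrality (weighted, Brandes)
#'
#' For each node \eqn{v}, the sum over unordered pairs of other nodes
#' \eqn{(s, t)} of the fraction of shortest \eqn{s}-\eqn{t} paths (over
#' connection lengths) passing through \eqn{v}. Endpoints are excluded and
#' no normalization is applied.
#'
#' @inheritParams shortest_paths
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(lengths) {
  L <- as.matrix(lengths)
  n <- nrow(L)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dj <- dijkstra_sigma(L, s)
    delta <- numeric(n)
    for (w in rev(dj$order)) {
      for (u in dj$preds[[w]])
        delta[u] <- delta[u] + dj$sigma[u] / dj$sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc / 2, colnames(L))  # each unordered pair counted once
}

#' Closeness centrality (component-scaled)
#'
#' For a connected network, \eqn{CC(v) = (n - 1) / \sum_u d(v, u)}. On a
#' disconnected network the component-scaled convention is used:
#' \eqn{CC(v) = (r / (n - 1)) \cdot (r / \sum_{u \in R(v)} d(v, u))} with
#' \eqn{R(v)} the set of (other) nodes reachable from \eqn{v} and
#' \eqn{r = |R(v)|}; isolated nodes get 0. A message is emitted when the
#' network is disconnected.
#'
#' @param sp A `shortest_paths` object or a length matrix.
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(sp) {
  if (!inherits(sp, "shortest_paths")) sp <- shortest_paths(sp)
  D <- sp$distances
  n <- nrow(D)
  finite <- is.finite(D) & row(D) != col(D)
  if (!all(is.finite(D))) message("network is disconnected; ",
                                  "component-scaled closeness used")
  cc <- vapply(seq_len(n), function(v) {
    r <- sum(finite[v, ])
    if (r == 0L) return(0)
    (r / (n - 1)) * (r / sum(D[v, finite[v, ]]))
  }, 0)
  stats::setNames(cc, colnames(D))
}

#' Weighted clustering coefficient (Onnela)
#'
#' Geometric-mean triangle intensity around each node on the
#' max-normalized weights \eqn{\hat w = w / \max(w)}:
#' \deqn{C_i = \frac{\sum_{j \ne k} (\hat w_{ij} \hat w_{jk} \hat w_{ik})^{1/3}}
#'   {k_i (k_i - 1)},}
#' with \eqn{k_i} the binary degree; nodes of degree < 2 get 0. Values lie
#' in \eqn{[0, 1]}.
#'
#' @inheritParams node_strength
#' @return Named numeric vector.
#' @export
clustering_coefficient <- function(net) {
  W <- as_weight_matrix(net)
  n <- nrow(W)
  k <- rowSums(W > 0)
  if (max(W) == 0) return(stats::setNames(numeric(n), colnames(W)))
  Wh <- (W / max(W))^(1 / 3)
  cyc <- diag(Wh %*% Wh %*% Wh)
  C <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  stats::setNames(C, colnames(W))
}

#' Centrality table with ranks and hub flags
#'
#' Computes strength, betweenness, closeness and clustering for every node
#' of an absolute-weight network, competition ranks (1 = highest; ties
#' share the best rank) for the three centrality measures, and flags hubs
#' via [detect_hubs()]. Clustering is reported but is not a hub criterion.
#'
#' @param net An [ising_network()] (absolute weights are taken) or weight
#'   matrix.
#' @param top_fraction,min_measures Passed to [detect_hubs()].
#' @return Data frame of class `centrality_table`, one row per node.
#' @export
centrality_table <- function(net, top_fraction = 0.20, min_measures = 2) {
  W <- as_weight_matrix(net)
  L <- edge_lengths(W)
  sp <- shortest_paths(L)
  tab <- data.frame(
    node = colnames(W),
    strength = unname(node_strength(W)),
    betweenness = unname(betweenness_centrality(L)),
    closeness = unname(closeness_centrality(sp)),
    clustering = unname(clustering_coefficient(W)),
    stringsAsFactors = FALSE
  )
  for (m in c("strength", "betweenness", "closeness"))
    tab[[paste0("rank_", m)]] <- rank(-tab[[m]], ties.method = "min")
  tab$is_hub <- tab$node %in% detect_hubs(tab, top_fraction, min_measures)
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' Rank-based hub detection
#'
#' A node is a hub when its competition rank is within the top
#' `round(top_fraction * p)` ranks (p = node count) in at least
#' `min_measures` of the three centrality measures strength, betweenness
#' and closeness. With 24 nodes and the default fraction 0.20 the cutoff is
#' rank 5. When ties push more than `round(top_fraction * p)` nodes into
#' the top ranks of a measure, all tied nodes count (with a warning).
#'
#' @param table A [centrality_table()] (or data frame with columns `node`,
#'   `strength`, `betweenness`, `closeness`).
#' @param top_fraction Fraction of top ranks that qualify (default 0.20).
#' @param min_measures Number of measures required (default 2).
#' @return Character vector of hub node labels.
#' @export
detect_hubs <- function(table, top_fraction = 0.20, min_measures = 2) {
  stopifnot(top_fraction > 0, top_fraction <= 1,
            all(c("node", "strength", "betweenness", "closeness") %in%
                  names(table)))
  p <- nrow(table)
  r_star <- round(top_fraction * p)
  if (r_star < 1L) return(character(0))
  in_top <- vapply(c("strength", "betweenness", "closeness"), function(m) {
    rk <- rank(-table[[m]], ties.method = "min")
    top <- rk <= r_star
    if (sum(top) > r_star)
      warning("ties extend the top-", r_star, " set for ", m,
              " to ", sum(top), " nodes")
    top
  }, logical(p))
  table$node[rowSums(in_top) >= min_measures]
}
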