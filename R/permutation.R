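# Pre/post comparison of regional network measures with a
# refitted-pseudo-network permutation null.

#' Regional measure of one node on an absolute-weight network
#'
#' @param net An [ising_network()] with absolute weights (see
#'   [to_absolute_network()]) or a weight matrix.
#' @param node Node label.
#' @param measure One of `"clustering"`, `"strength"`, `"betweenness"`,
#'   `"closeness"`.
#' @return Numeric scalar.
#' @export
network_measure <- function(net, node,
                            measure = c("clustering", "strength",
                                        "betweenness", "closeness")) {
  measure <- match.arg(measure)
  W <- as_weight_matrix(net)
  if (!node %in% colnames(W)) stop("node not in network: ", node)
  vals <- switch(measure,
    clustering = clustering_coefficient(W),
    strength = node_strength(W),
    betweenness = betweenness_centrality(edge_lengths(W)),
    closeness = closeness_centrality(edge_lengths(W))
  )
  unname(vals[node])
}

fit_abs <- function(m, ...) to_absolute_network(fit_ising(m, ...))

#' Observed pre/post difference in a regional measure
#'
#' Fits one Ising network per time point ([fit_ising()] followed by
#' [to_absolute_network()]) and returns the post - pre difference of the
#' chosen regional measure at one node.
#'
#' @param binary_pre,binary_post Binary response tables (same retained node
#'   set).
#' @param node Node label.
#' @inheritParams network_measure
#' @param ... Passed to [fit_ising()] (e.g. `gamma`, `rule`, `nlambda`).
#' @return List with `pre`, `post`, `diff` (= post - pre).
#' @export
observed_difference <- function(binary_pre, binary_post, node,
                                measure = "clustering", ...) {
  pre_m <- as_binary_matrix(binary_pre)
  post_m <- as_binary_matrix(binary_post)
  if (!identical(colnames(pre_m), colnames(post_m)))
    stop("pre and post tables must share one retained node set")
  v_pre <- network_measure(fit_abs(pre_m, ...), node, measure)
  v_post <- network_measure(fit_abs(post_m, ...), node, measure)
  list(pre = v_pre, post = v_post, diff = v_post - v_pre)
}

group_degenerate <- function(m) {
  cs <- colSums(m)
  any(cs == 0 | cs == nrow(m))
}

#' Permutation test for pre/post change in a regional measure
#'
#' Builds the null distribution of the pre/post difference by repeatedly
#' splitting the pooled `2N` participant-time-point records at random into
#' two pseudo-groups of size `N`, refitting an Ising network on each
#' pseudo-group, and recording the difference of the regional measure
#' (pseudo-networks). The default split is unrestricted by participant; a
#' `paired = TRUE` mode instead flips each participant's pre/post labels
#' with probability 1/2. The two-sided p-value uses the add-one estimator
#' \deqn{p = \frac{1 + \#\{|d_{null}| \ge |d_{obs}|\}}{1 + B},}
#' so p is never exactly 0. Permutations in which a pseudo-group leaves
#' some node constant (degenerate variance) are redrawn and counted.
#'
#' @inheritParams observed_difference
#' @param n_permutations Number of pseudo-network pairs (default 5000; use
#'   a few hundred for exploratory runs).
#' @param seed Integer seed for reproducibility.
#' @param paired Flip labels within participant instead of the unrestricted
#'   split (default `FALSE`). Requires rows of `binary_pre` and
#'   `binary_post` to be aligned by participant.
#' @return Object of class `permutation_result`: `node`, `measure`,
#'   `observed_pre`, `observed_post`, `observed_diff`, `null_diffs`,
#'   `p_value`, `n_permutations`, `n_redraws`, `seed`.
#' @export
permutation_null <- function(binary_pre, binary_post, node,
                             measure = "clustering",
                             n_permutations = 5000, seed = NULL,
                             paired = FALSE, ...) {
  pre_m <- as_binary_matrix(binary_pre)
  post_m <- as_binary_matrix(binary_post)
  if (!identical(colnames(pre_m), colnames(post_m)))
    stop("pre and post tables must share one retained node set")
  N <- nrow(pre_m)
  if (nrow(post_m) != N)
    stop("equal participant counts per time point required")
  obs <- observed_difference(pre_m, post_m, node, measure, ...)
  pooled <- rbind(pre_m, post_m)

  null_diffs <- numeric(n_permutations)
  n_redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      repeat {
        if (paired) {
          flip <- runif(N) < 0.5
          idx1 <- ifelse(flip, N + seq_len(N), seq_len(N))
        } else {
          idx1 <- sample.int(2L * N, N)
        }
        g1 <- pooled[idx1, , drop = FALSE]
        g2 <- pooled[-idx1, , drop = FALSE]
        if (!group_degenerate(g1) && !group_degenerate(g2)) break
        n_redraws <- n_redraws + 1L
      }
      d1 <- network_measure(fit_abs(g1, ...), node, measure)
      d2 <- network_measure(fit_abs(g2, ...), node, measure)
      null_diffs[b] <- d2 - d1
    }
  })
  if (n_redraws > 0L)
    message(n_redraws, " degenerate permutation(s) redrawn")
  p <- (1 + sum(abs(null_diffs) >= abs(obs$diff) - 1e-12)) /
    (1 + n_permutations)
  structure(list(node = node, measure = measure,
                 observed_pre = obs$pre, observed_post = obs$post,
                 observed_diff = obs$diff, null_diffs = null_diffs,
                 p_value = p, n_permutations = n_permutations,
                 n_redraws = n_redraws, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s of '%s': pre %.4f, post %.4f, diff %+.4f; p = %.4g (%d permutations)\n",
              x$measure, x$node, x$observed_pre, x$observed_post,
              x$observed_diff, x$p_value, x$n_permutations))
  invisible(x)
}

#' Permutation scan over nodes
#'
#' Runs [permutation_null()] for each of several nodes on one measure and
#' tabulates the results, optionally with Benjamini-Hochberg adjustment
#' across nodes.
#'
#' @inheritParams permutation_null
#' @param nodes Node labels (default all columns).
#' @param adjust `"none"` (default; mirrors a fixed per-node screen) or
#'   `"BH"`.
#' @return Data frame with one row per node: observed values, difference,
#'   `p_value` (and `p_adjusted` when requested).
#' @export
permutation_scan <- function(binary_pre, binary_post, nodes = NULL,
                             measure = "clustering", n_permutations = 5000,
                             seed = NULL, adjust = c("none", "BH"), ...) {
  adjust <- match.arg(adjust)
  pre_m <- as_binary_matrix(binary_pre)
  nodes <- nodes %||% colnames(pre_m)
  res <- lapply(seq_along(nodes), function(k) {
    r <- permutation_null(binary_pre, binary_post, nodes[k], measure,
                          n_permutations = n_permutations,
                          seed = if (is.null(seed)) NULL else seed + k - 1L,
                          ...)
    data.frame(node = r$node, measure = r$measure,
               observed_pre = r$observed_pre,
               observed_post = r$observed_post,
               observed_diff = r$observed_diff,
               p_value = r$p_value, n_redraws = r$n_redraws,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
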