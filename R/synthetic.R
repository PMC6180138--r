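# Ground-truth Ising models, Gibbs sampling of binary responses,
# threshold calibration to target marginals, Likert expansion, and paired
# pre/post datasets with planted changes.

#' Random sparse Ising model
#'
#' Draws an Erdos-Renyi edge support at the given density, edge weights
#' uniform on `weight_range` and node thresholds uniform on
#' `threshold_range`.
#'
#' @param p Number of nodes.
#' @param edge_density Probability of each of the `p(p-1)/2` edges.
#' @param weight_range Range of the (signed) uniform edge weights.
#' @param threshold_range Range of the uniform thresholds.
#' @param labels Optional node labels.
#' @param seed Integer seed.
#' @return An [ising_network()] with `meta$generator` recording the call.
#' @export
random_ising_model <- function(p, edge_density, weight_range = c(-1.5, 1.5),
                               threshold_range = c(-1, 0), labels = NULL,
                               seed = NULL) {
  stopifnot(p >= 1, edge_density >= 0, edge_density <= 1)
  labels <- labels %||% paste0("V", seq_len(p))
  with_seed(seed, {
    W <- matrix(0, p, p)
    ut <- upper.tri(W)
    on_edge <- runif(sum(ut)) < edge_density
    w <- ifelse(on_edge, runif(sum(ut), weight_range[1], weight_range[2]), 0)
    W[ut] <- w
    W <- W + t(W)
    tau <- runif(p, threshold_range[1], threshold_range[2])
    ising_network(W, tau, labels,
                  meta = list(generator = list(p = p,
                                               edge_density = edge_density,
                                               weight_range = weight_range,
                                               threshold_range = threshold_range,
                                               seed = seed)))
  })
}

#' Gibbs sampling from an Ising model
#'
#' Sequential-scan Gibbs sampler under the \{0,1\} coding,
#' \eqn{P(x_i = 1 | x_{-i}) = \mathrm{logistic}(\tau_i + \sum_j \beta_{ij} x_j)}.
#' The first `burn_in` full sweeps are discarded and every `thin`-th sweep
#' thereafter is kept.
#'
#' @param model An [ising_network()] used as ground truth.
#' @param n_samples Number of kept sweeps (rows).
#' @param burn_in Discarded initial sweeps (default 1000).
#' @param thin Keep every `thin`-th sweep (default 10).
#' @param seed Integer seed (`NULL` uses, and advances, the current RNG
#'   stream).
#' @return Integer 0/1 matrix `n_samples` x `p` with node labels as column
#'   names.
#' @export
gibbs_sample <- function(model, n_samples, burn_in = 1000, thin = 10,
                         seed = NULL) {
  stopifnot(inherits(model, "ising_network"), n_samples >= 1)
  out <- with_seed(seed,
    .gibbs_sample_cpp(model$thresholds, model$weights,
                      as.integer(n_samples), as.integer(burn_in),
                      as.integer(thin)))
  colnames(out) <- model$labels
  out
}

#' Exact state probabilities of a small Ising model
#'
#' Enumerates all \eqn{2^p} binary states (p <= 16) and returns their exact
#' probabilities under
#' \eqn{P(x) \propto \exp(\sum_i \tau_i x_i + \sum_{i<j} \beta_{ij} x_i x_j)}.
#' Used as the enumeration oracle for the Gibbs sampler and for exact
#' marginal computations.
#'
#' @param model An [ising_network()].
#' @return List with `states` (matrix, one row per state) and `prob`.
#' @export
ising_exact_probs <- function(model) {
  p <- length(model$labels)
  stopifnot(p <= 16)
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  colnames(states) <- model$labels
  logw <- states %*% model$thresholds +
    rowSums((states %*% model$weights) * states) / 2
  w <- exp(logw - max(logw))
  list(states = states, prob = as.numeric(w / sum(w)))
}

ising_exact_marginals <- function(model) {
  ex <- ising_exact_probs(model)
  as.numeric(crossprod(ex$states, ex$prob))
}

#' Calibrate thresholds to target presence counts
#'
#' Adjusts the thresholds \eqn{\tau} of a model (couplings fixed) until the
#' sampled marginal presence frequencies match `target_counts / N` to
#' within `tol`. For models of at most 12 nodes the marginals are computed
#' exactly by state enumeration and matched by damped logit updates;
#' larger models use the same update with Monte Carlo marginal estimates
#' (stochastic approximation). Non-convergence within `max_iter` iterations
#' produces a warning reporting the achieved marginals.
#'
#' @param model An [ising_network()].
#' @param target_counts Per-node integer targets, strictly between 0 and
#'   `N`.
#' @param N Number of participants the counts refer to.
#' @param tol Maximum absolute deviation of achieved frequency from
#'   `target_counts / N` (default 0.03).
#' @param max_iter Maximum update iterations (default 200).
#' @param seed Integer seed (Monte Carlo path only).
#' @return The model with adjusted thresholds; achieved marginal
#'   frequencies in `meta$calibration`.
#' @export
calibrate_marginals <- function(model, target_counts, N, tol = 0.03,
                                max_iter = 200, seed = NULL) {
  p <- length(model$labels)
  stopifnot(length(target_counts) == p, all(target_counts > 0),
            all(target_counts < N))
  target <- target_counts / N
  exact <- p <= 12

  with_seed(seed, {
    achieved <- NULL
    for (it in seq_len(max_iter)) {
      achieved <- if (exact) ising_exact_marginals(model) else {
        m <- gibbs_sample(model, n_samples = 600, burn_in = 300, thin = 2)
        pmin(pmax(colMeans(m), 1 / 1200), 1 - 1 / 1200)
      }
      if (max(abs(achieved - target)) <= (if (exact) tol / 3 else tol * 0.8)) break
      # cooperative couplings amplify simultaneous threshold moves, so the
      # step must decay to avoid oscillation
      step <- if (exact) 0.6 / (1 + it / 25) else 0.8 / (1 + it / 40)
      model$thresholds <- model$thresholds +
        step * (qlogis(target) - qlogis(achieved))
    }
    if (!exact) {
      m <- gibbs_sample(model, n_samples = 4000, burn_in = 500, thin = 2)
      achieved <- colMeans(m)
    }
    if (max(abs(achieved - target)) > tol)
      warning("calibration did not reach tolerance ", tol,
              "; worst deviation ",
              format(max(abs(achieved - target)), digits = 3))
    model$meta$calibration <- list(target = target,
                                   achieved = as.numeric(achieved),
                                   iterations = it)
    model
  })
}

#' Expand a binary table back to Likert scores
#'
#' Inverse of [binarize_table()] up to within-category choice: every binary
#' value is replaced by a score drawn uniformly from its preimage under the
#' instrument's binarization rule (respecting reverse-keyed items), so
#' `binarize_table(likert_expand(B))` returns `B` exactly.
#'
#' @param binary Binary response table (data frame or matrix) whose item
#'   columns follow the `"<instrument>: <item>"` label convention.
#' @param specs Named list of [instrument_spec()]s.
#' @param seed Integer seed.
#' @return Table of the same shape with ordinal scores.
#' @export
likert_expand <- function(binary, specs = default_instruments(), seed = NULL) {
  is_df <- is.data.frame(binary)
  tab <- if (is_df) binary else as.data.frame(binary, check.names = FALSE)
  parts <- split_response_table(tab)
  info <- parse_item_labels(parts$item_cols, specs)
  with_seed(seed, {
    for (k in seq_along(parts$item_cols)) {
      cl <- parts$item_cols[k]
      spec <- specs[[info$instrument_id[k]]]
      scores <- spec$scale_min:spec$scale_max
      hi <- scores[scores >= spec$binarize_cut]
      lo <- scores[scores < spec$binarize_cut]
      one <- if (info$item[k] %in% spec$reversed_items) lo else hi
      zero <- setdiff(scores, one)
      v <- tab[[cl]]
      out <- rep(NA_integer_, length(v))
      n1 <- sum(v == 1, na.rm = TRUE); n0 <- sum(v == 0, na.rm = TRUE)
      out[which(v == 1)] <- one[sample.int(length(one), n1, replace = TRUE)]
      out[which(v == 0)] <- zero[sample.int(length(zero), n0, replace = TRUE)]
      tab[[cl]] <- out
    }
    tab
  })
}

#' Planted pre/post change descriptor helpers
#'
#' `apply_network_change()` returns a copy of a model with the listed edge
#' weights replaced (a weight of 0 removes the edge); thresholds are kept.
#' `remove_node_edges()` builds the descriptor that removes every edge
#' incident to one node.
#'
#' @param model An [ising_network()].
#' @param change Data frame with columns `node_a`, `node_b`, `weight`.
#' @return `apply_network_change()`: the changed model;
#'   `remove_node_edges()`: a change descriptor.
#' @export
apply_network_change <- function(model, change) {
  if (is.null(change) || nrow(change) == 0L) return(model)
  stopifnot(all(c("node_a", "node_b", "weight") %in% names(change)))
  W <- model$weights
  for (k in seq_len(nrow(change))) {
    a <- change$node_a[k]; b <- change$node_b[k]
    stopifnot(a %in% model$labels, b %in% model$labels, a != b)
    W[a, b] <- W[b, a] <- change$weight[k]
  }
  ising_network(W, model$thresholds, model$labels,
                meta = c(model$meta, list(planted_change = change)))
}

#' @rdname apply_network_change
#' @param node Node whose incident edges are removed.
#' @export
remove_node_edges <- function(model, node) {
  stopifnot(node %in% model$labels)
  nb <- model$labels[model$weights[node, ] != 0]
  if (!length(nb)) return(data.frame(node_a = character(0),
                                     node_b = character(0),
                                     weight = numeric(0)))
  data.frame(node_a = node, node_b = nb, weight = 0,
             stringsAsFactors = FALSE)
}

#' Paired pre/post dataset with a planted change
#'
#' Samples a pre-time-point dataset from `model_pre` and a post dataset
#' from `model_pre` with `change` applied, independently (no
#' within-participant dependence across time points; see the methods
#' vignette for what this simplification implies).
#'
#' @param model_pre Ground-truth [ising_network()] at the first time point.
#' @param change Change descriptor (see [apply_network_change()]) or `NULL`
#'   for no change.
#' @param N Participants per time point (default 40).
#' @param seed Integer seed.
#' @param burn_in,thin Passed to [gibbs_sample()].
#' @return List `pre`, `post` (binary matrices), `model_pre`, `model_post`.
#' @export
generate_paired_dataset <- function(model_pre, change = NULL, N = 40,
                                    seed = NULL, burn_in = 1000, thin = 10) {
  model_post <- apply_network_change(model_pre, change)
  with_seed(seed, {
    pre <- gibbs_sample(model_pre, N, burn_in = burn_in, thin = thin)
    post <- gibbs_sample(model_post, N, burn_in = burn_in, thin = thin)
    list(pre = pre, post = post, model_pre = model_pre,
         model_post = model_post)
  })
}

#' Simulate a small demonstration study
#'
#' Builds a ground-truth Ising model over a subset of real item labels
#' (mixing ordinary and reverse-keyed items from all four instruments),
#' samples `N` participants at two time points, and expands the binary
#' responses to Likert scores, yielding a raw table in the exact input
#' format of [run_pipeline()]. An optional planted change is applied
#' between time points.
#'
#' @param N Participants per time point (default 40).
#' @param seed Integer seed.
#' @param change Optional change descriptor (see
#'   [apply_network_change()]).
#' @param edge_density,weight_range Passed to [random_ising_model()].
#' @param negative_fraction Fraction of edges given a negative sign
#'   (default 0.25), mirroring the mixed-polarity couplings of real
#'   symptom networks; an all-positive strong model is ferromagnetic and
#'   collapses onto all-present/all-absent response patterns.
#' @return List `likert` (raw response data frame), `binary_pre`,
#'   `binary_post`, `model_pre`, `model_post`.
#' @export
simulate_demo_study <- function(N = 40, seed = 1, change = NULL,
                                edge_density = 0.5,
                                weight_range = c(1.2, 1.8),
                                negative_fraction = 0.25) {
  labels <- c("DASS-21: 11", "DASS-21: 12", "DASS-21: 5", "DASS-21: 9",
              "EQ-short: 7", "EQ-short: 2", "JSE-S: 6",
              "EES: 3", "EES: 12", "EES: 13")
  with_seed(seed, {
    model <- random_ising_model(length(labels), edge_density,
                                weight_range = weight_range,
                                threshold_range = c(-0.5, 0), labels = labels)
    flip <- upper.tri(model$weights) & model$weights != 0 &
      matrix(runif(length(labels)^2) < negative_fraction, length(labels))
    model$weights[flip] <- -model$weights[flip]
    model$weights[lower.tri(model$weights)] <-
      t(model$weights)[lower.tri(model$weights)]
    # keep marginals mid-range so the prevalence filter passes
    model <- calibrate_marginals(model,
                                 target_counts = rep(round(N / 2), length(labels)),
                                 N = N, tol = 0.05)
    ds <- generate_paired_dataset(model, change, N = N)
    lik_pre <- likert_expand(ds$pre)
    lik_post <- likert_expand(ds$post)
    likert <- rbind(
      cbind(data.frame(participant_id = paste0("P", seq_len(N)),
                       time_point = "PRE", stringsAsFactors = FALSE),
            as.data.frame(lik_pre, check.names = FALSE)),
      cbind(data.frame(participant_id = paste0("P", seq_len(N)),
                       time_point = "POST", stringsAsFactors = FALSE),
            as.data.frame(lik_post, check.names = FALSE))
    )
    list(likert = likert, binary_pre = ds$pre, binary_post = ds$post,
         model_pre = ds$model_pre, model_post = ds$model_post)
  })
}
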