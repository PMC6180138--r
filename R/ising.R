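#' Ising network objects
#'
#' An `ising_network` holds a symmetric coupling matrix with zero diagonal
#' (pairwise edge weights \eqn{\beta_{ij}}) and a per-node threshold vector
#' \eqn{\tau_i}, under the \{0,1\} coding in which the conditional model for
#' node \eqn{j} is
#' \deqn{P(x_j = 1 \mid x_{-j}) = \mathrm{logistic}(\tau_j + \sum_i \beta_{ij} x_i).}
#'
#' @param weights Symmetric numeric matrix, zero diagonal.
#' @param thresholds Numeric vector, one per node.
#' @param labels Node labels; default taken from `colnames(weights)`.
#' @param meta List of estimation/generation metadata.
#' @return An object of class `ising_network`.
#' @export
ising_network <- function(weights, thresholds, labels = colnames(weights),
                          meta = list()) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  stopifnot(ncol(weights) == p, length(thresholds) == p, length(labels) == p)
  if (max(abs(weights - t(weights))) > 1e-8) stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal")
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = labels, weights = weights,
                 thresholds = stats::setNames(as.numeric(thresholds), labels),
                 meta = meta),
            class = "ising_network")
}

#' @export
print.ising_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<ising_network> %d nodes, %d edges", length(x$labels), ne))
  if (!is.null(x$meta$rule))
    cat(sprintf(" (eLasso: gamma = %s, %s rule, n = %d)",
                format(x$meta$ebic_gamma), x$meta$rule, x$meta$n_observations))
  cat("\n")
  invisible(x)
}

# Coerce a binary response table (data.frame with optional id columns, or
# matrix) to a 0/1 numeric matrix with column labels.
as_binary_matrix <- function(x) {
  if (is.data.frame(x)) {
    parts <- split_response_table(x)
    x <- as.matrix(parts$items)
  }
  storage.mode(x) <- "numeric"
  if (anyNA(x)) {
    drop <- !stats::complete.cases(x)
    warning(sum(drop), " record(s) with missing values dropped")
    x <- x[!drop, , drop = FALSE]
  }
  if (!all(x %in% c(0, 1))) stop("expected a binary (0/1) response matrix")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

#' l1-penalized logistic regression path
#'
#' Fits the lasso-penalized logistic regression of a binary response on a
#' binary design matrix along a descending lambda path, by iteratively
#' reweighted least squares with cyclic coordinate descent on each quadratic
#' approximation (intercept unpenalized, warm starts along the path,
#' objective tolerance `tol`, at most `maxit` coordinate sweeps per lambda).
#' The default path has `nlambda` log-spaced values from
#' \eqn{\lambda_{max} = \max_j |x_j^T (y - \bar y)| / n} (the smallest value
#' at which all coefficients are zero) down to
#' `lambda_min_ratio * lambda_max`.
#'
#' @param y Binary response vector.
#' @param X Binary design matrix (one column per predictor).
#' @param lambdas Optional descending positive lambda values; overrides
#'   `nlambda`/`lambda_min_ratio`.
#' @param nlambda Path length (default 100).
#' @param lambda_min_ratio Smallest lambda as a fraction of `lambda_max`
#'   (default 0.01).
#' @param tol Convergence tolerance on the penalized objective (default 1e-6).
#' @param maxit Maximum coordinate-descent sweeps per lambda (default 10000).
#' @return Object of class `lasso_path`: `lambdas`, `intercepts`,
#'   `coefficients` (predictors x lambdas), `loglik` (unpenalized, sum
#'   form), `df` (non-zero coefficients), `n`.
#' @export
logistic_lasso_path <- function(y, X, lambdas = NULL, nlambda = 100,
                                lambda_min_ratio = 0.01,
                                tol = 1e-6, maxit = 10000) {
  X <- as.matrix(X)
  storage.mode(X) <- "numeric"
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n, all(y %in% c(0, 1)), all(X %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("degenerate node: response is constant")
  if (is.null(lambdas)) {
    lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
    if (lambda_max <= 0) lambda_max <- 1e-3
    lambdas <- exp(seq(log(lambda_max), log(lambda_min_ratio * lambda_max),
                       length.out = nlambda))
  } else {
    stopifnot(all(lambdas > 0), !is.unsorted(rev(lambdas)))
  }
  fit <- .cd_logistic_path(X, y, lambdas, tol, as.integer(maxit))
  rownames(fit$beta) <- colnames(X)
  structure(list(lambdas = lambdas, intercepts = fit$a0,
                 coefficients = fit$beta, loglik = fit$loglik,
                 df = fit$df, n = n),
            class = "lasso_path")
}

#' Extended BIC model selection along a lasso path
#'
#' Picks the lambda minimizing
#' \deqn{\mathrm{EBIC} = -2\,\ell + k \log n + 2 \gamma k \log(p - 1),}
#' where \eqn{\ell} is the unpenalized log-likelihood, \eqn{k} the number of
#' non-zero coefficients (intercept excluded) and \eqn{p - 1} the number of
#' candidate predictors (all other nodes of a `p`-node network). Ties are
#' broken toward the larger lambda (sparser model).
#'
#' @param path A `lasso_path` from [logistic_lasso_path()].
#' @param n Number of observations.
#' @param p Number of network nodes (so `p - 1` candidate predictors).
#' @param gamma EBIC hyperparameter \eqn{\gamma \ge 0} (default 0.25).
#' @return Index into the path of the selected lambda.
#' @export
ebic_select <- function(path, n, p, gamma = 0.25) {
  stopifnot(inherits(path, "lasso_path"), gamma >= 0, p >= 2)
  k <- path$df
  ebic <- -2 * path$loglik + k * log(n) + 2 * gamma * k * log(p - 1)
  which(ebic <= min(ebic) + 1e-9)[1L]
}

#' Estimate a sparse Ising network by eLasso
#'
#' Runs, for every node, an l1-penalized logistic regression of that node on
#' all others ([logistic_lasso_path()]), selects the penalty by extended BIC
#' ([ebic_select()]), and symmetrizes the directed neighborhood estimates
#' into an undirected coupling matrix. Under the default `"AND"` rule an
#' edge \eqn{i - j} is kept only when both nodewise regressions select it,
#' with weight the arithmetic mean of the two directed coefficients; under
#' `"OR"` one selection suffices and the unselected direction enters the
#' mean as 0. Node thresholds are the selected intercepts.
#'
#' @param binary Binary response table (data frame from [binarize_table()]
#'   restricted to retained items, or a 0/1 matrix). Rows are independent
#'   observations; the estimate is invariant to their order.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule `"AND"` (default) or `"OR"` edge rule.
#' @param nlambda,lambda_min_ratio,tol,maxit Passed to
#'   [logistic_lasso_path()].
#' @return An [ising_network()] with estimation metadata in `meta`
#'   (including the directed coefficient matrix `meta$directed`, with
#'   `directed[i, j]` the effect of node i in the regression of node j).
#' @export
fit_ising <- function(binary, gamma = 0.25, rule = c("AND", "OR"),
                      nlambda = 100, lambda_min_ratio = 0.01,
                      tol = 1e-6, maxit = 10000) {
  rule <- match.arg(rule)
  m <- as_binary_matrix(binary)
  p <- ncol(m)
  n <- nrow(m)
  if (p < 2L) stop("need at least 2 nodes")
  labels <- colnames(m)
  const <- which(apply(m, 2, function(v) length(unique(v)) < 2L))
  if (length(const))
    stop("degenerate node(s) with constant responses: ",
         paste(labels[const], collapse = ", "))

  directed <- matrix(0, p, p, dimnames = list(labels, labels))
  tau <- numeric(p)
  for (j in seq_len(p)) {
    path <- logistic_lasso_path(m[, j], m[, -j, drop = FALSE],
                                nlambda = nlambda,
                                lambda_min_ratio = lambda_min_ratio,
                                tol = tol, maxit = maxit)
    sel <- ebic_select(path, n = n, p = p, gamma = gamma)
    directed[-j, j] <- path$coefficients[, sel]
    tau[j] <- path$intercepts[sel]
  }
  if (max(abs(directed)) > 10)
    warning("selected coefficient(s) exceed 10 in absolute value; ",
            "near-separation likely")

  both <- (directed != 0) & (t(directed) != 0)
  avg <- (directed + t(directed)) / 2
  weights <- if (rule == "AND") ifelse(both, avg, 0) else avg
  ising_network(weights, tau, labels,
                meta = list(n_observations = n, ebic_gamma = gamma,
                            rule = rule,
                            lambda_path = list(nlambda = nlambda,
                                               min_ratio = lambda_min_ratio),
                            directed = directed))
}

#' Absolute-value transform of a network
#'
#' Replaces every edge weight by its absolute value, as required before the
#' distance-based graph analyses; thresholds are untouched. The signed
#' weights are retained in `meta$signed_weights` so edge polarity can still
#' be reported.
#'
#' @param net An [ising_network()].
#' @return The transformed `ising_network`.
#' @export
to_absolute_network <- function(net) {
  stopifnot(inherits(net, "ising_network"))
  meta <- net$meta
  if (is.null(meta$signed_weights)) meta$signed_weights <- net$weights
  meta$absolute <- TRUE
  ising_network(abs(net$weights), net$thresholds, net$labels, meta)
}
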