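test_that("full shrinkage at lambda_max leaves only the intercept", {
  set.seed(1)
  n <- 100
  X <- matrix(rbinom(n * 4, 1, 0.5), n)
  y <- rbinom(n, 1, 0.6)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  path <- logistic_lasso_path(y, X, lambdas = c(lambda_max * 1.01, lambda_max * 0.9))
  expect_equal(sum(path$coefficients[, 1] != 0), 0)
  expect_equal(path$intercepts[1], qlogis(mean(y)), tolerance = 1e-6)
  expect_error(logistic_lasso_path(rep(1, n), X), "degenerate")
})

test_that("coordinate descent reaches the penalized optimum (objective oracles)", {
  set.seed(2)
  n <- 30
  X <- matrix(rbinom(n * 3, 1, 0.5), n)
  y <- rbinom(n, 1, plogis(-0.3 + X[, 1]))
  path <- logistic_lasso_path(y, X, nlambda = 8, lambda_min_ratio = 0.05)
  for (l in c(1, 4, 8)) {
    ours <- penalized_objective(path$intercepts[l], path$coefficients[, l],
                                y, X, path$lambdas[l])
    orac <- oracle_lasso_fit(y, X, path$lambdas[l])
    expect_lt(abs(ours - orac$objective), 1e-5)
  }
})

test_that("solution path agrees with an independent lasso implementation", {
  set.seed(3)
  n <- 150
  X <- matrix(rbinom(n * 6, 1, 0.5), n)
  y <- rbinom(n, 1, plogis(-0.5 + X[, 2] - 0.8 * X[, 5]))
  path <- logistic_lasso_path(y, X, nlambda = 40)
  g <- glmnet::glmnet(X, y, family = "binomial", lambda = path$lambdas,
                      standardize = FALSE, thresh = 1e-12)
  expect_lt(max(abs(as.matrix(g$beta) - path$coefficients)), 1e-4)
  expect_lt(max(abs(g$a0 - path$intercepts)), 1e-4)
})

test_that("EBIC selection minimizes the criterion with sparse tie-breaking", {
  # two fits with equal log-likelihood, k = 1 vs k = 2, n = 40, p = 24:
  # the sparser model wins by exactly log(40) + 0.5 * log(23)
  fake <- structure(list(lambdas = c(0.2, 0.1), intercepts = c(0, 0),
                         coefficients = matrix(0, 3, 2),
                         loglik = c(-20, -20), df = c(1L, 2L), n = 40),
                    class = "lasso_path")
  gamma <- 0.25
  ebic <- -2 * fake$loglik + fake$df * log(40) + 2 * gamma * fake$df * log(23)
  expect_equal(ebic[2] - ebic[1], log(40) + 0.5 * log(23))
  expect_equal(ebic_select(fake, 40, 24, gamma), 1L)
  # exact ties break toward the larger lambda
  fake$df <- c(1L, 1L)
  expect_equal(ebic_select(fake, 40, 24, gamma), 1L)

  # random path: selection equals brute-force evaluation
  set.seed(4)
  n <- 120
  X <- matrix(rbinom(n * 5, 1, 0.5), n)
  y <- rbinom(n, 1, plogis(-0.2 + 0.8 * X[, 1]))
  path <- logistic_lasso_path(y, X, nlambda = 30)
  for (gamma in c(0, 0.25, 0.5)) {
    ebic <- -2 * path$loglik + path$df * log(n) + 2 * gamma * path$df * log(5)
    expect_equal(path$lambdas[ebic_select(path, n, 6, gamma)],
                 path$lambdas[which.min(ebic)])
  }
})

test_that("independent nodes yield an (almost) empty network", {
  set.seed(5)
  m <- matrix(rbinom(500 * 4, 1, 0.5), 500, 4,
              dimnames = list(NULL, paste0("V", 1:4)))
  net <- fit_ising(m)
  expect_lte(sum(net$weights[upper.tri(net$weights)] != 0), 1)
})

test_that("a strongly dependent pair is recovered as a single positive edge", {
  set.seed(6)
  x1 <- rbinom(500, 1, 0.5)
  flip <- rbinom(500, 1, 0.05)
  m <- cbind(V1 = x1, V2 = ifelse(flip == 1, 1 - x1, x1))
  net <- fit_ising(m)
  expect_gt(net$weights["V1", "V2"], 0)
  expect_equal(sum(net$weights != 0), 2)  # the one symmetric edge
})

test_that("AND-rule edges are a subset of OR-rule edges", {
  set.seed(7)
  model <- chain_model(beta = 0.8)
  for (rep in 1:5) {
    m <- gibbs_sample(model, 150, burn_in = 200, thin = 2)
    a <- fit_ising(m, rule = "AND", nlambda = 30)
    o <- fit_ising(m, rule = "OR", nlambda = 30)
    expect_true(all(o$weights[a$weights != 0] != 0))
  }
})

test_that("the estimate is invariant to participant (row) order", {
  set.seed(8)
  m <- gibbs_sample(chain_model(), 200, burn_in = 200, thin = 2)
  net1 <- fit_ising(m, nlambda = 30)
  net2 <- fit_ising(m[sample(nrow(m)), ], nlambda = 30)
  expect_equal(net1$weights, net2$weights)
  expect_equal(net1$thresholds, net2$thresholds)
})

test_that("larger EBIC gamma never yields a denser network", {
  set.seed(9)
  model <- chain_model(beta = 0.8, p = 5)
  for (rep in 1:20) {
    m <- gibbs_sample(model, 80, burn_in = 200, thin = 2)
    if (any(colSums(m) %in% c(0, nrow(m)))) next
    e0 <- sum(fit_ising(m, gamma = 0, nlambda = 30)$weights != 0)
    e5 <- sum(fit_ising(m, gamma = 0.5, nlambda = 30)$weights != 0)
    expect_lte(e5, e0)
  }
})

test_that("edge-weight recovery on the true support improves with sample size", {
  model <- chain_model()
  truth <- model$weights[upper.tri(model$weights)]
  support <- truth != 0
  cors <- vapply(c(100, 500, 2000), function(n) {
    r <- vapply(1:3, function(s) {
      m <- gibbs_sample(model, n, burn_in = 500, thin = 2, seed = 100 * n + s)
      est <- fit_ising(m, nlambda = 30)$weights[upper.tri(model$weights)]
      sqrt(mean((est[support] - truth[support])^2))  # rmse on true support
    }, 0)
    mean(r)
  }, 0)
  expect_true(cors[3] < cors[1])  # error shrinks from n = 100 to n = 2000
  expect_true(cors[2] < cors[1] * 1.2)
})

test_that("absolute-value transform keeps structure and signed weights", {
  W <- matrix(c(0, 0.5, -0.3, 0.5, 0, 0, -0.3, 0, 0), 3, 3)
  net <- ising_network(W, c(0.1, -0.2, 0), paste0("V", 1:3))
  a <- to_absolute_network(net)
  expect_equal(unname(a$weights), abs(W))
  expect_equal(a$thresholds, net$thresholds)
  expect_equal(a$meta$signed_weights, net$weights)
  # all-positive network unchanged; random matrix equals elementwise |.|
  set.seed(10)
  Wr <- random_weight_matrix(6, 0.5) * sample(c(-1, 1), 36, replace = TRUE)
  Wr <- (Wr + t(Wr)) / 2; diag(Wr) <- 0
  netr <- ising_network(Wr, rep(0, 6))
  expect_equal(unname(to_absolute_network(netr)$weights), unname(abs(Wr)))
})
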