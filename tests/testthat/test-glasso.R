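test_that("lambda at or above the max off-diagonal yields an exactly empty network", {
  for (seed in 1:5) {
    S <- random_corr(6, seed)
    lmax <- max(abs(S[upper.tri(S)]))
    theta <- glasso_solve(S, lmax)
    off <- theta; diag(off) <- 0
    expect_identical(max(abs(off)), 0)
    W <- partial_correlations(theta)
    expect_true(all(W == 0))
  }
})

test_that("the unpenalized solution matches direct matrix inversion", {
  for (seed in c(3, 14)) {
    S <- random_corr(5, seed)
    theta <- glasso_solve(S, 0, tol = 1e-9)
    expect_lt(max(abs(theta - solve(S))), 1e-6)
  }
})

test_that("a chain dependence structure is recovered with the middle link only", {
  # x1 - x2 - x3: the (1,3) partial is zero, the chain partials are not
  P <- diag(3)
  P[1, 2] <- P[2, 1] <- -0.4
  P[2, 3] <- P[3, 2] <- -0.4
  S <- stats::cov2cor(solve(P))
  theta <- glasso_solve(S, 0.02)
  expect_identical(theta[1, 3], 0)
  expect_true(theta[1, 2] != 0 && theta[2, 3] != 0)
})

test_that("penalized optima agree with an independent proximal-gradient solver", {
  for (case in list(list(p = 3, seed = 5, lambda = 0.1),
                    list(p = 4, seed = 9, lambda = 0.05),
                    list(p = 4, seed = 9, lambda = 0.3))) {
    S <- random_corr(case$p, case$seed)
    theta <- glasso_solve(S, case$lambda, tol = 1e-8)
    ref <- ista_glasso(S, case$lambda)
    expect_lt(max(abs(theta - ref)), 1e-4)
  }
})

test_that("partial correlations follow the precision-matrix identity", {
  theta <- diag(c(2, 3, 4))
  expect_true(all(partial_correlations(theta) == 0))
  theta2 <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_equal(partial_correlations(theta2)[1, 2], 0.5)
  # positive precision entries map to negative partials
  theta3 <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_lt(partial_correlations(theta3)[1, 2], 0)
  expect_error(partial_correlations(matrix(c(-1, 0, 0, 1), 2)), "definite")
})

test_that("EBIC follows the penalized-likelihood form", {
  p <- 5; n <- 1952
  expect_equal(ebic(diag(p), diag(p), n, 0.5),
               ebic(diag(p), diag(p), n, 0.9))  # E = 0: gamma irrelevant
  S <- random_corr(p, 4)
  theta <- glasso_solve(S, 0.1)
  E <- sum(abs(theta[upper.tri(theta)]) > 0)
  # gamma term separates additively
  expect_equal(ebic(theta, S, n, 0.5) - ebic(theta, S, n, 0),
               4 * 0.5 * E * log(p))
  # one extra edge with negligible likelihood change costs log n + 4*g*log p
  theta2 <- theta
  free <- which(theta == 0 & upper.tri(theta), arr.ind = TRUE)[1, ]
  theta2[free[1], free[2]] <- theta2[free[2], free[1]] <- 1e-8
  expect_equal(ebic(theta2, S, n, 0.5) - ebic(theta, S, n, 0.5),
               log(n) + 4 * 0.5 * log(p), tolerance = 1e-3)
})

test_that("the lambda grid is log-spaced from lambda_max down", {
  S <- random_corr(6, 11)
  g <- lambda_grid(S, 50, 0.01)
  expect_length(g, 50)
  expect_equal(g[1], max(abs(S[upper.tri(S)])))
  expect_equal(g[50], g[1] * 0.01)
  ratios <- g[-1] / g[-50]
  expect_lt(diff(range(ratios)), 1e-12)
  expect_warning(g0 <- lambda_grid(diag(3), 10, 0.01), "degenerate")
  expect_identical(g0, 0)
})

test_that("edge count grows monotonically as the penalty relaxes", {
  X <- sample_ordinal(make_ground_truth(), n = 400, seed = 31)
  S <- nearest_psd(spearman_matrix(X))
  lambdas <- lambda_grid(S, 30)
  thetas <- symptomnet:::fit_path(S, lambdas, 1e-6, 500L)
  counts <- vapply(thetas, function(t) sum(abs(t[upper.tri(t)]) > 0),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("network selection is deterministic and returns an aligned path", {
  X <- sample_ordinal(make_ground_truth(), n = 500, seed = 17)
  fit1 <- select_network(X, selection_config(mode = "cv_ebic", n_folds = 5))
  fit2 <- select_network(X, selection_config(mode = "cv_ebic", n_folds = 5))
  expect_identical(fit1$model$weights, fit2$model$weights)
  expect_identical(fit1$model$lambda_used, fit2$model$lambda_used)
  expect_length(fit1$path$ebic, length(fit1$path$lambda_grid))
  expect_equal(fit1$path$lambda_grid[fit1$path$selected_index],
               fit1$model$lambda_used)
  W <- fit1$model$weights
  expect_identical(W, t(W))
  expect_true(all(diag(W) == 0))
  expect_true(all(abs(W) < 1))
})

test_that("tiny folds are rejected with advice", {
  X <- random_items(60, 2)
  expect_error(select_network(X, selection_config(mode = "cv_ebic",
                                                  n_folds = 10)), "folds")
})

test_that("gamma sensitivity reports consistent, comparable models", {
  X <- sample_ordinal(make_ground_truth(), n = 600, seed = 23)
  one <- gamma_sensitivity(X, gammas = 0.5, config = fast_estimator)
  expect_length(one$models, 1)
  expect_equal(nrow(one$comparisons), 0)
  sens <- gamma_sensitivity(X, gammas = c(0.1, 0.5, 0.9),
                            config = fast_estimator)
  expect_true(all(diff(unname(sens$edge_counts)) <= 0))
  expect_true(all(sens$comparisons$jaccard >= 0 &
                    sens$comparisons$jaccard <= 1))
})

test_that("cross-community edge extraction filters and orders by weight", {
  W <- matrix(0, 4, 4, dimnames = list(c("A1", "A2", "B1", "B2"),
                                       c("A1", "A2", "B1", "B2")))
  comm <- c(A1 = "anxiety", A2 = "anxiety",
            B1 = "depression", B2 = "depression")
  W["A1", "A2"] <- W["A2", "A1"] <- 0.5   # within
  model <- toy_model(W, comm)
  expect_equal(nrow(cross_community_edges(model)), 0)
  W["A1", "B1"] <- W["B1", "A1"] <- 0.2
  W["A2", "B2"] <- W["B2", "A2"] <- -0.3
  model <- toy_model(W, comm)
  ce <- cross_community_edges(model)
  expect_equal(nrow(ce), 2)
  expect_equal(ce$weight[1], -0.3)  # sorted by |weight| descending
  expect_equal(ce$node_a[2], "A1")
})
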