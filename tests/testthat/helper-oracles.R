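# Independent proximal-gradient (ISTA) solver for the penalized Gaussian
# log-likelihood max log det(Theta) - tr(S Theta) - lambda * sum_{i!=j}|theta_ij|.
# Deliberately a different algorithm from the package's block coordinate
# descent; usable as an oracle at small p.
ista_glasso <- function(S, lambda, step = 0.005, max_iter = 200000,
                        tol = 1e-10) {
  p <- nrow(S)
  theta <- diag(p)
  for (it in seq_len(max_iter)) {
    G <- solve(theta) - S
    tn <- theta + step * G
    off <- tn; diag(off) <- 0
    off <- sign(off) * pmax(abs(off) - step * lambda, 0)
    tn <- off + diag(diag(tn))
    tn <- (tn + t(tn)) / 2
    if (max(abs(tn - theta)) < tol) { theta <- tn; break }
    theta <- tn
  }
  theta
}

# random correlation-like PD matrix with unit diagonal
random_corr <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) + p * diag(p)
  stats::cov2cor(S)
}

# complete ordinal item matrix with random independent columns
random_items <- function(n, seed, p = 17) {
  set.seed(seed)
  X <- matrix(sample(0:3, n * p, replace = TRUE), n, p,
              dimnames = list(NULL, node_labels()[seq_len(p)]))
  attr(X, "communities") <- node_communities()[seq_len(p)]
  class(X) <- c("item_matrix", class(X))
  X
}

# roster of n fully complete living-alone records
complete_roster <- function(n, seed = 1) {
  inject_missingness(random_items(n, seed), c(0L, 0L, 0L), seed = seed)
}

# small toy network model from an explicit weight matrix
toy_model <- function(W, communities = NULL) {
  p <- nrow(W)
  labels <- colnames(W)
  if (is.null(labels)) labels <- paste0("N", seq_len(p))
  dimnames(W) <- list(labels, labels)
  if (is.null(communities))
    communities <- stats::setNames(rep("all", p), labels)
  symptomnet:::new_network_model(W, labels, communities,
                                 lambda = 0.1, gamma = 0.5)
}

fast_estimator <- selection_config(mode = "direct_ebic", n_lambda = 25L)
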