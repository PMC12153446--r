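#' Default cross-community bridge specification
#'
#' Four strong anxiety-depression bridges with target partial correlations
#' 0.34, 0.28, 0.13 and 0.12, mirroring the dominant cross-community links
#' reported for this symptom network (nervousness--sleep disturbance,
#' excessive worry--everything an effort, trouble relaxing--loneliness,
#' irritability--feeling blue).
#'
#' @return Data frame with columns `node_a`, `node_b`, `weight`.
#' @export
default_bridge_spec <- function() {
  data.frame(node_a = c("GAD1", "GAD3", "GAD4", "GAD6"),
             node_b = c("CESD10", "CESD4", "CESD8", "CESD3"),
             weight = c(0.34, 0.28, 0.13, 0.12),
             stringsAsFactors = FALSE)
}

#' Planted sparse partial-correlation network
#'
#' Builds a ground-truth Gaussian graphical model with two item communities
#' (anxiety, depression). Within each community the nodes are linked in a
#' positive chain (weight `chain_weight`), plus random extra within-community
#' edges at density `within_density` (weight `extra_weight`); the requested
#' cross-community bridges are planted on top. The partial-correlation
#' matrix is converted to a precision matrix with unit diagonal, whose
#' implied partial correlations then equal the planted weights exactly; the
#' construction errors if the requested weights do not admit a positive
#' definite precision matrix, and verifies the implied partials are within
#' 0.02 of the targets.
#'
#' @param p_anx,p_dep Community sizes (defaults 7 and 10).
#' @param within_density Probability of an extra (non-chain) within-community
#'   edge (default 0.1).
#' @param bridge_spec Data frame of cross-community edges
#'   (default [default_bridge_spec()]).
#' @param seed Seed for the random extra edges (default 20170101).
#' @param chain_weight,extra_weight Within-community partial correlations
#'   (defaults 0.3 and 0.1).
#' @return A `ground_truth_network`: `precision`, `partials`, `communities`,
#'   `bridge_edges`, `node_labels`.
#' @export
make_ground_truth <- function(p_anx = 7L, p_dep = 10L, within_density = 0.1,
                              bridge_spec = default_bridge_spec(),
                              seed = 20170101L, chain_weight = 0.3,
                              extra_weight = 0.1) {
  p <- p_anx + p_dep
  labels <- c(paste0("GAD", seq_len(p_anx)), paste0("CESD", seq_len(p_dep)))
  communities <- setNames(c(rep("anxiety", p_anx), rep("depression", p_dep)),
                          labels)
  P <- matrix(0, p, p, dimnames = list(labels, labels))
  chain <- function(idx) {
    for (k in seq_len(length(idx) - 1)) {
      P[idx[k], idx[k + 1]] <<- chain_weight
      P[idx[k + 1], idx[k]] <<- chain_weight
    }
  }
  anx <- seq_len(p_anx); dep <- p_anx + seq_len(p_dep)
  chain(anx); chain(dep)
  set.seed(seed)
  for (idx in list(anx, dep)) {
    pairs <- utils::combn(idx, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      if (abs(a - b) > 1 && P[a, b] == 0 && stats::runif(1) < within_density) {
        P[a, b] <- extra_weight; P[b, a] <- extra_weight
      }
    }
  }
  if (nrow(bridge_spec)) {
    for (j in seq_len(nrow(bridge_spec))) {
      a <- bridge_spec$node_a[j]; b <- bridge_spec$node_b[j]
      if (!(a %in% labels) || !(b %in% labels))
        stop("bridge_spec names unknown node(s): ", a, ", ", b)
      if (communities[a] == communities[b])
        stop("bridge edge ", a, "--", b, " does not cross communities")
      P[a, b] <- bridge_spec$weight[j]; P[b, a] <- bridge_spec$weight[j]
    }
  }
  theta <- diag(p) - P
  dimnames(theta) <- dimnames(P)
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    stop("requested weights do not yield a positive definite precision ",
         "matrix (min eigenvalue ", signif(min(ev), 3),
         "); reduce edge weights or density")
  implied <- partial_correlations(theta)
  if (max(abs(implied - P)) > 0.02)
    stop("implied partial correlations deviate from targets by more than 0.02")
  structure(list(precision = theta, partials = implied,
                 communities = communities,
                 bridge_edges = bridge_spec, node_labels = labels),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  ne <- sum(x$partials[upper.tri(x$partials)] != 0)
  cat(sprintf("Planted ground-truth network: %d nodes, %d edges, %d bridges\n",
              nrow(x$precision), ne, nrow(x$bridge_edges)))
  invisible(x)
}

#' Default ordinal thresholds matching right-skewed item marginals
#'
#' Latent-scale cut points for each of the 17 items, chosen so the implied
#' item means span roughly 0.15-1.9 on the 0-3 scale: anxiety items are
#' strongly right-skewed (most respondents endorse 0), depression items
#' less so. Category probabilities follow a geometric-ratio family
#' `p_k proportional to r^k`, with `r` solved per item from its target mean;
#' cut points are the normal quantiles of the cumulative probabilities.
#'
#' @param target_means Per-item target means on the 0-3 scale; the default
#'   uses the canonical 17-item profile (GAD items 0.15-0.34, CES-D items
#'   0.79-1.90).
#' @return Matrix (p x 3) of increasing latent cut points, rownames the
#'   node labels, with a `target_means` attribute.
#' @export
default_thresholds <- function(target_means = c(
  GAD1 = 0.34, GAD2 = 0.25, GAD3 = 0.29, GAD4 = 0.20, GAD5 = 0.17,
  GAD6 = 0.17, GAD7 = 0.15,
  CESD1 = 1.05, CESD2 = 1.47, CESD3 = 1.03, CESD4 = 1.63, CESD5 = 1.63,
  CESD6 = 0.89, CESD7 = 1.90, CESD8 = 1.41, CESD9 = 0.79, CESD10 = 1.47)) {
  stopifnot(all(target_means > 0), all(target_means < 3))
  cuts <- t(vapply(target_means, function(m) {
    mean_of_r <- function(r) {
      w <- r^(0:3); sum((0:3) * w) / sum(w)
    }
    r <- stats::uniroot(function(r) mean_of_r(r) - m,
                        interval = c(1e-6, 1e6), tol = 1e-12)$root
    pk <- r^(0:3) / sum(r^(0:3))
    stats::qnorm(cumsum(pk)[1:3])
  }, numeric(3)))
  colnames(cuts) <- paste0("cut", 1:3)
  attr(cuts, "target_means") <- target_means
  cuts
}

#' Sample ordinal item responses from a planted network
#'
#' Latent-Gaussian copula discretization: draws latent multivariate-normal
#' vectors with correlation matrix equal to the standardized inverse of the
#' planted precision matrix, then cuts each coordinate into \{0,1,2,3\} at
#' its item thresholds.
#'
#' @param truth A `ground_truth_network`.
#' @param thresholds Cut-point matrix (default [default_thresholds()]).
#' @param n Number of respondents.
#' @param seed Random seed.
#' @return An `item_matrix` (n x p) of ordinal responses, with the truth's
#'   community attribute.
#' @export
sample_ordinal <- function(truth, thresholds = default_thresholds(), n,
                           seed = 20170101L) {
  p <- nrow(truth$precision)
  stopifnot(nrow(thresholds) == p)
  sigma <- stats::cov2cor(solve(truth$precision))
  L <- chol(sigma)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% L
  X <- matrix(0L, n, p, dimnames = list(NULL, truth$node_labels))
  for (j in seq_len(p))
    X[, j] <- as.integer(findInterval(Z[, j], thresholds[j, ]))
  attr(X, "communities") <- truth$communities
  class(X) <- c("item_matrix", class(X))
  X
}

#' Build a raw roster fixture with controlled screening failures
#'
#' Wraps complete item responses in roster form (ids, demographics, living
#' arrangement) and then degrades exactly the configured number of records
#' at each screening stage: stage-1 records lose age or sex, or more than a
#' third of their items; stage-2 records lose one GAD-7 item; stage-3
#' records lose one CES-D item. Placement is deterministic under the seed,
#' so the staged exclusion counts are exact by construction.
#'
#' @param data Complete `item_matrix` (n x 17).
#' @param stage_counts Integer vector of length 3: records to fail at each
#'   stage (default `c(0, 0, 0)`).
#' @param seed Seed controlling demographics and placement.
#' @return A `participant_roster` data frame of all n records, all coded as
#'   living alone.
#' @export
inject_missingness <- function(data, stage_counts = c(0L, 0L, 0L),
                               seed = 20170101L) {
  n <- nrow(data)
  stage_counts <- as.integer(stage_counts)
  stopifnot(length(stage_counts) == 3, all(stage_counts >= 0))
  if (sum(stage_counts) > n)
    stop("requested stage counts (", sum(stage_counts),
         ") exceed the number of records (", n, ")")
  set.seed(seed)
  roster <- data.frame(id = sprintf("P%05d", seq_len(n)),
                       age = sample(65:105, n, replace = TRUE),
                       sex = sample(c("male", "female"), n, replace = TRUE,
                                    prob = c(0.38, 0.62)),
                       residence = sample(c("city", "town", "rural"), n,
                                          replace = TRUE,
                                          prob = c(0.18, 0.34, 0.48)),
                       living = 2L, stringsAsFactors = FALSE)
  items <- as.data.frame(unclass(data))
  names(items) <- ALL_ITEMS
  roster <- cbind(roster, items)

  marked <- sample.int(n, sum(stage_counts))
  s1 <- marked[seq_len(stage_counts[1])]
  s2 <- marked[stage_counts[1] + seq_len(stage_counts[2])]
  s3 <- marked[stage_counts[1] + stage_counts[2] + seq_len(stage_counts[3])]
  for (i in s1) {
    if (stats::runif(1) < 0.5) roster$age[i] <- NA
    else roster[i, sample(ALL_ITEMS, 6L)] <- NA  # 6/17 > 1/3
  }
  for (i in s2) roster[i, sample(GAD_ITEMS, 1L)] <- NA
  for (i in s3) roster[i, sample(CESD_ITEMS, 1L)] <- NA
  class(roster) <- c("participant_roster", "data.frame")
  roster
}

#' Edge-recovery metrics of an estimated network against the planted truth
#'
#' @param truth A `ground_truth_network`.
#' @param model An estimated `network_model` on the same node set.
#' @param min_weight Only true edges with `|partial| >= min_weight` count
#'   toward the true-positive rate (default 0, i.e. all true edges).
#' @return A list: `tpr` (share of qualifying true edges recovered), `fpr`
#'   (share of true non-edges estimated nonzero), `sign_agreement` (among
#'   recovered true edges), `weight_cor` (Pearson correlation of estimated
#'   vs true partials over the union support), and `bridge_top_match`
#'   (named logical: per community, is the top-BEI node the planted
#'   dominant bridge carrier?).
#' @export
recovery_metrics <- function(truth, model, min_weight = 0) {
  stopifnot(identical(truth$node_labels, model$node_labels))
  Wt <- truth$partials; We <- model$weights
  ut <- upper.tri(Wt)
  true_nz <- Wt != 0 & ut
  est_nz <- We != 0 & ut
  qualifying <- true_nz & abs(Wt) >= min_weight
  tpr <- if (sum(qualifying)) sum(est_nz[qualifying]) / sum(qualifying) else NA_real_
  nonedges <- !true_nz & ut
  fpr <- if (sum(nonedges)) sum(est_nz[nonedges]) / sum(nonedges) else NA_real_
  both <- true_nz & est_nz
  sign_agreement <- if (sum(both))
    mean(sign(Wt[both]) == sign(We[both])) else NA_real_
  support <- (true_nz | est_nz)
  weight_cor <- if (sum(support) >= 2 && stats::sd(We[support]) > 0)
    stats::cor(Wt[support], We[support]) else NA_real_

  # planted dominant bridge carrier per community: node with the largest
  # signed cross-community sum in the true partials
  truth_model <- new_network_model(Wt, truth$node_labels, truth$communities,
                                   lambda = 0, gamma = NA_real_)
  bei_true <- bridge_expected_influence(truth_model)
  bei_est <- suppressWarnings(bridge_expected_influence(model))
  comm <- truth$communities
  bridge_top_match <- vapply(unique(comm), function(g) {
    sel <- comm == g
    names(which.max(bei_true[sel])) == names(which.max(bei_est[sel]))
  }, logical(1))
  list(tpr = tpr, fpr = fpr, sign_agreement = sign_agreement,
       weight_cor = weight_cor, bridge_top_match = bridge_top_match)
}
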