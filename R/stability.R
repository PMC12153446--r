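#' Bootstrap configuration
#'
#' @param n_boot Bootstrap iterations (default 1000). In the case-dropping
#'   bootstrap this many draws are taken at every drop proportion.
#' @param seed Seed for all resampling (default 20170101).
#' @param ci_level Confidence level for edge intervals (default 0.95).
#' @param drop_proportions Case-dropping grid (default 0.10 to 0.75 by 0.05).
#' @param cs_correlation Correlation threshold in the CS coefficient
#'   (default 0.7).
#' @param cs_probability Required probability of exceeding the threshold
#'   (default 0.95).
#' @return A `boot_config` list.
#' @export
boot_config <- function(n_boot = 1000L, seed = 20170101L, ci_level = 0.95,
                        drop_proportions = seq(0.10, 0.75, by = 0.05),
                        cs_correlation = 0.7, cs_probability = 0.95) {
  stopifnot(n_boot >= 1, ci_level > 0, ci_level < 1,
            all(drop_proportions > 0), all(drop_proportions < 1),
            !is.unsorted(drop_proportions))
  structure(list(n_boot = as.integer(n_boot), seed = as.integer(seed),
                 ci_level = ci_level, drop_proportions = drop_proportions,
                 cs_correlation = cs_correlation,
                 cs_probability = cs_probability),
            class = "boot_config")
}

pair_index <- function(labels) {
  p <- length(labels)
  ut <- which(upper.tri(diag(p)), arr.ind = TRUE)
  data.frame(i = ut[, 1], j = ut[, 2],
             node_a = labels[ut[, 1]], node_b = labels[ut[, 2]],
             stringsAsFactors = FALSE)
}

estimate_once <- function(m, communities, estimator) {
  x <- m
  attr(x, "communities") <- communities
  select_network(x, estimator)$model
}

# Draw resample index sets up front (so the estimator's internal seeding
# cannot disturb the resampling stream); redraw any resample that produces
# a zero-variance column.
draw_resamples <- function(m, n_boot, replace = TRUE, size = nrow(m)) {
  n <- nrow(m)
  out <- vector("list", n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, size, replace = replace)
      v <- matrixStats_colVars(m[idx, , drop = FALSE])
      if (all(v > 0)) break
      redraws <- redraws + 1L
      if (redraws > 100L * n_boot)
        stop("could not draw resamples with nonzero column variances")
    }
    out[[b]] <- idx
  }
  attr(out, "redraws") <- redraws
  out
}

matrixStats_colVars <- function(x) apply(x, 2, stats::var)

#' Nonparametric bootstrap of edge weights (and centralities)
#'
#' For each of `n_boot` iterations, resamples the rows with replacement,
#' re-estimates the whole network (regularization re-selected inside every
#' resample), and collects the edge weights and node centralities. Edge
#' confidence intervals are empirical percentile intervals at `ci_level`.
#'
#' @param data An `item_matrix` of screened responses.
#' @param estimator A [selection_config()] describing the estimator to
#'   bootstrap.
#' @param config A [boot_config()].
#' @return An `edge_boot` object: `edges` (data frame with point estimate,
#'   bootstrap mean, lower, upper per node pair), draw matrices
#'   (`edge_draws`, `ei_draws`, `bei_draws`), the full-sample `model`, and
#'   the number of redrawn resamples.
#' @export
bootstrap_edges <- function(data, estimator = selection_config(),
                            config = boot_config()) {
  m <- unclass(data); attr(m, "communities") <- NULL
  storage.mode(m) <- "double"
  communities <- attr(data, "communities")
  labels <- colnames(m)
  full <- estimate_once(m, communities, estimator)
  pairs <- pair_index(full$node_labels)

  set.seed(config$seed)
  resamples <- draw_resamples(m, config$n_boot, replace = TRUE)

  K <- nrow(pairs); p <- ncol(m)
  edge_draws <- matrix(NA_real_, config$n_boot, K)
  ei_draws <- matrix(NA_real_, config$n_boot, p,
                     dimnames = list(NULL, full$node_labels))
  bei_draws <- ei_draws
  for (b in seq_len(config$n_boot)) {
    mod <- estimate_once(m[resamples[[b]], , drop = FALSE], communities,
                         estimator)
    W <- mod$weights
    edge_draws[b, ] <- W[cbind(pairs$i, pairs$j)]
    ei_draws[b, ] <- expected_influence(mod)
    bei_draws[b, ] <- suppressWarnings(bridge_expected_influence(mod))
  }
  alpha <- (1 - config$ci_level) / 2
  qs <- apply(edge_draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  edges <- data.frame(pairs[, c("node_a", "node_b")],
                      estimate = full$weights[cbind(pairs$i, pairs$j)],
                      boot_mean = colMeans(edge_draws),
                      lower = qs[1, ], upper = qs[2, ],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, edge_draws = edge_draws,
                 ei_draws = ei_draws, bei_draws = bei_draws,
                 model = full, config = config,
                 n_redrawn = attr(resamples, "redraws")),
            class = "edge_boot")
}

#' @export
print.edge_boot <- function(x, ...) {
  cat(sprintf("Edge-weight bootstrap: %d iterations, %.0f%% percentile CIs\n",
              x$config$n_boot, 100 * x$config$ci_level))
  nz <- x$edges[x$edges$estimate != 0, ]
  cat(sprintf("  %d nonzero edges; mean CI width %.3f\n", nrow(nz),
              mean(nz$upper - nz$lower)))
  invisible(x)
}

#' Case-dropping subset bootstrap and CS coefficient
#'
#' For each drop proportion `d`, repeatedly re-estimates the network on a
#' random `(1-d)`-fraction of the rows (without replacement) and correlates
#' the subset centralities with the full-sample centralities. The CS
#' coefficient for an index is the largest `d` at which the correlation is
#' at least `cs_correlation` with probability at least `cs_probability`
#' (0 if no grid value qualifies). Values below 0.25 are conventionally
#' considered inadequate and values above 0.50 robust; the result annotates
#' both thresholds without enforcing them.
#'
#' @inheritParams bootstrap_edges
#' @return A `cs_result`: `cs` (named vector, one CS value per index),
#'   `curve` (per-proportion mean correlation and exceedance probability per
#'   index), and the thresholds used.
#' @export
case_drop_bootstrap <- function(data, estimator = selection_config(),
                                config = boot_config()) {
  m <- unclass(data); attr(m, "communities") <- NULL
  storage.mode(m) <- "double"
  communities <- attr(data, "communities")
  n <- nrow(m); p <- ncol(m)
  full <- estimate_once(m, communities, estimator)
  ei_full <- expected_influence(full)
  bei_full <- suppressWarnings(bridge_expected_influence(full))

  set.seed(config$seed)
  rows <- list(); keep_d <- numeric(0)
  for (d in config$drop_proportions) {
    size <- floor((1 - d) * n)
    if (size < p + 1) {
      warning(sprintf("drop proportion %.2f leaves %d < p+1 rows; skipped",
                      d, size))
      next
    }
    rows[[length(rows) + 1L]] <-
      draw_resamples(m, config$n_boot, replace = FALSE, size = size)
    keep_d <- c(keep_d, d)
  }

  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  curve <- do.call(rbind, lapply(seq_along(keep_d), function(k) {
    cors_ei <- numeric(config$n_boot); cors_bei <- numeric(config$n_boot)
    for (b in seq_len(config$n_boot)) {
      mod <- estimate_once(m[rows[[k]][[b]], , drop = FALSE], communities,
                           estimator)
      cors_ei[b] <- safe_cor(expected_influence(mod), ei_full)
      cors_bei[b] <- safe_cor(
        suppressWarnings(bridge_expected_influence(mod)), bei_full)
    }
    ok_ei <- !is.na(cors_ei) & cors_ei >= config$cs_correlation
    ok_bei <- !is.na(cors_bei) & cors_bei >= config$cs_correlation
    data.frame(drop = keep_d[k],
               mean_cor_ei = mean(cors_ei, na.rm = FALSE),
               mean_cor_bei = mean(cors_bei, na.rm = FALSE),
               prob_ei = mean(ok_ei), prob_bei = mean(ok_bei))
  }))
  cs_of <- function(prob) {
    ok <- curve$drop[prob >= config$cs_probability]
    if (length(ok)) max(ok) else 0
  }
  cs <- c(ei = cs_of(curve$prob_ei), bei = cs_of(curve$prob_bei))
  structure(list(cs = cs, curve = curve,
                 cs_correlation = config$cs_correlation,
                 cs_probability = config$cs_probability,
                 interpretation = vapply(cs, function(v)
                   if (v < 0.25) "inadequate (< 0.25)"
                   else if (v > 0.50) "robust (> 0.50)"
                   else "acceptable (0.25-0.50)", character(1))),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat("Correlation-stability (CS) coefficients from case-dropping bootstrap\n")
  for (nm in names(x$cs))
    cat(sprintf("  %-4s CS = %.2f  [%s]\n", toupper(nm), x$cs[[nm]],
                x$interpretation[[nm]]))
  invisible(x)
}

quantile_excludes_zero <- function(d, level) {
  alpha <- (1 - level) / 2
  q <- stats::quantile(d, probs = c(alpha, 1 - alpha), names = FALSE)
  q[1] > 0 || q[2] < 0
}

#' Bootstrapped difference test for edge weights
#'
#' For every pair of edges, the difference is significant when the
#' percentile bootstrap interval of `w_e^(b) - w_f^(b)` excludes zero.
#' No multiple-testing correction is applied (exploratory, following the
#' usual bootstrap protocol for these networks).
#'
#' @param boot An `edge_boot` from [bootstrap_edges()].
#' @param level Interval level (defaults to the bootstrap's `ci_level`).
#' @return Symmetric logical matrix (edge-by-edge), with `FALSE` diagonal;
#'   dimnames are `"node_a--node_b"` edge names.
#' @export
difference_test_edges <- function(boot, level = NULL) {
  if (is.null(level)) level <- boot$config$ci_level
  nm <- paste0(boot$edges$node_a, "--", boot$edges$node_b)
  D <- boot$edge_draws
  K <- ncol(D)
  sig <- matrix(FALSE, K, K, dimnames = list(nm, nm))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    s <- quantile_excludes_zero(D[, a] - D[, b], level)
    sig[a, b] <- s; sig[b, a] <- s
  }
  sig
}

#' Bootstrapped difference test for node centralities
#'
#' As [difference_test_edges()], applied to the per-node EI (or BEI) draws
#' collected during the nonparametric bootstrap.
#'
#' @param boot An `edge_boot` from [bootstrap_edges()].
#' @param index `"ei"` or `"bei"`.
#' @param level Interval level (defaults to the bootstrap's `ci_level`).
#' @return Symmetric logical node-by-node matrix with `FALSE` diagonal.
#' @export
difference_test_centrality <- function(boot, index = c("ei", "bei"),
                                       level = NULL) {
  index <- match.arg(index)
  if (is.null(level)) level <- boot$config$ci_level
  D <- if (index == "ei") boot$ei_draws else boot$bei_draws
  p <- ncol(D)
  sig <- matrix(FALSE, p, p, dimnames = list(colnames(D), colnames(D)))
  for (a in seq_len(p - 1)) for (b in (a + 1):p) {
    s <- quantile_excludes_zero(D[, a] - D[, b], level)
    sig[a, b] <- s; sig[b, a] <- s
  }
  sig
}
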