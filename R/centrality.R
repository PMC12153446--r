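#' Expected influence of each node
#'
#' The `absolute` variant (the default, matching how EI is usually reported
#' for these symptom networks) sums the absolute edge weights incident to a
#' node: `EI_i = sum_{j != i} |w_ij|`. The `signed` variant sums the raw
#' weights; the two coincide on all-positive networks.
#'
#' @param model A `network_model`.
#' @param variant `"absolute"` (default) or `"signed"`.
#' @return Named numeric vector of per-node expected influence.
#' @export
expected_influence <- function(model, variant = c("absolute", "signed")) {
  variant <- match.arg(variant)
  W <- model$weights
  v <- if (variant == "absolute") rowSums(abs(W)) else rowSums(W)
  setNames(v, model$node_labels)
}

#' Bridge expected influence of each node
#'
#' The signed sum of a node's edge weights to nodes in the other community:
#' `BEI_i = sum_{j : comm(j) != comm(i)} w_ij`. High-BEI nodes are candidate
#' conduits of cross-disorder symptom activation.
#'
#' @param model A `network_model` with community assignments.
#' @return Named numeric vector of per-node bridge expected influence.
#' @export
bridge_expected_influence <- function(model) {
  W <- model$weights
  comm <- model$communities
  if (length(unique(comm)) < 2) {
    warning("single-community network: all bridge expected influences are 0")
    return(setNames(rep(0, nrow(W)), model$node_labels))
  }
  cross <- outer(comm, comm, FUN = "!=")
  setNames(rowSums(W * cross), model$node_labels)
}

#' Centrality table with EI and BEI ranks
#'
#' Raw (unstandardized) EI and BEI per node, with EI ranked over all nodes
#' descending and BEI ranked within each community descending. Ties are
#' broken by node label in lexicographic order, making ranks deterministic.
#'
#' @param model A `network_model`.
#' @param ei_variant Passed to [expected_influence()] (default `"absolute"`).
#' @param standardized Also include z-standardized EI/BEI columns
#'   (default FALSE).
#' @return A `centrality_table` data frame with columns `node`, `community`,
#'   `ei`, `bei`, `ei_rank`, `bei_rank_within_community` (and optionally
#'   `ei_z`, `bei_z`).
#' @export
centrality_table <- function(model, ei_variant = "absolute",
                             standardized = FALSE) {
  ei <- expected_influence(model, ei_variant)
  bei <- bridge_expected_influence(model)
  nodes <- model$node_labels
  comm <- model$communities
  # descending rank with lexicographic tie-break
  rank_desc <- function(v, labels) {
    o <- order(-v, labels)
    r <- integer(length(v)); r[o] <- seq_along(v); r
  }
  ei_rank <- rank_desc(ei, nodes)
  bei_rank <- integer(length(nodes))
  for (g in unique(comm)) {
    sel <- comm == g
    bei_rank[sel] <- rank_desc(bei[sel], nodes[sel])
  }
  out <- data.frame(node = nodes, community = unname(comm),
                    ei = unname(ei), bei = unname(bei),
                    ei_rank = ei_rank,
                    bei_rank_within_community = bei_rank,
                    stringsAsFactors = FALSE)
  if (standardized) {
    out$ei_z <- as.numeric(scale(out$ei))
    out$bei_z <- as.numeric(scale(out$bei))
  }
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' @export
print.centrality_table <- function(x, digits = 3, ...) {
  cat("Node centrality (raw expected influence / bridge expected influence)\n")
  df <- as.data.frame(x)
  df$ei <- round(df$ei, digits); df$bei <- round(df$bei, digits)
  print(df[order(df$ei_rank), ], row.names = FALSE)
  invisible(x)
}
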