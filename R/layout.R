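#' Fruchterman-Reingold force-directed layout
#'
#' Classic spring-embedder iteration with `|w|`-weighted attraction along
#' edges, all-pairs repulsion `k^2/d`, a linear cooling schedule down to
#' zero over `n_iter` steps, and seeded uniform initial positions. Final
#' coordinates are rescaled to the unit box `[-1, 1]^2`. With `k =
#' sqrt(area/p)` and initial temperature `0.1 * sqrt(area)` (`area = 1`),
#' the classic parameterization.
#'
#' @param model A `network_model` (only `|weights|` are used as attraction
#'   strengths).
#' @param seed Seed for the initial positions (default 20170101).
#' @param n_iter Iterations (default 500).
#' @return Data frame with `node`, `x`, `y` (in `[-1, 1]`), plus attributes
#'   `iterations_used` and `seed`.
#' @export
fruchterman_reingold <- function(model, seed = 20170101L, n_iter = 500L) {
  W <- abs(model$weights)
  p <- nrow(W)
  set.seed(seed)
  if (p == 1L) {
    pos <- matrix(0, 1, 2)
  } else {
    area <- 1
    k <- sqrt(area / p)
    pos <- matrix(stats::runif(2 * p, -0.5, 0.5), p, 2)
    t0 <- 0.1 * sqrt(area)
    eps <- 1e-9
    for (it in seq_len(n_iter)) {
      temp <- t0 * (1 - (it - 1) / n_iter)
      disp <- matrix(0, p, 2)
      for (i in seq_len(p - 1)) for (j in (i + 1):p) {
        delta <- pos[i, ] - pos[j, ]
        d <- sqrt(sum(delta^2)) + eps
        # repulsion
        f <- (k^2 / d) / d
        disp[i, ] <- disp[i, ] + delta * f
        disp[j, ] <- disp[j, ] - delta * f
        # weighted attraction along edges
        if (W[i, j] > 0) {
          fa <- (d^2 / k) * W[i, j] / d
          disp[i, ] <- disp[i, ] - delta * fa
          disp[j, ] <- disp[j, ] + delta * fa
        }
      }
      len <- sqrt(rowSums(disp^2)) + eps
      step <- pmin(len, temp) / len
      pos <- pos + disp * step
    }
    rng <- apply(pos, 2, function(v) diff(range(v)))
    for (c2 in 1:2) {
      if (rng[c2] > 0)
        pos[, c2] <- 2 * (pos[, c2] - min(pos[, c2])) / rng[c2] - 1
      else pos[, c2] <- 0
    }
  }
  out <- data.frame(node = model$node_labels, x = pos[, 1], y = pos[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "iterations_used") <- as.integer(n_iter)
  attr(out, "seed") <- as.integer(seed)
  out
}

edge_styles <- function(model, max_thickness = 4) {
  el <- edge_list(model)
  if (nrow(el) == 0) {
    el$sign_class <- character(0); el$thickness <- numeric(0)
    el$saturation <- numeric(0)
    return(el)
  }
  wmax <- max(abs(el$weight))
  el$sign_class <- ifelse(el$weight >= 0, "positive", "negative")
  el$thickness <- max_thickness * abs(el$weight) / wmax
  el$saturation <- abs(el$weight) / wmax
  el
}

#' Render the network figure with machine-readable sidecars
#'
#' Draws the partial-correlation network at the given layout: positive edges
#' blue, negative edges red, line thickness and saturation proportional to
#' `|weight|`; nodes coloured by community. Writes the figure as SVG and PNG
#' and two delimited sidecar tables (node table with coordinates and
#' community colour class; edge table with style fields) next to it.
#'
#' @param model A `network_model`.
#' @param coords Layout from [fruchterman_reingold()] (computed if `NULL`).
#' @param out_prefix Path prefix; writes `<prefix>.svg`, `<prefix>.png`,
#'   `<prefix>_nodes.csv`, `<prefix>_edges.csv`.
#' @param community_colors Named fill colours for the two communities.
#' @return Invisibly, a list with the sidecar data frames and file paths.
#' @export
render_network <- function(model, coords = NULL, out_prefix,
                           community_colors = c(anxiety = "#4477CC",
                                                depression = "#EE8833")) {
  if (is.null(coords)) coords <- fruchterman_reingold(model)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  nodes <- data.frame(coords,
                      community = unname(model$communities[coords$node]),
                      stringsAsFactors = FALSE)
  nodes$color <- unname(community_colors[nodes$community])
  edges <- edge_styles(model)
  if (nrow(edges)) {
    ia <- match(edges$node_a, nodes$node); ib <- match(edges$node_b, nodes$node)
    edges$x_a <- nodes$x[ia]; edges$y_a <- nodes$y[ia]
    edges$x_b <- nodes$x[ib]; edges$y_b <- nodes$y[ib]
  }

  gg <- ggplot2::ggplot()
  if (nrow(edges))
    gg <- gg + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x_a, y = .data$y_a,
                   xend = .data$x_b, yend = .data$y_b),
      colour = ifelse(edges$sign_class == "positive", "#2255BB", "#CC3333"),
      linewidth = 0.3 + edges$thickness,
      alpha = 0.25 + 0.75 * edges$saturation)
  gg <- gg +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        fill = nodes$color, size = 9, shape = 21,
                        colour = "grey30") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node), size = 2.2) +
    ggplot2::coord_equal(xlim = c(-1.15, 1.15), ylim = c(-1.15, 1.15)) +
    ggplot2::theme_void()

  paths <- list(svg = paste0(out_prefix, ".svg"),
                png = paste0(out_prefix, ".png"),
                nodes = paste0(out_prefix, "_nodes.csv"),
                edges = paste0(out_prefix, "_edges.csv"))
  ok_svg <- tryCatch({
    ggplot2::ggsave(paths$svg, gg, width = 6, height = 6, device = grDevices::svg)
    TRUE
  }, error = function(e) FALSE)
  ok_png <- tryCatch({
    ggplot2::ggsave(paths$png, gg, width = 6, height = 6, dpi = 150,
                    device = grDevices::png, type = "cairo")
    TRUE
  }, error = function(e) FALSE)
  if (!ok_svg && !ok_png)
    warning("no graphics device available; only sidecar tables written")
  utils::write.csv(nodes, paths$nodes, row.names = FALSE)
  utils::write.csv(edges, paths$edges, row.names = FALSE)
  invisible(list(nodes = nodes, edges = edges, paths = paths))
}

#' Combined descriptive and centrality table
#'
#' One row per symptom with columns Symptom (community), Abb (node label),
#' M, SD, EI, BEI, in fixed instrument order (GAD1..GAD7 then
#' CESD1..CESD10), rounded to 2 decimals as conventionally printed.
#'
#' @param desc Output of [descriptives()].
#' @param centrality A `centrality_table`.
#' @param digits Rounding (default 2).
#' @return Data frame in fixed node order.
#' @export
make_table1 <- function(desc, centrality, digits = 2) {
  a <- desc$items; b <- as.data.frame(centrality)
  if (!setequal(a$node, b$node))
    stop("node sets differ: ",
         paste(c(setdiff(a$node, b$node), setdiff(b$node, a$node)),
               collapse = ", "))
  ord <- node_labels()[node_labels() %in% a$node]
  a <- a[match(ord, a$node), ]; b <- b[match(ord, b$node), ]
  data.frame(Symptom = unname(b$community), Abb = a$node,
             M = round(a$mean, digits), SD = round(a$sd, digits),
             EI = round(b$ei, digits), BEI = round(b$bei, digits),
             row.names = NULL, stringsAsFactors = FALSE)
}
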