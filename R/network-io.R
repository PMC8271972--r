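#' Write a motion network as GraphML
#'
#' Weighted undirected GraphML with node attributes (angle name, region,
#' display rank) and graph attributes (participant, movement). Only
#' thresholded edges are serialized; the full weight matrix round-trips via
#' [write_network_json()].
#'
#' @param network a `motion_network`.
#' @param path output file.
#' @param angles angle metadata tibble (see [default_joint_angles()]); when
#'   omitted, generic labels are used.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, angles = NULL) {
  n <- nrow(network$weights)
  if (is.null(angles)) {
    angles <- tibble(id = seq_len(n), name = paste0("angle_", seq_len(n)),
                     region = NA_character_, display_rank = seq_len(n))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(angles$id)
  igraph::V(g)$angle_name <- angles$name
  igraph::V(g)$region <- as.character(angles$region)
  igraph::V(g)$display_rank <- angles$display_rank
  e <- network$edges
  if (nrow(e) > 0) {
    g <- igraph::add_edges(g, rbind(e$angle_i, e$angle_j))
    igraph::E(g)$weight <- e$weight
  }
  g <- igraph::set_graph_attr(g, "participant", as.character(network$participant))
  g <- igraph::set_graph_attr(g, "movement", as.integer(network$movement))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML motion network (edges only)
#'
#' @param path GraphML file written by [write_network_graphml()].
#' @return a `motion_network` whose weight matrix carries the serialized
#'   (thresholded) edges.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(g)
  W <- matrix(0, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0) {
    W[el] <- igraph::E(g)$weight
    W[el[, c(2, 1), drop = FALSE]] <- igraph::E(g)$weight
  }
  structure(
    list(
      participant = igraph::graph_attr(g, "participant"),
      movement = as.integer(igraph::graph_attr(g, "movement")),
      weights = W,
      edges = tibble(
        angle_i = pmin(el[, 1], el[, 2]),
        angle_j = pmax(el[, 1], el[, 2]),
        weight = if (nrow(el) > 0) igraph::E(g)$weight else numeric()
      ),
      config = NULL
    ),
    class = "motion_network"
  )
}

#' Write / read a motion network as JSON adjacency
#'
#' Lossless round trip of the full weight matrix, provenance and the edge
#' threshold used.
#'
#' @param network a `motion_network`.
#' @param path JSON file.
#' @return `path` (write) / a `motion_network` (read).
#' @export
write_network_json <- function(network, path) {
  jsonlite::write_json(
    list(
      participant = network$participant,
      movement = network$movement,
      weights = network$weights,
      edge_threshold_rel = network$config$edge_threshold_rel %||% NA_real_
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(x$weights)
  thr <- x$edge_threshold_rel
  if (is.null(thr) || is.na(thr)) thr <- 0.2
  structure(
    list(
      participant = x$participant, movement = as.integer(x$movement),
      weights = W, edges = edge_table(W, thr),
      config = gl_config(edge_threshold_rel = thr)
    ),
    class = "motion_network"
  )
}
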