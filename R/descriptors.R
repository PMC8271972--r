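#' Per-series measures: mean, entropy, energy
#'
#' `mean` is the arithmetic mean, `energy` the sum of squared values, and
#' `entropy` the natural-log Shannon entropy of the 100-bin value histogram
#' over the series' own range, normalized to probabilities. A constant
#' series occupies a single bin and has entropy 0.
#'
#' @param values numeric vector, length >= 1, finite.
#' @param bins histogram bins for the entropy (default 100).
#' @return one-row tibble with `mean`, `entropy`, `energy`.
#' @export
series_measures <- function(values, bins = 100) {
  check_finite_numeric(values, "series values")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    ent <- 0
  } else {
    cuts <- seq(rng[1], rng[2], length.out = bins + 1)
    counts <- tabulate(findInterval(values, cuts, rightmost.closed = TRUE),
                       nbins = bins)
    p <- counts[counts > 0] / length(values)
    ent <- -sum(p * log(p))
  }
  tibble(mean = mean(values), entropy = ent, energy = sum(values^2))
}

#' Group summary curves
#'
#' Pointwise mean and standard deviation over a set of same-(movement,
#' angle) series from different participants, plus the display length used
#' by the "Proportional" view (the mean of the original durations) or the
#' common length ("SameLength").
#'
#' @param series tibble slice with `values` (equal-length list column) and
#'   `original_length`, or a plain list of equal-length vectors.
#' @param mode `"Proportional"` or `"SameLength"`.
#' @param group optional group label carried through to plots.
#' @return a `group_summary` object: tibble `curve` (`t`, `mean`, `sd`) plus
#'   `display_length`, `group`, `n`.
#' @export
group_summary <- function(series, mode = c("SameLength", "Proportional"),
                          group = NA_character_) {
  mode <- match.arg(mode)
  if (is.data.frame(series)) {
    orig <- series$original_length
    series <- series$values
  } else {
    orig <- lengths(series)
  }
  if (length(series) == 0) {
    abort("empty series set", class = c("kinegraph_domain_error",
                                        "kinegraph_error"))
  }
  lens <- lengths(series)
  if (length(unique(lens)) != 1) {
    stop_invalid("all series must share the common length")
  }
  X <- do.call(rbind, series)
  mu <- colMeans(X)
  sdv <- if (nrow(X) > 1) apply(X, 2, sd) else rep(0, ncol(X))
  structure(
    list(
      curve = tibble(t = seq_len(ncol(X)), mean = mu, sd = sdv),
      display_length = if (mode == "Proportional") mean(orig) else ncol(X),
      mode = mode, group = group, n = nrow(X)
    ),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: n = %d, length %d, display length %.0f\n",
              x$group, x$n, nrow(x$curve), x$display_length))
  invisible(x)
}

closeness_from_distances <- function(D) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    if (!any(reach)) return(0)
    sum(reach) / sum(d[reach])
  }, numeric(1))
}

eigencentrality_by_component <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)$membership
  for (c_id in unique(comp)) {
    idx <- which(comp == c_id)
    if (length(idx) < 2) next  # isolated vertex: 0 by convention
    ev <- eigen(W[idx, idx, drop = FALSE], symmetric = TRUE)
    v <- abs(ev$vectors[, 1])
    out[idx] <- v / max(v)
  }
  out
}

#' Network centrality feature vector
#'
#' Concatenation `[degree | closeness | eigencentrality | clustering]`, each
#' of length N_A, computed on the thresholded weighted graph: degree is the
#' weighted vertex strength; closeness the inverse mean shortest-path
#' distance (edge length = 1/weight) to reachable vertices; eigencentrality
#' the principal adjacency eigenvector per connected component (scaled to
#' max 1 within the component); clustering the binary local clustering
#' coefficient of the thresholded edge set. Isolated vertices score 0 on
#' closeness, eigencentrality and clustering.
#'
#' @param network a `motion_network`.
#' @return numeric vector of length `4 * N_A`.
#' @export
network_features <- function(network) {
  n <- nrow(network$weights)
  W <- matrix(0, n, n)
  e <- network$edges
  if (nrow(e) > 0) {
    W[cbind(e$angle_i, e$angle_j)] <- e$weight
    W[cbind(e$angle_j, e$angle_i)] <- e$weight
  }
  degree <- rowSums(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = if (nrow(e) > 0) 1 / igraph::E(g)$weight
                                      else NULL)
  closeness <- closeness_from_distances(D)
  eig <- eigencentrality_by_component(W)
  gb <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                            diag = FALSE)
  clus <- igraph::transitivity(gb, type = "localundirected", isolates = "zero")
  clus[is.na(clus)] <- 0
  c(degree, closeness, eig, clus)
}

#' Per-participant network feature vectors
#'
#' One row per participant: the [network_features()] of the selected
#' movement's network, or the concatenation over all movements
#' (`N_M * 4 * N_A` values).
#'
#' @param networks tibble from [build_all_networks()].
#' @param movement movement id, or NULL for all movements concatenated.
#' @return tibble `participant` + `features` list column.
#' @export
network_feature_vectors <- function(networks, movement = NULL) {
  keep <- if (is.null(movement)) networks else
    networks[networks$movement %in% movement, ]
  keep |>
    arrange(.data$participant, .data$movement) |>
    group_by(.data$participant) |>
    summarise(features = list(unlist(map(.data$network, network_features))),
              .groups = "drop")
}

#' PCA projection to 2-D
#'
#' Mean-centered principal component scores on the top two components, with
#' a deterministic sign convention: each component's largest-magnitude
#' loading is positive.
#'
#' @param vectors list of equal-length numeric vectors, or a numeric matrix
#'   (rows = observations).
#' @return tibble with columns `x`, `y` (second column 0 when the data have
#'   rank 1).
#' @export
pca_project <- function(vectors) {
  X <- if (is.matrix(vectors)) vectors else do.call(rbind, vectors)
  if (nrow(X) < 2) stop_invalid("need at least two vectors")
  if (nrow(unique(as.data.frame(X))) < 2) {
    abort("all vectors identical: PCA is degenerate",
          class = c("kinegraph_degenerate_input", "kinegraph_error"))
  }
  p <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  rot <- p$rotation
  for (k in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, k])), k] < 0) {
      rot[, k] <- -rot[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  sc <- p$x
  if (ncol(sc) < 2) sc <- cbind(sc, 0)
  tibble(x = sc[, 1], y = sc[, 2])
}

#' Classical MDS projection to 2-D
#'
#' Torgerson double-centering embedding of the Euclidean distance matrix.
#' When the input is intrinsically two-dimensional the configuration
#' reproduces the distances exactly (up to a rigid transform). All-identical
#' input collapses to the origin with a warning.
#'
#' @param vectors list of equal-length numeric vectors or a numeric matrix.
#' @return tibble with columns `x`, `y`.
#' @export
mds_project <- function(vectors) {
  X <- if (is.matrix(vectors)) vectors else do.call(rbind, vectors)
  if (nrow(X) < 3) stop_invalid("need at least three vectors")
  D <- dist(X)
  if (max(D) == 0) {
    warn("all vectors identical: MDS configuration collapses to the origin")
    return(tibble(x = rep(0, nrow(X)), y = rep(0, nrow(X))))
  }
  sc <- cmdscale(D, k = 2)
  if (ncol(sc) < 2) sc <- cbind(sc, rep(0, nrow(X)))
  tibble(x = sc[, 1], y = sc[, 2])
}
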