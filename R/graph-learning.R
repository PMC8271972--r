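#' Graph-learning configuration
#'
#' Parameters of the smoothness-based graph-learning problem
#' \deqn{W^* = \arg\min_{W \in \mathcal W} \tfrac12 \sum_{i,j} W_{ij} Z_{ij}
#'   - \alpha \, 1^T \log(W 1) + \gamma \|W\|_F^2}
#' over symmetric, non-negative, zero-diagonal matrices. The log-degree
#' barrier (weight `barrier_weight`, \eqn{\alpha}) forces every vertex to
#' keep positive total edge weight; the Frobenius term (`frobenius_weight`,
#' \eqn{\gamma}) bounds the solution and spreads weight.
#'
#' `z_scaling = "mean-to-n"` rescales Z so its off-diagonal mean equals the
#' number of vertices before solving. Relative to the barrier weight this
#' sets the sparsity regime: at that scale most optimal weights are exactly
#' zero and only strongly synchronized pairs carry weight, while the barrier
#' floor (the weight a penalized vertex is forced to carry) stays an order
#' of magnitude below the strong weights. `"none"` solves on Z as given.
#'
#' An entry counts as an edge when it exceeds `edge_threshold_rel` times the
#' largest weight; the default 0.2 sits above the barrier floor, so null and
#' near-constant channels end up edge-free.
#'
#' @param barrier_weight positive log-degree barrier weight (default 1).
#' @param frobenius_weight non-negative Frobenius weight (default 0.5).
#' @param z_scaling `"mean-to-n"` (default) or `"none"`.
#' @param max_iterations primal-dual iteration cap (default 20000).
#' @param tolerance relative objective-change stopping rule (default 1e-6).
#' @param edge_threshold_rel relative edge threshold in [0, 1) (default 0.2).
#' @return a `gl_config` list.
#' @export
gl_config <- function(barrier_weight = 1, frobenius_weight = 0.5,
                      z_scaling = c("mean-to-n", "none"),
                      max_iterations = 20000, tolerance = 1e-6,
                      edge_threshold_rel = 0.2) {
  z_scaling <- match.arg(z_scaling)
  if (!is.finite(barrier_weight) || barrier_weight <= 0) {
    stop_invalid("barrier_weight must be > 0 (it guarantees connectivity)")
  }
  if (!is.finite(frobenius_weight) || frobenius_weight < 0) {
    stop_invalid("frobenius_weight must be >= 0")
  }
  if (edge_threshold_rel < 0 || edge_threshold_rel >= 1) {
    stop_invalid("edge_threshold_rel must lie in [0, 1)")
  }
  structure(
    list(
      barrier_weight = barrier_weight, frobenius_weight = frobenius_weight,
      z_scaling = z_scaling, max_iterations = as.integer(max_iterations),
      tolerance = tolerance, edge_threshold_rel = edge_threshold_rel
    ),
    class = "gl_config"
  )
}

# upper-triangular pair index (i < j), row-major, shared by all solvers
upper_pairs <- function(n) {
  p <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}

# degree operator: d = S w for w on the upper-triangular pairs
degree_operator <- function(n) {
  pairs <- upper_pairs(n)
  S <- matrix(0, n, nrow(pairs))
  S[cbind(pairs[, 1], seq_len(nrow(pairs)))] <- 1
  S[cbind(pairs[, 2], seq_len(nrow(pairs)))] <- 1
  list(S = S, pairs = pairs)
}

check_wz <- function(W, Z) {
  if (!is.matrix(W) || !is.matrix(Z) || any(dim(W) != dim(Z)) ||
      nrow(W) != ncol(W)) {
    stop_invalid("W and Z must be square matrices of the same size")
  }
}

#' Graph-learning objective value
#'
#' \eqn{\tfrac12 \sum_{ij} W_{ij}Z_{ij} - \alpha \sum_i \log(\sum_j W_{ij})
#' + \gamma \|W\|_F^2}; `+Inf` when any row sum is zero (an isolated vertex
#' hits the log barrier).
#'
#' @param W candidate adjacency (symmetric, non-negative, zero diagonal).
#' @param Z dissimilarity matrix of the same size.
#' @param config a [gl_config()]; `z_scaling` is not applied here — the
#'   objective is evaluated on Z as given.
#' @return real number or `+Inf`.
#' @export
gl_objective <- function(W, Z, config = gl_config()) {
  check_wz(W, Z)
  d <- rowSums(W)
  if (any(d <= 0)) return(Inf)
  sum(W * Z) / 2 - config$barrier_weight * sum(log(d)) +
    config$frobenius_weight * sum(W^2)
}

# objective in the upper-tri vector parameterization (internal)
gl_objective_w <- function(w, z, S, alpha, gamma) {
  d <- as.vector(S %*% w)
  if (any(d <= 0)) return(Inf)
  sum(w * z) - alpha * sum(log(d)) + 2 * gamma * sum(w^2)
}

#' Learn a graph from a dissimilarity matrix
#'
#' Solves the graph-learning problem by primal-dual splitting
#' (Monotone+Lipschitz forward-backward-forward) on the upper-triangular
#' weight vector with the linear degree operator carrying the barrier term.
#' The non-negativity-plus-linear term is handled by its proximal operator
#' (a shifted positive part, which produces exact zeros), the barrier by the
#' proximal operator of its convex conjugate, and the Frobenius term by its
#' gradient. Step size is fixed from the operator norm
#' \eqn{\|S\| = \sqrt{2(n-1)}} and the Frobenius Lipschitz constant.
#' Deterministic: identical inputs give bit-identical output.
#'
#' @param Z symmetric non-negative dissimilarity matrix, zero diagonal.
#' @param config a [gl_config()].
#' @return symmetric, non-negative, zero-diagonal weight matrix with
#'   attribute `"iterations"`; every row sum is positive.
#' @export
learn_graph <- function(Z, config = gl_config()) {
  if (!is.matrix(Z) || nrow(Z) != ncol(Z)) stop_invalid("Z must be square")
  if (max(abs(Z - t(Z))) > 1e-8) stop_invalid("Z must be symmetric")
  n <- nrow(Z)
  if (n < 2) stop_invalid("need at least two vertices")
  if (config$z_scaling == "mean-to-n") {
    mu <- mean(Z[upper.tri(Z)])
    if (mu > 0) Z <- Z * (n / mu)
  }
  op <- degree_operator(n)
  S <- op$S
  z <- Z[op$pairs]
  alpha <- config$barrier_weight
  gamma <- config$frobenius_weight
  step <- 0.99 / (4 * gamma + sqrt(2 * (n - 1)))
  w <- rep(if (mean(z) > 0) mean(z) else 1, length(z))
  v <- as.vector(S %*% w)
  obj_old <- gl_objective_w(w, z, S, alpha, gamma)
  check_every <- 25L
  converged <- FALSE
  last_rel <- Inf
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    y <- w - step * (4 * gamma * w + as.vector(crossprod(S, v)))
    yb <- v + step * as.vector(S %*% w)
    p <- pmax(0, y - step * z)
    pb <- (yb - sqrt(yb^2 + 4 * alpha * step)) / 2
    w <- w - y + p - step * (4 * gamma * p + as.vector(crossprod(S, pb)))
    v <- v - yb + pb + step * as.vector(S %*% p)
    if (it %% check_every == 0L) {
      obj <- gl_objective_w(w, z, S, alpha, gamma)
      if (is.finite(obj) && is.finite(obj_old)) {
        last_rel <- abs(obj - obj_old) / max(1, abs(obj))
        if (last_rel <= config$tolerance) {
          converged <- TRUE
          break
        }
      }
      obj_old <- obj
    }
  }
  if (!converged && it >= config$max_iterations) {
    abort(
      sprintf(
        "graph learning did not converge in %d iterations (last relative objective change %.3g)",
        config$max_iterations, last_rel
      ),
      class = c("kinegraph_convergence_error", "kinegraph_error")
    )
  }
  w <- pmax(w, 0)
  W <- matrix(0, n, n)
  W[op$pairs] <- w
  W <- W + t(W)
  dimnames(W) <- dimnames(Z)
  attr(W, "iterations") <- it
  W
}

# reference solve of the same objective by a generic convex-programming
# routine (L-BFGS-B with analytic gradient); used as an independent check
# in the test-suite, never by the pipeline
gl_reference_solve <- function(Z, config = gl_config(z_scaling = "none")) {
  n <- nrow(Z)
  op <- degree_operator(n)
  S <- op$S
  z <- Z[op$pairs]
  alpha <- config$barrier_weight
  gamma <- config$frobenius_weight
  fn <- function(w) {
    d <- as.vector(S %*% w)
    if (any(d <= 1e-300)) return(1e12)
    sum(w * z) - alpha * sum(log(d)) + 2 * gamma * sum(w^2)
  }
  gr <- function(w) {
    d <- pmax(as.vector(S %*% w), 1e-300)
    z - alpha * as.vector(crossprod(S, 1 / d)) + 4 * gamma * w
  }
  w0 <- rep(max(mean(z), 0.1), length(z))
  res <- optim(w0, fn, gr, method = "L-BFGS-B", lower = 1e-12,
               control = list(maxit = 5000, factr = 1e3))
  W <- matrix(0, n, n)
  W[op$pairs] <- res$par
  W <- W + t(W)
  W
}

edge_table <- function(W, threshold_rel, angle_names = NULL) {
  n <- nrow(W)
  pairs <- upper_pairs(n)
  w <- W[pairs]
  keep <- w > threshold_rel * max(W)
  tibble(
    angle_i = pairs[keep, 1], angle_j = pairs[keep, 2], weight = w[keep]
  )
}

#' Build the synchronization network of one (participant, movement)
#'
#' Runs the full per-network pipeline: pairwise dissimilarity (with the
#' normalized z1 composition, see [dissimilarity_matrix()]), graph learning,
#' and relative-threshold edge extraction.
#'
#' @param series list of equal-length numeric vectors, one per angle in angle
#'   id order, or the corresponding cohort series tibble slice.
#' @param participant,movement provenance identifiers.
#' @param weights a [penalty_weights()].
#' @param config a [gl_config()].
#' @return object of class `motion_network`: weights matrix, edge tibble,
#'   provenance and the config used.
#' @export
build_network <- function(series, participant = NA_character_,
                          movement = NA_integer_,
                          weights = penalty_weights(),
                          config = gl_config()) {
  if (is.data.frame(series)) {
    series <- series[order(series$angle), ]
    series <- series$values
  }
  Z <- dissimilarity_matrix(series, weights = weights, normalize = TRUE)
  W <- learn_graph(Z, config)
  structure(
    list(
      participant = participant, movement = movement, weights = W,
      edges = edge_table(W, config$edge_threshold_rel),
      config = config
    ),
    class = "motion_network"
  )
}

#' @export
print.motion_network <- function(x, ...) {
  cat(sprintf("<motion_network> %s / M%s: %d vertices, %d edges\n",
              x$participant, x$movement, nrow(x$weights), nrow(x$edges)))
  invisible(x)
}

#' Tidy a motion network into its edge list
#'
#' @param x a `motion_network`.
#' @param ... unused.
#' @return tibble with `participant`, `movement`, `angle_i`, `angle_j`,
#'   `weight`.
#' @exportS3Method generics::tidy
tidy.motion_network <- function(x, ...) {
  mutate(x$edges, participant = x$participant, movement = x$movement,
         .before = 1)
}

#' One-row summary of a motion network
#'
#' @param x a `motion_network`.
#' @param ... unused.
#' @return tibble with vertex/edge counts and total weight.
#' @exportS3Method generics::glance
glance.motion_network <- function(x, ...) {
  tibble(
    participant = x$participant, movement = x$movement,
    n_vertices = nrow(x$weights), n_edges = nrow(x$edges),
    total_weight = sum(x$weights) / 2,
    max_weight = max(x$weights)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Build all networks of a cohort
#'
#' One network per (participant-side, movement), in participant-major,
#' movement-minor order. Any per-network failure aborts with the failing
#' pair identified.
#'
#' @param cohort a resampled `motion_cohort`.
#' @param weights a [penalty_weights()].
#' @param config a [gl_config()].
#' @param progress print a line every 100 networks.
#' @return tibble with columns `participant`, `movement`, `network` (list of
#'   `motion_network`).
#' @export
build_all_networks <- function(cohort, weights = penalty_weights(),
                               config = gl_config(), progress = FALSE) {
  stopifnot(inherits(cohort, "motion_cohort"))
  idx <- tidyr::expand_grid(
    participant = cohort$participants$id, movement = cohort$movements$id
  )
  ser <- cohort$series
  ord <- order(ser$participant, ser$movement, ser$angle)
  ser <- ser[ord, ]
  split_key <- paste(ser$participant, ser$movement, sep = "\r")
  values_by_net <- split(ser$values, factor(split_key, levels = unique(split_key)))
  nets <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    key <- paste(idx$participant[k], idx$movement[k], sep = "\r")
    vals <- values_by_net[[key]]
    nets[[k]] <- tryCatch(
      build_network(vals, idx$participant[k], idx$movement[k],
                    weights = weights, config = config),
      error = function(e) {
        abort(
          sprintf("network (%s, M%d) failed: %s",
                  idx$participant[k], idx$movement[k], conditionMessage(e)),
          class = c("kinegraph_network_error", "kinegraph_error")
        )
      }
    )
    if (progress && k %% 100 == 0) {
      message(sprintf("  %d / %d networks", k, nrow(idx)))
    }
  }
  mutate(idx, network = nets)
}
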