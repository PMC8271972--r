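#' Project the individuals of a cohort to 2-D
#'
#' The three comparison-view projection schemes: `"net-pca"` (PCA of the
#' per-network centrality feature vectors), `"curve-pca"` (PCA of the
#' concatenated per-series standardized motion curves), and `"ae-mds"`
#' (classical MDS of the concatenated autoencoder embeddings). All operate
#' per selected movement and return one point per participant-side with its
#' group/side/FMA metadata attached.
#'
#' @param cohort a resampled `motion_cohort`.
#' @param movement movement id.
#' @param method projection scheme.
#' @param networks tibble from [build_all_networks()]; required for
#'   `"net-pca"`.
#' @param groups group-side tokens to include (default all).
#' @param encoder optional pre-trained `motion_encoder` for `"ae-mds"`;
#'   trained on the selected series when omitted.
#' @param seed seed for autoencoder training.
#' @param epochs,batch_size,learning_rate autoencoder training parameters
#'   (see [train_autoencoder()]).
#' @return tibble `participant`, `x`, `y`, `group`, `side`, `group_side`,
#'   `fma_total`.
#' @export
project_cohort <- function(cohort, movement,
                           method = c("net-pca", "curve-pca", "ae-mds"),
                           networks = NULL, groups = all_group_sides,
                           encoder = NULL, seed = 1L, epochs = 30L,
                           batch_size = 32L, learning_rate = 1e-3) {
  method <- match.arg(method)
  part <- cohort$participants
  part$group_side <- group_side_token(part$group, part$side)
  part <- part[part$group_side %in% groups, ]
  if (nrow(part) < 3) stop_invalid("need at least three participant-sides")
  ser <- cohort$series[cohort$series$movement == movement &
                         cohort$series$participant %in% part$id, ]
  if (nrow(ser) == 0) {
    abort(sprintf("no series for movement M%d", movement),
          class = c("kinegraph_domain_error", "kinegraph_error"))
  }
  if (method == "net-pca") {
    if (is.null(networks)) stop_invalid("net-pca needs the networks table")
    fv <- network_feature_vectors(
      networks[networks$participant %in% part$id, ], movement)
    ids <- fv$participant
    coords <- pca_project(fv$features)
  } else if (method == "curve-pca") {
    std <- function(v) {
      s <- sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    cv <- ser |>
      arrange(.data$participant, .data$angle) |>
      group_by(.data$participant) |>
      summarise(curve = list(unlist(map(.data$values, std))),
                .groups = "drop")
    ids <- cv$participant
    coords <- pca_project(cv$curve)
  } else {
    if (is.null(encoder)) {
      encoder <- train_autoencoder(ser$values, seed = seed, epochs = epochs,
                                   batch_size = batch_size,
                                   learning_rate = learning_rate)
    }
    emb <- cohort_embeddings(cohort, encoder, movement,
                             participants = part$id)
    ids <- emb$participant
    coords <- mds_project(emb$embedding)
  }
  tibble(participant = ids) |>
    mutate(x = coords$x, y = coords$y) |>
    left_join(select(part, "id", "group", "side", "group_side", "fma_total"),
              by = c(participant = "id"))
}
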