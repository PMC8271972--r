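# Compact 1D-convolutional autoencoder for fixed-length (1500-sample)
# kinematic series. Six encoder layers: one stride-1 convolution lifting the
# single input channel to 4 channels at full length, then five stride-2
# convolutions (kernel 3, unit zero padding, 4 channels) halving the length
# to 750, 375, 188, 94, 47; the flattened 4 x 47 = 188 activation is the
# embedding. ReLU in the encoder; the mirrored decoder (five transposed
# convolutions plus a final stride-1 convolution back to one channel) uses
# no activation. Trained by Adam on mean squared reconstruction error.
# Written directly in R (forward + analytic backprop); the layer algebra is
# plain matrix arithmetic over im2col patches.

AE_INPUT_LEN <- 1500L
AE_ENC_LENS <- c(1500L, 750L, 375L, 188L, 94L, 47L)
AE_CHANNELS <- 4L

conv_forward <- function(X, W, b, stride) {
  cin <- nrow(X)
  L <- ncol(X)
  Xp <- cbind(0, X, 0)
  L_out <- (L - 1L) %/% stride + 1L
  pos <- 1L + stride * (seq_len(L_out) - 1L)
  Xc <- rbind(Xp[, pos, drop = FALSE],
              Xp[, pos + 1L, drop = FALSE],
              Xp[, pos + 2L, drop = FALSE])
  list(Y = W %*% Xc + b, Xc = Xc, pos = pos, L = L, cin = cin)
}

conv_backward <- function(cache, W, dY, stride) {
  dW <- dY %*% t(cache$Xc)
  db <- rowSums(dY)
  dXc <- crossprod(W, dY)
  cin <- cache$cin
  dXp <- matrix(0, cin, cache$L + 2L)
  for (tap in 1:3) {
    rows <- ((tap - 1L) * cin + 1L):(tap * cin)
    idx <- cache$pos + tap - 1L
    dXp[, idx] <- dXp[, idx] + dXc[rows, , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dXp[, 2L:(cache$L + 1L), drop = FALSE])
}

tconv_forward <- function(X, W, b, stride, out_len) {
  cin <- nrow(X)
  L_in <- ncol(X)
  cout <- nrow(W)
  Yp <- matrix(0, cout, out_len + 2L)
  base <- 1L + stride * (seq_len(L_in) - 1L)
  for (tap in 1:3) {
    cols <- ((tap - 1L) * cin + 1L):(tap * cin)
    idx <- base + tap - 1L
    keep <- idx <= out_len + 2L
    Yp[, idx[keep]] <- Yp[, idx[keep]] +
      W[, cols, drop = FALSE] %*% X[, keep, drop = FALSE]
  }
  list(Y = Yp[, 2L:(out_len + 1L), drop = FALSE] + b, X = X, base = base)
}

tconv_backward <- function(cache, W, dY, out_len) {
  cin <- ncol(W) / 3L
  dYp <- matrix(0, nrow(dY), out_len + 2L)
  dYp[, 2L:(out_len + 1L)] <- dY
  dW <- matrix(0, nrow(W), ncol(W))
  dX <- matrix(0, nrow(cache$X), ncol(cache$X))
  for (tap in 1:3) {
    cols <- ((tap - 1L) * cin + 1L):(tap * cin)
    idx <- cache$base + tap - 1L
    keep <- idx <= out_len + 2L
    dslice <- dYp[, idx[keep], drop = FALSE]
    dW[, cols] <- dW[, cols] + dslice %*% t(cache$X[, keep, drop = FALSE])
    dX[, keep] <- dX[, keep] + crossprod(W[, cols, drop = FALSE], dslice)
  }
  list(dW = dW, db = rowSums(dY), dX = dX)
}

ae_init_layers <- function() {
  mk <- function(cout, cin) {
    sdv <- sqrt(2 / (cin * 3))
    list(W = matrix(rnorm(cout * cin * 3, 0, sdv), cout, cin * 3),
         b = rep(0, cout))
  }
  enc <- c(list(mk(AE_CHANNELS, 1L)),
           lapply(1:5, function(i) mk(AE_CHANNELS, AE_CHANNELS)))
  dec <- c(lapply(1:5, function(i) mk(AE_CHANNELS, AE_CHANNELS)),
           list(mk(1L, AE_CHANNELS)))
  list(enc = enc, dec = dec)
}

ae_forward <- function(layers, x, keep_cache = FALSE) {
  X <- matrix(x, nrow = 1)
  caches <- list()
  acts <- list()
  for (i in seq_along(layers$enc)) {
    stride <- if (i == 1L) 1L else 2L
    fw <- conv_forward(X, layers$enc[[i]]$W, layers$enc[[i]]$b, stride)
    A <- pmax(fw$Y, 0)
    if (keep_cache) {
      caches[[i]] <- fw
      acts[[i]] <- A
    }
    X <- A
  }
  emb <- as.vector(X)
  dec_caches <- list()
  targets <- rev(AE_ENC_LENS)[-1]  # 94, 188, 375, 750, 1500
  for (i in 1:5) {
    fw <- tconv_forward(X, layers$dec[[i]]$W, layers$dec[[i]]$b, 2L,
                        targets[i])
    if (keep_cache) dec_caches[[i]] <- fw
    X <- fw$Y
  }
  fw <- conv_forward(X, layers$dec[[6]]$W, layers$dec[[6]]$b, 1L)
  if (keep_cache) dec_caches[[6]] <- fw
  list(recon = as.vector(fw$Y), embedding = emb,
       enc_caches = caches, enc_acts = acts, dec_caches = dec_caches)
}

ae_backward <- function(layers, x, fw) {
  m <- length(x)
  dY <- matrix(2 * (fw$recon - x) / m, nrow = 1)
  grads <- list(enc = vector("list", 6), dec = vector("list", 6))
  bw <- conv_backward(fw$dec_caches[[6]], layers$dec[[6]]$W, dY, 1L)
  grads$dec[[6]] <- bw[c("dW", "db")]
  dX <- bw$dX
  targets <- rev(AE_ENC_LENS)[-1]
  for (i in 5:1) {
    bw <- tconv_backward(fw$dec_caches[[i]], layers$dec[[i]]$W, dX, targets[i])
    grads$dec[[i]] <- bw[c("dW", "db")]
    dX <- bw$dX
  }
  for (i in 6:1) {
    dX <- dX * (fw$enc_acts[[i]] > 0)  # ReLU gate
    stride <- if (i == 1L) 1L else 2L
    bw <- conv_backward(fw$enc_caches[[i]], layers$enc[[i]]$W, dX, stride)
    grads$enc[[i]] <- bw[c("dW", "db")]
    dX <- bw$dX
  }
  grads
}

adam_init <- function(layers) {
  rapply(layers, function(p) p * 0, how = "replace")
}

adam_step <- function(layers, grads, m_state, v_state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (part in c("enc", "dec")) {
    for (i in seq_along(layers[[part]])) {
      for (nm in c("W", "b")) {
        g <- grads[[part]][[i]][[if (nm == "W") "dW" else "db"]]
        m_state[[part]][[i]][[nm]] <- beta1 * m_state[[part]][[i]][[nm]] +
          (1 - beta1) * g
        v_state[[part]][[i]][[nm]] <- beta2 * v_state[[part]][[i]][[nm]] +
          (1 - beta2) * g^2
        mhat <- m_state[[part]][[i]][[nm]] / (1 - beta1^t)
        vhat <- v_state[[part]][[i]][[nm]] / (1 - beta2^t)
        layers[[part]][[i]][[nm]] <- layers[[part]][[i]][[nm]] -
          lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(layers = layers, m = m_state, v = v_state)
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Train the time-series autoencoder
#'
#' Trains the 1D-convolutional autoencoder on a set of length-1500 series.
#' The training set is augmented with every series in reversed order
#' (doubling its size). Inputs are scaled by a single global factor (the
#' largest absolute value over the training set) for optimizer stability;
#' the factor is stored in the encoder and applied on [encode()], so it
#' rescales all embeddings uniformly. Reproducible: the same seed, data and
#' configuration give identical weights.
#'
#' @param series list of numeric vectors of length 1500 (or a cohort series
#'   tibble slice with a `values` list column).
#' @param seed integer RNG seed for initialization and batch shuffling.
#' @param epochs training epochs (default 200).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param verbose print the epoch loss every 10 epochs.
#' @return a `motion_encoder` object (layers, scale, loss history).
#' @export
train_autoencoder <- function(series, seed = 1L, epochs = 200L,
                              batch_size = 32L, learning_rate = 1e-3,
                              verbose = FALSE) {
  if (is.data.frame(series)) series <- series$values
  if (length(series) == 0) stop_invalid("no training series")
  lens <- lengths(series)
  if (any(lens != AE_INPUT_LEN)) {
    abort(sprintf("autoencoder input must have length %d (got %s); the architecture is length-specific",
                  AE_INPUT_LEN, paste(unique(lens[lens != AE_INPUT_LEN])[1:min(3, sum(lens != AE_INPUT_LEN))], collapse = ", ")),
          class = c("kinegraph_shape_error", "kinegraph_error"))
  }
  train <- c(series, lapply(series, rev))
  scale <- max(abs(unlist(train)))
  if (scale == 0) scale <- 1
  train <- lapply(train, function(v) v / scale)
  with_local_seed(seed, {
    layers <- ae_init_layers()
    m_state <- adam_init(layers)
    v_state <- adam_init(layers)
    losses <- numeric(epochs)
    step_t <- 0L
    for (ep in seq_len(if (epochs > 0) epochs else 0)) {
      ord <- sample(length(train))
      ep_loss <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        batch <- ord[start:min(start + batch_size - 1, length(ord))]
        gsum <- NULL
        for (s in batch) {
          x <- train[[s]]
          fw <- ae_forward(layers, x, keep_cache = TRUE)
          ep_loss <- ep_loss + mean((fw$recon - x)^2)
          g <- ae_backward(layers, x, fw)
          gsum <- if (is.null(gsum)) g else accumulate_grads(gsum, g)
        }
        gsum <- scale_grads(gsum, 1 / length(batch))
        step_t <- step_t + 1L
        upd <- adam_step(layers, gsum, m_state, v_state, learning_rate, step_t)
        layers <- upd$layers
        m_state <- upd$m
        v_state <- upd$v
      }
      losses[ep] <- ep_loss / length(train)
      if (verbose && ep %% 10 == 0) {
        message(sprintf("epoch %d: mse %.6f", ep, losses[ep]))
      }
    }
    structure(
      list(layers = layers, scale = scale, losses = losses,
           epochs = epochs, seed = seed, n_train = length(train)),
      class = "motion_encoder"
    )
  })
}

accumulate_grads <- function(a, b) {
  for (part in c("enc", "dec")) {
    for (i in seq_along(a[[part]])) {
      a[[part]][[i]]$dW <- a[[part]][[i]]$dW + b[[part]][[i]]$dW
      a[[part]][[i]]$db <- a[[part]][[i]]$db + b[[part]][[i]]$db
    }
  }
  a
}

scale_grads <- function(g, f) {
  for (part in c("enc", "dec")) {
    for (i in seq_along(g[[part]])) {
      g[[part]][[i]]$dW <- g[[part]][[i]]$dW * f
      g[[part]][[i]]$db <- g[[part]][[i]]$db * f
    }
  }
  g
}

#' @export
print.motion_encoder <- function(x, ...) {
  final <- if (x$epochs > 0) sprintf(", final mse %.5f", x$losses[x$epochs])
           else " (untrained)"
  cat(sprintf("<motion_encoder> 6-layer conv1d, embedding %d, %d training series%s\n",
              autoencoder_embedding_dim(), x$n_train, final))
  invisible(x)
}

#' Embedding dimension of the encoder
#'
#' Flattened size of the last encoder activation: 4 channels times the
#' length after five halvings of 1500 (750, 375, 188, 94, 47), i.e. 188.
#'
#' @return integer.
#' @export
autoencoder_embedding_dim <- function() {
  AE_CHANNELS * AE_ENC_LENS[length(AE_ENC_LENS)]
}

#' Encode a series
#'
#' @param encoder a `motion_encoder`.
#' @param values numeric vector of length 1500.
#' @return numeric embedding vector of length 188.
#' @export
encode <- function(encoder, values) {
  if (length(values) != AE_INPUT_LEN) {
    abort(sprintf("encoder input must have length %d, got %d",
                  AE_INPUT_LEN, length(values)),
          class = c("kinegraph_shape_error", "kinegraph_error"))
  }
  ae_forward(encoder$layers, values / encoder$scale)$embedding
}

#' Reconstruct a series through the autoencoder
#'
#' @param encoder a `motion_encoder`.
#' @param values numeric vector of length 1500.
#' @return reconstructed numeric vector of length 1500.
#' @export
reconstruct <- function(encoder, values) {
  if (length(values) != AE_INPUT_LEN) {
    abort(sprintf("encoder input must have length %d, got %d",
                  AE_INPUT_LEN, length(values)),
          class = c("kinegraph_shape_error", "kinegraph_error"))
  }
  ae_forward(encoder$layers, values / encoder$scale)$recon * encoder$scale
}

#' Per-participant embedding vectors for one movement
#'
#' Concatenates the angle-wise encodings (angle id order) of the selected
#' movement for each participant, giving one `N_A * 188` vector per
#' participant-side.
#'
#' @param cohort a resampled `motion_cohort`.
#' @param encoder a `motion_encoder`.
#' @param movement movement id.
#' @param participants optional subset of participant-side ids.
#' @return tibble `participant` + `embedding` list column.
#' @export
cohort_embeddings <- function(cohort, encoder, movement,
                              participants = NULL) {
  ser <- cohort$series[cohort$series$movement == movement, ]
  if (!is.null(participants)) {
    ser <- ser[ser$participant %in% participants, ]
  }
  ser |>
    arrange(.data$participant, .data$angle) |>
    group_by(.data$participant) |>
    summarise(embedding = list(unlist(map(.data$values,
                                          ~ encode(encoder, .x)))),
              .groups = "drop")
}
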