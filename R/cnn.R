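# Small convolutional network for 14 x 14 calcification patches.
#
# A full mobile-scale architecture is degenerate at this input size, so the
# verifier is a four-convolution network with global average pooling:
#   conv 3x3 (1 -> 8)  + ReLU, 2x2 average pool   (14 -> 7)
#   conv 3x3 (8 -> 16) + ReLU, 2x2 average pool   (7 -> 3, floor)
#   conv 3x3 (16 -> 32) + ReLU
#   conv 3x3 (32 -> 64) + ReLU, global average pool -> 64 features
#   fully connected 64 -> 1, sigmoid
# The same trunk doubles as the patch feature extractor (64-dim output).
# Convolutions use zero padding ("same"); weights W[di, dj, c_in, c_out] with
# di/dj indexing the kernel row/column offsets -1, 0, +1.

conv_w_as_matrix <- function(W4) {
  d <- dim(W4)
  m <- aperm(W4, c(3L, 1L, 2L, 4L))  # (ci, di, dj, co)
  dim(m) <- c(d[3L] * 9L, d[4L])
  m
}

# X: (B, H, W, Ci) -> cols ((B*H*W) x (9*Ci)), offset-major, channel fastest
conv_im2col <- function(X) {
  d <- dim(X)
  B <- d[1L]; H <- d[2L]; Wd <- d[3L]; Ci <- d[4L]
  P <- array(0, c(B, H + 2L, Wd + 2L, Ci))
  P[, 1L + seq_len(H), 1L + seq_len(Wd), ] <- X
  blocks <- vector("list", 9L)
  k <- 0L
  for (dj in 1:3) for (di in 1:3) {
    k <- k + 1L
    s <- P[, (seq_len(H)) + (di - 1L), (seq_len(Wd)) + (dj - 1L), ,
           drop = FALSE]
    dim(s) <- c(B * H * Wd, Ci)
    blocks[[k]] <- s
  }
  do.call(cbind, blocks)
}

conv_col2im <- function(dcols, dims) {
  B <- dims[1L]; H <- dims[2L]; Wd <- dims[3L]; Ci <- dims[4L]
  dP <- array(0, c(B, H + 2L, Wd + 2L, Ci))
  k <- 0L
  for (dj in 1:3) for (di in 1:3) {
    k <- k + 1L
    blk <- dcols[, (k - 1L) * Ci + seq_len(Ci), drop = FALSE]
    dim(blk) <- c(B, H, Wd, Ci)
    dP[, seq_len(H) + (di - 1L), seq_len(Wd) + (dj - 1L), ] <-
      dP[, seq_len(H) + (di - 1L), seq_len(Wd) + (dj - 1L), , drop = FALSE] +
      blk
  }
  dP[, 1L + seq_len(H), 1L + seq_len(Wd), , drop = FALSE]
}

conv_fwd <- function(X, W4, b) {
  d <- dim(X)
  cols <- conv_im2col(X)
  Y <- cols %*% conv_w_as_matrix(W4)
  Y <- sweep(Y, 2L, b, `+`)
  dim(Y) <- c(d[1L], d[2L], d[3L], length(b))
  list(Y = Y, cols = cols, in_dims = d)
}

conv_bwd <- function(cache, W4, dY) {
  d <- dim(dY)
  dYm <- dY
  dim(dYm) <- c(d[1L] * d[2L] * d[3L], d[4L])
  Wm <- conv_w_as_matrix(W4)
  dWm <- crossprod(cache$cols, dYm)            # (9*Ci) x Co
  db <- colSums(dYm)
  ci <- dim(W4)[3L]
  dW4 <- array(dWm, c(ci, 3L, 3L, d[4L]))
  dW4 <- aperm(dW4, c(2L, 3L, 1L, 4L))
  dX <- conv_col2im(dYm %*% t(Wm), cache$in_dims)
  list(dW = dW4, db = db, dX = dX)
}

avgpool2_fwd <- function(X) {
  d <- dim(X)
  H2 <- d[2L] %/% 2L; W2 <- d[3L] %/% 2L
  o1 <- seq.int(1L, by = 2L, length.out = H2)
  o2 <- seq.int(1L, by = 2L, length.out = W2)
  (X[, o1, o2, , drop = FALSE] + X[, o1 + 1L, o2, , drop = FALSE] +
     X[, o1, o2 + 1L, , drop = FALSE] + X[, o1 + 1L, o2 + 1L, , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dY, in_dims) {
  dX <- array(0, in_dims)
  d <- dim(dY)
  o1 <- seq.int(1L, by = 2L, length.out = d[2L])
  o2 <- seq.int(1L, by = 2L, length.out = d[3L])
  q <- dY / 4
  for (a in 0:1) for (b in 0:1) {
    dX[, o1 + a, o2 + b, ] <- dX[, o1 + a, o2 + b, , drop = FALSE] + q
  }
  dX
}

gap_fwd <- function(X) {
  d <- dim(X)
  X3 <- X
  dim(X3) <- c(d[1L], d[2L] * d[3L], d[4L])
  colMeans(aperm(X3, c(2L, 1L, 3L)))           # (B, C)
}

gap_bwd <- function(dG, in_dims) {
  B <- in_dims[1L]; HW <- in_dims[2L] * in_dims[3L]; C <- in_dims[4L]
  dX <- array(0, c(B, HW, C))
  for (m in seq_len(HW)) dX[, m, ] <- dG / HW
  dim(dX) <- in_dims
  dX
}

cnn_init_params <- function(channels = c(8L, 16L, 32L, 64L), seed = 0L) {
  set.seed(seed)
  cin <- c(1L, channels[-length(channels)])
  params <- list()
  for (l in seq_along(channels)) {
    fan_in <- 9L * cin[l]
    params[[paste0("Wc", l)]] <-
      array(rnorm(9L * cin[l] * channels[l], sd = sqrt(2 / fan_in)),
            c(3L, 3L, cin[l], channels[l]))
    params[[paste0("bc", l)]] <- rep(0, channels[l])
  }
  params$Wfc <- matrix(rnorm(channels[length(channels)], sd = 0.1), ncol = 1L)
  params$bfc <- 0
  params
}

# forward through the conv trunk; returns feature matrix (B x C_last) and,
# optionally, the caches needed for backprop
cnn_trunk_fwd <- function(params, X, n_layers = 4L, keep_cache = FALSE) {
  caches <- list()
  H <- X
  for (l in seq_len(n_layers)) {
    cv <- conv_fwd(H, params[[paste0("Wc", l)]], params[[paste0("bc", l)]])
    A <- pmax(cv$Y, 0)
    cache <- list(conv = cv, pre = cv$Y, pooled = FALSE, relu_in_dims = dim(A))
    if (l <= 2L) {
      cache$pool_in_dims <- dim(A)
      A <- avgpool2_fwd(A)
      cache$pooled <- TRUE
    }
    if (keep_cache) caches[[l]] <- cache
    H <- A
  }
  feats <- gap_fwd(H)
  list(features = feats, last_dims = dim(H), caches = caches)
}

cnn_verifier_fwd <- function(params, X, keep_cache = FALSE) {
  tr <- cnn_trunk_fwd(params, X, keep_cache = keep_cache)
  logits <- tr$features %*% params$Wfc + params$bfc
  probs <- 1 / (1 + exp(-logits))
  list(probs = as.numeric(probs), logits = as.numeric(logits), trunk = tr)
}

cnn_verifier_bwd <- function(params, X, fwd, dlogit) {
  grads <- list()
  tr <- fwd$trunk
  grads$Wfc <- crossprod(tr$features, matrix(dlogit, ncol = 1L))
  grads$bfc <- sum(dlogit)
  dfeat <- matrix(dlogit, ncol = 1L) %*% t(params$Wfc)
  dH <- gap_bwd(dfeat, tr$last_dims)
  for (l in 4:1) {
    cache <- tr$caches[[l]]
    if (cache$pooled) dH <- avgpool2_bwd(dH, cache$pool_in_dims)
    dH <- dH * (cache$pre > 0)
    bw <- conv_bwd(cache$conv, params[[paste0("Wc", l)]], dH)
    grads[[paste0("Wc", l)]] <- bw$dW
    grads[[paste0("bc", l)]] <- bw$db
    dH <- bw$dX
  }
  grads
}

patches_to_array <- function(patches, d) {
  if (is.array(patches) && length(dim(patches)) == 3L) {
    B <- dim(patches)[1L]
    assert_that(all(dim(patches)[2:3] == d), "patch size mismatch: expected ",
                d, "x", d, class = "calcgraph_shape_error")
    X <- array(patches, c(B, d, d, 1L))
    return(X)
  }
  assert_that(is.list(patches) && length(patches) > 0, "empty patch set")
  assert_that(all(vapply(patches, function(p) all(dim(p) == d), TRUE)),
              "patch size mismatch: expected ", d, "x", d,
              class = "calcgraph_shape_error")
  B <- length(patches)
  X <- array(0, c(B, d, d, 1L))
  for (i in seq_len(B)) X[i, , , 1L] <- patches[[i]]
  X
}

#' Per-sample binary cross-entropy of the patch verifier
#'
#' The verifier training objective: mean over patches of
#' `-(y log p + (1 - y) log(1 - p))`. A verifier that outputs 0.5 everywhere
#' scores `ln 2` per sample; a perfect one approaches 0.
#'
#' @param probs Predicted probabilities in (0, 1).
#' @param labels Binary labels (0/1).
#' @param eps Clamping bound for numerical safety.
#' @return Mean per-sample loss (scalar).
#' @export
verifier_loss <- function(probs, labels, eps = 1e-12) {
  p <- clamp(probs, eps, 1 - eps)
  mean(-(labels * log(p) + (1 - labels) * log(1 - p)))
}

#' Train the patch-verifier CNN
#'
#' Fits the four-convolution verifier network to labelled `D x D` patches
#' (1 = true calcification, 0 = false detection) by minimising binary
#' cross-entropy with Adam. Training is fully deterministic given `seed`.
#'
#' @param patches List of `D x D` matrices or a `(B, D, D)` array.
#' @param labels Binary vector, one per patch; both classes must be present.
#' @param patch_size Patch side length D (default 14).
#' @param epochs Training epochs (default 100).
#' @param lr Adam learning rate.
#' @param seed RNG seed for weight initialisation.
#' @param channels Channel widths of the four convolution layers.
#'
#' @return A `calc_verifier` model; `$training$loss_history` records the
#'   per-epoch loss.
#' @export
train_verifier <- function(patches, labels, patch_size = 14L, epochs = 100L,
                           lr = 1e-3, seed = 0L,
                           channels = c(8L, 16L, 32L, 64L)) {
  X <- patches_to_array(patches, patch_size)
  labels <- as.numeric(labels)
  assert_that(length(labels) == dim(X)[1L], "labels/patches length mismatch")
  assert_that(length(unique(labels)) == 2L,
              "verifier training needs both classes present",
              class = "calcgraph_degenerate_error")
  # normalize intensities to a stable scale
  scale <- max(X)
  if (scale > 0) X <- X / scale
  params <- cnn_init_params(channels, seed = seed)
  state <- adam_init(params)
  B <- dim(X)[1L]
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fwd <- cnn_verifier_fwd(params, X, keep_cache = TRUE)
    history[ep] <- verifier_loss(fwd$probs, labels)
    dlogit <- (fwd$probs - labels) / B
    grads <- cnn_verifier_bwd(params, X, fwd, dlogit)
    st <- adam_step(params, grads, state, lr)
    params <- st$params
    state <- st$state
  }
  structure(list(params = params, channels = channels,
                 patch_size = as.integer(patch_size), input_scale = scale,
                 architecture_tag = "conv4-gap",
                 training = list(epochs = epochs, seed = seed, lr = lr,
                                 loss_history = history,
                                 final_loss = history[epochs])),
            class = "calc_verifier")
}

#' Score patches with a trained verifier
#'
#' @param model A `calc_verifier` from [train_verifier()].
#' @param patches List of patches or `(B, D, D)` array.
#' @return Vector of probabilities in (0, 1).
#' @export
predict_verifier <- function(model, patches) {
  X <- patches_to_array(patches, model$patch_size)
  if (model$input_scale > 0) X <- X / model$input_scale
  cnn_verifier_fwd(model$params, X)$probs
}

#' Build a patch feature extractor from a verifier trunk
#'
#' Reuses the convolutional trunk of a trained verifier and taps the
#' globally-average-pooled feature map of `tap_layer` (default: the last
#' convolution, 64 features).
#'
#' @param model A `calc_verifier`.
#' @param tap_layer Convolution layer to tap (1-4).
#' @return A `calc_feature_extractor`.
#' @export
feature_extractor <- function(model, tap_layer = 4L) {
  assert_that(tap_layer >= 1L && tap_layer <= length(model$channels),
              "tap_layer out of range")
  structure(list(params = model$params, channels = model$channels,
                 patch_size = model$patch_size,
                 input_scale = model$input_scale,
                 tap_layer = as.integer(tap_layer),
                 out_dim = model$channels[tap_layer]),
            class = "calc_feature_extractor")
}

#' Extract deep patch features
#'
#' Runs each patch through the extractor trunk in evaluation mode and returns
#' the pooled feature map at the tap layer; deterministic for fixed weights.
#'
#' @param patches List of patches or `(B, D, D)` array.
#' @param extractor A `calc_feature_extractor` from [feature_extractor()].
#' @return `N x out_dim` feature matrix.
#' @export
extract_patch_features <- function(patches, extractor) {
  X <- patches_to_array(patches, extractor$patch_size)
  if (extractor$input_scale > 0) X <- X / extractor$input_scale
  tr <- cnn_trunk_fwd(extractor$params, X, n_layers = extractor$tap_layer)
  tr$features
}
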