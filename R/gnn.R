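#' Model configuration for the edge-conditioned graph classifier
#'
#' The classifier stacks three edge-conditioned convolution (ECC) layers, a
#' readout, and a two-layer fully connected head ending in an elementwise
#' sigmoid over the five class logits (the probabilities are *not*
#' renormalised to sum to one; the predicted class is the argmax). Each ECC
#' layer generates its per-edge filter matrix from the 3-dimensional
#' geometric edge label through a two-layer feed-forward filter network with
#' `tanh` hidden units.
#'
#' Readout modes: `"mean"` (column mean over nodes; permutation invariant,
#' the default for variable-size graphs) or `"flatten"` (nodes in `(y, x)`
#' order, truncated to the `n_max` highest detector scores and zero-padded,
#' then row-major flattened).
#'
#' @param d_feat Width of the static node features (9 geometric or 64 patch).
#' @param d_emb Width of the learnable spatial embedding (0 disables it).
#' @param ecc_dims Output widths of the three ECC layers.
#' @param filter_hidden Hidden width of the edge filter networks.
#' @param head_hidden Hidden width of the fully connected head.
#' @param readout `"mean"` or `"flatten"`.
#' @param n_max Node capacity of the flatten readout (default 128).
#' @param n_classes Number of classes (5).
#' @param class_names Ordered class names.
#' @return A `gnn_config` list.
#' @export
gnn_config <- function(d_feat = 9L, d_emb = 4L, ecc_dims = c(10L, 10L, 10L),
                       filter_hidden = 6L, head_hidden = 32L,
                       readout = c("mean", "flatten"), n_max = 128L,
                       n_classes = 5L, class_names = calc_classes()) {
  readout <- match.arg(readout)
  assert_that(length(ecc_dims) >= 1L, "need at least one ECC layer")
  assert_that(length(class_names) == n_classes, "class_names length mismatch")
  structure(list(d_feat = as.integer(d_feat), d_emb = as.integer(d_emb),
                 ecc_dims = as.integer(ecc_dims),
                 filter_hidden = as.integer(filter_hidden),
                 head_hidden = as.integer(head_hidden), readout = readout,
                 n_max = as.integer(n_max), n_classes = as.integer(n_classes),
                 class_names = class_names),
            class = "gnn_config")
}

#' Image-pipeline model configuration
#'
#' Defaults matching the full image pipeline: 64 deep patch features fused
#' with a 16-dimensional spatial embedding into 80-dimensional node features.
#'
#' @param ... Overrides passed to [gnn_config()].
#' @return A `gnn_config`.
#' @export
gnn_config_image <- function(...) {
  gnn_config(d_feat = 64L, d_emb = 16L, ecc_dims = c(32L, 32L, 32L),
             filter_hidden = 16L, head_hidden = 64L, ...)
}

#' Training configuration
#'
#' Adam with an initial learning rate of 3e-4, halved every `decay_every`
#' epochs, 100 epochs, minibatches of 32 graphs, and focal loss with
#' focusing parameter `gamma` (default 2; `gamma = 0` recovers plain
#' cross-entropy summed over the sigmoid components).
#'
#' @param epochs Number of epochs.
#' @param lr Initial Adam learning rate.
#' @param decay_every Epoch interval of the step decay.
#' @param decay_factor Multiplicative decay factor.
#' @param batch_size Graphs per minibatch.
#' @param gamma Focal focusing parameter (>= 0).
#' @param alpha Optional per-class weights (length 5; default uniform 1).
#' @param clip_norm Global gradient-norm clip (Inf disables).
#' @param seed RNG seed controlling init and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, lr = 3e-4, decay_every = 30L,
                         decay_factor = 0.5, batch_size = 32L, gamma = 2,
                         alpha = NULL, clip_norm = 5, seed = 0L) {
  assert_that(gamma >= 0, "gamma must be >= 0",
              class = "calcgraph_config_error")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 decay_every = as.integer(decay_every),
                 decay_factor = decay_factor,
                 batch_size = as.integer(batch_size), gamma = gamma,
                 alpha = alpha, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Training settings for the synthetic graph benchmark
#'
#' The synthetic graphs are small and carry low-dimensional geometric node
#' features, so the benchmark uses a larger learning rate (1e-3), a slower
#' step decay (halved every 50 epochs) and 150 epochs compared with the
#' image schedule.
#'
#' @param seed RNG seed.
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
benchmark_train_config <- function(seed = 0L, ...) {
  train_config(epochs = 150L, lr = 1e-3, decay_every = 50L, seed = seed, ...)
}

#' Focal loss over the five sigmoid outputs
#'
#' Per component `c`: `p_t = p_c` if the one-hot label has `y_c = 1`, else
#' `p_t = 1 - p_c`, and the loss term is
#' `-alpha_c (1 - p_t)^gamma log(p_t)`; the total is the sum over the five
#' components, with `p_t` clamped away from 0 and 1 for numerical safety.
#' With `gamma = 0` this is exactly the summed binary cross-entropy.
#'
#' @param probs Length-5 probability vector in (0, 1).
#' @param y One-hot label vector (exactly one 1) or class index (1-based).
#' @param gamma Focusing parameter.
#' @param alpha Optional per-class weights.
#' @param eps Clamping bound.
#' @return Scalar loss.
#' @export
focal_loss <- function(probs, y, gamma = 2, alpha = NULL, eps = 1e-7) {
  k <- length(probs)
  if (length(y) == 1L) {
    yi <- integer(k); yi[y] <- 1L; y <- yi
  }
  assert_that(sum(y == 1) == 1L && all(y %in% c(0, 1)),
              "y must be one-hot")
  alpha <- alpha %||% rep(1, k)
  pt <- ifelse(y == 1, probs, 1 - probs)
  pt <- clamp(pt, eps, 1 - eps)
  sum(alpha * (1 - pt)^gamma * (-log(pt)))
}

#' One edge-conditioned convolution layer (pre-activation)
#'
#' Computes, for every node `i`,
#' `X_l(i) = (1/|N(i)|) * sum_{j in N(i)} F_l(L_{j,i}) X_{l-1}(j) + b_l`,
#' where the filter matrix `F_l(L)` is generated from the edge label by the
#' layer's two-layer filter network. Returned without nonlinearity; the
#' network applies ReLU between layers.
#'
#' @param graph A `calcification_graph`.
#' @param layer Layer weights: list with `W1` (3 x h), `c1` (h), `W2`
#'   (h x d_out*d_in), `c2` (d_out*d_in), `b` (d_out).
#' @param X_prev `N x d_in` input node features.
#' @return `N x d_out` matrix.
#' @export
ecc_forward <- function(graph, layer, X_prev) {
  assert_that(ncol(X_prev) * length(layer$b) == length(layer$c2),
              "feature width does not match layer filter dimensions",
              class = "calcgraph_shape_error")
  deg <- tabulate(graph$edge_dst, nbins = nrow(X_prev))
  assert_that(all(deg >= 1L), "every node needs at least one in-edge")
  .cg_ecc_forward(X_prev, graph$edge_src - 1L, graph$edge_dst - 1L,
                  graph$edge_labels, as.numeric(deg),
                  as.matrix(layer$W1), as.matrix(layer$c1),
                  as.matrix(layer$W2), as.matrix(layer$c2),
                  as.matrix(layer$b))
}

#' Graph readout
#'
#' `"flatten"`: nodes (already in `(y, x)` order) are truncated to the
#' `n_max` rows with the highest scores (ties towards the earlier node),
#' zero-padded to `n_max`, and concatenated row-major. `"mean"`: column
#' means, a permutation-invariant length-`D` vector.
#'
#' @param node_features `N x D` matrix.
#' @param mode `"flatten"` or `"mean"`.
#' @param scores Per-node scores used for truncation (default all equal, so
#'   truncation keeps the first `n_max` nodes).
#' @param n_max Capacity of the flatten readout.
#' @return Numeric vector (length `n_max * D` or `D`).
#' @export
readout <- function(node_features, mode = c("flatten", "mean"),
                    scores = NULL, n_max = 128L) {
  mode <- match.arg(mode)
  X <- as.matrix(node_features)
  if (mode == "mean") return(colMeans(X))
  keep <- readout_keep(nrow(X), scores, n_max)
  out <- matrix(0, n_max, ncol(X))
  out[seq_along(keep), ] <- X[keep, , drop = FALSE]
  as.numeric(t(out))
}

# indices kept by the flatten readout: top-n_max scores, in node order
readout_keep <- function(n, scores, n_max) {
  if (n <= n_max) return(seq_len(n))
  scores <- scores %||% rep(1, n)
  sort(order(scores, decreasing = TRUE)[seq_len(n_max)])
}

#' Sigmoid classification head
#'
#' `y_hat = sigmoid(x %*% W_fc + b_fc)` over the five class logits. The
#' components are independent sigmoids (they need not sum to one); the
#' predicted class is the argmax.
#'
#' @param representation Graph representation vector.
#' @param W_fc Weight matrix (`length(representation) x 5`).
#' @param b_fc Bias vector (5).
#' @param class_names Class name order.
#' @return A `class_probabilities` list with `probs` and `predicted`.
#' @export
classify <- function(representation, W_fc, b_fc,
                     class_names = calc_classes()) {
  logits <- as.numeric(representation %*% W_fc + b_fc)
  assert_that(all(is.finite(logits)), "non-finite logits in classifier head",
              class = "calcgraph_numeric_error")
  probs <- 1 / (1 + exp(-logits))
  names(probs) <- class_names
  structure(list(probs = probs,
                 predicted = factor(class_names[which.max(probs)],
                                    levels = class_names)),
            class = "class_probabilities")
}

#' @export
print.class_probabilities <- function(x, ...) {
  cat("<class_probabilities> predicted:", as.character(x$predicted), "\n")
  print(round(x$probs, 4))
  invisible(x)
}

# ---- parameter initialisation -------------------------------------------

gnn_init_params <- function(config, seed = 0L) {
  set.seed(seed)
  p <- list()
  d0 <- config$d_feat + config$d_emb
  if (config$d_emb > 0L) {
    p$Wemb <- matrix(rnorm(2L * config$d_emb, sd = 0.5), 2L, config$d_emb)
    p$bemb <- matrix(0, config$d_emb, 1L)
  }
  din <- d0
  h <- config$filter_hidden
  for (l in seq_along(config$ecc_dims)) {
    dout <- config$ecc_dims[l]
    p[[paste0("W1_", l)]] <- matrix(rnorm(3L * h, sd = 1), 3L, h)
    p[[paste0("c1_", l)]] <- matrix(0, h, 1L)
    p[[paste0("W2_", l)]] <- matrix(rnorm(h * dout * din,
                                          sd = 0.1 / sqrt(h)),
                                    h, dout * din)
    # bias the generated filter towards (truncated) identity so the initial
    # layer approximates a neighbourhood average of its input features
    eye <- diag(1, dout, din)
    p[[paste0("c2_", l)]] <- matrix(as.numeric(eye), dout * din, 1L)
    p[[paste0("b_", l)]] <- matrix(0, dout, 1L)
    din <- dout
  }
  dr <- if (config$readout == "mean") din else config$n_max * din
  p$Whid <- matrix(rnorm(dr * config$head_hidden, sd = sqrt(2 / dr)),
                   dr, config$head_hidden)
  p$chid <- matrix(0, config$head_hidden, 1L)
  p$Wout <- matrix(rnorm(config$head_hidden * config$n_classes,
                         sd = sqrt(1 / config$head_hidden)),
                   config$head_hidden, config$n_classes)
  p$cout <- matrix(0, config$n_classes, 1L)
  p
}

# ---- graph preparation for the C++ core ---------------------------------

gnn_prepare_graph <- function(graph, config, label_required = FALSE) {
  n <- nrow(graph$coords)
  assert_that(ncol(graph$features) == config$d_feat,
              "graph feature width ", ncol(graph$features),
              " does not match model d_feat ", config$d_feat,
              class = "calcgraph_shape_error")
  deg <- tabulate(graph$edge_dst, nbins = n)
  y <- if (!is.null(graph$label)) {
    match(as.character(graph$label), config$class_names) - 1L
  } else {
    if (label_required) stop_calc("graph has no label",
                                  class = "calcgraph_degenerate_error")
    -1L
  }
  sh <- graph$image_shape
  list(Xt = t(as.matrix(graph$features)),
       St = rbind(graph$coords[, 1L] / sh[2L], graph$coords[, 2L] / sh[1L]),
       src = graph$edge_src - 1L, dst = graph$edge_dst - 1L,
       ELt = t(graph$edge_labels), deg = as.numeric(deg),
       keep = readout_keep(n, graph$scores, config$n_max) - 1L,
       y = as.integer(y))
}

gnn_cpp_config <- function(config, tc = NULL) {
  list(n_layers = length(config$ecc_dims),
       readout = if (config$readout == "mean") 0L else 1L,
       nmax = config$n_max,
       gamma = if (is.null(tc)) 0 else tc$gamma,
       alpha = if (is.null(tc) || is.null(tc$alpha)) rep(1, config$n_classes)
               else tc$alpha,
       eps = 1e-7,
       use_emb = as.integer(config$d_emb > 0L))
}

# ---- training ------------------------------------------------------------

#' Train the edge-conditioned graph classifier
#'
#' Minimises the mean focal loss over labelled calcification graphs with
#' Adam. The spatial embedding, ECC layers and head are optimised jointly;
#' patch features (or geometric features) enter as fixed node inputs.
#' Training is fully deterministic given `train_config$seed`.
#'
#' @param graphs List of labelled `calcification_graph`s (at least two
#'   classes present).
#' @param config A [gnn_config()].
#' @param tc A [train_config()].
#' @param verbose Print the loss every 10 epochs?
#' @return A `calc_gnn` model (weights, configs, seed, loss history).
#' @export
train_gnn <- function(graphs, config = gnn_config(), tc = train_config(),
                      verbose = FALSE) {
  assert_that(length(graphs) >= 2L, "need at least two training graphs")
  labels <- vapply(graphs, function(g) as.character(g$label %||% NA_character_),
                   "")
  assert_that(!anyNA(labels), "all training graphs must be labelled",
              class = "calcgraph_degenerate_error")
  assert_that(length(unique(labels)) >= 2L,
              "training set contains a single class",
              class = "calcgraph_degenerate_error")
  prepared <- lapply(graphs, gnn_prepare_graph, config = config,
                     label_required = TRUE)
  cppcfg <- gnn_cpp_config(config, tc)
  params <- gnn_init_params(config, seed = tc$seed)
  state <- adam_init(params)
  set.seed(tc$seed + 1L)
  n <- length(prepared)
  history <- data.frame(epoch = seq_len(tc$epochs), loss = NA_real_,
                        accuracy = NA_real_, lr = NA_real_)
  for (ep in seq_len(tc$epochs)) {
    lr <- tc$lr * tc$decay_factor^((ep - 1L) %/% tc$decay_every)
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq.int(1L, n, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n)]
      res <- .cg_batch_grad(params, prepared[idx], cppcfg)
      grads <- lapply(res$grads, function(g) g / length(idx))
      if (is.finite(tc$clip_norm)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
        if (gn > tc$clip_norm) {
          grads <- lapply(grads, function(g) g * (tc$clip_norm / gn))
        }
      }
      st <- adam_step(params, grads, state, lr)
      params <- st$params
      state <- st$state
      ep_loss <- ep_loss + res$loss
      ep_correct <- ep_correct + res$correct
    }
    history$loss[ep] <- ep_loss / n
    history$accuracy[ep] <- ep_correct / n
    history$lr[ep] <- lr
    if (verbose && (ep %% 10L == 0L || ep == 1L)) {
      message(sprintf("epoch %3d  loss %.4f  train acc %.3f", ep,
                      history$loss[ep], history$accuracy[ep]))
    }
  }
  structure(list(params = params, config = config, train_config = tc,
                 class_names = config$class_names, history = history,
                 n_train = n),
            class = "calc_gnn")
}

#' @export
print.calc_gnn <- function(x, ...) {
  cat(sprintf(
    "<calc_gnn> %d ECC layers (%s), readout %s, trained %d epochs on %d graphs\n",
    length(x$config$ecc_dims), paste(x$config$ecc_dims, collapse = "-"),
    x$config$readout, x$train_config$epochs, x$n_train))
  cat(sprintf("final training loss %.4f, accuracy %.3f\n",
              tail(x$history$loss, 1), tail(x$history$accuracy, 1)))
  invisible(x)
}

#' Predict the distribution class of a calcification graph
#'
#' Deterministic forward pass; returns all five sigmoid probabilities and the
#' argmax class.
#'
#' @param model A `calc_gnn` from [train_gnn()].
#' @param graph A `calcification_graph`, or a list of them.
#' @return A `class_probabilities` (or, for a list input, an `n x 5`
#'   probability matrix with a `"predicted"` attribute).
#' @export
predict_gnn <- function(model, graph) {
  cppcfg <- gnn_cpp_config(model$config)
  if (inherits(graph, "calcification_graph")) {
    prep <- gnn_prepare_graph(graph, model$config)
    fw <- .cg_forward(model$params, prep, cppcfg)
    probs <- as.numeric(fw$probs)
    names(probs) <- model$class_names
    return(structure(list(probs = probs,
                          predicted = factor(
                            model$class_names[which.max(probs)],
                            levels = model$class_names)),
                     class = "class_probabilities"))
  }
  prepared <- lapply(graph, gnn_prepare_graph, config = model$config)
  res <- .cg_batch_eval(model$params, prepared, cppcfg)
  probs <- res$probs
  colnames(probs) <- model$class_names
  attr(probs, "predicted") <- factor(
    model$class_names[max.col(probs, ties.method = "first")],
    levels = model$class_names)
  probs
}

#' Save / load a trained model
#'
#' The file stores the weights together with the full model and training
#' configuration, seed and class-name order; `predict_gnn()` on a reloaded
#' model is bit-identical to the original.
#'
#' @param model A `calc_gnn`.
#' @param path File path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  assert_that(inherits(model, "calc_gnn"), "not a calc_gnn model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  assert_that(inherits(m, "calc_gnn"), "file does not contain a calc_gnn")
  m
}
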