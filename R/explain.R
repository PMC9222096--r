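#' Per-node saliency for a predicted class
#'
#' Gradient-based node importance (a graph adaptation of class-activation
#' mapping): the gradient of the target-class logit with respect to the last
#' ECC layer's node activations is averaged over nodes to give per-channel
#' weights; node importance is the ReLU of the weighted channel sum,
#' min--max normalised to \[0, 1\]. If the raw scores are constant (e.g. a
#' saturated model with zero gradient) the result is all zeros, with a
#' warning. The alternative `"gradxact"` mode scores each node by the ReLU
#' of the elementwise gradient-times-activation sum.
#'
#' @param model A `calc_gnn`.
#' @param graph A `calcification_graph`.
#' @param target_class Class index (1-5) or name; defaults to the predicted
#'   class.
#' @param mode `"gradcam"` (channel-mean gradients) or `"gradxact"`
#'   (per-node gradient times activation).
#' @param layer Hook point: `"input"` (the fused node features plus spatial
#'   embedding, the default) or `"last"` (the last ECC layer's activations).
#' @return A `node_saliency` object: `scores` in \[0, 1\] (length N),
#'   `target_class`, `graph_ref`.
#' @export
node_saliency <- function(model, graph, target_class = NULL,
                          mode = c("gradcam", "gradxact"),
                          layer = c("input", "last")) {
  mode <- match.arg(mode)
  layer <- match.arg(layer)
  cfg <- model$config
  prep <- gnn_prepare_graph(graph, cfg)
  fw <- .cg_forward(model$params, prep, gnn_cpp_config(cfg))
  if (is.null(target_class)) target_class <- which.max(fw$probs)
  if (is.character(target_class)) {
    target_class <- match(target_class, model$class_names)
  }
  assert_that(!is.na(target_class) && target_class >= 1L &&
                target_class <= cfg$n_classes,
              "target_class out of range", class = "calcgraph_range_error")
  if (layer == "input") {
    ig <- .cg_input_grad(model$params, prep, gnn_cpp_config(cfg),
                         target_class - 1L)
    H <- ig$H0
    dH <- ig$dH0
    n <- nrow(H)
  } else {
    H <- fw$H_last                            # N x D
    n <- nrow(H); D <- ncol(H)
    # gradient of the target logit w.r.t. H through the head and readout
    dhid <- model$params$Wout[, target_class]
    dhpre <- dhid * as.numeric(fw$hpre > 0)
    dr <- as.numeric(model$params$Whid %*% dhpre)
    dH <- matrix(0, n, D)
    if (cfg$readout == "mean") {
      dH <- matrix(rep(dr / n, each = n), n, D)
    } else {
      keep <- readout_keep(n, graph$scores, cfg$n_max)
      for (s in seq_along(keep)) {
        dH[keep[s], ] <- dr[(s - 1L) * D + seq_len(D)]
      }
    }
  }
  raw <- if (mode == "gradcam") {
    w <- colMeans(dH)
    pmax(as.numeric(H %*% w), 0)
  } else {
    pmax(rowSums(dH * H), 0)
  }
  rng <- range(raw)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("constant saliency scores (zero gradient); returning all zeros")
    scores <- rep(0, n)
  } else {
    scores <- (raw - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(scores = scores, target_class = as.integer(target_class),
                 class_name = model$class_names[target_class],
                 mode = mode, graph_ref = graph$image_id),
            class = "node_saliency")
}

#' @export
print.node_saliency <- function(x, ...) {
  cat(sprintf("<node_saliency> %s (%s): %d nodes, mean score %.3f\n",
              x$class_name, x$mode, length(x$scores), mean(x$scores)))
  invisible(x)
}

#' Blue-yellow-red saliency colormap
#'
#' Maps importance in \[0, 1\] to colours: blue (low) through yellow (0.5)
#' to red (high).
#'
#' @param t Numeric vector in \[0, 1\].
#' @return `length(t) x 3` matrix of RGB values in \[0, 1\].
#' @export
saliency_colors <- function(t) {
  t <- clamp(t, 0, 1)
  lo <- t <= 0.5
  u <- ifelse(lo, t * 2, (t - 0.5) * 2)
  r <- ifelse(lo, u, 1)
  g <- ifelse(lo, u, 1 - u)
  b <- ifelse(lo, 1 - u, 0)
  cbind(r = r, g = g, b = b)
}

#' Render a saliency overlay image
#'
#' Draws the graph nodes on top of the grayscale image as filled disks
#' coloured by [saliency_colors()], and writes a PNG. Output is
#' deterministic: re-rendering identical inputs produces a byte-identical
#' file.
#'
#' @param image The source [mammogram_image()].
#' @param graph The `calcification_graph` built from that image.
#' @param saliency A [node_saliency()] for the graph.
#' @param out Output PNG path.
#' @param radius Node disk radius in pixels.
#' @return `out`, invisibly.
#' @export
render_overlay <- function(image, graph, saliency, out, radius = 4L) {
  assert_that(identical(graph$image_id, image$source_id),
              "graph provenance (", graph$image_id,
              ") does not match image (", image$source_id, ")",
              class = "calcgraph_consistency_error")
  assert_that(length(saliency$scores) == nrow(graph$coords),
              "saliency length does not match node count",
              class = "calcgraph_consistency_error")
  px <- image$pixels
  base <- px / max(px, 1e-12)
  rgb <- array(rep(base, 3L), c(dim(px), 3L))
  cols <- saliency_colors(saliency$scores)
  off <- which(outer(-radius:radius, -radius:radius,
                     function(a, b) a^2 + b^2 <= radius^2),
               arr.ind = TRUE) - radius - 1L
  for (i in seq_len(nrow(graph$coords))) {
    rr <- graph$coords[i, 2L] + 1L + off[, 1L]
    cc <- graph$coords[i, 1L] + 1L + off[, 2L]
    okk <- rr >= 1 & rr <= nrow(px) & cc >= 1 & cc <= ncol(px)
    for (ch in 1:3) {
      rgb[cbind(rr[okk], cc[okk], ch)] <- cols[i, ch]
    }
  }
  png::writePNG(rgb, out)
  invisible(out)
}
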