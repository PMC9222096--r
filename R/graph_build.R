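#' k-nearest-neighbour adjacency from 2D point coordinates
#'
#' `A[i, j] = 1` iff `j` is among the `k` smallest Euclidean distances from
#' `i` (self excluded), then symmetrised by `A <- max(A, t(A))` so the graph
#' neighbourhood is defined both ways. Distance ties are broken towards the
#' lower node index. When `N - 1 < k` all off-diagonal pairs are connected;
#' the diagonal is always zero. Duplicate coordinates (distance 0) are
#' allowed.
#'
#' @param coords `N x 2` matrix of `(x, y)` coordinates.
#' @param k Neighbour count (default 8).
#' @return `N x N` binary symmetric matrix.
#' @export
knn_adjacency <- function(coords, k = 8L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  assert_that(n >= 1L && k >= 1L, "need N >= 1 and k >= 1")
  A <- matrix(0L, n, n)
  if (n == 1L) return(A)
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d2[i, others], others)]
    A[i, ord[seq_len(min(k, n - 1L))]] <- 1L
  }
  pmax(A, t(A))
}

#' Geometric edge labels for a calcification graph
#'
#' For each directed edge `j -> i` (a message from neighbour `j` into `i`)
#' the label is `(dx, dy, d)` where `dx = (x_j - x_i) / diag`,
#' `dy = (y_j - y_i) / diag` and `d` the Euclidean distance normalised by the
#' image diagonal `sqrt(H^2 + W^2)`. Offsets of the reverse edge are the
#' negatives; `d` is shared. Directed edges are enumerated by destination,
#' then source, for determinism.
#'
#' @param coords `N x 2` matrix of `(x, y)` pixel coordinates.
#' @param adjacency `N x N` binary symmetric matrix.
#' @param image_shape `(H, W)` of the source image.
#' @return List with `src`, `dst` (1-based node indices) and `labels`
#'   (`E x 3` matrix, columns `dx, dy, d`).
#' @export
compute_edge_labels <- function(coords, adjacency, image_shape) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  diag_len <- image_diagonal(image_shape)
  src <- integer(0); dst <- integer(0)
  for (i in seq_len(n)) {
    nb <- which(adjacency[i, ] > 0)
    src <- c(src, nb)
    dst <- c(dst, rep(i, length(nb)))
  }
  if (length(src) == 0L) {
    return(list(src = integer(0), dst = integer(0),
                labels = matrix(0, 0L, 3L,
                                dimnames = list(NULL, c("dx", "dy", "d")))))
  }
  dxy <- (coords[src, , drop = FALSE] - coords[dst, , drop = FALSE]) / diag_len
  labels <- cbind(dx = dxy[, 1L], dy = dxy[, 2L],
                  d = sqrt(rowSums(dxy^2)))
  list(src = src, dst = dst, labels = labels)
}

#' Learnable spatial embedding of node coordinates
#'
#' @param d_emb Embedding dimension.
#' @param seed RNG seed for the initial weights.
#' @return A `spatial_embedder` with weights `W_emb` (2 x d_emb) and bias
#'   `b_emb`.
#' @export
spatial_embedder <- function(d_emb = 16L, seed = 0L) {
  set.seed(seed)
  structure(list(W_emb = matrix(rnorm(2L * d_emb, sd = 0.5), 2L, d_emb),
                 b_emb = rep(0, d_emb), d_emb = as.integer(d_emb)),
            class = "spatial_embedder")
}

#' Embed node coordinates
#'
#' Coordinates are first normalised to \[0, 1\] by the image width and height
#' (`x / W`, `y / H`), then affinely mapped:
#' `row_i = s_i %*% W_emb + b_emb`.
#'
#' @param coords `N x 2` matrix of `(x, y)` pixel coordinates.
#' @param embedder A [spatial_embedder()] (or any list with `W_emb`, `b_emb`).
#' @param image_shape `(H, W)`.
#' @return `N x d_emb` embedding matrix.
#' @export
embed_coordinates <- function(coords, embedder, image_shape) {
  coords <- as.matrix(coords)
  s <- cbind(coords[, 1L] / image_shape[2L], coords[, 2L] / image_shape[1L])
  sweep(s %*% embedder$W_emb, 2L, embedder$b_emb, `+`)
}

#' Fuse patch features with spatial embeddings
#'
#' Row-wise concatenation, patch block first. With the defaults of the image
#' pipeline (64 patch features, 16 embedding dimensions) the fused node
#' feature width is 80.
#'
#' @param patch_features `N x D_patch` matrix.
#' @param spatial_embeddings `N x D_emb` matrix.
#' @return `N x (D_patch + D_emb)` matrix.
#' @export
fuse_node_features <- function(patch_features, spatial_embeddings) {
  patch_features <- as.matrix(patch_features)
  spatial_embeddings <- as.matrix(spatial_embeddings)
  assert_that(nrow(patch_features) == nrow(spatial_embeddings),
              "row counts of feature blocks disagree",
              class = "calcgraph_shape_error")
  cbind(patch_features, spatial_embeddings)
}

#' Coordinate-derived node features
#'
#' Purely geometric per-node descriptors used when no image patches are
#' available (graph-only datasets) or for null experiments. Distances are
#' normalised by the image diagonal:
#' * `r_c` -- distance to the point-set centroid,
#' * `d_nn1` -- distance to the nearest neighbour,
#' * `d_nn3` -- mean distance to the three nearest neighbours,
#' * `r_perp` -- absolute perpendicular residual to the first principal axis
#'   of the point set,
#' * `t_axis` -- absolute centred projection along that axis,
#' * `n_log` -- `log1p(N) / log1p(300)`, a graph-size cue shared by all nodes,
#' * `dens1 = exp(-d_nn1 / 0.02)`, `densc = exp(-r_c / 0.1)`,
#'   `line_aff = exp(-r_perp / 0.01)` -- proximity-coded companions of the
#'   distance features.
#'
#' The three exponential-decay features exist so that membership in a
#' *compact* structure (a tight cluster, a narrow line) is represented by a
#' *large* activation rather than only by the smallness of a distance;
#' gradient-based node saliency can then attribute class evidence to the
#' member nodes directly. All nine are invariant under global translation of
#' the point set.
#'
#' @param coords `N x 2` matrix of `(x, y)` pixel coordinates.
#' @param image_shape `(H, W)`.
#' @return `N x 9` feature matrix.
#' @export
geometric_node_features <- function(coords, image_shape) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  diag_len <- image_diagonal(image_shape)
  ctr <- colMeans(coords)
  centered <- sweep(coords, 2L, ctr)
  r_c <- sqrt(rowSums(centered^2)) / diag_len
  if (n >= 2L) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    sorted <- apply(d, 1L, sort)
    d_nn1 <- sorted[1L, ] / diag_len
    d_nn3 <- colMeans(sorted[seq_len(min(3L, n - 1L)), , drop = FALSE]) /
      diag_len
    sv <- svd(centered, nu = 0L, nv = 2L)
    axis <- sv$v[, 1L]
    t_axis <- abs(centered %*% axis) / diag_len
    r_perp <- abs(centered[, 1L] * axis[2L] - centered[, 2L] * axis[1L]) /
      diag_len
  } else {
    d_nn1 <- d_nn3 <- t_axis <- r_perp <- rep(0, n)
  }
  cbind(r_c = r_c, d_nn1 = d_nn1, d_nn3 = d_nn3,
        r_perp = as.numeric(r_perp), t_axis = as.numeric(t_axis),
        n_log = rep(log1p(n) / log1p(300), n),
        dens1 = exp(-d_nn1 / 0.02), densc = exp(-r_c / 0.1),
        line_aff = exp(-as.numeric(r_perp) / 0.01))
}

new_calcification_graph <- function(features, coords, image_shape, adjacency,
                                    edges, label = NULL, scores = NULL,
                                    image_id = "unknown", k = NA_integer_,
                                    feature_mode = "patch") {
  structure(list(features = features, coords = coords,
                 image_shape = as.integer(image_shape),
                 adjacency = adjacency, edge_src = edges$src,
                 edge_dst = edges$dst, edge_labels = edges$labels,
                 label = if (is.null(label)) NULL else as_calc_label(label),
                 scores = scores %||% rep(1, nrow(coords)),
                 image_id = image_id, k = as.integer(k),
                 feature_mode = feature_mode),
            class = "calcification_graph")
}

#' @export
print.calcification_graph <- function(x, ...) {
  cat(sprintf(
    "<calcification_graph> %s: %d nodes, %d directed edges, %d features%s\n",
    x$image_id, nrow(x$coords), length(x$edge_src), ncol(x$features),
    if (!is.null(x$label)) paste0(", label = ", as.character(x$label)) else ""))
  invisible(x)
}

#' Build a calcification graph from detected candidates
#'
#' Assembles the per-image graph: node features are deep patch features from
#' the extractor (the raw coordinates are kept separately and embedded by the
#' model's learnable spatial embedding at training time), adjacency is the
#' symmetrised kNN graph, and edge labels are the geometric
#' `(dx, dy, d)` attributes. Candidates are sorted by `(y, x)` upstream, so
#' node order is deterministic. A single-node graph receives a self-loop with
#' a zero edge label so the neighbourhood average stays defined.
#'
#' @param candidates Non-empty candidate list from [extract_candidates()].
#' @param image The source [mammogram_image()] (for shape and provenance).
#' @param extractor A [feature_extractor()], or `NULL` to use
#'   [geometric_node_features()].
#' @param k kNN neighbour count (default 8).
#' @param label Optional distribution class label.
#' @return A `calcification_graph`.
#' @export
build_graph <- function(candidates, image, extractor = NULL, k = 8L,
                        label = NULL) {
  if (length(candidates) == 0L) {
    stop_calc("no calcification candidates in image ",
              if (inherits(image, "mammogram_image")) image$source_id else "",
              ": graph cannot be built",
              class = "calcgraph_empty_graph_error")
  }
  shape <- if (inherits(image, "mammogram_image")) dim(image$pixels) else
    as.integer(image)
  coords <- t(vapply(candidates, `[[`, numeric(2), "center"))
  colnames(coords) <- c("x", "y")
  scores <- vapply(candidates, `[[`, numeric(1), "detector_score")
  feats <- if (is.null(extractor)) {
    geometric_node_features(coords, shape)
  } else {
    extract_patch_features(lapply(candidates, `[[`, "patch"), extractor)
  }
  graph_from_parts(feats, coords, shape, k, label, scores,
                   image_id = if (inherits(image, "mammogram_image"))
                     image$source_id else "unknown",
                   feature_mode = if (is.null(extractor)) "geometric"
                   else "patch")
}

graph_from_parts <- function(features, coords, image_shape, k, label, scores,
                             image_id, feature_mode) {
  n <- nrow(coords)
  A <- knn_adjacency(coords, k)
  edges <- compute_edge_labels(coords, A, image_shape)
  if (n == 1L) {
    edges <- list(src = 1L, dst = 1L,
                  labels = matrix(0, 1L, 3L,
                                  dimnames = list(NULL, c("dx", "dy", "d"))))
  }
  new_calcification_graph(features, coords, image_shape, A, edges, label,
                          scores, image_id, k, feature_mode)
}

#' Build a graph directly from point coordinates
#'
#' Convenience constructor for graph-only workflows (synthetic benchmarks,
#' null experiments): node features are [geometric_node_features()] of the
#' coordinates (or seeded random noise in `"random"` mode).
#'
#' @param coords `N x 2` matrix of `(x, y)` coordinates.
#' @param image_shape `(H, W)` reference frame.
#' @param label Optional distribution class.
#' @param k kNN neighbour count.
#' @param feature_mode `"geometric"` or `"random"`.
#' @param image_id Provenance string.
#' @param rng_seed Seed for `"random"` features.
#' @return A `calcification_graph`.
#' @export
graph_from_coords <- function(coords, image_shape, label = NULL, k = 8L,
                              feature_mode = c("geometric", "random"),
                              image_id = "synthetic", rng_seed = 0L) {
  feature_mode <- match.arg(feature_mode)
  coords <- as.matrix(coords)
  assert_that(nrow(coords) >= 1L, "graph needs at least one node",
              class = "calcgraph_empty_graph_error")
  ord <- order(coords[, 2L], coords[, 1L])
  coords <- coords[ord, , drop = FALSE]
  feats <- if (feature_mode == "geometric") {
    geometric_node_features(coords, image_shape)
  } else {
    set.seed(rng_seed)
    matrix(rnorm(nrow(coords) * 9L), nrow(coords), 9L)
  }
  graph_from_parts(feats, coords, image_shape, k, label,
                   scores = rep(1, nrow(coords)), image_id = image_id,
                   feature_mode = feature_mode)
}

#' Serialize / restore a calcification graph
#'
#' Graphs round-trip exactly (field-by-field) through R's native
#' serialization.
#'
#' @param graph A `calcification_graph`.
#' @param path Destination / source file.
#' @return `read_graph` returns the graph; `write_graph` returns `path`.
#' @export
write_graph <- function(graph, path) {
  assert_that(inherits(graph, "calcification_graph"),
              "not a calcification_graph")
  saveRDS(graph, path)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  g <- readRDS(path)
  assert_that(inherits(g, "calcification_graph"),
              "file does not contain a calcification_graph")
  g
}
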