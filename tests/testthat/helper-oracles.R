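# Independent brute-force oracles used to cross-check the implementation.

# grayscale erosion/dilation/opening by literal per-pixel loops over the
# structuring element ("ignore outside" border convention)
oracle_morph <- function(img, se, op) {
  r <- (nrow(se) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  off <- which(se, arr.ind = TRUE) - r - 1L
  out <- matrix(NA_real_, nr, nc)
  agg <- if (op == "erode") min else max
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- i + off[, 1L]; jj <- j + off[, 2L]
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      out[i, j] <- agg(img[cbind(ii[ok], jj[ok])])
    }
  }
  out
}

oracle_opening <- function(img, se) {
  oracle_morph(oracle_morph(img, se, "erode"), se, "dilate")
}

oracle_top_hat <- function(img, radius) {
  img - oracle_opening(img, disk_se(radius))
}

# O(N^2) kNN graph: per node, full distance sort with index tie-break, then
# mutual-or symmetrization
oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  A <- matrix(0L, n, n)
  if (n == 1L) return(A)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j != i) d[j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
    ord <- order(d, seq_len(n))
    A[i, ord[seq_len(min(k, n - 1L))]] <- 1L
  }
  pmax(A, t(A))
}

# literal per-node edge-conditioned convolution:
# X_l(i) = (1/|N(i)|) sum_{j in N(i)} F_l(L_{j,i}) X_{l-1}(j) + b_l
oracle_ecc <- function(graph, layer, X_prev) {
  n <- nrow(X_prev)
  dout <- length(layer$b)
  out <- matrix(NA_real_, n, dout)
  filt <- function(L) {
    hid <- tanh(as.numeric(L %*% layer$W1) + as.numeric(layer$c1))
    theta <- as.numeric(hid %*% layer$W2) + as.numeric(layer$c2)
    matrix(theta, dout, ncol(X_prev))   # column-major reshape
  }
  for (i in seq_len(n)) {
    eids <- which(graph$edge_dst == i)
    acc <- rep(0, dout)
    for (e in eids) {
      j <- graph$edge_src[e]
      acc <- acc + filt(graph$edge_labels[e, , drop = FALSE]) %*% X_prev[j, ]
    }
    out[i, ] <- acc / length(eids) + as.numeric(layer$b)
  }
  out
}

# random ECC layer weights for a given width
random_ecc_layer <- function(din, dout, h = 4L, seed = 0L) {
  set.seed(seed)
  list(W1 = matrix(rnorm(3L * h), 3L, h), c1 = rnorm(h),
       W2 = matrix(rnorm(h * dout * din, sd = 0.3), h, dout * din),
       c2 = rnorm(dout * din, sd = 0.3), b = rnorm(dout))
}

# match planted spot centers to detections within a tolerance; returns
# recall/precision
match_detections <- function(truth_xy, det_xy, tol = 4) {
  if (nrow(det_xy) == 0L) {
    return(c(recall = 0, precision = NA_real_))
  }
  dmat <- sqrt(outer(truth_xy[, 1], det_xy[, 1], `-`)^2 +
                 outer(truth_xy[, 2], det_xy[, 2], `-`)^2)
  c(recall = mean(apply(dmat, 1, min) <= tol),
    precision = mean(apply(dmat, 2, min) <= tol))
}

# small deterministic random graph for GNN tests
random_test_graph <- function(n, seed, label = NULL, shape = c(100L, 100L)) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, shape[2] - 1), runif(n, 0, shape[1] - 1))
  graph_from_coords(coords, shape, label = label, k = min(3L, n),
                    image_id = paste0("test-", seed))
}
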