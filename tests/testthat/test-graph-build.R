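test_that("kNN adjacency handles degenerate and collinear layouts", {
  expect_identical(knn_adjacency(matrix(c(5, 5), 1, 2)),
                   matrix(0L, 1, 1))
  # three collinear equally spaced points with k = 1: symmetrization gives
  # the path 0-1, 1-2 (middle point ties broken towards the lower index)
  coords <- cbind(c(0, 10, 20), c(0, 0, 0))
  A <- knn_adjacency(coords, k = 1)
  expected <- matrix(0L, 3, 3)
  expected[1, 2] <- expected[2, 1] <- 1L
  expected[2, 3] <- expected[3, 2] <- 1L
  expect_identical(A, expected)
  # N - 1 < k connects everything off-diagonal
  A2 <- knn_adjacency(coords, k = 8)
  expect_identical(A2, matrix(1L, 3, 3) - diag(1L, 3))
  # duplicate coordinates allowed
  A3 <- knn_adjacency(rbind(c(1, 1), c(1, 1), c(5, 5)), k = 1)
  expect_identical(diag(A3), rep(0L, 3))
  expect_identical(A3[1, 2], 1L)
})

test_that("kNN adjacency equals the brute-force oracle across sizes", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(2:40, 1)
    coords <- matrix(runif(2 * n, 0, 100), n, 2)
    for (k in c(1L, 3L, 8L)) {
      expect_identical(knn_adjacency(coords, k), oracle_knn(coords, k),
                       info = sprintf("seed %d n %d k %d", seed, n, k))
    }
  }
})

test_that("edge labels carry normalized antisymmetric offsets", {
  coords <- rbind(c(10, 50), c(20, 50))
  A <- knn_adjacency(coords, 1)
  el <- compute_edge_labels(coords, A, c(100L, 100L))
  diagonal <- sqrt(2 * 100^2)
  i12 <- which(el$src == 1 & el$dst == 2)
  i21 <- which(el$src == 2 & el$dst == 1)
  expect_equal(unname(el$labels[i21, "dx"]), 10 / diagonal)
  expect_equal(unname(el$labels[i21, "dy"]), 0)
  expect_equal(unname(el$labels[i12, "dx"]), -10 / diagonal)
  expect_equal(unname(el$labels[i12, "d"]), unname(el$labels[i21, "d"]))
  # coincident nodes give a zero label
  cdup <- rbind(c(5, 5), c(5, 5))
  eld <- compute_edge_labels(cdup, knn_adjacency(cdup, 1), c(100L, 100L))
  expect_true(all(eld$labels == 0))
})

test_that("coordinate embedding is the documented affine map", {
  emb <- spatial_embedder(d_emb = 4, seed = 1)
  coords <- rbind(c(50, 25), c(10, 80))
  shape <- c(100L, 200L)
  # zero weights: every row equals the bias
  emb0 <- emb; emb0$W_emb[] <- 0; emb0$b_emb <- c(1, 2, 3, 4)
  X0 <- embed_coordinates(coords, emb0, shape)
  expect_equal(X0, matrix(c(1, 2, 3, 4), 2, 4, byrow = TRUE))
  # identity-like weights recover the normalized coordinates
  embi <- list(W_emb = diag(1, 2, 2), b_emb = c(0, 0))
  Xi <- embed_coordinates(coords, embi, shape)
  expect_equal(Xi, cbind(coords[, 1] / 200, coords[, 2] / 100))
  # random weights match the explicit matrix-product oracle
  s <- cbind(coords[, 1] / shape[2], coords[, 2] / shape[1])
  expect_equal(embed_coordinates(coords, emb, shape),
               s %*% emb$W_emb + matrix(emb$b_emb, 2, 4, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("feature fusion concatenates patch-first and is invertible", {
  set.seed(2)
  Xp <- matrix(rnorm(5 * 64), 5, 64)
  Xe <- matrix(rnorm(5 * 16), 5, 16)
  Xn <- fuse_node_features(Xp, Xe)
  expect_identical(ncol(Xn), 80L)
  expect_equal(Xn[, 1:64], Xp)
  expect_equal(Xn[, 65:80], Xe)
  Xz <- fuse_node_features(Xp, matrix(0, 5, 16))
  expect_equal(Xz[, 1:64], Xp)
  expect_error(fuse_node_features(Xp, Xe[1:3, ]),
               class = "calcgraph_shape_error")
})

test_that("patch features match a literal convolution forward pass", {
  set.seed(5)
  patches <- lapply(1:3, function(i) matrix(runif(196), 14, 14))
  verifier <- train_verifier(patches, c(1, 0, 1), epochs = 1, seed = 1)
  ext <- feature_extractor(verifier, tap_layer = 1L)
  got <- extract_patch_features(patches, ext)
  # literal same-padded 3x3 convolution + ReLU + 2x2 average pool + GAP
  p <- patches[[1]] / verifier$input_scale
  W <- verifier$params$Wc1; b <- verifier$params$bc1
  conv <- array(0, c(14, 14, dim(W)[4]))
  for (co in seq_len(dim(W)[4])) {
    for (i in 1:14) for (j in 1:14) {
      acc <- b[co]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= 14 && jj >= 1 && jj <= 14) {
          acc <- acc + p[ii, jj] * W[di + 2, dj + 2, 1, co]
        }
      }
      conv[i, j, co] <- max(acc, 0)
    }
  }
  pooled <- array(0, c(7, 7, dim(W)[4]))
  for (co in seq_len(dim(W)[4])) {
    for (i in 1:7) for (j in 1:7) {
      pooled[i, j, co] <- mean(conv[2 * i - 1:0, 2 * j - 1:0, co])
    }
  }
  expect_equal(got[1, ], apply(pooled, 3, mean), tolerance = 1e-5)
  # identical patches give identical rows; zero patch with zero biases gives
  # zero features
  got2 <- extract_patch_features(list(patches[[1]], patches[[1]]), ext)
  expect_identical(got2[1, ], got2[2, ])
  ext0 <- ext; ext0$params$bc1[] <- 0
  z <- extract_patch_features(list(matrix(0, 14, 14)), ext0)
  expect_true(all(z == 0))
})

test_that("graphs assemble, serialize and permute consistently", {
  spec <- pattern_spec("grouped", n_spots = 12, seed = 9)
  coords <- sample_pattern_coords(spec)
  g <- graph_from_coords(coords, c(256L, 256L), label = "grouped", k = 8)
  # 12 nodes, k = 8: every node has degree >= 1, zero diagonal, symmetric
  expect_true(all(diag(g$adjacency) == 0))
  expect_identical(g$adjacency, t(g$adjacency))
  expect_true(all(rowSums(g$adjacency) >= 1))
  # grouped geometry: all pairwise distances within twice the cluster radius
  geomr <- attr(coords, "geometry")$radius
  expect_lte(max(dist(g$coords)), 2 * geomr + 1e-9)
  # round trip
  f <- withr::local_tempfile(fileext = ".rds")
  write_graph(g, f)
  expect_identical(read_graph(f), g)
  # n = 5 with k = 8: complete graph minus self-loops
  g5 <- graph_from_coords(coords[1:5, ], c(256L, 256L), k = 8)
  expect_identical(g5$adjacency, matrix(1L, 5, 5) - diag(1L, 5))
  # single node: self-loop with zero label
  g1 <- graph_from_coords(coords[1, , drop = FALSE], c(256L, 256L), k = 8)
  expect_identical(g1$edge_src, 1L)
  expect_identical(g1$edge_dst, 1L)
  expect_true(all(g1$edge_labels == 0))
  # empty input refuses
  expect_error(graph_from_coords(matrix(0, 0, 2), c(256L, 256L)),
               class = "calcgraph_empty_graph_error")
})

test_that("node permutation permutes features, adjacency and labels coherently", {
  set.seed(13)
  coords <- matrix(runif(30, 0, 200), 15, 2)
  shape <- c(256L, 256L)
  A <- knn_adjacency(coords, 3)
  X <- geometric_node_features(coords, shape)
  perm <- sample(15)
  A_p <- knn_adjacency(coords[perm, ], 3)
  X_p <- geometric_node_features(coords[perm, ], shape)
  expect_identical(A_p, A[perm, perm])
  expect_equal(X_p, X[perm, ], ignore_attr = TRUE)
  el <- compute_edge_labels(coords, A, shape)
  el_p <- compute_edge_labels(coords[perm, ], A_p, shape)
  # edge sets coincide after mapping through the permutation
  key <- function(s, d) paste(s, d)
  inv <- order(perm)
  expect_setequal(key(inv[el$src], inv[el$dst]), key(el_p$src, el_p$dst))
})
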