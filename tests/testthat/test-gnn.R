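test_that("edge-conditioned convolution matches hand computations", {
  # zero input features, zero bias, zero filter -> zero output
  g <- random_test_graph(4, seed = 1)
  layer0 <- random_ecc_layer(3, 2, seed = 2)
  layer0$b[] <- 0; layer0$W2[] <- 0; layer0$c2[] <- 0
  out0 <- ecc_forward(g, layer0, matrix(0, 4, 3))
  expect_true(all(out0 == 0))
  # constant identity filter on a 3-node path graph: each node's output is
  # the mean of its neighbours' inputs
  coords <- cbind(c(0, 10, 20), c(0, 0, 0))
  gp <- graph_from_coords(coords, c(100L, 100L), k = 1)
  lid <- list(W1 = matrix(0, 3, 2), c1 = rep(0, 2),
              W2 = matrix(0, 2, 4), c2 = as.numeric(diag(2)), b = rep(0, 2))
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  out <- ecc_forward(gp, lid, X)
  expect_equal(out[1, ], X[2, ])
  expect_equal(out[2, ], (X[1, ] + X[3, ]) / 2)
  expect_equal(out[3, ], X[2, ])
})

test_that("edge-conditioned convolution equals the literal per-node loop", {
  for (seed in 1:50) {
    set.seed(seed + 1000)
    n <- sample(2:10, 1)
    g <- random_test_graph(n, seed = seed + 1000)
    din <- sample(2:5, 1); dout <- sample(2:5, 1)
    layer <- random_ecc_layer(din, dout, seed = seed)
    X <- matrix(rnorm(n * din), n, din)
    expect_equal(ecc_forward(g, layer, X), oracle_ecc(g, layer, X),
                 tolerance = 1e-6, info = paste("seed", seed))
  }
})

test_that("readout modes follow the flatten and mean contracts", {
  X <- matrix(seq_len(12), 4, 3)
  # N = n_max: exact row-major concatenation
  expect_equal(readout(X, "flatten", n_max = 4), as.numeric(t(X)))
  # N = 1, mean: the single node's features
  expect_equal(readout(X[1, , drop = FALSE], "mean"), X[1, ])
  # truncation drops exactly the lowest-score rows
  set.seed(4)
  X2 <- matrix(rnorm(9 * 2), 9, 2)
  scores <- c(5, 1, 4, 9, 2, 8, 7, 3, 6)
  r <- readout(X2, "flatten", scores = scores, n_max = 4)
  keep <- sort(order(scores, decreasing = TRUE)[1:4])
  expect_equal(r, as.numeric(t(X2[keep, ])))
  # zero padding
  r2 <- readout(X, "flatten", n_max = 6)
  expect_length(r2, 18)
  expect_true(all(r2[13:18] == 0))
})

test_that("sigmoid head matches the affine oracle and flags non-finite logits", {
  # zero weights: all probabilities 0.5
  p0 <- classify(rep(0, 4), matrix(0, 4, 5), rep(0, 5))
  expect_equal(unname(p0$probs), rep(0.5, 5))
  # dominant logit wins with probability > 0.999
  p1 <- classify(1, matrix(c(10, -10, -10, -10, -10), 1, 5), rep(0, 5))
  expect_identical(as.character(p1$predicted), "diffuse")
  expect_gt(p1$probs[1], 0.999)
  # random case against the explicit oracle
  set.seed(6)
  x <- rnorm(7); W <- matrix(rnorm(35), 7, 5); b <- rnorm(5)
  pc <- classify(x, W, b)
  expect_equal(unname(pc$probs), 1 / (1 + exp(-(as.numeric(x %*% W) + b))),
               tolerance = 1e-9)
  expect_error(classify(Inf, matrix(1, 1, 5), rep(0, 5)),
               class = "calcgraph_numeric_error")
})

test_that("focal loss reduces to cross-entropy at gamma 0 and behaves monotonically", {
  set.seed(8)
  for (i in 1:1000) {
    p <- runif(5, 0.01, 0.99)
    y <- sample(5, 1)
    yh <- integer(5); yh[y] <- 1L
    ce <- -sum(yh * log(p) + (1 - yh) * log(1 - p))
    expect_equal(focal_loss(p, yh, gamma = 0), ce, tolerance = 1e-9)
  }
  # p_t = 1 everywhere -> zero loss (up to clamping)
  expect_lt(focal_loss(c(1, 0, 0, 0, 0), 1L, gamma = 2), 1e-5)
  # single active component with p_t = 0.5 at gamma 2: 0.25 * ln 2
  # (the other components have p = 0, i.e. p_t = 1, contributing ~0)
  expect_equal(focal_loss(c(0.5, 0, 0, 0, 0), 1L, gamma = 2),
               0.25 * log(2), tolerance = 1e-6)
  term <- function(pt, gamma) -(1 - pt)^gamma * log(pt)
  # focal term decreasing in p_t; larger gamma never increases the loss of a
  # correctly classified component
  pts <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(term(pts, 2)) < 0))
  for (pt in pts[pts > 0.5]) {
    expect_lte(term(pt, 3), term(pt, 2))
  }
})

test_that("training reduces the loss and reaches high accuracy on separable graphs", {
  ds <- generate_graph_dataset(class_mix("balanced"), n_graphs = 50, seed = 3)
  tc <- benchmark_train_config(seed = 1)
  model <- train_gnn(ds$graphs, gnn_config(), tc)
  expect_lt(tail(model$history$loss, 1), model$history$loss[1])
  expect_gte(tail(model$history$accuracy, 1), 0.9)
  # degenerate single-class input errors
  sub <- Filter(function(g) g$label == "grouped", ds$graphs)
  expect_error(train_gnn(sub, gnn_config(), tc),
               class = "calcgraph_degenerate_error")
})

test_that("an unlearnable contradictory dataset plateaus without crashing", {
  g <- random_test_graph(6, seed = 2, label = "grouped")
  g2 <- g
  g2$label <- factor("linear", levels = calc_classes())
  model <- train_gnn(list(g, g2, g, g2), gnn_config(),
                     train_config(epochs = 30, seed = 0))
  expect_gt(tail(model$history$loss, 1), 0)
  expect_true(all(is.finite(model$history$loss)))
})

test_that("identical seeds give identical weights; save/load is bit-stable", {
  ds <- generate_graph_dataset(class_mix("balanced"), n_graphs = 15, seed = 5)
  tc <- train_config(epochs = 10, seed = 7)
  m1 <- train_gnn(ds$graphs, gnn_config(), tc)
  m2 <- train_gnn(ds$graphs, gnn_config(), tc)
  expect_identical(m1$params, m2$params)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m1, f)
  m3 <- load_model(f)
  g <- ds$graphs[[1]]
  expect_identical(predict_gnn(m3, g)$probs, predict_gnn(m1, g)$probs)
})

test_that("mean-readout predictions are invariant to node permutation and translation", {
  set.seed(9)
  coords <- matrix(runif(24, 40, 200), 12, 2)
  shape <- c(256L, 256L)
  ds <- generate_graph_dataset(class_mix("balanced"), n_graphs = 15, seed = 6)
  cfg <- gnn_config(d_emb = 0L)   # disable the spatial embedding
  model <- train_gnn(ds$graphs, cfg, train_config(epochs = 5, seed = 1))
  g <- graph_from_coords(coords, shape, k = 3)
  perm <- sample(12)
  gp <- graph_from_coords(coords[perm, ], shape, k = 3)
  expect_equal(predict_gnn(model, g)$probs, predict_gnn(model, gp)$probs,
               tolerance = 1e-12)
  # translation: geometric features and offset-based edge labels are
  # translation invariant, so prediction is unchanged
  gt <- graph_from_coords(sweep(coords, 2, c(15, -10), `+`), shape, k = 3)
  expect_equal(predict_gnn(model, g)$probs, predict_gnn(model, gt)$probs,
               tolerance = 1e-10)
})
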