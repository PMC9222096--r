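#' Classification metrics for distribution-pattern predictions
#'
#' Builds the 5 x 5 confusion matrix from the argmax predictions and reports
#' per-class one-vs-rest precision, sensitivity (recall), specificity, F1
#' and AUC, together with macro (unweighted class mean) and micro (pooled
#' count) averages. Micro-averaged recall equals accuracy by construction.
#' AUC is the rank-based (Mann-Whitney) one-vs-rest area computed from the
#' raw scores; a class absent from `y_true` gets `NA` and is excluded from
#' the macro AUC with a warning.
#'
#' @param y_true True class labels (factor or character).
#' @param y_prob `N x 5` score matrix in canonical class-column order, or a
#'   factor/character vector of hard predictions.
#' @param class_names Class order.
#' @return A `calc_eval_report`: `confusion`, `per_class` data frame,
#'   `macro`, `micro`, `accuracy`, plus the inputs for downstream plotting.
#' @export
compute_metrics <- function(y_true, y_prob, class_names = calc_classes()) {
  y_true <- factor(as.character(y_true), levels = class_names)
  if (is.matrix(y_prob)) {
    assert_that(nrow(y_prob) == length(y_true) &&
                  ncol(y_prob) == length(class_names),
                "score matrix shape mismatch")
    assert_that(all(is.finite(y_prob)), "scores must be finite")
    y_pred <- factor(class_names[max.col(y_prob, ties.method = "first")],
                     levels = class_names)
  } else {
    y_pred <- factor(as.character(y_prob), levels = class_names)
    y_prob <- NULL
  }
  k <- length(class_names)
  confusion <- table(true = y_true, predicted = y_pred)
  total <- sum(confusion)
  accuracy <- sum(diag(confusion)) / total

  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- total - tp - fp - fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  specificity <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  auc <- rep(NA_real_, k)
  if (!is.null(y_prob)) {
    for (c in seq_len(k)) {
      auc[c] <- auc_rank(y_true == class_names[c], y_prob[, c])
    }
    if (anyNA(auc)) {
      warning("AUC undefined for class(es) absent from y_true: ",
              paste(class_names[is.na(auc)], collapse = ", "))
    }
  }
  per_class <- data.frame(class = class_names, support = as.numeric(rowSums(confusion)),
                          precision = as.numeric(precision),
                          recall = as.numeric(recall),
                          specificity = as.numeric(specificity),
                          f1 = as.numeric(f1), auc = auc)
  macro <- c(precision = mean(precision, na.rm = TRUE),
             recall = mean(recall, na.rm = TRUE),
             specificity = mean(specificity, na.rm = TRUE),
             f1 = mean(f1, na.rm = TRUE),
             auc = if (all(is.na(auc))) NA_real_ else mean(auc, na.rm = TRUE))
  micro <- c(precision = sum(tp) / sum(tp + fp),
             recall = sum(tp) / sum(tp + fn),
             specificity = sum(tn) / sum(tn + fp))
  structure(list(confusion = confusion, per_class = per_class,
                 macro = macro, micro = micro, accuracy = accuracy,
                 y_true = y_true, y_prob = y_prob,
                 class_names = class_names),
            class = "calc_eval_report")
}

# Mann-Whitney AUC with tie correction; NA when a class is fully absent (or
# fully present) in the truth vector
auc_rank <- function(is_pos, scores) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.calc_eval_report <- function(x, digits = 3, ...) {
  cat("<calc_eval_report>\n")
  cat(sprintf("accuracy: %.3f (micro recall %.3f)\n", x$accuracy,
              x$micro["recall"]))
  cat(sprintf("macro: precision %.3f  recall %.3f  specificity %.3f  F1 %.3f  AUC %s\n",
              x$macro["precision"], x$macro["recall"], x$macro["specificity"],
              x$macro["f1"],
              if (is.na(x$macro["auc"])) "NA" else
                sprintf("%.3f", x$macro["auc"])))
  print(round(data.frame(x$per_class[, -1], row.names = x$per_class$class),
              digits))
  if (!is.null(x$folds)) {
    cat(sprintf("%d-fold CV: accuracy %.3f +/- %.3f, macro recall %.3f +/- %.3f\n",
                length(unique(x$folds$fold)),
                mean(x$folds$accuracy), sd(x$folds$accuracy),
                mean(x$folds$macro_recall), sd(x$folds$macro_recall)))
  }
  invisible(x)
}

#' Stratified fold assignment
#'
#' Assigns cases to `n_folds` folds, stratified by class: within each class,
#' cases are shuffled (seeded) and dealt round-robin. All graphs sharing a
#' case identifier land in the same fold.
#'
#' @param labels Class labels, one per graph.
#' @param n_folds Number of folds.
#' @param seed RNG seed.
#' @param case_ids Optional case (patient) identifiers; folds are assigned
#'   at case level.
#' @return Integer fold vector (1..n_folds), one entry per graph.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 0L,
                             case_ids = NULL) {
  labels <- as.character(labels)
  case_ids <- case_ids %||% seq_along(labels)
  # one label per case (the first seen)
  cases <- !duplicated(case_ids)
  case_label <- labels[cases]
  case_key <- case_ids[cases]
  tab <- table(case_label)
  short <- names(tab)[tab < n_folds]
  assert_that(length(short) == 0L,
              "class(es) with fewer cases than folds: ",
              paste(short, collapse = ", "),
              class = "calcgraph_stratification_error")
  set.seed(seed)
  fold_of_case <- integer(length(case_key))
  for (cl in unique(case_label)) {
    idx <- which(case_label == cl)
    idx <- idx[sample.int(length(idx))]
    fold_of_case[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold_of_case[match(case_ids, case_key)]
}

#' Cross-validated training and evaluation
#'
#' Stratified k-fold cross-validation of the graph classifier: for each
#' fold, a model is trained on the remaining folds (with the fold index
#' folded into the training seed so folds are independent but reproducible)
#' and evaluated on the held-out graphs. Pooled predictions across folds
#' give the overall report; per-fold accuracy and macro recall are recorded
#' as mean +/- sd.
#'
#' @param graphs List of labelled `calcification_graph`s.
#' @param config A [gnn_config()].
#' @param tc A [train_config()].
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param case_ids Optional case identifiers (fold unit = case).
#' @return A `calc_eval_report` with extra elements `folds` (per-fold
#'   metrics) and `fold_assignment`.
#' @export
cross_validate <- function(graphs, config = gnn_config(),
                           tc = train_config(), n_folds = 5L, seed = 0L,
                           case_ids = NULL) {
  labels <- vapply(graphs, function(g) as.character(g$label), "")
  folds <- stratified_folds(labels, n_folds, seed, case_ids)
  n <- length(graphs)
  probs <- matrix(NA_real_, n, config$n_classes)
  fold_stats <- data.frame(fold = seq_len(n_folds), accuracy = NA_real_,
                           macro_recall = NA_real_)
  for (f in seq_len(n_folds)) {
    test_idx <- which(folds == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    tc_f <- tc
    tc_f$seed <- tc$seed + f
    model <- train_gnn(graphs[train_idx], config, tc_f)
    p <- predict_gnn(model, graphs[test_idx])
    probs[test_idx, ] <- p
    rep_f <- compute_metrics(labels[test_idx], p, config$class_names)
    fold_stats$accuracy[f] <- rep_f$accuracy
    fold_stats$macro_recall[f] <- rep_f$macro["recall"]
  }
  report <- compute_metrics(labels, probs, config$class_names)
  report$folds <- fold_stats
  report$fold_assignment <- folds
  report
}

#' Write confusion-matrix and ROC figures
#'
#' Renders a confusion-matrix heatmap and the five one-vs-rest ROC curves
#' (per-class AUC in the legend) from an evaluation report containing
#' scores. Files are written deterministically.
#'
#' @param report A `calc_eval_report` from [compute_metrics()] or
#'   [cross_validate()].
#' @param out_dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
plot_outputs <- function(report, out_dir) {
  assert_that(!is.null(report$y_prob),
              "report carries no scores; ROC curves need probabilities")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cm <- as.data.frame(report$confusion)
  p1 <- ggplot2::ggplot(cm, ggplot2::aes(x = predicted, y = true,
                                         fill = Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = Freq), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(report$class_names)) +
    ggplot2::labs(title = "Distribution classification confusion matrix",
                  x = "predicted", y = "true") +
    ggplot2::theme_minimal()
  f1 <- file.path(out_dir, "confusion_matrix.png")
  ggplot2::ggsave(f1, p1, width = 5.5, height = 4.5, dpi = 150)

  curves <- do.call(rbind, lapply(seq_along(report$class_names), function(c) {
    cl <- report$class_names[c]
    is_pos <- report$y_true == cl
    if (!any(is_pos) || all(is_pos)) return(NULL)
    sc <- report$y_prob[, c]
    ord <- order(sc, decreasing = TRUE)
    tpr <- c(0, cumsum(is_pos[ord]) / sum(is_pos))
    fpr <- c(0, cumsum(!is_pos[ord]) / sum(!is_pos))
    a <- auc_rank(is_pos, sc)
    data.frame(class = sprintf("%s (AUC %.2f)", cl, a), fpr = fpr, tpr = tpr)
  }))
  p2 <- ggplot2::ggplot(curves, ggplot2::aes(x = fpr, y = tpr,
                                             colour = class)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(title = "One-vs-rest ROC curves",
                  x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
  f2 <- file.path(out_dir, "roc_curves.png")
  ggplot2::ggsave(f2, p2, width = 6, height = 4.5, dpi = 150)
  invisible(c(f1, f2))
}

utils::globalVariables(c("predicted", "true", "Freq", "fpr", "tpr"))
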