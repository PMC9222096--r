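# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_calc <- function(..., class) {
  stop(structure(class = c(class, "calcgraph_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ..., class = "calcgraph_input_error") {
  if (!isTRUE(ok)) stop_calc(..., class = class)
  invisible(TRUE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# image diagonal used to normalize pixel distances; image_shape = c(H, W)
image_diagonal <- function(image_shape) {
  sqrt(sum(as.numeric(image_shape)^2))
}

# factor in the canonical class order
as_calc_label <- function(x) {
  cls <- calc_classes()
  if (is.factor(x)) x <- as.character(x)
  assert_that(all(x %in% cls), "unknown distribution label: ",
              paste(setdiff(x, cls), collapse = ", "))
  factor(x, levels = cls)
}
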