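#' Detection configuration
#'
#' Parameters of the morphological calcification detector. Three threshold
#' rules are supported for the top-hat response restricted to the breast
#' mask: a fixed value (`threshold = list(fixed = T)`), a percentile
#' (`threshold = list(percentile = q)`), or a noise-scaled rule
#' (`threshold = list(nmad = k)`, the default with k = 5) where
#' `T = median + k * MAD` of the within-mask response. The noise-scaled rule
#' is the default because a percentile bounds the *number* of detected
#' pixels, so no single percentile works across sparse and dense
#' calcification patterns, while the median/MAD of the response track the
#' noise floor regardless of how many spots are present. The patch window is
#' `patch_size` x `patch_size` with the candidate center at 0-based window
#' index `(patch_size/2, patch_size/2)` -- for the default even size of 14
#' the window spans offsets -7..+6 around the center.
#'
#' @param se_radius Disk radius of the top-hat structuring element (px).
#' @param threshold Threshold rule, `list(fixed = )` or `list(percentile = )`.
#' @param patch_size Patch side length D in pixels (default 14).
#' @param min_blob_area,max_blob_area Area bounds (px^2) for detected blobs.
#' @param verifier_cutoff Probability cutoff used by [filter_candidates()].
#' @param enhance Use the optional morphological contrast-enhancement mode
#'   (`I + tophat - bottomhat`) before the top-hat detector? Default `FALSE`.
#'
#' @return A `detection_config` list.
#' @export
detection_config <- function(se_radius = 3L,
                             threshold = list(nmad = 5),
                             patch_size = 14L,
                             min_blob_area = 2L,
                             max_blob_area = 300L,
                             verifier_cutoff = 0.5,
                             enhance = FALSE) {
  assert_that(patch_size >= 3L, "patch_size must be >= 3",
              class = "calcgraph_config_error")
  assert_that(min_blob_area < max_blob_area,
              "min_blob_area must be smaller than max_blob_area",
              class = "calcgraph_config_error")
  assert_that(verifier_cutoff >= 0 && verifier_cutoff <= 1,
              "verifier_cutoff must lie in [0, 1]",
              class = "calcgraph_config_error")
  assert_that(length(threshold) == 1L &&
                names(threshold) %in% c("fixed", "percentile", "nmad"),
              "threshold must be list(fixed = ), list(percentile = ) or ",
              "list(nmad = )", class = "calcgraph_config_error")
  structure(list(se_radius = se_radius, threshold = threshold,
                 patch_size = as.integer(patch_size),
                 min_blob_area = min_blob_area,
                 max_blob_area = max_blob_area,
                 verifier_cutoff = verifier_cutoff, enhance = enhance),
            class = "detection_config")
}

#' Threshold the top-hat response inside the breast mask
#'
#' The detection mask is 1 exactly where the response reaches the threshold
#' *and* the breast mask is true. With the percentile rule the threshold is
#' the configured percentile (type-7 quantile) of the response restricted to
#' the mask; with the noise-scaled rule it is `median + nmad * MAD` of the
#' same restricted response.
#'
#' @param response Top-hat response matrix.
#' @param mask A `breast_mask` or logical matrix.
#' @param config A [detection_config()].
#' @return Logical detection mask with attribute `"threshold"`.
#' @export
threshold_detect <- function(response, mask, config = detection_config()) {
  m <- if (inherits(mask, "breast_mask")) mask$mask else mask
  assert_that(all(dim(response) == dim(m)),
              "response and mask shapes disagree")
  assert_that(any(m), "empty breast mask",
              class = "calcgraph_degenerate_error")
  thr <- if (!is.null(config$threshold$fixed)) {
    config$threshold$fixed
  } else if (!is.null(config$threshold$percentile)) {
    unname(quantile(response[m], config$threshold$percentile / 100,
                    type = 7))
  } else {
    v <- response[m]
    median(v) + config$threshold$nmad * stats::mad(v)
  }
  out <- response >= thr & m
  attr(out, "threshold") <- thr
  out
}

clamp_index <- function(i, n) pmin(pmax(i, 1L), n)

# D x D patch centered at 0-based (x, y) with replicate padding; center sits
# at 0-based window index (D %/% 2, D %/% 2)
extract_patch <- function(pixels, x, y, d) {
  half <- d %/% 2L
  rows <- clamp_index((y + 1L) + seq.int(-half, d - half - 1L), nrow(pixels))
  cols <- clamp_index((x + 1L) + seq.int(-half, d - half - 1L), ncol(pixels))
  pixels[rows, cols, drop = FALSE]
}

#' Extract calcification candidates from a detection mask
#'
#' 8-connected components of the detection mask with area inside the
#' configured bounds become candidates. The candidate center is the
#' response-weighted centroid rounded to the nearest pixel; the patch is a
#' `patch_size` square window around it (replicate-padded at borders).
#' Candidates are sorted by `(y, x)` for determinism.
#'
#' @param detection_mask Logical matrix from [threshold_detect()].
#' @param image A [mammogram_image()] or matrix supplying patch intensities.
#' @param config A [detection_config()].
#' @param response Optional response matrix used for centroid weights and
#'   detector scores; defaults to the image intensities.
#'
#' @return List of `calc_candidate` objects with fields `center` (0-based
#'   `(x, y)`), `patch`, `detector_score`, `verifier_prob`.
#' @export
extract_candidates <- function(detection_mask, image,
                               config = detection_config(),
                               response = NULL) {
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  resp <- response %||% px
  lab <- .cg_label_components(matrix(as.integer(detection_mask),
                                     nrow(detection_mask)), 8L)
  n_comp <- max(lab)
  if (n_comp == 0L) return(list())
  cands <- list()
  for (cc in seq_len(n_comp)) {
    idx <- which(lab == cc, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < config$min_blob_area || area > config$max_blob_area) next
    w <- resp[idx]
    if (sum(w) <= 0) w <- rep(1, area)
    cy <- round(sum((idx[, 1L] - 1L) * w) / sum(w))
    cx <- round(sum((idx[, 2L] - 1L) * w) / sum(w))
    cands[[length(cands) + 1L]] <- structure(
      list(center = c(x = cx, y = cy),
           patch = extract_patch(px, cx, cy, config$patch_size),
           detector_score = max(resp[idx]),
           verifier_prob = NA_real_),
      class = "calc_candidate")
  }
  if (length(cands) == 0L) return(list())
  ord <- order(vapply(cands, function(c) c$center["y"], 0),
               vapply(cands, function(c) c$center["x"], 0))
  cands[ord]
}

#' Run the full calcification detector on one image
#'
#' Segments the breast (unless a mask is given), computes the white top-hat
#' response, thresholds it and extracts candidates. If a trained verifier
#' model is supplied, candidates are filtered at the configured cutoff.
#'
#' @param image A [mammogram_image()].
#' @param mask Optional precomputed `breast_mask`.
#' @param config A [detection_config()].
#' @param verifier Optional verifier model from [train_verifier()].
#' @return List of candidates (see [extract_candidates()]).
#' @export
detect_calcifications <- function(image, mask = NULL,
                                  config = detection_config(),
                                  verifier = NULL) {
  if (is.null(mask)) mask <- segment_breast(image)
  base <- if (isTRUE(config$enhance)) {
    mammogram_image(pmax(enhance_contrast(image, config$se_radius), 0),
                    source_id = image$source_id, bit_depth = NA_integer_)
  } else {
    image
  }
  resp <- top_hat_transform(base, config$se_radius)
  det <- threshold_detect(resp, mask, config)
  cands <- extract_candidates(det, image, config, response = resp)
  if (!is.null(verifier)) {
    cands <- filter_candidates(cands, verifier, config$verifier_cutoff)
  }
  cands
}

#' Filter candidates with a trained verifier
#'
#' Scores every candidate patch with the verifier CNN and keeps those with
#' probability at or above the cutoff; kept candidates are annotated with
#' `verifier_prob`, in their original order.
#'
#' @param candidates List of candidates from [extract_candidates()].
#' @param model A verifier model from [train_verifier()].
#' @param cutoff Probability cutoff in \[0, 1\].
#' @return Filtered candidate list.
#' @export
filter_candidates <- function(candidates, model, cutoff = 0.5) {
  if (length(candidates) == 0L) return(candidates)
  probs <- predict_verifier(model, lapply(candidates, `[[`, "patch"))
  out <- list()
  for (i in seq_along(candidates)) {
    if (probs[i] >= cutoff) {
      cand <- candidates[[i]]
      cand$verifier_prob <- probs[i]
      out[[length(out) + 1L]] <- cand
    }
  }
  out
}
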