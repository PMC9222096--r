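# Synthetic mammographic phantoms with exact calcification ground truth.
#
# The breast is a half-ellipse of bright parenchyma attached to the left
# (chest-wall) image edge, with smoothed random texture and i.i.d. pixel
# noise. Calcifications are small Gaussian blobs planted according to the
# geometry of the five BI-RADS distribution descriptors. All scales default
# to a 256 x 256 frame and scale linearly with the image minimum dimension.

breast_geometry <- function(image_shape) {
  h <- image_shape[1L]; w <- image_shape[2L]
  list(cx = 0, cy = (h - 1) / 2, a = 0.82 * w, b = 0.42 * h)
}

inside_breast <- function(x, y, geom, shrink = 1) {
  ((x - geom$cx) / (geom$a * shrink))^2 +
    ((y - geom$cy) / (geom$b * shrink))^2 <= 1 & x >= geom$cx
}

#' Pattern specification for a synthetic phantom
#'
#' Encodes one of the five distribution descriptors with its geometric
#' parameters. Class geometries (in pixels, at the default 256 x 256 frame;
#' they scale with the image minimum dimension):
#' * `grouped`: spots uniform in a disc of radius 18 (a small cluster),
#' * `regional`: disc of radius 55 (a large, non-duct-conforming area),
#' * `diffuse`: uniform over the whole breast,
#' * `linear`: a band of half-width 2.5 along a random line of length 120,
#' * `segmental`: a wedge of half-angle 12 degrees and length 140 with its
#'   apex at the nipple point of the breast boundary.
#' Spots are kept at least `min_separation` apart so individual
#' calcifications stay resolvable.
#'
#' @param label One of the five distribution classes.
#' @param n_spots Spot count, or `NULL` to draw uniformly from the class
#'   default range (grouped 8-25, regional 20-60, diffuse 40-120, linear
#'   8-20, segmental 20-60).
#' @param image_shape `(H, W)` of the phantom.
#' @param spot_radius_range Spot radius range in px (default 1-4, i.e.
#'   diameters of roughly 2-8 px).
#' @param spot_amplitude Peak spot intensity above the local background.
#' @param noise_sigma Standard deviation of the i.i.d. pixel noise.
#' @param texture_amplitude Amplitude of the smoothed parenchymal texture.
#' @param min_separation Minimum distance between planted spot centers (px).
#' @param n_decoys Additional decoy spots scattered diffusely over the whole
#'   breast regardless of the class geometry (default 0). Decoys emulate
#'   incidental calcifications that do not belong to the annotated pattern;
#'   the ground truth marks them (`is_decoy` attribute), so interpretability
#'   experiments can ask whether explanations ignore them.
#' @param seed RNG seed; every artifact is a pure function of its spec.
#' @return A `pattern_spec` list.
#' @export
pattern_spec <- function(label, n_spots = NULL, image_shape = c(256L, 256L),
                         spot_radius_range = c(1, 4), spot_amplitude = 0.25,
                         noise_sigma = 0.02, texture_amplitude = 0.06,
                         min_separation = 6, n_decoys = 0L, seed = 0L) {
  label <- as.character(as_calc_label(label))
  structure(list(label = label, n_spots = n_spots,
                 image_shape = as.integer(image_shape),
                 spot_radius_range = spot_radius_range,
                 spot_amplitude = spot_amplitude, noise_sigma = noise_sigma,
                 texture_amplitude = texture_amplitude,
                 min_separation = min_separation,
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed)),
            class = "pattern_spec")
}

default_spot_range <- function(label) {
  switch(label,
         grouped = c(8L, 25L), regional = c(20L, 60L),
         diffuse = c(40L, 120L), linear = c(8L, 20L),
         segmental = c(20L, 60L))
}

# rejection-sample one point inside the (shrunken) breast
sample_in_breast <- function(geom, shrink = 0.9) {
  repeat {
    x <- runif(1, 0, geom$a * shrink)
    y <- runif(1, geom$cy - geom$b * shrink, geom$cy + geom$b * shrink)
    if (inside_breast(x, y, geom, shrink)) return(c(x, y))
  }
}

far_enough <- function(pt, pts, dmin) {
  if (length(pts) == 0L) return(TRUE)
  m <- matrix(pts, ncol = 2L, byrow = TRUE)
  all((m[, 1L] - pt[1L])^2 + (m[, 2L] - pt[2L])^2 >= dmin^2)
}

#' Sample calcification coordinates for a distribution pattern
#'
#' Draws spot centers according to the class geometry of the `pattern_spec`,
#' entirely inside the breast, honouring the minimum separation. Uses the
#' spec's seed, so repeated calls are identical.
#'
#' @param spec A [pattern_spec()].
#' @return `n x 2` matrix of `(x, y)` coordinates with the sampled geometry
#'   parameters attached as attribute `"geometry"`.
#' @export
sample_pattern_coords <- function(spec) {
  set.seed(spec$seed)
  geom <- breast_geometry(spec$image_shape)
  s <- min(spec$image_shape) / 256
  n <- spec$n_spots %||% {
    r <- default_spot_range(spec$label)
    sample(seq.int(r[1L], r[2L]), 1L)
  }
  dmin <- spec$min_separation
  info <- list(label = spec$label, n = n)
  pts <- numeric(0)

  draw <- function(proposal) {
    tries <- 0L
    repeat {
      p <- proposal()
      tries <- tries + 1L
      if ((far_enough(p, pts, dmin) &&
           inside_breast(p[1L], p[2L], geom, 0.95)) || tries > 400L) {
        return(p)
      }
    }
  }

  if (n > 0L) {
    if (spec$label == "diffuse") {
      for (i in seq_len(n)) pts <- c(pts, draw(function() sample_in_breast(geom, 0.9)))
    } else if (spec$label %in% c("grouped", "regional")) {
      radius <- if (spec$label == "grouped") 18 * s else 55 * s
      repeat {
        ctr <- sample_in_breast(geom, 0.7)
        edge <- ctr + c(radius, 0)
        if (inside_breast(edge[1L], edge[2L], geom, 0.95) &&
            inside_breast(ctr[1L] - radius, ctr[2L], geom, 0.95) &&
            ctr[1L] - radius >= 0) break
      }
      info$center <- ctr; info$radius <- radius
      for (i in seq_len(n)) {
        pts <- c(pts, draw(function() {
          u <- sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
          ctr + radius * u * c(cos(th), sin(th))
        }))
      }
    } else if (spec$label == "linear") {
      len <- 120 * s; hw <- 2.5 * s
      repeat {
        ctr <- sample_in_breast(geom, 0.6)
        th <- runif(1, 0, pi)
        e1 <- ctr + len / 2 * c(cos(th), sin(th))
        e2 <- ctr - len / 2 * c(cos(th), sin(th))
        if (inside_breast(e1[1L], e1[2L], geom, 0.92) &&
            inside_breast(e2[1L], e2[2L], geom, 0.92) &&
            min(e1[1L], e2[1L]) >= 0) break
      }
      info$center <- ctr; info$theta <- th; info$length <- len
      info$half_width <- hw
      dir <- c(cos(th), sin(th)); nrm <- c(-sin(th), cos(th))
      for (i in seq_len(n)) {
        pts <- c(pts, draw(function() {
          ctr + runif(1, -len / 2, len / 2) * dir + runif(1, -hw, hw) * nrm
        }))
      }
    } else { # segmental
      wl <- 140 * s; half_angle <- 12 * pi / 180
      apex <- c(0.95 * geom$a, geom$cy)
      tilt <- runif(1, -10, 10) * pi / 180
      dir_angle <- pi + tilt   # pointing from the nipple towards the chest wall
      info$apex <- apex; info$angle <- dir_angle; info$length <- wl
      info$half_angle <- half_angle
      for (i in seq_len(n)) {
        pts <- c(pts, draw(function() {
          t <- wl * sqrt(runif(1))
          phi <- dir_angle + runif(1, -half_angle, half_angle)
          apex + t * c(cos(phi), sin(phi))
        }))
      }
    }
  }
  n_pattern <- length(pts) / 2L
  n_dec <- spec$n_decoys %||% 0L
  for (i in seq_len(n_dec)) {
    pts <- c(pts, draw(function() sample_in_breast(geom, 0.9)))
  }
  coords <- matrix(pts, ncol = 2L, byrow = TRUE,
                   dimnames = list(NULL, c("x", "y")))
  attr(coords, "geometry") <- info
  attr(coords, "is_decoy") <- c(rep(FALSE, n_pattern), rep(TRUE, n_dec))
  coords
}

#' Generate a synthetic mammogram phantom
#'
#' Builds the textured half-ellipse breast, plants Gaussian calcification
#' spots at coordinates from [sample_pattern_coords()], and adds pixel
#' noise. Deterministic per spec/seed.
#'
#' @param spec A [pattern_spec()].
#' @return List with `image` (a unit-scaled [mammogram_image()]), `mask`
#'   (the exact analytic breast mask), `spots` (data frame of planted
#'   centers `x, y`, `radius`), `label`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  coords <- sample_pattern_coords(spec)
  set.seed(spec$seed + 1L)
  h <- spec$image_shape[1L]; w <- spec$image_shape[2L]
  geom <- breast_geometry(spec$image_shape)
  xg <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  yg <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  breast <- inside_breast(xg, yg, geom)

  img <- matrix(0.02, h, w)
  tex <- matrix(rnorm(h * w), h, w)
  tex <- EBImage::gblur(tex, sigma = 8)
  tex <- (tex - mean(tex)) / sd(tex)
  img[breast] <- 0.35 + spec$texture_amplitude * tex[breast]

  n <- nrow(coords)
  radii <- if (n > 0L) runif(n, spec$spot_radius_range[1L],
                             spec$spot_radius_range[2L]) else numeric(0)
  for (i in seq_len(n)) {
    sg <- radii[i] / 2
    win <- ceiling(3 * sg)
    cx <- coords[i, 1L]; cy <- coords[i, 2L]
    rr <- max(1L, floor(cy + 1 - win)):min(h, ceiling(cy + 1 + win))
    cc <- max(1L, floor(cx + 1 - win)):min(w, ceiling(cx + 1 + win))
    blob <- spec$spot_amplitude *
      exp(-(outer((rr - 1 - cy)^2, (cc - 1 - cx)^2, `+`)) / (2 * sg^2))
    img[rr, cc] <- img[rr, cc] + blob
  }
  img <- img + rnorm(h * w, sd = spec$noise_sigma)
  img <- clamp(img, 0, 1)
  list(image = mammogram_image(img, source_id = sprintf("phantom-%s-%d",
                                                        spec$label, spec$seed)),
       mask = breast,
       spots = data.frame(x = coords[, 1L], y = coords[, 2L],
                          radius = radii),
       label = as_calc_label(spec$label), spec = spec)
}

largest_remainder_counts <- function(mix, n) {
  raw <- mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Class-mix presets
#'
#' `"balanced"` gives equal proportions; `"clinical"` mirrors the strong
#' imbalance of symptomatic breast-cancer cohorts, where grouped
#' calcifications dominate: diffuse 6.0%, regional 27.7%, grouped 50.1%,
#' linear 2.0%, segmental 14.2%.
#'
#' @param preset `"clinical"` or `"balanced"`.
#' @return Named numeric vector summing to 1, in canonical class order.
#' @export
class_mix <- function(preset = c("clinical", "balanced")) {
  preset <- match.arg(preset)
  if (preset == "balanced") {
    setNames(rep(0.2, 5L), calc_classes())
  } else {
    c(diffuse = 0.060, regional = 0.277, grouped = 0.501, linear = 0.020,
      segmental = 0.142)
  }
}

#' Generate a labelled phantom image dataset
#'
#' Stratified sampling of pattern specs with largest-remainder rounding of
#' the class mix; the manifest records every per-image spec and seed, so the
#' dataset is a pure function of `(class_mix, n_images, seed)`.
#'
#' @param mix Named class proportions summing to 1 (see [class_mix()]).
#' @param n_images Number of phantoms.
#' @param seed Master seed.
#' @param image_shape Phantom size.
#' @param ... Further arguments to [pattern_spec()].
#' @return List with `phantoms` (list from [generate_phantom()]), `labels`
#'   and `manifest`.
#' @export
generate_dataset <- function(mix = class_mix("clinical"), n_images = 100L,
                             seed = 0L, image_shape = c(256L, 256L), ...) {
  mix <- mix[calc_classes()]
  assert_that(!anyNA(mix) && abs(sum(mix) - 1) < 1e-8,
              "class mix must cover all classes and sum to 1")
  counts <- largest_remainder_counts(mix, n_images)
  labels <- rep(calc_classes(), counts)
  assert_that(n_images >= sum(mix > 0), "n_images too small for the mix")
  set.seed(seed)
  item_seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  manifest <- data.frame(id = seq_len(n_images), label = labels,
                         seed = item_seeds)
  phantoms <- lapply(seq_len(n_images), function(i) {
    generate_phantom(pattern_spec(labels[i], image_shape = image_shape,
                                  seed = item_seeds[i], ...))
  })
  list(phantoms = phantoms, labels = as_calc_label(labels),
       manifest = manifest)
}

#' Generate a labelled graph dataset (no images)
#'
#' Samples node coordinates directly from the pattern geometries and builds
#' kNN calcification graphs, skipping the imaging stage. `feature_mode
#' = "geometric"` uses [geometric_node_features()]; `"random"` replaces them
#' with seeded noise so the features carry no signal (for null experiments).
#'
#' @inheritParams generate_dataset
#' @param n_graphs Number of graphs.
#' @param feature_mode `"geometric"` or `"random"`.
#' @param k kNN neighbour count.
#' @return List with `graphs`, `labels` and `manifest`.
#' @export
generate_graph_dataset <- function(mix = class_mix("clinical"),
                                   n_graphs = 100L, seed = 0L,
                                   feature_mode = c("geometric", "random"),
                                   image_shape = c(256L, 256L), k = 8L, ...) {
  feature_mode <- match.arg(feature_mode)
  mix <- mix[calc_classes()]
  assert_that(!anyNA(mix) && abs(sum(mix) - 1) < 1e-8,
              "class mix must cover all classes and sum to 1")
  counts <- largest_remainder_counts(mix, n_graphs)
  labels <- rep(calc_classes(), counts)
  set.seed(seed)
  item_seeds <- sample.int(.Machine$integer.max - 1L, n_graphs)
  manifest <- data.frame(id = seq_len(n_graphs), label = labels,
                         seed = item_seeds)
  graphs <- lapply(seq_len(n_graphs), function(i) {
    coords <- sample_pattern_coords(
      pattern_spec(labels[i], image_shape = image_shape,
                   seed = item_seeds[i], ...))
    graph_from_coords(coords, image_shape, label = labels[i], k = k,
                      feature_mode = feature_mode,
                      image_id = sprintf("graph-%s-%d", labels[i],
                                         item_seeds[i]),
                      rng_seed = item_seeds[i])
  })
  list(graphs = graphs, labels = as_calc_label(labels), manifest = manifest)
}
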