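# Synthetic phantom generator: bright compact regions on a dark background,
# optional corner wedge, smooth illumination gradient and seeded noise, with
# exact ground-truth masks. Emulates the structure the segmenter assumes in
# mammogram-style images (bright masses on darker tissue).

with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic phantom image with ground truth
#'
#' Builds a single-channel test image: a uniform dark background carrying
#' one or more bright disks (optionally with soft, linearly ramped edges), an
#' optional bright corner wedge emulating a pectoral-muscle-like distractor,
#' an optional smooth illumination gradient, and optional additive Gaussian
#' noise. All randomness is fixed by `seed`; intensities are clipped to
#' `[0, 255]`. Ground truth for each blob is its exact support
#' `{x : dist(x, center) < radius}`, unaffected by softness, gradient or
#' noise.
#'
#' @param shape Integer vector `c(rows, cols)`. Default `c(128, 128)`.
#' @param background Background intensity. Default 30.
#' @param blobs List of blob specs: `list(center = c(row, col), radius,
#'   intensity, softness = 0)`. `softness` is the width (pixels) of a linear
#'   intensity ramp outside the radius, emulating weak or blurred edges.
#' @param wedge Optional `list(size, intensity)`: a right triangle of leg
#'   `size` pixels in the top-left corner.
#' @param illumination Optional `list(direction, amplitude)` with direction
#'   `"horizontal"` or `"vertical"`: adds a linear ramp of
#'   `amplitude * (t - 0.5)` across the image, `t` in `[0, 1]`.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#'   Default 0.
#' @param seed Integer seed fixing the noise; `NULL` leaves the RNG state
#'   alone.
#' @return List with `image` (numeric matrix in `[0, 255]`) and `truth`
#'   (list of logical matrices, one per blob).
#' @export
make_phantom <- function(shape = c(128, 128), background = 30,
                         blobs = list(), wedge = NULL, illumination = NULL,
                         noise_sigma = 0, seed = NULL) {
  nr <- as.integer(shape[1])
  nc <- as.integer(shape[2])
  if (background < 0 || background > 255) {
    stop("`background` must lie in [0, 255]", call. = FALSE)
  }
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img <- matrix(background, nr, nc)
  truth <- vector("list", length(blobs))
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    softness <- if (is.null(b$softness)) 0 else b$softness
    if (is.null(b$center) || is.null(b$radius) || is.null(b$intensity)) {
      stop("each blob needs `center`, `radius` and `intensity`",
           call. = FALSE)
    }
    if (b$radius <= 0) stop("blob radius must be positive", call. = FALSE)
    if (b$intensity < 0 || b$intensity > 255) {
      stop("blob intensity must lie in [0, 255]", call. = FALSE)
    }
    if (b$center[1] - b$radius < 1 || b$center[1] + b$radius > nr ||
        b$center[2] - b$radius < 1 || b$center[2] + b$radius > nc) {
      stop("blob extends outside the image frame", call. = FALSE)
    }
    d <- sqrt((rr - b$center[1])^2 + (cc - b$center[2])^2)
    core <- d < b$radius
    img[core] <- b$intensity
    if (softness > 0) {
      ramp <- d >= b$radius & d < b$radius + softness
      frac <- (d[ramp] - b$radius) / softness
      img[ramp] <- b$intensity + (background - b$intensity) * frac
    }
    truth[[i]] <- core
  }
  if (!is.null(wedge)) {
    tri <- (rr - 1) + (cc - 1) < wedge$size
    img[tri] <- wedge$intensity
  }
  if (!is.null(illumination)) {
    t <- if (identical(illumination$direction, "vertical")) {
      (rr - 1) / (nr - 1)
    } else {
      (cc - 1) / (nc - 1)
    }
    img <- img + illumination$amplitude * (t - 0.5)
  }
  if (noise_sigma > 0) {
    img <- img + with_seed(seed,
                           matrix(stats::rnorm(nr * nc, 0, noise_sigma),
                                  nr, nc))
  }
  img <- pmin(pmax(img, 0), 255)
  list(image = img, truth = truth)
}

#' Generate a concentric stepped phantom
#'
#' A nested sequence of concentric disks with strictly decreasing radii and
#' strictly increasing intensities, so an inward-evolving segmentation
#' produces a chain of nested contours and the innermost region carries the
#' global intensity maximum. Supports the inclusion-tree analyses.
#'
#' @param levels List of `c(radius, intensity)` pairs (or a 2-column
#'   matrix), outermost first; radii strictly decreasing, intensities
#'   strictly increasing.
#' @param shape Integer vector `c(rows, cols)`. Default `c(128, 128)`.
#' @param background Background intensity. Default 30.
#' @param center Disk center `c(row, col)`; default the image center.
#' @param noise_sigma,seed As in [make_phantom()].
#' @return List with `image` and `truth` (one logical mask per level,
#'   outermost first).
#' @export
make_nested_phantom <- function(levels, shape = c(128, 128),
                                background = 30, center = NULL,
                                noise_sigma = 0, seed = NULL) {
  if (is.matrix(levels)) {
    levels <- lapply(seq_len(nrow(levels)), function(i) levels[i, ])
  }
  radii <- vapply(levels, `[`, 0, 1)
  intens <- vapply(levels, `[`, 0, 2)
  if (length(radii) == 0) stop("`levels` must be nonempty", call. = FALSE)
  if (any(diff(radii) >= 0)) {
    stop("radii must be strictly decreasing", call. = FALSE)
  }
  if (any(diff(intens) <= 0)) {
    stop("intensities must be strictly increasing", call. = FALSE)
  }
  nr <- as.integer(shape[1])
  nc <- as.integer(shape[2])
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  img <- matrix(background, nr, nc)
  truth <- vector("list", length(radii))
  for (i in seq_along(radii)) {
    if (center[1] - radii[i] < 1 || center[1] + radii[i] > nr ||
        center[2] - radii[i] < 1 || center[2] + radii[i] > nc) {
      stop("disk extends outside the image frame", call. = FALSE)
    }
    mask <- d < radii[i]
    img[mask] <- intens[i]
    truth[[i]] <- mask
  }
  if (noise_sigma > 0) {
    img <- img + with_seed(seed,
                           matrix(stats::rnorm(nr * nc, 0, noise_sigma),
                                  nr, nc))
    img <- pmin(pmax(img, 0), 255)
  }
  list(image = img, truth = truth)
}
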