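# Grid numerics shared by the level-set evolver: regularized Heaviside/Dirac,
# central-difference gradients, curvature, Gaussian kernel regularization and
# level-set initialization.

#' Regularized Heaviside function
#'
#' Smooth arctangent surrogate for the unit step,
#' \eqn{H_\epsilon(z) = \frac{1}{2}\left(1 + \frac{2}{\pi}\arctan(z/\epsilon)\right)}.
#' Used to weight interior/exterior region membership of the level-set field.
#'
#' @param z Numeric scalar, vector or matrix.
#' @param epsilon Positive regularization width (grid units). Default 1.5.
#' @return Object shaped like `z`, values strictly inside (0, 1).
#' @seealso [dirac()], its analytic derivative.
#' @examples
#' heaviside(0)            # 0.5
#' heaviside(1.5, 1.5)     # 0.75
#' @export
heaviside <- function(z, epsilon = 1.5) {
  check_epsilon(epsilon)
  0.5 * (1 + (2 / pi) * atan(z / epsilon))
}

#' Regularized Dirac delta
#'
#' Derivative of [heaviside()]:
#' \eqn{\delta_\epsilon(z) = \epsilon / (\pi (z^2 + \epsilon^2))}.
#'
#' @inheritParams heaviside
#' @return Nonnegative object shaped like `z`, maximal at `z = 0` where it
#'   equals `1/(pi * epsilon)`.
#' @export
dirac <- function(z, epsilon = 1.5) {
  check_epsilon(epsilon)
  epsilon / (pi * (z^2 + epsilon^2))
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("`epsilon` must be a single positive number", call. = FALSE)
  }
  invisible(epsilon)
}

# Central-difference gradient with replicate-edge padding. Returns the
# row-direction and column-direction derivatives (1/pixel).
grad_central <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  list(dr = (dn - up) / 2, dc = (rt - lf) / 2)
}

#' Curvature of the level-set field
#'
#' Mean curvature of the isolines of `phi`,
#' \eqn{\kappa = \mathrm{div}(\nabla\phi / |\nabla\phi|)}, computed with
#' central differences (replicate-edge padding). The gradient magnitude is
#' guarded by a small constant so flat regions return 0 rather than 0/0.
#'
#' @param phi Numeric matrix (the level-set field).
#' @param eta Positive guard added to the gradient magnitude. Default 1e-10.
#' @return Numeric matrix of curvatures (1/pixel), finite everywhere.
#' @export
curvature <- function(phi, eta = 1e-10) {
  stopifnot(is.matrix(phi), all(is.finite(phi)))
  g <- grad_central(phi)
  mag <- sqrt(g$dr^2 + g$dc^2) + eta
  divergence(g$dr / mag, g$dc / mag)
}

# Divergence of a vector field given by row/column components.
divergence <- function(fr, fc) {
  grad_central(fr)$dr + grad_central(fc)$dc
}

# Normalized K x K Gaussian kernel as a 1-D separable weight vector.
gaussian_weights <- function(kernel_width, kernel_sigma) {
  if (!is.numeric(kernel_width) || length(kernel_width) != 1L ||
      kernel_width < 1 || kernel_width %% 2 != 1) {
    stop("`kernel_width` must be an odd positive integer", call. = FALSE)
  }
  if (!is.numeric(kernel_sigma) || length(kernel_sigma) != 1L ||
      kernel_sigma <= 0) {
    stop("`kernel_sigma` must be a single positive number", call. = FALSE)
  }
  half <- (kernel_width - 1) / 2
  w <- exp(-(seq(-half, half))^2 / (2 * kernel_sigma^2))
  w / sum(w)
}

# Separable convolution with a symmetric 1-D kernel, replicate-edge padding.
conv_separable <- function(m, w) {
  k <- length(w)
  p <- (k - 1L) / 2L
  nr <- nrow(m)
  nc <- ncol(m)
  idx <- c(rep(1L, p), seq_len(nr), rep(nr, p))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_len(k)) {
    out <- out + w[j] * mp[j:(j + nr - 1L), , drop = FALSE]
  }
  idx <- c(rep(1L, p), seq_len(nc), rep(nc, p))
  mp <- out[, idx, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_len(k)) {
    out <- out + w[j] * mp[, j:(j + nc - 1L), drop = FALSE]
  }
  out
}

#' Gaussian kernel regularization of the level-set field
#'
#' Convolves `phi` with a normalized `K x K` Gaussian
#' (\eqn{\phi \leftarrow G_\sigma * \phi}), the smoothing that replaces
#' reinitialization to a signed distance function in this model. Edges are
#' handled by replicate padding; the discrete kernel weights sum to 1, so the
#' output is a convex combination of input values and never exceeds the input
#' range.
#'
#' @param phi Numeric matrix.
#' @param kernel_width Odd positive integer window side `K`. Default 5.
#' @param kernel_sigma Positive Gaussian standard deviation (pixels).
#'   Default 1.
#' @return Numeric matrix, same shape as `phi`.
#' @export
gaussian_regularize <- function(phi, kernel_width = 5, kernel_sigma = 1) {
  stopifnot(is.matrix(phi))
  conv_separable(phi, gaussian_weights(kernel_width, kernel_sigma))
}

#' Initialize the level-set field
#'
#' Builds the initial field \eqn{\phi_0}: `+rho` strictly inside the initial
#' contour, 0 on it, `-rho` outside, so that \eqn{\phi > 0} marks the
#' interior. The default contour is an axis-aligned rectangle inset `margin`
#' pixels from the image border, the placement used to compute whole-image
#' contour maps.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param region Initial contour geometry: either
#'   `list(type = "rect", rmin, rmax, cmin, cmax)` (1-based inclusive bounds
#'   of the contour itself) or `list(type = "circle", center = c(row, col),
#'   radius)`. `NULL` (default) uses the inset rectangle.
#' @param rho Positive initialization magnitude. Default 2.
#' @param margin Border inset (pixels) for the default rectangle. Default 5.
#' @return Numeric matrix of dimension `shape` with values in
#'   `{-rho, 0, +rho}`.
#' @export
init_levelset <- function(shape, region = NULL, rho = 2, margin = 5) {
  if (length(shape) != 2L || any(shape < 3)) {
    stop("`shape` must be two grid dimensions of at least 3", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) {
    stop("`rho` must be a single positive number", call. = FALSE)
  }
  nr <- as.integer(shape[1])
  nc <- as.integer(shape[2])
  if (is.null(region)) {
    region <- list(type = "rect", rmin = margin + 1, rmax = nr - margin,
                   cmin = margin + 1, cmax = nc - margin)
  }
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  if (identical(region$type, "circle")) {
    ctr <- region$center
    rad <- region$radius
    if (rad <= 0 || ctr[1] - rad < 1 || ctr[1] + rad > nr ||
        ctr[2] - rad < 1 || ctr[2] + rad > nc) {
      stop("initial circle is empty or extends outside the image domain",
           call. = FALSE)
    }
    d <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
    phi <- rho * sign(rad - d)
  } else if (identical(region$type, "rect")) {
    with(region, {
      if (rmin < 1 || cmin < 1 || rmax > nr || cmax > nc ||
          rmax - rmin < 2 || cmax - cmin < 2) {
        stop("initial rectangle is empty or extends outside the image domain",
             call. = FALSE)
      }
    })
    inside <- rr > region$rmin & rr < region$rmax &
      cc > region$cmin & cc < region$cmax
    outside <- rr < region$rmin | rr > region$rmax |
      cc < region$cmin | cc > region$cmax
    phi <- matrix(0, nr, nc)
    phi[inside] <- rho
    phi[outside] <- -rho
  } else {
    stop("unknown initial contour type: ", region$type, call. = FALSE)
  }
  phi
}
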