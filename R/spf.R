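# The region model: masked region means c1/c2, the two-phase global fitted
# image, the masked signed pressure force field, and the subregion recursion.

#' Masked region means
#'
#' Mean intensities of the interior and exterior of the current contour,
#' restricted to the current subregion mask:
#' \deqn{c_1 = \frac{\sum I\, H_\epsilon(\phi)\, M}{\sum H_\epsilon(\phi)\, M},
#'       \qquad
#'       c_2 = \frac{\sum I\, (1-H_\epsilon(\phi))\, M}{\sum (1-H_\epsilon(\phi))\, M}.}
#' Because the regularized Heaviside is strictly inside (0, 1), both
#' denominators are positive whenever the mask is nonempty; an empty weighted
#' region is reported via `degenerate = TRUE` and is used by the segmentation
#' loop as a termination signal.
#'
#' @param image Numeric matrix of intensities.
#' @param phi Level-set field, same shape.
#' @param mask Logical matrix, the current subregion indicator `M^k`.
#' @param epsilon Heaviside regularization width. Default 1.5.
#' @return List with elements `c1`, `c2` (intensity units) and `degenerate`
#'   (logical).
#' @export
region_means <- function(image, phi, mask, epsilon = 1.5) {
  stopifnot(is.matrix(image), all(dim(image) == dim(phi)),
            all(dim(image) == dim(mask)))
  h <- heaviside(phi, epsilon)
  m <- mask * 1
  d1 <- sum(h * m)
  d2 <- sum((1 - h) * m)
  if (d1 <= 0 || d2 <= 0) {
    return(list(c1 = NA_real_, c2 = NA_real_, degenerate = TRUE))
  }
  list(c1 = sum(image * h * m) / d1,
       c2 = sum(image * (1 - h) * m) / d2,
       degenerate = FALSE)
}

#' Two-phase global fitted image
#'
#' Piecewise approximation of the image from the two region means,
#' \eqn{I_{GFI} = c_1 H_\epsilon(\phi) + c_2 (1 - H_\epsilon(\phi))}.
#'
#' @param stats List with `c1`, `c2` as returned by [region_means()].
#' @param phi Level-set field.
#' @param epsilon Heaviside regularization width. Default 1.5.
#' @return Numeric matrix with every value in `[min(c1,c2), max(c1,c2)]`.
#' @export
global_fitted_image <- function(stats, phi, epsilon = 1.5) {
  if (!is.finite(stats$c1) || !is.finite(stats$c2)) {
    stop("region means are not finite; cannot build the fitted image",
         call. = FALSE)
  }
  h <- heaviside(phi, epsilon)
  stats$c1 * h + stats$c2 * (1 - h)
}

#' Masked signed pressure force field
#'
#' The force that drives the contour:
#' \deqn{\mathrm{spf}(x) = \frac{(I(x) - I_{GFI}(x))\, M(x)}
#'                              {\max_\Omega |I - I_{GFI}|}}
#' for \eqn{I(x) \neq 0}, and 0 where \eqn{I(x) = 0}. The normalizing maximum
#' is taken over the whole image domain before mask multiplication, so values
#' lie in `[-1, 1]`, are exactly 0 off-mask and at zero-intensity pixels, and
#' `|spf| = 1` is attained whenever the maximizing pixel is masked-in and
#' nonzero. On a bright object over a darker background the sign is negative
#' in the masked background and positive inside the object, which moves the
#' contour inwards onto the bright region.
#'
#' A perfectly fitted (constant) image makes the normalizer zero; the field
#' is then all zero with attribute `degenerate = TRUE`, which terminates the
#' segmentation loop gracefully.
#'
#' @param image Numeric matrix of intensities.
#' @param gfi Global fitted image from [global_fitted_image()].
#' @param mask Logical matrix, current subregion indicator.
#' @param zero_tol Tolerance for the `I = 0` test (exact on 8-bit integer
#'   data; a small tolerance covers float input). Default 1e-12.
#' @return Numeric matrix in `[-1, 1]` with attribute `degenerate`.
#' @export
spf <- function(image, gfi, mask, zero_tol = 1e-12) {
  stopifnot(all(dim(image) == dim(gfi)), all(dim(image) == dim(mask)))
  d <- image - gfi
  mx <- max(abs(d))
  if (mx == 0) {
    out <- matrix(0, nrow(image), ncol(image))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- d * (mask * 1) / mx
  out[abs(image) <= zero_tol] <- 0
  attr(out, "degenerate") <- FALSE
  out
}

#' Subregion mask from the level-set field
#'
#' The characteristic function of the current subregion,
#' \eqn{M^k(x) = [\phi(x) > 0]}. An all-`FALSE` result signals that the
#' formulation has degenerated and the algorithm terminates.
#'
#' @param phi Level-set field.
#' @return Logical matrix.
#' @export
update_mask <- function(phi) {
  stopifnot(is.matrix(phi), all(is.finite(phi)))
  phi > 0
}

#' Outer subregion between two nested masks
#'
#' The region discarded between consecutive contours,
#' \eqn{\bar w_k = w_{k-1} \setminus w_k}. `curr` is intersected with `prev`
#' first, so the result together with `curr` always partitions `prev`.
#'
#' @param prev Logical matrix, previous (enclosing) subregion.
#' @param curr Logical matrix, current (nested) subregion.
#' @return Logical matrix.
#' @export
outer_region <- function(prev, curr) {
  stopifnot(all(dim(prev) == dim(curr)))
  prev & !(curr & prev)
}
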