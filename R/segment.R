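# The outer segmentation loop and the S3 surface of the fitted object.

#' Segment bright regions of interest by an inward-moving active contour
#'
#' Fits the region-based active contour: a level-set contour initialized
#' near the image border evolves strictly inwards under a masked signed
#' pressure force, discarding the outer subregion at every iteration, until
#' the similarity-based stopping rule fires, the subregion degenerates, or
#' the iteration cap is reached. Each iteration runs
#' [region_means()] -> [global_fitted_image()] -> [spf()] ->
#' [evolve_step()] -> [update_mask()] -> [gaussian_regularize()] ->
#' [stopping_check()]. After `n` iterations the run has represented `n + 1`
#' nested regions from the initial to the final contour.
#'
#' The subregion masks are nested by construction (\eqn{M^k \subseteq
#' M^{k-1}}): the new \eqn{\phi > 0} indicator is intersected with the
#' previous mask, so the recorded mask areas are non-increasing.
#'
#' @param image Numeric matrix of intensities in `[0, 255]`.
#' @param region Initial contour geometry passed to [init_levelset()];
#'   `NULL` uses the default rectangle inset `config$margin` pixels from the
#'   border.
#' @param config A [seg_config()].
#' @return An object of class `"spf_seg"`: a list with the input `image`,
#'   `final_mask` (logical), `phi` (final level-set field), `history` (data
#'   frame of iteration, c1, c2, mask area, stop ratio), `snapshots` (list
#'   of level-set fields recorded every `config$record_step` iterations) and
#'   `snapshot_iters`, `initial_mask`, `region`, `config`, `stopping_value`,
#'   `iterations`, and `termination` (one of `"stopping_rule"`,
#'   `"degenerate"`, `"max_iters"`).
#' @seealso [contour_map()], [seg_metrics()], [make_phantom()].
#' @examples
#' ph <- make_phantom(shape = c(64, 64),
#'                    blobs = list(list(center = c(32, 32), radius = 12,
#'                                      intensity = 220)))
#' fit <- spf_segment(ph$image, config = seg_config(max_iters = 100))
#' fit
#' dice(fit$final_mask, ph$truth[[1]])
#' @export
spf_segment <- function(image, region = NULL, config = seg_config()) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(image))) {
    stop("`image` must be finite everywhere", call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("`image` intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!inherits(config, "seg_config")) {
    stop("`config` must be created by seg_config()", call. = FALSE)
  }

  phi <- init_levelset(dim(image), region, rho = config$rho,
                       margin = config$margin)
  mask <- update_mask(phi)
  initial_mask <- mask
  if (!any(mask)) {
    stop("initial contour encloses no pixels", call. = FALSE)
  }
  sv <- if (is.numeric(config$stopping_value)) {
    config$stopping_value
  } else {
    compute_stopping_value(image, mask, config$threshold_T)
  }

  hist_iter <- integer(0)
  hist_c1 <- hist_c2 <- hist_area <- hist_ratio <- numeric(0)
  snapshots <- list()
  snapshot_iters <- integer(0)
  termination <- "max_iters"
  mask_moved <- FALSE
  quiet_run <- 0L
  iter <- 0L

  while (iter < config$max_iters) {
    iter <- iter + 1L
    rm <- region_means(image, phi, mask, config$epsilon)
    if (rm$degenerate) {
      termination <- "degenerate"
      iter <- iter - 1L
      break
    }
    gfi <- global_fitted_image(rm, phi, config$epsilon)
    force_field <- spf(image, gfi, mask)
    if (attr(force_field, "degenerate")) {
      termination <- "degenerate"
      iter <- iter - 1L
      break
    }
    phi <- evolve_step(phi, force_field, config)
    new_mask <- update_mask(phi) & mask
    phi <- gaussian_regularize(phi, config$kernel_width, config$kernel_sigma)

    old_area <- sum(mask)
    area <- sum(new_mask)
    ratio <- if (old_area > 0) 100 * area / old_area else 0
    hist_iter <- c(hist_iter, iter)
    hist_c1 <- c(hist_c1, rm$c1)
    hist_c2 <- c(hist_c2, rm$c2)
    hist_area <- c(hist_area, area)
    hist_ratio <- c(hist_ratio, ratio)
    if (config$verbose >= 1) {
      message(sprintf(
        "iter %4d  c1 = %8.3f  c2 = %8.3f  area = %7d  ratio = %7.3f%%",
        iter, rm$c1, rm$c2, area, ratio))
    }
    if (config$record_step > 0 && iter %% config$record_step == 0L) {
      snapshots[[length(snapshots) + 1L]] <- phi
      snapshot_iters <- c(snapshot_iters, iter)
    }

    big_change <- stopping_check(new_mask, mask, sv)
    if (config$stop_mode == "literal") {
      stop_now <- big_change
    } else {
      # converge: stop when, after the contour has started moving in
      # earnest (a > (100 - sv)% single-iteration change has occurred at
      # least once), `patience` consecutive iterations again keep at least
      # sv% of the previous area; an empty mask is handled by the
      # degeneracy branch below.
      quiet_run <- if (mask_moved && !big_change) quiet_run + 1L else 0L
      stop_now <- area > 0 && quiet_run >= config$patience
    }
    if (big_change) mask_moved <- TRUE
    mask <- new_mask
    if (stop_now) {
      termination <- "stopping_rule"
      break
    }
    if (area == 0) {
      termination <- "degenerate"
      break
    }
  }

  # the final contour always belongs to the map (the run represents n + 1
  # regions from the initial to the final contour)
  if (config$record_step > 0 && iter > 0 &&
      (length(snapshot_iters) == 0 ||
         snapshot_iters[length(snapshot_iters)] != iter)) {
    snapshots[[length(snapshots) + 1L]] <- phi
    snapshot_iters <- c(snapshot_iters, iter)
  }

  structure(list(
    image = image,
    final_mask = mask,
    phi = phi,
    history = data.frame(iteration = hist_iter, c1 = hist_c1, c2 = hist_c2,
                         area = hist_area, stop_ratio = hist_ratio),
    snapshots = snapshots,
    snapshot_iters = snapshot_iters,
    initial_mask = initial_mask,
    region = region,
    config = config,
    stopping_value = sv,
    iterations = iter,
    termination = termination
  ), class = "spf_seg")
}

#' @export
print.spf_seg <- function(x, ...) {
  cat("Region-based active contour segmentation (masked SPF)\n")
  cat(sprintf("  image: %d x %d, intensities [%g, %g]\n",
              nrow(x$image), ncol(x$image), min(x$image), max(x$image)))
  cat(sprintf("  iterations: %d (termination: %s)\n",
              x$iterations, x$termination))
  cat(sprintf("  stopping value: %.4f (mode: %s)\n",
              x$stopping_value, x$config$stop_mode))
  cat(sprintf("  final region: %d px (%.2f%% of initial region)\n",
              sum(x$final_mask),
              100 * sum(x$final_mask) / max(1, sum(x$initial_mask))))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final region means: c1 = %.3f, c2 = %.3f\n",
                last$c1, last$c2))
  }
  invisible(x)
}

#' @export
summary.spf_seg <- function(object, ...) {
  structure(list(fit = object), class = "summary.spf_seg")
}

#' @export
print.summary.spf_seg <- function(x, ...) {
  print(x$fit)
  h <- x$fit$history
  if (nrow(h) > 0) {
    cat("\nIteration history (last 6):\n")
    print(utils::tail(h, 6), row.names = FALSE)
  }
  cat(sprintf("\nSnapshots recorded: %d (every %d iterations)\n",
              length(x$fit$snapshots), x$fit$config$record_step))
  invisible(x)
}

#' Final region means of a fitted segmentation
#'
#' @param object An `"spf_seg"` fit.
#' @param ... Unused.
#' @return Named vector `c(c1 = , c2 = )`, the interior/exterior mean
#'   intensities at the final iteration.
#' @export
coef.spf_seg <- function(object, ...) {
  h <- object$history
  if (nrow(h) == 0) {
    return(c(c1 = NA_real_, c2 = NA_real_))
  }
  c(c1 = h$c1[nrow(h)], c2 = h$c2[nrow(h)])
}

#' Global fitted image of a segmentation
#'
#' @param object An `"spf_seg"` fit.
#' @param ... Unused.
#' @return The two-phase global fitted image
#'   \eqn{c_1 H_\epsilon(\phi) + c_2 (1-H_\epsilon(\phi))} at the final
#'   state, a numeric matrix.
#' @export
fitted.spf_seg <- function(object, ...) {
  cf <- coef(object)
  if (!all(is.finite(cf))) {
    stop("fit has no recorded iterations", call. = FALSE)
  }
  global_fitted_image(list(c1 = cf[["c1"]], c2 = cf[["c2"]]), object$phi,
                      object$config$epsilon)
}

#' @export
residuals.spf_seg <- function(object, ...) {
  object$image - fitted(object)
}

#' Plot a fitted segmentation
#'
#' @param x An `"spf_seg"` fit.
#' @param type `"overlay"` draws the image with the initial contour (green),
#'   the final contour (blue) and, if given, the ground-truth contour (red);
#'   `"map"` draws the recorded isocontour map on the image.
#' @param truth Optional logical matrix of ground truth for the overlay.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.spf_seg <- function(x, type = c("overlay", "map"), truth = NULL, ...) {
  type <- match.arg(type)
  draw_image(x$image, ...)
  if (type == "overlay") {
    draw_mask_outline(x$initial_mask, col = "green3", lwd = 2)
    draw_mask_outline(x$final_mask, col = "blue", lwd = 2)
    if (!is.null(truth)) draw_mask_outline(truth, col = "red", lwd = 2)
  } else {
    for (snap in x$snapshots) {
      draw_zero_level(snap, col = "yellow", lwd = 1)
    }
    draw_mask_outline(x$final_mask, col = "blue", lwd = 2)
  }
  invisible(x)
}

# Display helpers: image pixel (r, c) is drawn at x = c, y = nrow + 1 - r.
draw_image <- function(img, ...) {
  nr <- nrow(img)
  nc <- ncol(img)
  graphics::image(x = seq_len(nc), y = seq_len(nr),
                  z = t(img)[, nr:1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1),
                  asp = 1, xlab = "", ylab = "", axes = FALSE,
                  useRaster = TRUE, ...)
}

draw_zero_level <- function(phi, ...) {
  cl <- grDevices::contourLines(x = seq_len(nrow(phi)) - 1,
                                y = seq_len(ncol(phi)) - 1,
                                z = phi, levels = 0)
  nr <- nrow(phi)
  for (ct in cl) {
    graphics::lines(ct$y + 1, nr - ct$x, ...)
  }
}

draw_mask_outline <- function(mask, ...) {
  draw_zero_level((mask * 2) - 1, ...)
}
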