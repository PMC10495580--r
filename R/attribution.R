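#' Gradient of a class score with respect to the input
#'
#' S3 generic backing [integrated_gradients()]: returns the derivative of
#' the model's softmax probability for class `class_idx` with respect to
#' every input point, for each row of `X`. Methods exist for the network
#' models; tree models have no gradients.
#'
#' @param model A trained model.
#' @param X Input matrix (rows = spectra).
#' @param class_idx Index into the model's class vector (1 = "good").
#' @return Matrix of the same shape as `X`.
#' @export
input_gradient <- function(model, X, class_idx) UseMethod("input_gradient")

#' @export
input_gradient.default <- function(model, X, class_idx) {
  stop("integrated gradients need a differentiable network model; ",
       class(model)[1L], " has no input gradients")
}

#' @export
input_gradient.qc_net <- function(model, X, class_idx) {
  if (!isTRUE(model$trained))
    stop("model has not been fitted; call qc_fit() first")
  fwd <- nn_forward(model$net, X, keep_cache = TRUE)
  p <- softmax_rows(fwd$logits)
  # d p_c / d z_j = p_c (delta_cj - p_j)
  dZ <- -p * p[, class_idx]
  dZ[, class_idx] <- dZ[, class_idx] + p[, class_idx]
  nn_backward(model$net, fwd, dZ, need_dx = TRUE)$dX
}

# softmax probability of one class, per row
class_prob <- function(model, X, class_idx) {
  predict_prob_matrix(model, X)[, class_idx]
}

#' Integrated-gradients attribution for one spectrum
#'
#' Path-integral feature importance: each spectral point's attribution is
#' `(x_i - b_i)` times the average gradient of the predicted-class
#' probability along the straight path from the baseline `b` to the input
#' `x`, discretized with a midpoint Riemann rule of `steps` points. The
#' attribution is computed for the model's *predicted* class. The
#' completeness axiom (attributions summing to `F(x) - F(b)`) holds in the
#' limit of many steps; the residual gap is recorded, never hidden.
#'
#' @param model A trained differentiable model (`qc_cnn`/`qc_icnn`, or any
#'   class with an [input_gradient()] method).
#' @param spectrum Preprocessed spectrum: numeric vector or
#'   [voxel_spectrum].
#' @param baseline `"zero"` (all-zero spectrum in normalized space,
#'   default), `"mean"` with `reference` spectra to average, or a numeric
#'   vector.
#' @param steps Path resolution, >= 2 (default 256).
#' @param reference Spectra matrix used when `baseline = "mean"`.
#' @return An object of class `qc_attribution`: `attributions`, `baseline`,
#'   `steps`, `predicted_class`, `completeness_gap`, and the input.
#' @export
integrated_gradients <- function(model, spectrum, baseline = "zero",
                                 steps = 256L, reference = NULL) {
  x <- if (inherits(spectrum, "voxel_spectrum")) spectrum$intensities
       else as.numeric(spectrum)
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 2L) stop("steps must be >= 2")
  b <- if (is.numeric(baseline)) {
    if (length(baseline) != length(x))
      stop("numeric baseline must match the input length")
    baseline
  } else if (identical(baseline, "zero")) {
    numeric(length(x))
  } else if (identical(baseline, "mean")) {
    if (is.null(reference))
      stop("baseline = \"mean\" needs reference spectra")
    colMeans(as.matrix(reference))
  } else stop("baseline must be \"zero\", \"mean\" or a numeric vector")

  xm <- matrix(x, nrow = 1L)
  class_idx <- max.col(predict_prob_matrix(model,
                                           rbind(xm)), ties.method = "first")
  alphas <- (seq_len(steps) - 0.5) / steps
  path <- matrix(rep(b, each = steps), steps) +
    outer(alphas, x - b)
  grads <- input_gradient(model, path, class_idx)
  attributions <- (x - b) * colMeans(grads)
  f_x <- class_prob(model, xm, class_idx)
  f_b <- class_prob(model, matrix(b, nrow = 1L), class_idx)
  structure(list(attributions = attributions, baseline = b, steps = steps,
                 predicted_class = model$classes[class_idx],
                 completeness_gap = abs(sum(attributions) - (f_x - f_b)),
                 delta_f = f_x - f_b, input = x),
            class = "qc_attribution")
}

#' @export
print.qc_attribution <- function(x, ...) {
  cat(sprintf(
    "<qc_attribution> %d points, predicted \"%s\", steps %d\n",
    length(x$attributions), x$predicted_class, x$steps))
  cat(sprintf("  sum(attr) = %.5f, F(x) - F(b) = %.5f, gap %.2e\n",
              sum(x$attributions), x$delta_f, x$completeness_gap))
  invisible(x)
}

#' Normalized attribution mask
#'
#' Absolute attributions rescaled to a maximum of 1 (identically zero when
#' every attribution is zero, avoiding division blowup): the per-point
#' importance mask overlaid on spectra in attribution figures.
#'
#' @param result A `qc_attribution`.
#' @return Numeric vector in \[0, 1\], same length as the input.
#' @export
attribution_mask <- function(result) {
  stopifnot(inherits(result, "qc_attribution"))
  a <- abs(result$attributions)
  m <- max(a)
  if (m == 0) a else a / m
}

#' Plot a spectrum with its attribution overlay
#'
#' Renders the spectrum against chemical shift with ppm decreasing
#' left-to-right (NMR display convention), the integrated-gradients curve
#' overlaid, and the attribution mask as background shading.
#'
#' @param x A `qc_attribution`.
#' @param axis A [spectral_axis] matching the input length.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.qc_attribution <- function(x, axis = canonical_axis(), ...) {
  stopifnot(inherits(axis, "spectral_axis"),
            axis$n_points == length(x$input))
  mask <- attribution_mask(x)
  ppm <- axis$ppm
  graphics::plot(ppm, x$input, type = "n", xlim = rev(range(ppm)),
                 xlab = "chemical shift (ppm)",
                 ylab = "normalized intensity", ...)
  shade <- grDevices::rgb(1, 0.4, 0.2, alpha = pmin(1, mask) * 0.6)
  graphics::segments(ppm, graphics::par("usr")[3L], ppm,
                     graphics::par("usr")[4L], col = shade)
  graphics::lines(ppm, x$input, col = "grey25")
  ig <- x$attributions
  scale <- if (max(abs(ig)) > 0)
    0.5 * diff(range(x$input)) / max(abs(ig)) else 1
  graphics::lines(ppm, ig * scale + min(x$input), col = "dodgerblue3")
  graphics::legend("topleft",
                   c("spectrum", "IG curve (scaled)", "attribution mask"),
                   col = c("grey25", "dodgerblue3", shade[which.max(mask)]),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(mask)
}
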