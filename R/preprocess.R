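#' Consensus of two rater verdicts
#'
#' The conservative consensus rule: a voxel is "good" only if both raters
#' labeled it good; a voxel labeled poor quality by either rater is "bad".
#' Vectorized over pairs of verdicts.
#'
#' @param rater_a,rater_b Character vectors with entries `"good"` or `"bad"`.
#' @return Character vector of consensus verdicts.
#' @examples
#' aggregate_labels("good", "good")  # "good"
#' aggregate_labels("good", "bad")   # "bad"
#' @export
aggregate_labels <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b))
    stop("rater verdict vectors differ in length")
  if (length(rater_a) == 0L) stop("no verdicts supplied")
  ok <- function(v) !anyNA(v) && all(v %in% c("good", "bad"))
  if (!ok(rater_a) || !ok(rater_b))
    stop("verdicts must all be \"good\" or \"bad\" with none missing")
  ifelse(rater_a == "good" & rater_b == "good", "good", "bad")
}

#' Preprocessing configuration
#'
#' Window bounds and target input length for the model preprocessing chain.
#' Defaults match the standard analysis window: 1.4 to 4.1 ppm, 850 points.
#'
#' @param ppm_lo,ppm_hi Closed-window bounds in ppm, `ppm_lo < ppm_hi`.
#' @param target_points Number of points the models expect.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(ppm_lo = 1.4, ppm_hi = 4.1, target_points = 850L) {
  if (!is.finite(ppm_lo) || !is.finite(ppm_hi) || ppm_lo >= ppm_hi)
    stop("need finite ppm_lo < ppm_hi")
  target_points <- as.integer(target_points)
  if (is.na(target_points) || target_points < 2L)
    stop("target_points must be at least 2")
  structure(list(ppm_lo = ppm_lo, ppm_hi = ppm_hi,
                 target_points = target_points),
            class = "preprocess_config")
}

#' Extract the real part of a spectrum
#'
#' Real-valued spectra are extracted from complex signals; real input is
#' passed through unchanged (idempotent).
#'
#' @param x A [voxel_spectrum] or [qc_cohort].
#' @return The same class of object with real intensities.
#' @export
take_real <- function(x) UseMethod("take_real")

#' @export
take_real.voxel_spectrum <- function(x) {
  x$intensities <- Re(x$intensities)
  x
}

#' @export
take_real.qc_cohort <- function(x) {
  x$spectra <- Re(x$spectra)
  x
}

# indices of axis points inside the closed window, with coverage checks
window_index <- function(axis, cfg) {
  lo <- cfg$ppm_lo; hi <- cfg$ppm_hi
  if (axis$ppm[1L] > lo)
    stop(sprintf(
      "axis starts at %.4g ppm and does not cover the lower window bound %.4g ppm",
      axis$ppm[1L], lo))
  if (axis$ppm[axis$n_points] < hi)
    stop(sprintf(
      "axis ends at %.4g ppm and does not cover the upper window bound %.4g ppm",
      axis$ppm[axis$n_points], hi))
  which(axis$ppm >= lo & axis$ppm <= hi)
}

#' Crop a spectrum to the analysis window
#'
#' Keeps exactly the axis points falling inside the closed interval
#' \[`ppm_lo`, `ppm_hi`\], preserving order. Fails, naming the uncovered
#' side, if the axis does not span the window.
#'
#' @param x A [voxel_spectrum] or [qc_cohort].
#' @param cfg A [preprocess_config].
#' @return The cropped object.
#' @export
crop_to_window <- function(x, cfg = preprocess_config()) UseMethod("crop_to_window")

#' @export
crop_to_window.voxel_spectrum <- function(x, cfg = preprocess_config()) {
  idx <- window_index(x$axis, cfg)
  x$intensities <- x$intensities[idx]
  x$axis <- spectral_axis(x$axis$ppm[idx])
  x
}

#' @export
crop_to_window.qc_cohort <- function(x, cfg = preprocess_config()) {
  idx <- window_index(x$axis, cfg)
  x$spectra <- x$spectra[, idx, drop = FALSE]
  x$axis <- spectral_axis(x$axis$ppm[idx])
  x
}

# z-normalize rows of a matrix with the population (divide-by-n) sd
znorm_rows <- function(m) {
  mu <- rowMeans(m)
  centered <- m - mu
  sdp <- sqrt(rowMeans(centered^2))
  zero <- sdp <= 0 | !is.finite(sdp)
  if (any(zero))
    stop("zero-variance spectrum cannot be z-normalized (row ",
         paste(which(zero), collapse = ", "), "); record flagged unusable")
  centered / sdp
}

#' Z-normalize spectrum intensities
#'
#' Normalizes each spectrum to mean 0 and standard deviation 1 (population,
#' divide-by-n convention) for model input. A constant spectrum has zero
#' variance and cannot satisfy the contract; it is rejected with an error.
#'
#' @param x A [voxel_spectrum] or [qc_cohort] with real intensities.
#' @return The normalized object.
#' @export
znormalize <- function(x) UseMethod("znormalize")

#' @export
znormalize.voxel_spectrum <- function(x) {
  if (is.complex(x$intensities))
    stop("znormalize expects real intensities; call take_real() first")
  x$intensities <- drop(znorm_rows(matrix(x$intensities, nrow = 1L)))
  x
}

#' @export
znormalize.qc_cohort <- function(x) {
  if (is.complex(x$spectra))
    stop("znormalize expects real intensities; call take_real() first")
  x$spectra <- znorm_rows(x$spectra)
  x
}

#' Full model-input preprocessing chain
#'
#' Applies, in order: real-part extraction, cropping to the closed ppm
#' window, and per-spectrum z-normalization. If the cropped axis length
#' differs from `cfg$target_points` the spectra are linearly resampled onto a
#' uniform grid of `target_points` points spanning the window (an extension
#' needed for real acquisitions whose grid is not the canonical one; the
#' canonical simulator axis crops to exactly 850 points and is never
#' resampled).
#'
#' @param x A [voxel_spectrum] or [qc_cohort].
#' @param cfg A [preprocess_config].
#' @return The preprocessed object, ready for model input.
#' @export
preprocess <- function(x, cfg = preprocess_config()) UseMethod("preprocess")

#' @export
preprocess.voxel_spectrum <- function(x, cfg = preprocess_config()) {
  x <- crop_to_window(take_real(x), cfg)
  if (x$axis$n_points != cfg$target_points) {
    grid <- seq(cfg$ppm_lo, cfg$ppm_hi, length.out = cfg$target_points)
    x$intensities <- stats::approx(x$axis$ppm, x$intensities, xout = grid,
                                   rule = 2)$y
    x$axis <- spectral_axis(grid)
  }
  znormalize(x)
}

#' @export
preprocess.qc_cohort <- function(x, cfg = preprocess_config()) {
  x <- crop_to_window(take_real(x), cfg)
  if (x$axis$n_points != cfg$target_points) {
    grid <- seq(cfg$ppm_lo, cfg$ppm_hi, length.out = cfg$target_points)
    x$spectra <- t(apply(x$spectra, 1L, function(row)
      stats::approx(x$axis$ppm, row, xout = grid, rule = 2)$y))
    rownames(x$spectra) <- x$manifest$voxel_id
    x$axis <- spectral_axis(grid)
  }
  znormalize(x)
}
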