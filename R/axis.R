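#' Chemical-shift axis for MRS spectra
#'
#' A `spectral_axis` stores the chemical shift (ppm) of each spectral point,
#' strictly ascending. Spectra are always *stored* on an ascending axis; the
#' NMR display convention (ppm decreasing left-to-right) is applied only when
#' plotting.
#'
#' @param ppm Numeric vector of chemical shifts in ppm, strictly increasing,
#'   length at least 2, all finite.
#' @return An object of class `spectral_axis`.
#' @examples
#' ax <- spectral_axis(seq(1.4, 4.1, length.out = 850))
#' ax$n_points
#' @export
spectral_axis <- function(ppm) {
  ppm <- as.numeric(ppm)
  if (length(ppm) < 2L)
    stop("a spectral axis needs at least 2 points, got ", length(ppm))
  if (any(!is.finite(ppm)))
    stop("spectral axis contains non-finite ppm values")
  if (any(diff(ppm) <= 0))
    stop("spectral axis must be strictly ascending in ppm")
  structure(list(ppm = ppm, n_points = length(ppm)), class = "spectral_axis")
}

#' Canonical 850-point acquisition window
#'
#' The canonical axis used throughout the package: `n` uniformly spaced points
#' on the closed interval \[`ppm_lo`, `ppm_hi`\], defaulting to the standard
#' 850-point window from 1.4 to 4.1 ppm so that network input length matches
#' the expected 850 samples without resampling.
#'
#' @param ppm_lo,ppm_hi Window bounds in ppm.
#' @param n Number of points.
#' @return A `spectral_axis`.
#' @export
canonical_axis <- function(ppm_lo = 1.4, ppm_hi = 4.1, n = 850L) {
  spectral_axis(seq(ppm_lo, ppm_hi, length.out = n))
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d points, %.4g to %.4g ppm (step ~%.4g)\n",
              x$n_points, x$ppm[1L], x$ppm[x$n_points],
              mean(diff(x$ppm))))
  invisible(x)
}

# grid step of a (uniform) axis; used for frequency-shift rolling
axis_step <- function(axis) mean(diff(axis$ppm))
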