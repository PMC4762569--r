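#' Re-bin intensities onto another momentum-transfer grid
#'
#' Indirect-transform programs may have re-binned the experimental data to
#' a larger angular step before computing the regularized fit, so the grid
#' stored with the fit need not match the grid of the original curve. This
#' translates intensities back onto a target grid by linear interpolation;
#' exact for locally linear (affine) intensities and the identity on an
#' unchanged grid. Target points outside the source range are returned as
#' `NA` (absent), never extrapolated.
#'
#' @param src_s,src_I source grid and intensities (src_s strictly
#'   increasing, at least 2 points).
#' @param dst_s target grid, strictly increasing.
#' @return numeric vector of length `length(dst_s)`.
#' @examples
#' rebin_to_grid(c(0, 1, 2), c(0, 10, 20), c(0.5, 1.5))  # 5, 15
#' @export
rebin_to_grid <- function(src_s, src_I, dst_s) {
  src_s <- as.numeric(src_s); src_I <- as.numeric(src_I)
  dst_s <- as.numeric(dst_s)
  if (length(src_s) < 2L) abort("need at least 2 source points to re-bin")
  if (length(src_s) != length(src_I)) abort("src_s and src_I lengths differ")
  if (any(diff(src_s) <= 0)) abort("src_s must be strictly increasing")
  if (length(dst_s) > 1L && any(diff(dst_s) <= 0)) {
    abort("dst_s must be strictly increasing")
  }
  approx(src_s, src_I, xout = dst_s, method = "linear", rule = 1)$y
}
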