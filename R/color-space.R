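# sRGB <-> CIELab conversion (D65 white point) on [0, 1] channel scale.
#
# The individual typology angle (ITA) used for Fitzpatrick typing is defined
# in CIELab, so both the synthetic skin generator and the handcrafted
# extractor share these converters.

#' Convert sRGB values to CIELab
#'
#' @param rgb A numeric matrix with three columns (R, G, B) in `[0, 1]`, or a
#'   vector of length 3.
#' @return A matrix with columns `L`, `a`, `b` (D65 reference white).
#' @examples
#' rgb_to_lab(c(0.8, 0.6, 0.5))
#' @export
rgb_to_lab <- function(rgb) {
  if (is.vector(rgb)) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  assert_that_(ncol(rgb) == 3, "`rgb` must have three columns")
  out <- convertColor(rgb, from = "sRGB", to = "Lab", to.ref.white = "D65")
  colnames(out) <- c("L", "a", "b")
  out
}

#' Convert CIELab values to sRGB
#'
#' Out-of-gamut results are clipped to `[0, 1]`.
#'
#' @param lab A numeric matrix with columns L, a, b, or a vector of length 3.
#' @return A matrix with columns `R`, `G`, `B` in `[0, 1]`.
#' @export
lab_to_rgb <- function(lab) {
  if (is.vector(lab)) lab <- matrix(lab, ncol = 3, byrow = TRUE)
  assert_that_(ncol(lab) == 3, "`lab` must have three columns")
  out <- convertColor(lab, from = "Lab", to = "sRGB", from.ref.white = "D65")
  out <- clamp(out, 0, 1)
  colnames(out) <- c("R", "G", "B")
  out
}

# Luma used for grayscale reductions throughout (Rec. 601 weights).
rgb_to_gray <- function(img) {
  if (length(dim(img)) == 2) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
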