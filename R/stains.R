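# Ruifrok-Johnston color deconvolution for hematoxylin / eosin / DAB.
# Rows of the stain matrix are unit optical-density vectors for H, E, D.
.hed_matrix <- local({
  m <- rbind(
    h = c(0.650, 0.704, 0.286),
    e = c(0.072, 0.990, 0.105),
    d = c(0.268, 0.570, 0.776)
  )
  m / sqrt(rowSums(m^2))
})
.hed_inverse <- solve(.hed_matrix)

#' HED color deconvolution
#'
#' Separates an RGB histology image into hematoxylin, eosin and DAB
#' optical-density contributions using the standard Ruifrok-Johnston stain
#' vectors. Stain-free (white) pixels map to ~0 in all three channels;
#' larger values mean more stain.
#'
#' @param img RGB array `H x W x 3`, values in `[0, 255]`.
#' @return array `H x W x 3` with channels (hematoxylin, eosin, DAB) in
#'   optical-density units (nonnegative up to numerical noise).
#' @seealso [hed_to_rgb()], [hema_transform_hed()]
#' @export
rgb_to_hed <- function(img) {
  stopifnot_rgb(img)
  d <- dim(img)
  rgb01 <- pmax(matrix(img, ncol = 3L) / 255, 1e-6)
  od <- -log10(rgb01)
  hed <- od %*% .hed_inverse
  array(hed, dim = d)
}

#' Reconstruct RGB from HED optical densities
#'
#' Inverse of [rgb_to_hed()] (up to the clipping of negative densities).
#'
#' @param hed array `H x W x 3` of (hematoxylin, eosin, DAB) densities.
#' @return RGB array `H x W x 3` on the 0..255 scale.
#' @export
hed_to_rgb <- function(hed) {
  stopifnot_rgb(hed)
  d <- dim(hed)
  od <- pmax(matrix(hed, ncol = 3L), 0) %*% .hed_matrix
  rgb01 <- 10^(-od)
  array(clip01(rgb01) * 255, dim = d)
}

#' Hematoxylin-only image transform
#'
#' Maps an IHC RGB patch to a hematoxylin-only RGB patch by HED
#' deconvolution, zeroing the eosin and DAB components, and reconstructing
#' to RGB. Satisfies the hema-transform backend contract used by the
#' dual-branch cell detection (output dimensions equal input dimensions).
#' The practical effect is that brown DAB membrane staining disappears
#' while the bluish nuclear counterstain is preserved, which helps nucleus
#' detection on strongly DAB-stained patches.
#'
#' @param patch RGB array `H x W x 3`, values in `[0, 255]`.
#' @return RGB array of identical dimensions.
#' @export
hema_transform_hed <- function(patch) {
  hed <- rgb_to_hed(patch)
  hed[, , 2] <- 0
  hed[, , 3] <- 0
  hed_to_rgb(hed)
}
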