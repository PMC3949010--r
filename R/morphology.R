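## Binary morphology with a cubic structuring element, used to extract
## fracture gaps as close(bone) minus bone. Offsets of a side-k cube are
## centred as far as an even side allows (k = 2 uses {0, 1} per axis), the
## convention of voxel image-processing packages. A side-k element closes
## gaps of at most k - 1 voxels.

.seOffsets <- function(kernelPx) {
  k <- as.integer(kernelPx)
  if (k < 1L) stop("kernelPx must be >= 1")
  seq_len(k) - 1L - ((k - 1L) %/% 2L)
}

#' Binary dilation, erosion and closing with a cubic structuring element
#'
#' `dilateMask()` is the Minkowski sum of the mask with a cube of side
#' `kernelPx` voxels, `erodeMask()` the Minkowski difference, and
#' `closeMask()` the composition erode(dilate(mask)). Dilation pads the
#' array border with background and erosion with foreground (the
#' image-processing convention, e.g. scikit-image), so structures are not
#' artificially eroded where the field of view cuts them off.
#'
#' @param mask logical 3-D array.
#' @param kernelPx side of the cubic structuring element in voxels.
#' @return logical array of the same shape.
#' @export
dilateMask <- function(mask, kernelPx = 2L) {
  off <- .seOffsets(kernelPx)
  out <- array(FALSE, dim(mask))
  for (dx in off) for (dy in off) for (dz in off)
    out <- out | shiftArray(mask, c(dx, dy, dz))
  out
}

#' @rdname dilateMask
#' @export
erodeMask <- function(mask, kernelPx = 2L) {
  off <- .seOffsets(kernelPx)
  out <- array(TRUE, dim(mask))
  for (dx in off) for (dy in off) for (dz in off)
    out <- out & shiftArray(mask, c(-dx, -dy, -dz), fill = TRUE)
  out
}

#' @rdname dilateMask
#' @export
closeMask <- function(mask, kernelPx = 2L) {
  erodeMask(dilateMask(mask, kernelPx), kernelPx)
}
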