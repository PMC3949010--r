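# Desk-scale phantom geometries shared across tests. The "small" spec is
# the workhorse (2 mm voxels, ~2000 elements); the "tiny" spec backs the
# Monte-Carlo studies where many cohorts are solved.

smallSpec <- function(...) {
  args <- utils::modifyList(
    list(gridShape = c(14L, 14L, 22L), voxelMm = 2, bodyRadiusMm = 10,
         bodyHeightMm = 20, capThicknessMm = 6, capWidthMm = 24,
         grayFieldCorrelationMm = 4, markerRadiusMm = 2.5),
    list(...))
  do.call(phantomSpec, args)
}

tinySpec <- function(...) {
  args <- utils::modifyList(
    list(gridShape = c(12L, 12L, 18L), voxelMm = 2, bodyRadiusMm = 8,
         bodyHeightMm = 16, capThicknessMm = 4, capWidthMm = 20,
         grayFieldCorrelationMm = 4, markerRadiusMm = 2.5),
    list(...))
  do.call(phantomSpec, args)
}

# one partial transverse crack through the body midplane, snapped to a
# voxel-centre layer so it rasterises to a one-voxel-thick sheet
midCrack <- function(spec, radiusMm = 0.7 * spec@bodyRadiusMm,
                     tilt = c(0.1, 0)) {
  g <- spec@gridShape
  h <- spec@voxelMm
  zMid <- (round(g[3] / 2 - 0.5) + 0.5) * h
  list(list(point = c(g[1] * h / 2, g[2] * h / 2, zMid),
            normal = c(tilt[1], tilt[2], 1),
            thicknessMm = 0.9 * h, radiusMm = radiusMm))
}

# brute-force binary morphology straight from the Minkowski definitions,
# an independent oracle for the shift-based implementation
bruteDilate <- function(mask, off) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) for (dx in off) for (dy in off)
    for (dz in off) {
      p <- idx[r, ] + c(dx, dy, dz)
      if (all(p >= 1L) && all(p <= dm)) out[p[1], p[2], p[3]] <- TRUE
    }
  out
}

bruteErode <- function(mask, off) {
  ## positions outside the field of view count as foreground, matching
  ## the package's (and scikit-image's) erosion border convention
  dm <- dim(mask)
  out <- array(FALSE, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
    for (k in seq_len(dm[3])) {
      keep <- TRUE
      for (dx in off) for (dy in off) for (dz in off) {
        p <- c(i + dx, j + dy, k + dz)
        if (any(p < 1L) || any(p > dm)) next
        if (!mask[p[1], p[2], p[3]]) {
          keep <- FALSE
          break
        }
      }
      out[i, j, k] <- keep
    }
  out
}

bruteClose <- function(mask, kernelPx) {
  off <- seq_len(kernelPx) - 1L - ((kernelPx - 1L) %/% 2L)
  bruteErode(bruteDilate(mask, off), off)
}
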