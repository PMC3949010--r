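#' Evaluate an expression under a temporary RNG seed
#'
#' All randomness in the package flows through explicit seeds. `withSeed()`
#' seeds the generator, evaluates `code`, and restores the caller's RNG
#' state, so identical seeds give identical outputs without clobbering the
#' session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Translate a 3-D array by an integer offset, padding with `fill`.
shiftArray <- function(a, d, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dm[ax]; s <- d[ax]
    if (abs(s) >= n) return(out)
    if (s >= 0) { dst[[ax]] <- seq.int(1L + s, n); src[[ax]] <- seq.int(1L, n - s) }
    else        { dst[[ax]] <- seq.int(1L, n + s); src[[ax]] <- seq.int(1L - s, n) }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

#' Label 6-connected components of a voxel mask
#'
#' @param mask logical 3-D array.
#' @return integer array of the same shape; 0 outside the mask, components
#'   numbered from 1 inside.
#' @export
labelComponents <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  pos <- integer(prod(dm))
  pos[idx] <- seq_along(idx)
  strides <- c(1L, dm[1L], dm[1L] * dm[2L])
  ind <- arrayInd(idx, dm)
  edges <- vector("list", 3L)
  for (ax in 1:3) {
    ok <- ind[, ax] < dm[ax]
    nb <- idx[ok] + strides[ax]
    has <- pos[nb] > 0L
    if (any(has)) edges[[ax]] <- cbind(pos[idx[ok][has]], pos[nb[has]])
  }
  em <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  if (is.null(em) || nrow(em) == 0L) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  extra <- length(idx) - igraph::vcount(g)
  if (extra > 0L) g <- igraph::add_vertices(g, extra)
  lab[idx] <- as.integer(igraph::components(g)$membership[seq_along(idx)])
  lab
}

## Multiply a 3-D array along one axis by a matrix W (nOut x nIn).
applyAlongAxis <- function(a, W, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  p <- aperm(a, perm)
  dm <- dim(p)
  m <- as.matrix(W %*% matrix(p, nrow = dm[1L]))
  out <- array(m, c(nrow(W), dm[2L], dm[3L]))
  aperm(out, order(perm))
}

## Physical voxel-centre coordinate vectors along each axis.
voxelCenters <- function(dims, voxelMm, originMm = c(0, 0, 0)) {
  voxelMm <- rep(voxelMm, length.out = 3L)
  lapply(1:3, function(ax)
    originMm[ax] + (seq_len(dims[ax]) - 0.5) * voxelMm[ax])
}

## Fill interior cavities: background components that do not touch the
## array border become part of the mask.
fillHoles <- function(mask) {
  dm <- dim(mask)
  lab <- labelComponents(!mask)
  border <- array(FALSE, dm)
  border[c(1L, dm[1L]), , ] <- TRUE
  border[, c(1L, dm[2L]), ] <- TRUE
  border[, , c(1L, dm[3L])] <- TRUE
  touching <- unique(lab[border & !mask])
  mask | (lab > 0L & !(lab %in% touching))
}
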