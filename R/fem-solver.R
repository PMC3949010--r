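#' Axial stiffness accessor
#'
#' @param x an object carrying an axial stiffness (an [FESolution],
#'   [SimulatedMeasurement] or [CalibrationResult]).
#' @return scalar, N/mm (or MPa per grayscale unit for calibration results).
#' @export
setGeneric("stiffness", function(x) standardGeneric("stiffness"))

#' @rdname stiffness
setMethod("stiffness", "FESolution", function(x) x@stiffnessNPerMm)

#' @rdname stiffness
setMethod("stiffness", "SimulatedMeasurement", function(x) x@stiffnessNPerMm)

## ---------------------------------------------------------------------------
## Core axial compression solver.
##
## The element field lives on a voxel grid; every voxel with positive
## modulus becomes one cubic hexahedral element. The bottom faces of the
## lowest element layer are fully fixed. The top faces of the highest
## element layer are tied to a rigid reference at the pivot: in-plane node
## displacements are fixed and the axial displacement obeys the
## small-rotation kinematics uz = Uz + Rx (y - yp) - Ry (x - xp), so the
## plate cannot translate horizontally but is free to tilt about the
## loading point, like a ball joint. The compressive load acts on Uz.
##
## The stiffness is assembled as K = Kfix + alpha * Kbone so that studies
## which rescale one material family (the grayscale-to-modulus factor, the
## gap modulus, the cement modulus) can re-solve without re-assembly.
## ---------------------------------------------------------------------------

.assembleWeighted <- function(edof, w, K1v, ndof, chunk = 4000L) {
  keep <- which(w != 0)
  if (!length(keep)) return(NULL)
  i24 <- rep(1:24, times = 24)
  j24 <- rep(1:24, each = 24)
  K <- NULL
  for (s in unname(split(keep, ceiling(seq_along(keep) / chunk)))) {
    ed <- edof[s, , drop = FALSE]
    Kc <- Matrix::sparseMatrix(i = as.vector(ed[, i24]),
                               j = as.vector(ed[, j24]),
                               x = as.vector(outer(w[s], K1v)),
                               dims = c(ndof, ndof))
    K <- if (is.null(K)) Kc else K + Kc
  }
  K
}

.axialPrepare <- function(EFixed, gBone = NULL, h, originMm = c(0, 0, 0),
                          pivotMm = NULL, loadN = 4500, nu = 0.3,
                          rotationsFree = TRUE) {
  dims <- dim(EFixed)
  if (is.null(gBone)) gBone <- array(0, dims)
  EFixed[!is.finite(EFixed)] <- 0
  active <- which(EFixed > 0 | gBone > 0)
  if (!length(active)) stop("model contains no elements")

  ## keep only elements on a load path connecting base to plate
  act <- array(FALSE, dims); act[active] <- TRUE
  comp <- labelComponents(act)[active]
  eIJK <- arrayInd(active, dims)
  kmin <- min(eIJK[, 3L]); kmax <- max(eIJK[, 3L])
  good <- intersect(unique(comp[eIJK[, 3L] == kmin]),
                    unique(comp[eIJK[, 3L] == kmax]))
  if (!length(good))
    stop("no connected load path from the base to the loading plate")
  dropped <- sum(!(comp %in% good))
  if (dropped > 0) {
    warning(sprintf(
      "%d element(s) not connected to the load path were removed", dropped))
    keep <- comp %in% good
    active <- active[keep]
    eIJK <- eIJK[keep, , drop = FALSE]
  }
  m <- length(active)

  ## node numbering on the (n+1)^3 corner grid, compacted to used nodes
  nxn <- dims[1L] + 1L; nyn <- dims[2L] + 1L; nzn <- dims[3L] + 1L
  off <- as.matrix(expand.grid(0:1, 0:1, 0:1))   # local order: x fastest
  conn <- matrix(0, m, 8L)
  for (a in 1:8)
    conn[, a] <- (eIJK[, 1L] + off[a, 1L]) +
      (eIJK[, 2L] + off[a, 2L] - 1L) * nxn +
      (eIJK[, 3L] + off[a, 3L] - 1L) * nxn * nyn
  usedNodes <- sort(unique(as.vector(conn)))
  nn <- length(usedNodes)
  lookup <- integer(nxn * nyn * nzn)
  lookup[usedNodes] <- seq_len(nn)
  connC <- matrix(lookup[conn], m, 8L)

  ui <- (usedNodes - 1L) %% nxn                      # 0-based node indices
  uj <- ((usedNodes - 1L) %/% nxn) %% nyn
  uk <- (usedNodes - 1L) %/% (nxn * nyn)
  coords <- cbind(originMm[1L] + ui * h, originMm[2L] + uj * h,
                  originMm[3L] + uk * h)

  baseNodes <- which(uk == kmin - 1L)
  plateNodes <- which(uk == kmax)
  if (!length(baseNodes) || !length(plateNodes))
    stop("base or plate node set is empty")
  if (is.null(pivotMm))
    pivotMm <- c(mean(coords[plateNodes, 1L]), mean(coords[plateNodes, 2L]))
  px <- range(coords[plateNodes, 1L]); py <- range(coords[plateNodes, 2L])
  if (pivotMm[1L] < px[1L] - h / 2 || pivotMm[1L] > px[2L] + h / 2 ||
      pivotMm[2L] < py[1L] - h / 2 || pivotMm[2L] > py[2L] + h / 2)
    warning("pivot lies outside the plate footprint")

  ## reduction map u = T q; q = (free nodal dofs, Uz[, Rx, Ry])
  freeNodes <- setdiff(seq_len(nn), c(baseNodes, plateNodes))
  nFree <- length(freeNodes)
  nMaster <- if (rotationsFree) 3L else 1L
  nq <- 3L * nFree + nMaster
  colUz <- 3L * nFree + 1L
  iT <- c(rep(3L * (freeNodes - 1L), each = 3L) + 1:3,
          3L * (plateNodes - 1L) + 3L)
  jT <- c(seq_len(3L * nFree), rep(colUz, length(plateNodes)))
  xT <- c(rep(1, 3L * nFree), rep(1, length(plateNodes)))
  if (rotationsFree) {
    dy <- coords[plateNodes, 2L] - pivotMm[2L]
    dx <- coords[plateNodes, 1L] - pivotMm[1L]
    iT <- c(iT, rep(3L * (plateNodes - 1L) + 3L, 2L))
    jT <- c(jT, rep(colUz + 1L, length(plateNodes)),
            rep(colUz + 2L, length(plateNodes)))
    xT <- c(xT, dy, -dx)
  }
  T <- Matrix::sparseMatrix(i = iT, j = jT, x = xT, dims = c(3L * nn, nq))
  f <- numeric(nq)
  f[colUz] <- -loadN

  edof <- matrix(0, m, 24L)
  for (a in 1:8) for (cdof in 1:3)
    edof[, 3L * (a - 1L) + cdof] <- 3L * (connC[, a] - 1L) + cdof
  K1v <- as.vector(hexStiffness(1, nu, h))
  KfixFull <- .assembleWeighted(edof, EFixed[active], K1v, 3L * nn)
  KboneFull <- .assembleWeighted(edof, gBone[active], K1v, 3L * nn)
  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(3L * nn, 3L * nn))
  if (is.null(KfixFull)) KfixFull <- zero
  KfixRed <- Matrix::forceSymmetric(Matrix::crossprod(T, KfixFull %*% T))
  KboneRed <- if (is.null(KboneFull)) NULL else
    Matrix::forceSymmetric(Matrix::crossprod(T, KboneFull %*% T))

  list(KfixRed = KfixRed, KboneRed = KboneRed, KfixFull = KfixFull,
       KboneFull = KboneFull, T = T, f = f, colUz = colUz,
       rotationsFree = rotationsFree, nodeIndex = cbind(ui, uj, uk) + 1L,
       coords = coords, baseNodes = baseNodes, plateNodes = plateNodes,
       pivotMm = pivotMm[1:2], nElements = m, droppedElements = dropped,
       loadN = loadN, h = h, nDofs = nq, cache = new.env(parent = emptyenv()))
}

## Symmetric Jacobi scaling D K D with D = diag(s), in place on the
## compressed-sparse values.
.scaleSym <- function(K, s) {
  j <- rep.int(seq_len(ncol(K)), diff(K@p))
  K@x <- K@x * s[K@i + 1L] * s[j]
  K
}

.axialSolveAt <- function(prep, alphaBone = 1, tol = 1e-8, maxRefine = 25L,
                          reactions = TRUE) {
  K <- prep$KfixRed
  if (!is.null(prep$KboneRed)) K <- K + alphaBone * prep$KboneRed
  if (!methods::is(K, "dsCMatrix")) K <- Matrix::forceSymmetric(K)
  d <- Matrix::diag(K)
  if (any(d <= 0))
    stop(sprintf("singular system: %d unconstrained/empty DOF(s)",
                 sum(d <= 0)))
  s <- 1 / sqrt(d)
  Ks <- .scaleSym(K, s)
  ## the sparsity pattern is invariant across re-solves of one prepared
  ## system, so the symbolic analysis is cached and only the numeric
  ## factorisation is refreshed
  ch <- tryCatch({
    if (is.null(prep$cache$chol))
      prep$cache$chol <- Matrix::Cholesky(Ks, LDL = FALSE, super = TRUE,
                                          perm = TRUE)
    else prep$cache$chol <- Matrix::update(prep$cache$chol, Ks)
    prep$cache$chol
  }, error = function(e)
    stop("singular stiffness system: ", conditionMessage(e)))
  f <- prep$f
  q <- s * as.numeric(Matrix::solve(ch, s * f))
  normF <- sqrt(sum(f^2))
  history <- numeric(0)
  Kq <- NULL
  for (it in seq_len(maxRefine)) {
    Kq <- as.numeric(K %*% q)
    r <- f - Kq
    rel <- sqrt(sum(r^2)) / normF
    history <- c(history, rel)
    if (rel <= tol) break
    q <- q + s * as.numeric(Matrix::solve(ch, s * r))
  }
  if (history[length(history)] > tol)
    stop("solver did not reach the residual tolerance; residual history: ",
         paste(signif(history, 3), collapse = ", "))

  Uz <- q[prep$colUz]
  Rx <- if (prep$rotationsFree) q[prep$colUz + 1L] else 0
  Ry <- if (prep$rotationsFree) q[prep$colUz + 2L] else 0
  out <- list(q = q, Uz = Uz, Rx = Rx, Ry = Ry,
              stiffness = prep$loadN / abs(Uz),
              residual = history[length(history)],
              refineIterations = length(history),
              energy = 0.5 * sum(q * Kq))
  if (reactions) {
    u <- as.numeric(prep$T %*% q)
    Kfull <- prep$KfixFull
    if (!is.null(prep$KboneFull))
      Kfull <- Kfull + alphaBone * prep$KboneFull
    reac <- as.numeric(Kfull %*% u)
    out$u <- u
    out$baseReactionN <- sum(reac[3L * (prep$baseNodes - 1L) + 3L])
  }
  out
}

.asFESolution <- function(prep, sol) {
  nn <- nrow(prep$coords)
  U <- matrix(sol$u, nn, 3L, byrow = TRUE)
  new("FESolution", stiffnessNPerMm = sol$stiffness,
      plateDofs = c(Uz = sol$Uz, Rx = sol$Rx, Ry = sol$Ry),
      loadingPointDispMm = sol$Uz, nodeIndex = prep$nodeIndex,
      displacements = U,
      solverReport = list(residual = sol$residual,
                          refineIterations = sol$refineIterations,
                          nElements = prep$nElements, nDofs = prep$nDofs,
                          droppedElements = prep$droppedElements,
                          baseReactionN = sol$baseReactionN,
                          energy = sol$energy, appliedLoadN = prep$loadN,
                          pivotMm = prep$pivotMm))
}

#' Solve axial compression of a raw voxel modulus field
#'
#' Low-level entry to the voxel finite-element solver: every voxel with a
#' positive modulus becomes a cubic trilinear hexahedral element; the
#' bottom faces of the lowest element layer are fully fixed, and the top
#' faces of the highest layer are tied to a rigid reference at the pivot
#' (fixed in the horizontal plane, free to tilt) through which the
#' compressive load acts. Elements not path-connected to both base and
#' plate are removed with a warning. Useful for analytic verification
#' problems; specimen models should go through [buildModel()] and
#' [solveModel()].
#'
#' @param E numeric 3-D array of element moduli (MPa); 0 or `NA` marks
#'   empty voxels.
#' @param voxelMm cubic voxel edge (mm).
#' @param nu Poisson's ratio.
#' @param originMm physical origin (mm).
#' @param pivotMm length-2 (x, y) pivot (mm); default is the centroid of
#'   the tied top-surface nodes.
#' @param loadN compressive load magnitude (N).
#' @param rotationsFree logical; lock the plate tilt DOFs if `FALSE`.
#' @return an [FESolution].
#' @export
solveAxial <- function(E, voxelMm, nu = 0.3, originMm = c(0, 0, 0),
                       pivotMm = NULL, loadN = 4500, rotationsFree = TRUE) {
  prep <- .axialPrepare(E, NULL, h = voxelMm, originMm = originMm,
                        pivotMm = pivotMm, loadN = loadN, nu = nu,
                        rotationsFree = rotationsFree)
  .asFESolution(prep, .axialSolveAt(prep, 1))
}

setMethod("show", "FESolution", function(object) {
  rep <- object@solverReport
  cat(sprintf(paste0("FESolution: stiffness %.2f N/mm (load %.0f N, ",
                     "Uz %.4g mm)\n"), object@stiffnessNPerMm,
              rep$appliedLoadN %||% NA_real_, object@loadingPointDispMm))
  cat(sprintf("  %d elements, %d DOFs, relative residual %.2e\n",
              rep$nElements, rep$nDofs, rep$residual))
})
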