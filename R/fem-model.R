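#' Construct a MaterialTable
#'
#' Assembles the elastic constants of the model in working units (MPa)
#' from the conventional GPa values: end caps 2.45 GPa, fracture gap
#' 1e-9 GPa, steel plate 210 GPa, PMMA cement 1.035 GPa, CaP cement
#' 0.585 GPa, Poisson's ratio 0.3 for every material.
#'
#' @param alpha grayscale-to-modulus conversion factor, MPa per grayscale
#'   unit (the quantity [calibrateAlpha()] estimates).
#' @param EGapGPa,ECapGPa,ESteelGPa,ECementPMMAGPa,ECementCaPGPa moduli in GPa.
#' @param nu Poisson's ratio for all materials.
#' @param EBoneFloorMPa small positive lower bound (MPa) for bone moduli,
#'   guarding against nonpositive grayscale values.
#' @return a [MaterialTable].
#' @export
materialTable <- function(alpha = 0.5, EGapGPa = 1e-9, ECapGPa = 2.45,
                          ESteelGPa = 210, ECementPMMAGPa = 1.035,
                          ECementCaPGPa = 0.585, nu = 0.3,
                          EBoneFloorMPa = 1e-3) {
  new("MaterialTable", alpha = alpha, EGap = EGapGPa * 1000,
      ECap = ECapGPa * 1000, ESteel = ESteelGPa * 1000,
      ECementPMMA = ECementPMMAGPa * 1000, ECementCaP = ECementCaPGPa * 1000,
      nu = nu, EBoneFloor = EBoneFloorMPa)
}

setMethod("show", "MaterialTable", function(object) {
  cat(sprintf(paste0("MaterialTable (MPa): alpha %.4g/a.u., gap %.3g, cap ",
                     "%.4g, steel %.4g, PMMA %.4g, CaP %.4g, nu %.2f\n"),
              object@alpha, object@EGap, object@ECap, object@ESteel,
              object@ECementPMMA, object@ECementCaP, object@nu))
})

## model label codes (plate is synthesised, hence outside the mask table)
.MODEL_PLATE <- 7L

#' Build a voxel finite-element model from segmented masks
#'
#' Maps component masks and the grayscale image to per-element elastic
#' moduli: bone elements get `max(alpha * g, EBoneFloor)` from their voxel
#' grayscale `g`, fracture gaps the near-zero gap modulus, cement the
#' modulus of the chosen cement type, and the end caps the cap modulus.
#' A steel plate layer is synthesised on the footprint of the upper cap's
#' top surface. Marker voxels, which transmit no load, are removed after
#' their centroid is recorded; the pivot of the rigid loading tie defaults
#' to the marker centroid projected onto the plate plane.
#'
#' @param masks a [SpecimenMasks].
#' @param image the congruent [VoxelImage].
#' @param mat a [MaterialTable].
#' @param cementType `"PMMA"` or `"CaP"`; ignored when
#'   `cementEOverrideMPa` is given or the cement mask is empty.
#' @param cementEOverrideMPa optional cement modulus override (MPa).
#' @param pivotMm optional length-2 (x, y) pivot (mm); default marker
#'   centroid, else plate footprint centroid.
#' @param plateVoxels steel plate thickness in voxels.
#' @param appliedLoadN compressive load (N), default 4500.
#' @param rotationsFree logical; free plate tilt (default) or locked.
#' @param alpha conversion factor; defaults to `mat@alpha`.
#' @return a [VoxelFEModel].
#' @export
buildModel <- function(masks, image, mat = materialTable(),
                       cementType = c("PMMA", "CaP"),
                       cementEOverrideMPa = NULL, pivotMm = NULL,
                       plateVoxels = 3L, appliedLoadN = 4500,
                       rotationsFree = TRUE, alpha = NULL) {
  lab <- masks@labels
  dims <- dim(lab)
  if (!identical(dims, dim(image@data)))
    stop("masks and image are not congruent")
  vox <- image@voxelMm
  if (diff(range(vox)) > 1e-9 * vox[1L])
    stop("the finite-element mesh requires cubic voxels; down-sample first")
  h <- vox[1L]
  alpha <- alpha %||% mat@alpha

  if (any(lab == .MASK_LABELS[["marker"]])) {
    if (is.null(pivotMm)) {
      ctr <- locateMarker(lab == .MASK_LABELS[["marker"]], vox,
                          image@originMm)
      pivotMm <- ctr[1:2]
    }
    lab[lab == .MASK_LABELS[["marker"]]] <- 0L
  }

  capU <- lab == .MASK_LABELS[["cap_upper"]]
  if (!any(capU))
    stop("model has no upper cap; cannot synthesise the loading plate")
  kTop <- max(arrayInd(which(capU), dims)[, 3L])
  foot <- capU[, , kTop]
  if (kTop + plateVoxels > dims[3L])
    stop("grid too short above the upper cap for the steel plate layer")
  for (k in kTop + seq_len(plateVoxels)) {
    sl <- lab[, , k]
    sl[foot] <- .MODEL_PLATE
    lab[, , k] <- sl
  }

  cementE <- if (!is.null(cementEOverrideMPa)) cementEOverrideMPa else
    switch(match.arg(cementType), PMMA = mat@ECementPMMA,
           CaP = mat@ECementCaP)
  EFixed <- array(0, dims)
  EFixed[lab == .MASK_LABELS[["fracture"]]] <- mat@EGap
  EFixed[lab == .MASK_LABELS[["cement"]]] <- cementE
  EFixed[lab == .MASK_LABELS[["cap_lower"]] |
           lab == .MASK_LABELS[["cap_upper"]]] <- mat@ECap
  EFixed[lab == .MODEL_PLATE] <- mat@ESteel
  gBone <- array(0, dims)
  bone <- lab == .MASK_LABELS[["bone"]]
  gBone[bone] <- image@data[bone]

  if (is.null(pivotMm)) {
    fi <- which(foot, arr.ind = TRUE)
    pivotMm <- c(image@originMm[1L] + (mean(fi[, 1L]) - 0.5) * h,
                 image@originMm[2L] + (mean(fi[, 2L]) - 0.5) * h)
  }
  new("VoxelFEModel", labels = lab, EFixed = EFixed, gBone = gBone,
      alpha = alpha, EBoneFloor = mat@EBoneFloor, voxelMm = h,
      originMm = image@originMm, pivotMm = as.numeric(pivotMm[1:2]),
      appliedLoadN = appliedLoadN, nu = mat@nu,
      rotationsFree = rotationsFree)
}

#' Element modulus field of a model
#'
#' @param model a [VoxelFEModel].
#' @param alpha conversion factor; defaults to the model's.
#' @return numeric array of element moduli (MPa); 0 marks empty voxels.
#' @export
elementModuli <- function(model, alpha = NULL) {
  alpha <- alpha %||% model@alpha
  E <- model@EFixed
  bone <- model@gBone > 0 | model@labels == .MASK_LABELS[["bone"]]
  E[bone] <- pmax(alpha * model@gBone[bone], model@EBoneFloor)
  E
}

#' Solve a voxel finite-element model
#'
#' Assembles the global sparse symmetric stiffness system for the model's
#' element moduli and solves the axial compression problem (Jacobi-scaled
#' sparse Cholesky factorisation with iterative refinement to a relative
#' residual of 1e-8).
#'
#' @param model a [VoxelFEModel].
#' @param alpha optional conversion factor overriding the model's.
#' @return an [FESolution].
#' @export
solveModel <- function(model, alpha = NULL) {
  E <- elementModuli(model, alpha)
  prep <- .axialPrepare(E, NULL, h = model@voxelMm,
                        originMm = model@originMm, pivotMm = model@pivotMm,
                        loadN = model@appliedLoadN, nu = model@nu,
                        rotationsFree = model@rotationsFree)
  .asFESolution(prep, .axialSolveAt(prep, 1))
}

setMethod("show", "VoxelFEModel", function(object) {
  d <- dim(object@labels)
  cat(sprintf(paste0("VoxelFEModel: %d x %d x %d voxels at %g mm, %d ",
                     "elements; alpha %.4g; load %.0f N; pivot (%.1f, %.1f) ",
                     "mm; rotations %s\n"),
              d[1], d[2], d[3], object@voxelMm, sum(object@labels > 0),
              object@alpha, object@appliedLoadN, object@pivotMm[1],
              object@pivotMm[2],
              if (object@rotationsFree) "free" else "locked"))
})

#' Predicted axial stiffness of one specimen
#'
#' Convenience wrapper: build the model from masks and image and return
#' the solved axial stiffness.
#'
#' @inheritParams buildModel
#' @return stiffness in N/mm.
#' @export
specimenStiffness <- function(masks, image, mat = materialTable(),
                              cementType = c("PMMA", "CaP"), alpha = NULL) {
  stiffness(solveModel(buildModel(masks, image, mat,
                                  cementType = match.arg(cementType),
                                  alpha = alpha)))
}
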