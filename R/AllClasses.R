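#' @import methods
NULL

## Label encoding shared by SpecimenMasks and the volume writers.
.MASK_LABELS <- c(background = 0L, bone = 1L, fracture = 2L, cement = 3L,
                  cap_lower = 4L, cap_upper = 5L, marker = 6L)

#' VoxelImage: a 3-D grayscale volume with physical voxel geometry
#'
#' Container for a 3-D grayscale grid (arbitrary units) together with its
#' physical voxel size and origin, the in-memory surrogate for a micro-CT
#' scan. Voxel indices are 1-based in R; the physical centre of voxel
#' `(i,j,k)` is `origin + (c(i,j,k) - 0.5) * voxelMm`, and the third array
#' dimension is the axial (loading) direction.
#'
#' @slot data numeric 3-D array of grayscale values.
#' @slot voxelMm positive numeric length-3 vector, voxel edge lengths in mm.
#' @slot originMm numeric length-3 vector, physical position (mm) of the
#'   lower corner of voxel (1,1,1).
#' @exportClass VoxelImage
setClass("VoxelImage",
  representation(data = "array", voxelMm = "numeric", originMm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D array")
    if (length(object@voxelMm) != 3L || any(!is.finite(object@voxelMm)) ||
        any(object@voxelMm <= 0))
      msg <- c(msg, "voxelMm must be 3 positive finite values")
    if (length(object@originMm) != 3L || any(!is.finite(object@originMm)))
      msg <- c(msg, "originMm must be 3 finite values")
    if (is.null(msg)) TRUE else msg
  })

#' SpecimenMasks: disjoint component labels over one voxel grid
#'
#' One integer label volume encoding the segmented components of a potted
#' vertebral specimen: 0 background, 1 bone, 2 fracture gap, 3 cement,
#' 4 lower end cap, 5 upper end cap, 6 radiopaque marker. Storing a single
#' label volume makes the masks pairwise disjoint by construction; the
#' boolean grid for any component is recovered with [specimenMask()].
#'
#' @slot labels integer 3-D array with values in 0..6.
#' @exportClass SpecimenMasks
setClass("SpecimenMasks",
  representation(labels = "array"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3-D array")
    if (!all(object@labels %in% .MASK_LABELS))
      msg <- c(msg, "labels must take values in 0..6")
    if (is.null(msg)) TRUE else msg
  })

#' FractureScore: adapted grid-based fracture severity score
#'
#' Result of superimposing a grid on transverse slices of the fractured
#' vertebral body and scoring each cell 0 (no fracture evident), 1
#' (moderate) or 2 (severe/multiple fractures), normalised over all cells
#' scored; specimens are included when the normalised score reaches the
#' inclusion threshold.
#'
#' @slot cellScores integer array (rows, cols, slices) of per-cell scores
#'   in 0..2; `NA` for skipped slices.
#' @slot normalizedScore numeric in \[0,1\]: sum of cell scores divided by
#'   twice the number of cells scored.
#' @slot included logical inclusion decision.
#' @slot includeThreshold numeric threshold used for the decision.
#' @exportClass FractureScore
setClass("FractureScore",
  representation(cellScores = "array", normalizedScore = "numeric",
                 included = "logical", includeThreshold = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@normalizedScore < 0 || object@normalizedScore > 1)
      msg <- c(msg, "normalizedScore must lie in [0,1]")
    if (!identical(object@included,
                   object@normalizedScore >= object@includeThreshold))
      msg <- c(msg, "included must equal normalizedScore >= includeThreshold")
    if (is.null(msg)) TRUE else msg
  })

#' PhantomSpec: parameters of a synthetic voxel specimen
#'
#' Geometry, grayscale and randomisation parameters for a synthetic potted
#' vertebra: a circular-cylinder body between two rectangular PMMA end-cap
#' slabs, planar and/or ellipsoidal fracture voids, optional partial cement
#' fill, and a radiopaque marker in the upper cap. See [phantomSpec()].
#'
#' @slot gridShape integer length-3, voxel grid dimensions.
#' @slot voxelMm positive scalar voxel edge (mm); phantom voxels are cubic.
#' @slot bodyRadiusMm,bodyHeightMm cylinder body radius and height (mm).
#' @slot capThicknessMm,capWidthMm end-cap slab thickness and square side (mm).
#' @slot boneGrayMean,boneGraySd mean and SD of the bone grayscale field (a.u.).
#' @slot grayFieldCorrelationMm Gaussian correlation length of the bone
#'   grayscale field (mm); 0 gives voxelwise white noise.
#' @slot grayFloor,grayCeiling clip limits of the bone grayscale field (a.u.);
#'   the positive floor keeps the linear grayscale-to-modulus map positive.
#' @slot capGray,cementGray,markerGray plateau grayscale values (a.u.) of the
#'   non-bone components, ordered above `grayCeiling`.
#' @slot fracturePlanes list of `list(point, normal, thicknessMm)` planar voids.
#' @slot fractureBlobs list of `list(center, radiiMm)` ellipsoidal voids.
#' @slot fillFraction target fraction in \[0,1\] of the fracture void volume
#'   occupied by cement.
#' @slot cementLabel one of `"PMMA"`, `"CaP"`, `"none"`.
#' @slot markerCenterMm,markerRadiusMm marker sphere centre (mm) and radius (mm).
#' @slot seed integer seed controlling the grayscale field.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelMm = "numeric",
                 bodyRadiusMm = "numeric", bodyHeightMm = "numeric",
                 capThicknessMm = "numeric", capWidthMm = "numeric",
                 boneGrayMean = "numeric", boneGraySd = "numeric",
                 grayFieldCorrelationMm = "numeric",
                 grayFloor = "numeric", grayCeiling = "numeric",
                 capGray = "numeric", cementGray = "numeric",
                 markerGray = "numeric",
                 fracturePlanes = "list", fractureBlobs = "list",
                 fillFraction = "numeric", cementLabel = "character",
                 markerCenterMm = "numeric", markerRadiusMm = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    g <- object@gridShape; h <- object@voxelMm
    if (length(g) != 3L || any(g < 1L))
      msg <- c(msg, "gridShape must be 3 positive integers")
    if (length(h) != 1L || !is.finite(h) || h <= 0)
      msg <- c(msg, "voxelMm must be a positive scalar")
    if (object@fillFraction < 0 || object@fillFraction > 1)
      msg <- c(msg, "fillFraction must lie in [0,1]")
    if (!object@cementLabel %in% c("PMMA", "CaP", "none"))
      msg <- c(msg, "cementLabel must be one of PMMA, CaP, none")
    if (length(msg) == 0L) {
      if (2 * object@bodyRadiusMm > min(g[1], g[2]) * h)
        msg <- c(msg, "body cylinder does not fit inside the grid")
      if (object@capWidthMm > min(g[1], g[2]) * h)
        msg <- c(msg, "cap slabs do not fit inside the grid")
      if (2 * object@capThicknessMm + object@bodyHeightMm > g[3] * h)
        msg <- c(msg, "caps plus body exceed the grid height")
      if (!(object@grayFloor > 0 && object@grayFloor < object@grayCeiling &&
            object@grayCeiling < object@capGray &&
            object@capGray < object@cementGray &&
            object@cementGray < object@markerGray))
        msg <- c(msg, paste0("grayscale plateaus must satisfy 0 < floor < ",
                             "ceiling < cap < cement < marker"))
    }
    if (is.null(msg)) TRUE else msg
  })

#' SyntheticSpecimen: a generated phantom with ground truth
#'
#' A synthetic voxel specimen: the grayscale image, ground-truth component
#' masks, the true (pre-fill) fracture void and cement volumes, and the
#' generating [PhantomSpec]. Cemented voxels carry the cement label, so
#' `truthFractureVolumeMm3` records the full pre-augmentation void volume
#' (residual fracture plus cement).
#'
#' @slot image a [VoxelImage].
#' @slot masks ground-truth [SpecimenMasks].
#' @slot truthFractureVolumeMm3 pre-fill fracture void volume (mm^3).
#' @slot truthCementVolumeMm3 cement volume (mm^3).
#' @slot spec the generating [PhantomSpec].
#' @exportClass SyntheticSpecimen
setClass("SyntheticSpecimen",
  representation(image = "VoxelImage", masks = "SpecimenMasks",
                 truthFractureVolumeMm3 = "numeric",
                 truthCementVolumeMm3 = "numeric", spec = "PhantomSpec"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@image@data), dim(object@masks@labels)))
      msg <- c(msg, "image and masks must share one grid")
    if (object@truthFractureVolumeMm3 < 0 || object@truthCementVolumeMm3 < 0)
      msg <- c(msg, "truth volumes must be nonnegative")
    if (object@truthCementVolumeMm3 > object@truthFractureVolumeMm3 + 1e-9)
      msg <- c(msg, "cement volume cannot exceed the fracture void volume")
    if (is.null(msg)) TRUE else msg
  })

#' SimulatedMeasurement: surrogate axial compression test
#'
#' The simulated counterpart of an axial compression test on a materials
#' testing machine: a scalar measured stiffness (the forward finite-element
#' stiffness at the generating conversion factor, perturbed by multiplicative
#' Gaussian noise) and, optionally, a synthetic load-displacement curve with
#' a quadratic toe region followed by a linear segment of the measured slope.
#'
#' @slot stiffnessNPerMm measured (noisy) axial stiffness, N/mm.
#' @slot feStiffnessNPerMm noiseless forward-model stiffness, N/mm.
#' @slot curve data.frame with columns `displacement_mm`, `load_N`, or a
#'   zero-row data.frame when no curve was synthesised.
#' @slot alphaTrue generating grayscale-to-modulus factor (MPa per a.u.).
#' @slot noiseSdRel relative SD of the multiplicative measurement noise.
#' @slot seed integer seed of the noise draw.
#' @exportClass SimulatedMeasurement
setClass("SimulatedMeasurement",
  representation(stiffnessNPerMm = "numeric", feStiffnessNPerMm = "numeric",
                 curve = "data.frame", alphaTrue = "numeric",
                 noiseSdRel = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@stiffnessNPerMm <= 0) msg <- c(msg, "stiffness must be > 0")
    if (object@noiseSdRel < 0) msg <- c(msg, "noiseSdRel must be >= 0")
    if (nrow(object@curve) > 0) {
      if (!all(c("displacement_mm", "load_N") %in% names(object@curve)))
        msg <- c(msg, "curve must have columns displacement_mm, load_N")
      else if (is.unsorted(object@curve$load_N))
        msg <- c(msg, "curve load must be monotone nondecreasing")
    }
    if (is.null(msg)) TRUE else msg
  })

#' MaterialTable: material constants for the voxel FE model
#'
#' Elastic constants used when mapping component masks to element moduli.
#' Working units are mm / N / MPa; the constructor [materialTable()] takes
#' the familiar GPa values and converts. The defaults are: end caps
#' 2.45 GPa, fracture gap 1e-9 GPa (a near-zero filler that lets bone
#' fragments move relative to one another without contact mechanics),
#' steel plate 210 GPa, PMMA cement 1.035 GPa, CaP cement 0.585 GPa and a
#' single Poisson's ratio of 0.3 for all materials.
#'
#' @slot alpha grayscale-to-modulus conversion factor, MPa per grayscale unit.
#' @slot EGap,ECap,ESteel,ECementPMMA,ECementCaP elastic moduli in MPa.
#' @slot nu Poisson's ratio applied to every material.
#' @slot EBoneFloor small positive lower bound (MPa) on bone element moduli.
#' @exportClass MaterialTable
setClass("MaterialTable",
  representation(alpha = "numeric", EGap = "numeric", ECap = "numeric",
                 ESteel = "numeric", ECementPMMA = "numeric",
                 ECementCaP = "numeric", nu = "numeric",
                 EBoneFloor = "numeric"),
  validity = function(object) {
    msg <- NULL
    mods <- c(object@alpha, object@EGap, object@ECap, object@ESteel,
              object@ECementPMMA, object@ECementCaP, object@EBoneFloor)
    if (any(!is.finite(mods)) || any(mods <= 0))
      msg <- c(msg, "all moduli and alpha must be positive")
    if (object@nu < 0 || object@nu >= 0.5)
      msg <- c(msg, "Poisson's ratio must lie in [0, 0.5)")
    if (is.null(msg)) TRUE else msg
  })

#' VoxelFEModel: a voxel-hexahedral finite-element model of axial compression
#'
#' Per-voxel material labels and element moduli for one specimen, together
#' with the loading configuration: a synthesised steel plate atop the upper
#' cap, a compressive load applied at a pivot point (the radiopaque marker
#' position) through a rigid tie that is fixed in the horizontal plane but
#' free to rotate, and a fully fixed base on the flat underside of the
#' lower cap.
#'
#' @slot labels integer 3-D array; 0 none, 1 bone, 2 gap, 3 cement,
#'   4 lower cap, 5 upper cap, 7 steel plate.
#' @slot EFixed numeric array of fixed element moduli (MPa); 0 for bone voxels.
#' @slot gBone numeric array of bone voxel grayscales (a.u.); 0 elsewhere.
#' @slot alpha conversion factor (MPa per a.u.) applied to `gBone`.
#' @slot EBoneFloor lower bound (MPa) on bone moduli.
#' @slot voxelMm cubic voxel edge (mm).
#' @slot originMm physical origin (mm).
#' @slot pivotMm length-2 (x, y) pivot position (mm) of the rigid tie.
#' @slot appliedLoadN compressive load magnitude (N), default 4500.
#' @slot nu Poisson's ratio.
#' @slot rotationsFree logical; if `FALSE` the plate tilt DOFs are locked.
#' @exportClass VoxelFEModel
setClass("VoxelFEModel",
  representation(labels = "array", EFixed = "array", gBone = "array",
                 alpha = "numeric", EBoneFloor = "numeric",
                 voxelMm = "numeric", originMm = "numeric",
                 pivotMm = "numeric", appliedLoadN = "numeric",
                 nu = "numeric", rotationsFree = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@labels), dim(object@EFixed)) ||
        !identical(dim(object@labels), dim(object@gBone)))
      msg <- c(msg, "labels, EFixed and gBone must share one grid")
    if (object@appliedLoadN <= 0) msg <- c(msg, "appliedLoadN must be > 0")
    if (object@voxelMm <= 0) msg <- c(msg, "voxelMm must be > 0")
    if (any(object@EFixed < 0)) msg <- c(msg, "EFixed must be nonnegative")
    if (is.null(msg)) TRUE else msg
  })

#' FESolution: solved axial compression model
#'
#' Nodal displacements and the scalar axial stiffness of a solved
#' [VoxelFEModel]. The stiffness is the applied load divided by the axial
#' displacement of the loading point on the rigid tie.
#'
#' @slot stiffnessNPerMm axial stiffness, N/mm.
#' @slot plateDofs generalized plate coordinates `(Uz, Rx, Ry)` (mm, rad).
#' @slot loadingPointDispMm signed axial displacement of the loading point (mm).
#' @slot nodeIndex integer matrix (n x 3) of 1-based node grid indices.
#' @slot displacements numeric matrix (n x 3) of nodal displacements (mm).
#' @slot solverReport list: relative residual, refinement iterations, counts,
#'   base reaction, strain energy, dropped elements.
#' @exportClass FESolution
setClass("FESolution",
  representation(stiffnessNPerMm = "numeric", plateDofs = "numeric",
                 loadingPointDispMm = "numeric", nodeIndex = "matrix",
                 displacements = "matrix", solverReport = "list"),
  validity = function(object) {
    msg <- NULL
    if (object@stiffnessNPerMm <= 0) msg <- c(msg, "stiffness must be > 0")
    load <- object@solverReport$appliedLoadN
    if (!is.null(load)) {
      k <- load / abs(object@loadingPointDispMm)
      if (abs(k - object@stiffnessNPerMm) > 1e-8 * k)
        msg <- c(msg, "stiffness must equal load / |loading point displacement|")
    }
    if (is.null(msg)) TRUE else msg
  })

#' CalibrationResult: fitted grayscale-to-modulus conversion factor
#'
#' Result of iteratively adjusting the conversion factor until the mean
#' error between measured and model-predicted stiffness over a development
#' set is minimised.
#'
#' @slot alphaHat fitted conversion factor (MPa per grayscale unit).
#' @slot objective objective name, `"mape"` or `"signed"`.
#' @slot objectiveValue objective value at `alphaHat`.
#' @slot perSpecimen data.frame: id, predicted, measured, pctError.
#' @slot trace data.frame of every (alpha, objective) evaluation.
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(alphaHat = "numeric", objective = "character",
                 objectiveValue = "numeric", perSpecimen = "data.frame",
                 trace = "data.frame"),
  validity = function(object) {
    if (object@alphaHat <= 0) "alphaHat must be > 0" else TRUE
  })

#' SensitivityTable: fracture-gap modulus sensitivity study
#'
#' Stiffness of one specimen solved over a descending sequence of fracture
#' gap moduli; the plateau value is the first modulus at which a further
#' decrease changes the stiffness by less than the chosen tolerance, and
#' the recommended working value lies three orders of magnitude below it.
#'
#' @slot table data.frame: `eGapGPa`, `stiffnessNPerMm`.
#' @slot plateauEGapGPa plateau gap modulus (GPa).
#' @slot recommendedEGapGPa `plateauEGapGPa / 1000`.
#' @exportClass SensitivityTable
setClass("SensitivityTable",
  representation(table = "data.frame", plateauEGapGPa = "numeric",
                 recommendedEGapGPa = "numeric"),
  validity = function(object) {
    ok <- abs(object@recommendedEGapGPa - object@plateauEGapGPa / 1000) <=
      1e-12 * object@plateauEGapGPa
    if (!ok) "recommendedEGapGPa must equal plateauEGapGPa / 1000" else TRUE
  })

#' AugmentationStudyResult: virtual cement-swap study
#'
#' Every augmented specimen solved twice, with its cement region assigned
#' the PMMA modulus and then the CaP modulus, against a fractured baseline
#' in which the cement region is reassigned the fracture-gap modulus;
#' stiffness gains are correlated with the percentage fracture fill.
#'
#' @slot perSpecimen data.frame: id, percentFill, stiffnessFractured,
#'   stiffnessPMMAModulus, stiffnessCaPModulus, gainPMMA, gainCaP.
#' @slot correlations data.frame: cement, r, p, n.
#' @exportClass AugmentationStudyResult
setClass("AugmentationStudyResult",
  representation(perSpecimen = "data.frame", correlations = "data.frame"),
  validity = function(object) {
    ps <- object@perSpecimen
    if (nrow(ps) &&
        any(ps$stiffnessPMMAModulus < ps$stiffnessCaPModulus - 1e-6 *
              pmax(ps$stiffnessPMMAModulus, 1)))
      "stiffness at the PMMA modulus must be >= stiffness at the CaP modulus"
    else TRUE
  })
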