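#' Specify a synthetic voxel specimen
#'
#' Builds a [PhantomSpec] describing a potted-vertebra surrogate: a
#' circular-cylinder "vertebral body" of spatially correlated bone
#' grayscale between two rectangular end-cap slabs, optional planar and
#' ellipsoidal fracture voids, a partial cement fill spreading from two
#' pedicle-like entry axes, and a spherical radiopaque marker embedded in
#' the upper cap. The default grid is 40 x 40 x 56 voxels at 1 mm, the
#' working resolution of the finite-element mesh; the default phantom is
#' intact (no voids, no cement).
#'
#' @param gridShape integer length-3 grid dimensions (voxels).
#' @param voxelMm cubic voxel edge (mm).
#' @param bodyRadiusMm,bodyHeightMm body cylinder radius and height (mm).
#' @param capThicknessMm,capWidthMm end-cap slab thickness and square side (mm).
#' @param boneGrayMean,boneGraySd bone grayscale mean and SD (a.u.).
#' @param grayFieldCorrelationMm Gaussian correlation length (mm) of the bone
#'   grayscale field.
#' @param grayFloor,grayCeiling clip limits (a.u.) of the bone field; the
#'   positive floor guarantees positive bone moduli under a linear
#'   grayscale-to-modulus map.
#' @param capGray,cementGray,markerGray distinct plateau grayscales (a.u.)
#'   for caps, cement and marker, all above `grayCeiling`.
#' @param fracturePlanes list of `list(point, normal, thicknessMm)` slabs
#'   (mm units, grid coordinates) intersected with the body; an optional
#'   `radiusMm` bounds the in-plane extent of the crack about `point`
#'   (burst-fracture cracks are partial, leaving bone bridges that keep
#'   the fragments load-bearing).
#' @param fractureBlobs list of `list(center, radiiMm)` ellipsoids
#'   intersected with the body.
#' @param fillFraction target fraction in \[0,1\] of void volume cemented.
#' @param cementLabel `"PMMA"`, `"CaP"` or `"none"`.
#' @param markerCenterMm marker centre (mm); default mid upper cap.
#' @param markerRadiusMm marker sphere radius (mm).
#' @param seed integer seed for the grayscale field.
#' @return a validated [PhantomSpec].
#' @export
phantomSpec <- function(gridShape = c(40L, 40L, 56L), voxelMm = 1,
                        bodyRadiusMm = 16, bodyHeightMm = 32,
                        capThicknessMm = 8, capWidthMm = 36,
                        boneGrayMean = 250, boneGraySd = 60,
                        grayFieldCorrelationMm = 3,
                        grayFloor = 25, grayCeiling = 600,
                        capGray = 1000, cementGray = 1500, markerGray = 2000,
                        fracturePlanes = list(), fractureBlobs = list(),
                        fillFraction = 0, cementLabel = "none",
                        markerCenterMm = NULL, markerRadiusMm = 2,
                        seed = 1L) {
  gridShape <- as.integer(gridShape)
  if (is.null(markerCenterMm)) {
    zMargin <- (gridShape[3] * voxelMm -
                  (2 * capThicknessMm + bodyHeightMm)) / 2
    markerCenterMm <- c(gridShape[1] * voxelMm / 2,
                        gridShape[2] * voxelMm / 2,
                        zMargin + 1.5 * capThicknessMm + bodyHeightMm)
  }
  new("PhantomSpec", gridShape = gridShape, voxelMm = voxelMm,
      bodyRadiusMm = bodyRadiusMm, bodyHeightMm = bodyHeightMm,
      capThicknessMm = capThicknessMm, capWidthMm = capWidthMm,
      boneGrayMean = boneGrayMean, boneGraySd = boneGraySd,
      grayFieldCorrelationMm = grayFieldCorrelationMm,
      grayFloor = grayFloor, grayCeiling = grayCeiling, capGray = capGray,
      cementGray = cementGray, markerGray = markerGray,
      fracturePlanes = fracturePlanes, fractureBlobs = fractureBlobs,
      fillFraction = fillFraction, cementLabel = cementLabel,
      markerCenterMm = as.numeric(markerCenterMm),
      markerRadiusMm = markerRadiusMm, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  g <- object@gridShape
  cat(sprintf(paste0("PhantomSpec: %d x %d x %d voxels at %g mm; body r=%g ",
                     "h=%g mm; caps %g mm; %d plane(s), %d blob(s); fill ",
                     "%.2f (%s); seed %d\n"),
              g[1], g[2], g[3], object@voxelMm, object@bodyRadiusMm,
              object@bodyHeightMm, object@capThicknessMm,
              length(object@fracturePlanes), length(object@fractureBlobs),
              object@fillFraction, object@cementLabel, object@seed))
})

## Gaussian smoothing along every axis; edge kernels are renormalised.
.gaussSmooth <- function(a, sigmaVox) {
  if (sigmaVox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigmaVox))
  for (ax in 1:3) {
    n <- dim(a)[ax]
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      w <- stats::dnorm(j - i, sd = sigmaVox)
      W[i, j] <- w / sum(w)
    }
    a <- applyAlongAxis(a, W, ax)
  }
  a
}

## z layout of the phantom: margin | lower cap | body | upper cap | margin
.phantomLayout <- function(spec) {
  g <- spec@gridShape; h <- spec@voxelMm
  zMargin <- (g[3] * h - (2 * spec@capThicknessMm + spec@bodyHeightMm)) / 2
  list(cx = g[1] * h / 2, cy = g[2] * h / 2,
       zCapLower = c(zMargin, zMargin + spec@capThicknessMm),
       zBody = c(zMargin + spec@capThicknessMm,
                 zMargin + spec@capThicknessMm + spec@bodyHeightMm),
       zCapUpper = c(zMargin + spec@capThicknessMm + spec@bodyHeightMm,
                     zMargin + 2 * spec@capThicknessMm + spec@bodyHeightMm))
}

#' Generate a synthetic voxel specimen
#'
#' Rasterises the geometry of a [PhantomSpec] onto its voxel grid,
#' synthesises a smoothed Gaussian bone grayscale field (clipped to a
#' positive floor), assigns distinct plateau grayscales to the caps,
#' cement and marker, and near-zero grayscale to fracture voids and
#' background. Cement occupies the void voxels closest to two
#' pedicle-like entry axes until the target fill fraction is reached,
#' emulating the spatially coherent spread of a bi-pedicular injection.
#' Deterministic given `spec@seed`.
#'
#' @param spec a [PhantomSpec].
#' @return a [SyntheticSpecimen] with ground-truth masks and volumes.
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  g <- spec@gridShape; h <- spec@voxelMm
  lay <- .phantomLayout(spec)
  cc <- voxelCenters(g, h)
  X <- array(cc[[1]], g)
  Y <- array(rep(cc[[2]], each = g[1]), g)
  Z <- array(rep(cc[[3]], each = g[1] * g[2]), g)

  inBody <- (X - lay$cx)^2 + (Y - lay$cy)^2 <= spec@bodyRadiusMm^2 &
    Z >= lay$zBody[1] & Z < lay$zBody[2]
  inFoot <- abs(X - lay$cx) <= spec@capWidthMm / 2 &
    abs(Y - lay$cy) <= spec@capWidthMm / 2
  capLower <- inFoot & Z >= lay$zCapLower[1] & Z < lay$zCapLower[2]
  capUpper <- inFoot & Z >= lay$zCapUpper[1] & Z < lay$zCapUpper[2]

  void <- array(FALSE, g)
  for (pl in spec@fracturePlanes) {
    n <- pl$normal / sqrt(sum(pl$normal^2))
    d <- (X - pl$point[1]) * n[1] + (Y - pl$point[2]) * n[2] +
      (Z - pl$point[3]) * n[3]
    sl <- abs(d) <= pl$thicknessMm / 2
    r <- pl$radiusMm %||% Inf
    if (is.finite(r)) {
      r2 <- (X - pl$point[1])^2 + (Y - pl$point[2])^2 +
        (Z - pl$point[3])^2 - d^2
      sl <- sl & r2 <= r^2
    }
    void <- void | sl
  }
  for (bl in spec@fractureBlobs) {
    r <- rep(bl$radiiMm, length.out = 3L)
    void <- void | ((X - bl$center[1])^2 / r[1]^2 +
                      (Y - bl$center[2])^2 / r[2]^2 +
                      (Z - bl$center[3])^2 / r[3]^2 <= 1)
  }
  void <- void & inBody
  bone <- inBody & !void

  ## cement: fill void voxels nearest the two pedicle entry axes first
  cement <- array(FALSE, g)
  if (spec@cementLabel != "none" && spec@fillFraction > 0) {
    if (!any(void))
      stop("fillFraction requested but the phantom defines no fracture")
    nCem <- round(spec@fillFraction * sum(void))
    if (nCem > 0) {
      zMid <- mean(lay$zBody)
      xEntry <- lay$cx + c(-1, 1) * spec@bodyRadiusMm / 2
      vIdx <- which(void)
      dist <- pmin(sqrt((X[vIdx] - xEntry[1])^2 + (Z[vIdx] - zMid)^2),
                   sqrt((X[vIdx] - xEntry[2])^2 + (Z[vIdx] - zMid)^2))
      cement[vIdx[order(dist, vIdx)[seq_len(nCem)]]] <- TRUE
    }
  }
  fracture <- void & !cement

  marker <- (X - spec@markerCenterMm[1])^2 + (Y - spec@markerCenterMm[2])^2 +
    (Z - spec@markerCenterMm[3])^2 <= spec@markerRadiusMm^2
  if (!any(marker))
    stop("marker sphere rasterises to no voxels; increase markerRadiusMm")
  capUpper <- capUpper & !marker
  marker <- marker & !bone & !fracture & !cement & !capLower

  ## bone grayscale: smoothed Gaussian random field, standardised over the
  ## bone voxels, clipped to [floor, ceiling]
  gray <- array(0, g)
  if (any(bone)) {
    field <- withSeed(spec@seed, array(stats::rnorm(prod(g)), g))
    field <- .gaussSmooth(field, spec@grayFieldCorrelationMm / h)
    mu <- mean(field[bone]); sdv <- stats::sd(field[bone])
    std <- if (is.finite(sdv) && sdv > 0) (field - mu) / sdv else field * 0
    gray[bone] <- pmin(pmax(spec@boneGrayMean + spec@boneGraySd * std[bone],
                            spec@grayFloor), spec@grayCeiling)
  }
  gray[capLower | capUpper] <- spec@capGray
  gray[cement] <- spec@cementGray
  gray[marker] <- spec@markerGray

  masks <- SpecimenMasks(bone = bone, fracture = fracture, cement = cement,
                         capLower = capLower, capUpper = capUpper,
                         marker = marker)
  new("SyntheticSpecimen",
      image = VoxelImage(gray, h), masks = masks,
      truthFractureVolumeMm3 = sum(void) * h^3,
      truthCementVolumeMm3 = sum(cement) * h^3, spec = spec)
}

#' @describeIn generatePhantom image accessor.
#' @param specimen a [SyntheticSpecimen].
#' @export
specimenImage <- function(specimen) specimen@image

#' @describeIn generatePhantom ground-truth masks accessor.
#' @export
truthMasks <- function(specimen) specimen@masks

setMethod("show", "SyntheticSpecimen", function(object) {
  cat(sprintf(paste0("SyntheticSpecimen: void %.1f mm^3, cement %.1f mm^3 ",
                     "(%s)\n"), object@truthFractureVolumeMm3,
              object@truthCementVolumeMm3, object@spec@cementLabel))
  show(object@image)
})

#' Grayscale windows separating the phantom's components
#'
#' Midpoint windows between the phantom's bone grayscale range and the
#' plateau values of caps, cement and marker, suitable for
#' [segmentSpecimen()] on images produced by [generatePhantom()].
#'
#' @param spec a [PhantomSpec].
#' @return named list of `c(lo, hi)` windows.
#' @export
segmentationWindows <- function(spec) {
  list(bone = c(spec@grayFloor / 2, (spec@grayCeiling + spec@capGray) / 2),
       cap = c((spec@grayCeiling + spec@capGray) / 2,
               (spec@capGray + spec@cementGray) / 2),
       cement = c((spec@capGray + spec@cementGray) / 2,
                  (spec@cementGray + spec@markerGray) / 2),
       marker = c((spec@cementGray + spec@markerGray) / 2, Inf))
}

#' Simulate an axial compression measurement of a specimen
#'
#' Runs the voxel finite-element forward model at the generating
#' conversion factor `alphaTrue`, perturbs the stiffness with
#' multiplicative Gaussian noise, and optionally synthesises a
#' load-displacement curve with a quadratic toe region (slope-continuous
#' at the toe end) followed by a linear segment of the measured slope, the
#' shape a displacement-controlled test at constant rate produces.
#'
#' @param specimen a [SyntheticSpecimen].
#' @param alphaTrue generating conversion factor (MPa per grayscale unit).
#' @param noiseSdRel relative SD of the multiplicative measurement noise.
#' @param seed integer seed for the noise draw.
#' @param mat a [MaterialTable] for the forward model (its `alpha` is
#'   overridden by `alphaTrue`).
#' @param curve logical; synthesise the load-displacement curve?
#' @param toeMm toe-region length (mm).
#' @param loadCapN approximate load at which the synthetic curve stops (N);
#'   the linear segment always spans at least 0.8 mm so a 0.6 mm gradient
#'   window fits inside it.
#' @param curveStepMm displacement sampling step (mm).
#' @param feStiffnessNPerMm optional precomputed forward stiffness (N/mm),
#'   to avoid re-solving when drawing many noise replicates of one specimen.
#' @return a [SimulatedMeasurement].
#' @export
simulateMeasurement <- function(specimen, alphaTrue, noiseSdRel = 0,
                                seed = 1L, mat = materialTable(),
                                curve = TRUE, toeMm = 0.3, loadCapN = 4500,
                                curveStepMm = 0.01,
                                feStiffnessNPerMm = NULL) {
  if (is.null(feStiffnessNPerMm)) {
    mat@alpha <- alphaTrue
    model <- buildModel(truthMasks(specimen), specimenImage(specimen), mat,
                        cementType = if (specimen@spec@cementLabel == "CaP")
                          "CaP" else "PMMA")
    feStiffnessNPerMm <- stiffness(solveModel(model))
  }
  eps <- if (noiseSdRel > 0)
    withSeed(seed, stats::rnorm(1, 0, noiseSdRel)) else 0
  k <- feStiffnessNPerMm * (1 + eps)
  if (k <= 0) stop("noise draw produced a nonpositive stiffness")
  curveDf <- data.frame(displacement_mm = numeric(0), load_N = numeric(0))
  if (isTRUE(curve)) {
    dLin <- max(0.8, (loadCapN - k * toeMm / 2) / k)
    d <- seq(0, toeMm + dLin, by = curveStepMm)
    load <- ifelse(d <= toeMm, k * d^2 / (2 * toeMm),
                   k * toeMm / 2 + k * (d - toeMm))
    curveDf <- data.frame(displacement_mm = d, load_N = load)
  }
  new("SimulatedMeasurement", stiffnessNPerMm = k,
      feStiffnessNPerMm = feStiffnessNPerMm, curve = curveDf,
      alphaTrue = alphaTrue, noiseSdRel = noiseSdRel, seed = as.integer(seed))
}

setMethod("show", "SimulatedMeasurement", function(object) {
  cat(sprintf(paste0("SimulatedMeasurement: %.1f N/mm (FE %.1f, noise SD ",
                     "%.3f, seed %d)\n"), object@stiffnessNPerMm,
              object@feStiffnessNPerMm, object@noiseSdRel, object@seed))
})

#' Generate a cohort of synthetic specimens with simulated tests
#'
#' Builds intact, fractured and cement-augmented specimens from a common
#' base geometry with per-specimen randomised fracture severity and fill
#' fraction, and simulates their axial compression measurements.
#' Augmented specimens carry both the pre-augmentation (cement-free) and
#' post-augmentation images of the same geometry and grayscale field, and
#' a pre-augmentation measurement, mirroring a study in which fractured
#' specimens are tested, injected and re-tested. Default fill-fraction
#' targets are 0.53 (SD 0.055) for PMMA and 0.36 (SD 0.125) for CaP.
#'
#' @param nIntact,nFractured,nPMMA,nCaP group sizes.
#' @param baseSpec a [PhantomSpec] providing the common geometry.
#' @param seed integer master seed; all per-specimen seeds derive from it.
#' @param alphaTrue generating conversion factor (MPa per a.u.).
#' @param noiseSdRel relative measurement noise SD.
#' @param fillMeanPMMA,fillSdPMMA,fillMeanCaP,fillSdCaP fill-fraction
#'   sampling parameters per arm (clamped to \[0.05, 0.95\]).
#' @param simulateMeasurements logical; skip the (finite-element)
#'   measurement simulation when only geometry is needed.
#' @param mat a [MaterialTable] for the forward models.
#' @return list of records, one per specimen, each with elements `id`,
#'   `arm` (`"intact"`, `"fractured"`, `"PMMA"`, `"CaP"`), `specimen`,
#'   `preSpecimen` (augmented arms only, else `NULL`), `measurement`,
#'   `preMeasurement`, `targetFillFraction`.
#' @export
generateCohort <- function(nIntact, nFractured, nPMMA, nCaP,
                           baseSpec = phantomSpec(), seed = 1L,
                           alphaTrue = 0.5, noiseSdRel = 0.05,
                           fillMeanPMMA = 0.53, fillSdPMMA = 0.055,
                           fillMeanCaP = 0.36, fillSdCaP = 0.125,
                           simulateMeasurements = TRUE,
                           mat = materialTable()) {
  stopifnot(nIntact >= 0, nFractured >= 0, nPMMA >= 0, nCaP >= 0)
  arms <- rep(c("intact", "fractured", "PMMA", "CaP"),
              c(nIntact, nFractured, nPMMA, nCaP))
  n <- length(arms)
  if (n == 0L) return(list())
  lay <- .phantomLayout(baseSpec)
  h <- baseSpec@voxelMm
  draws <- withSeed(seed, {
    lapply(seq_len(n), function(i) {
      nPlanes <- sample(1:2, 1)
      ## two cracks are kept axially separated so their sub-voxel slabs
      ## cannot merge into a gap thicker than the closing kernel recovers
      zOffs <- if (nPlanes == 1L)
        stats::runif(1, -0.25, 0.25) * baseSpec@bodyHeightMm
      else c(-1, 1) * stats::runif(2, 0.12, 0.3) * baseSpec@bodyHeightMm
      planes <- lapply(zOffs, function(zOff) {
        tilt <- stats::runif(2, -0.12, 0.12)
        ctrOff <- stats::runif(2, -0.2, 0.2) * baseSpec@bodyRadiusMm
        ## snap the crack to the nearest voxel-centre layer so sub-voxel
        ## apertures always rasterise to a nonempty void
        zPlane <- (round((mean(lay$zBody) + zOff) / h - 0.5) + 0.5) * h
        list(point = c(lay$cx + ctrOff[1], lay$cy + ctrOff[2], zPlane),
             normal = c(tilt[1], tilt[2], 1),
             ## sub-voxel crack apertures: a side-2 closing kernel (the
             ## working segmentation default) recovers gaps one voxel thick
             thicknessMm = stats::runif(1, 0.5, 0.95) * h,
             radiusMm = stats::runif(1, 0.45, 0.8) * baseSpec@bodyRadiusMm)
      })
      fill <- switch(arms[i],
                     PMMA = stats::rnorm(1, fillMeanPMMA, fillSdPMMA),
                     CaP = stats::rnorm(1, fillMeanCaP, fillSdCaP), 0)
      list(planes = planes, fill = min(max(fill, 0.05), 0.95),
           seeds = sample.int(2147483646L, 3L))
    })
  })
  lapply(seq_len(n), function(i) {
    arm <- arms[i]
    dr <- draws[[i]]
    sp <- baseSpec
    sp@seed <- dr$seeds[1]
    if (arm != "intact") sp@fracturePlanes <- dr$planes
    if (arm %in% c("PMMA", "CaP")) {
      sp@cementLabel <- arm
      sp@fillFraction <- dr$fill
    } else {
      sp@cementLabel <- "none"
      sp@fillFraction <- 0
    }
    specimen <- generatePhantom(sp)
    preSpecimen <- NULL
    if (arm %in% c("PMMA", "CaP")) {
      spPre <- sp
      spPre@cementLabel <- "none"
      spPre@fillFraction <- 0
      preSpecimen <- generatePhantom(spPre)
    }
    measurement <- preMeasurement <- NULL
    if (simulateMeasurements) {
      measurement <- simulateMeasurement(specimen, alphaTrue, noiseSdRel,
                                         seed = dr$seeds[2], mat = mat)
      if (!is.null(preSpecimen))
        preMeasurement <- simulateMeasurement(preSpecimen, alphaTrue,
                                              noiseSdRel,
                                              seed = dr$seeds[3], mat = mat)
    }
    list(id = sprintf("S%02d", i), arm = arm, specimen = specimen,
         preSpecimen = preSpecimen, measurement = measurement,
         preMeasurement = preMeasurement,
         targetFillFraction = if (arm %in% c("PMMA", "CaP")) dr$fill else 0)
  })
}
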