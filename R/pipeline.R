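#' Run the full synthetic study pipeline
#'
#' End-to-end exercise of the methodology on a synthetic cohort: generate
#' phantoms and simulated compression tests; segment every image into
#' component masks (threshold windows, morphological fracture extraction);
#' score fracture severity; measure percent fracture fill against the
#' pre-augmentation void; calibrate the grayscale-to-modulus conversion
#' factor on a development set of fractured models and validate it on the
#' held-out fractured and augmented models (percentage errors, Lin's
#' concordance, Bland-Altman); run the gap-modulus sensitivity study; run
#' the virtual cement-swap study; and compare the groups (one-way ANOVA
#' with Tukey-Kramer on measured stiffness, unpaired t test on percent
#' fill, Pearson correlation of stiffness gain with percent fill).
#' Deterministic given `seed`.
#'
#' @param seed integer master seed.
#' @param baseSpec a [PhantomSpec]; its grid size sets the problem scale.
#' @param nIntact,nFractured,nPMMA,nCaP cohort group sizes.
#' @param alphaTrue generating conversion factor (MPa per grayscale unit).
#' @param noiseSdRel relative measurement noise SD.
#' @param devSize development-set size for the calibration.
#' @param mat a [MaterialTable].
#' @param calibrationBracket bracket passed to [calibrateAlpha()].
#' @param kernelPx fracture-closing kernel passed to [segmentSpecimen()].
#' @param eGapGPa descending gap-modulus sequence for [gapSensitivity()].
#' @param quiet suppress segmentation progress messages.
#' @return a nested list of results (numbers and small data.frames), ready
#'   for JSON serialisation.
#' @export
runPipeline <- function(seed = 1L, baseSpec = phantomSpec(),
                        nIntact = 5L, nFractured = 5L, nPMMA = 6L,
                        nCaP = 6L, alphaTrue = 0.5, noiseSdRel = 0.05,
                        devSize = 6L, mat = materialTable(),
                        calibrationBracket = c(0.05, 5), kernelPx = 2L,
                        eGapGPa = 10^seq(-3, -9, by = -1), quiet = TRUE) {
  seg <- if (quiet) function(x) suppressMessages(x) else identity
  cohort <- generateCohort(nIntact, nFractured, nPMMA, nCaP,
                           baseSpec = baseSpec, seed = seed,
                           alphaTrue = alphaTrue, noiseSdRel = noiseSdRel,
                           mat = mat)
  windows <- segmentationWindows(baseSpec)
  arms <- vapply(cohort, `[[`, character(1), "arm")
  measured <- vapply(cohort, function(e) stiffness(e$measurement),
                     numeric(1))

  segmented <- lapply(cohort, function(e) {
    post <- seg(segmentSpecimen(specimenImage(e$specimen), windows,
                                kernelPx))
    pre <- if (!is.null(e$preSpecimen))
      seg(segmentSpecimen(specimenImage(e$preSpecimen), windows, kernelPx))
    else NULL
    list(post = post, pre = pre)
  })
  vox <- baseSpec@voxelMm

  ## fracture scoring on the fracture-bearing (pre-augmentation) masks
  scores <- lapply(seq_along(cohort), function(i) {
    if (arms[i] == "intact") return(NULL)
    m <- segmented[[i]]$pre %||% segmented[[i]]$post
    fractureScore(specimenMask(m, "fracture"), specimenMask(m, "bone"))
  })
  scoreVals <- vapply(scores[!vapply(scores, is.null, logical(1))],
                      function(s) s@normalizedScore, numeric(1))
  scoreIncl <- vapply(scores[!vapply(scores, is.null, logical(1))],
                      function(s) s@included, logical(1))

  ## image-measured percent fill: post cement volume over pre void volume
  fills <- vapply(seq_along(cohort), function(i) {
    if (!arms[i] %in% c("PMMA", "CaP")) return(NA_real_)
    cem <- maskVolume(specimenMask(segmented[[i]]$post, "cement"), vox)
    void <- maskVolume(specimenMask(segmented[[i]]$pre, "fracture"), vox)
    if (void <= 0) return(NA_real_)
    suppressWarnings(percentFill(cem, void))
  }, numeric(1))

  ## the fractured-model set (pre-augmentation state of every non-intact
  ## specimen) carries the calibration and its validation
  fracIdx <- which(arms != "intact")
  fracSet <- lapply(fracIdx, function(i) {
    e <- cohort[[i]]
    pre <- arms[i] %in% c("PMMA", "CaP")
    list(id = e$id,
         masks = if (pre) segmented[[i]]$pre else segmented[[i]]$post,
         image = if (pre) specimenImage(e$preSpecimen) else
           specimenImage(e$specimen),
         measured = if (pre) stiffness(e$preMeasurement) else measured[i],
         cementType = "PMMA")
  })
  devSize <- min(devSize, length(fracSet))
  devIdx <- sort(withSeed(seed + 101L,
                          sample(seq_along(fracSet), devSize)))
  calib <- calibrateAlpha(fracSet[devIdx], objective = "mape",
                          bracket = calibrationBracket, mat = mat)
  aHat <- alphaHat(calib)
  valFrac <- if (length(fracSet) > devSize)
    validateAlpha(fracSet[-devIdx], aHat, mat) else NULL

  augIdx <- which(arms %in% c("PMMA", "CaP"))
  augSet <- lapply(augIdx, function(i)
    list(id = cohort[[i]]$id, masks = segmented[[i]]$post,
         image = specimenImage(cohort[[i]]$specimen),
         measured = measured[i], cementType = arms[i]))
  valAug <- if (length(augSet)) validateAlpha(augSet, aHat, mat) else NULL

  cccAll <- if (!is.null(valFrac) && !is.null(valAug))
    linCCC(c(valFrac$perSpecimen$measured, valAug$perSpecimen$measured),
           c(valFrac$perSpecimen$predicted, valAug$perSpecimen$predicted))
  else NA_real_

  gap <- if (length(fracSet))
    gapSensitivity(fracSet[[1L]], eGapGPa, mat, alpha = aHat) else NULL

  augStudy <- if (length(augSet))
    virtualAugmentation(augSet, mat, alpha = aHat) else NULL

  armOrder <- c("intact", "fractured", "PMMA", "CaP")
  groups <- lapply(armOrder, function(a) measured[arms == a])
  names(groups) <- armOrder
  groups <- groups[lengths(groups) >= 2L]
  groupStats <- if (length(groups) >= 2L) tukeyKramer(groups) else NULL
  fillT <- if (sum(!is.na(fills[arms == "PMMA"])) >= 2L &&
               sum(!is.na(fills[arms == "CaP"])) >= 2L)
    tTestUnpaired(fills[arms == "PMMA"][!is.na(fills[arms == "PMMA"])],
                  fills[arms == "CaP"][!is.na(fills[arms == "CaP"])])
  else NULL

  list(
    seed = as.integer(seed),
    cohort = data.frame(id = vapply(cohort, `[[`, character(1), "id"),
                        arm = arms, measuredStiffness = measured,
                        percentFill = fills),
    scores = list(meanNormalizedScore = mean(scoreVals),
                  fractionIncluded = mean(scoreIncl)),
    fill = list(meanPMMA = mean(fills[arms == "PMMA"], na.rm = TRUE),
                sdPMMA = stats::sd(fills[arms == "PMMA"], na.rm = TRUE),
                meanCaP = mean(fills[arms == "CaP"], na.rm = TRUE),
                sdCaP = stats::sd(fills[arms == "CaP"], na.rm = TRUE),
                tTest = fillT),
    calibration = list(alphaTrue = alphaTrue, alphaHat = aHat,
                       alphaPctError = 100 * (aHat - alphaTrue) / alphaTrue,
                       objectiveValue = calib@objectiveValue,
                       devIds = vapply(fracSet[devIdx], `[[`, character(1),
                                       "id"),
                       perSpecimen = calib@perSpecimen),
    validation = list(
      fractured = if (is.null(valFrac)) NULL else
        valFrac[c("perSpecimen", "meanAbsPctError", "ccc")],
      augmented = if (is.null(valAug)) NULL else
        valAug[c("perSpecimen", "meanAbsPctError", "ccc")],
      cccExcludingDev = cccAll),
    gapSensitivity = if (is.null(gap)) NULL else
      list(table = gap@table, plateauEGapGPa = gap@plateauEGapGPa,
           recommendedEGapGPa = gap@recommendedEGapGPa),
    augmentation = if (is.null(augStudy)) NULL else
      list(perSpecimen = augStudy@perSpecimen,
           correlations = augStudy@correlations),
    groupStats = if (is.null(groupStats)) NULL else
      list(F = groupStats$anova$F, dfBetween = groupStats$anova$dfBetween,
           dfWithin = groupStats$anova$dfWithin, p = groupStats$anova$p,
           groupMeans = as.list(groupStats$anova$groupMeans),
           tukeyPairs = groupStats$pairs, qCrit = groupStats$qCrit),
    stiffnessRange = range(measured))
}
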