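## Higher-level computational experiments: stiffness extraction from test
## curves, conversion-factor calibration/validation, gap-modulus
## sensitivity and the virtual cement-swap study.

## Normalise a heterogeneous specimen list: entries are either
## list(masks, image, measured, cementType) or cohort records from
## generateCohort() (optionally taking their pre-augmentation state).
.asSpecimenSet <- function(set, usePreAugmentation = FALSE) {
  lapply(seq_along(set), function(i) {
    e <- set[[i]]
    if (!is.null(e$masks)) {
      list(id = e$id %||% sprintf("spec%02d", i), masks = e$masks,
           image = e$image, measured = e$measured %||% NA_real_,
           cementType = e$cementType %||% "PMMA")
    } else if (!is.null(e$specimen)) {
      sp <- if (usePreAugmentation && !is.null(e$preSpecimen))
        e$preSpecimen else e$specimen
      ms <- if (usePreAugmentation && !is.null(e$preMeasurement))
        e$preMeasurement else e$measurement
      list(id = e$id %||% sprintf("spec%02d", i), masks = truthMasks(sp),
           image = specimenImage(sp),
           measured = if (!is.null(ms)) stiffness(ms) else NA_real_,
           cementType = if (identical(sp@spec@cementLabel, "CaP"))
             "CaP" else "PMMA")
    } else stop("cannot interpret specimen set entry ", i)
  })
}

## Prepare one specimen's FE system split as K = Kfix + m * Kscale, where
## the scalable family is the bone grayscale map, the fracture-gap
## modulus, or the cement modulus. predictAt() then re-solves at a new
## multiplier without re-assembly.
.prepareScalable <- function(masks, image, mat, alpha,
                             cementType = "PMMA",
                             scalePart = c("bone", "gap", "cement")) {
  scalePart <- match.arg(scalePart)
  model <- buildModel(masks, image, mat, cementType = cementType,
                      alpha = alpha)
  lab <- model@labels
  if (scalePart == "bone") {
    EFixed <- model@EFixed
    w <- model@gBone
    gPos <- w[lab == .MASK_LABELS[["bone"]]]
    gMin <- if (length(gPos)) min(gPos) else Inf
  } else {
    EFixed <- elementModuli(model)
    sel <- if (scalePart == "gap") lab == .MASK_LABELS[["fracture"]] else
      lab == .MASK_LABELS[["cement"]]
    EFixed[sel] <- 0
    w <- array(0, dim(lab))
    w[sel] <- 1
    gMin <- Inf
  }
  prep <- .axialPrepare(EFixed, w, h = model@voxelMm,
                        originMm = model@originMm, pivotMm = model@pivotMm,
                        loadN = model@appliedLoadN, nu = model@nu,
                        rotationsFree = model@rotationsFree)
  list(prep = prep, model = model, scalePart = scalePart, gMin = gMin,
       floor = model@EBoneFloor)
}

## Stiffness at multiplier m of the scalable family (alpha for bone,
## modulus in MPa for gap/cement). Falls back to full re-assembly when
## the bone floor would bind.
.predictAt <- function(ps, m) {
  if (ps$scalePart == "bone" && is.finite(ps$gMin) &&
      m * ps$gMin < ps$floor) {
    E <- elementModuli(ps$model, alpha = m)
    prep <- .axialPrepare(E, NULL, h = ps$model@voxelMm,
                          originMm = ps$model@originMm,
                          pivotMm = ps$model@pivotMm,
                          loadN = ps$model@appliedLoadN, nu = ps$model@nu,
                          rotationsFree = ps$model@rotationsFree)
    return(.axialSolveAt(prep, 1, reactions = FALSE)$stiffness)
  }
  .axialSolveAt(ps$prep, m, reactions = FALSE)$stiffness
}

#' Extract stiffness from a load-displacement curve
#'
#' The measured stiffness is the largest gradient of the load-displacement
#' curve over a sliding displacement window of `windowMm` (default
#' 0.6 mm). The curve is linearly interpolated onto a uniform displacement
#' grid and the least-squares slope of load on displacement is maximised
#' over all window positions.
#'
#' @param curve data.frame or matrix whose first two columns are
#'   displacement (mm) and load (N).
#' @param windowMm window width (mm).
#' @param stepMm window step (mm); default one interpolation sample (the
#'   median displacement increment of the input curve).
#' @return stiffness in N/mm.
#' @export
stiffnessFromCurve <- function(curve, windowMm = 0.6, stepMm = NULL) {
  if (is.matrix(curve)) curve <- as.data.frame(curve)
  d <- as.numeric(curve[[1L]]); l <- as.numeric(curve[[2L]])
  o <- order(d); d <- d[o]; l <- l[o]
  keep <- !duplicated(d); d <- d[keep]; l <- l[keep]
  if (length(d) < 2L) stop("curve needs at least two distinct points")
  span <- d[length(d)] - d[1L]
  if (span < windowMm)
    stop(sprintf("curve spans %.3f mm, smaller than the %.3f mm window",
                 span, windowMm))
  step <- stepMm %||% stats::median(diff(d))
  grid <- seq(d[1L], d[length(d)], by = step)
  y <- stats::approx(d, l, grid)$y
  nw <- max(2L, round(windowMm / step) + 1L)   # points per window
  n <- length(grid)
  if (nw > n) stop("window wider than the interpolated curve")
  px <- c(0, cumsum(grid)); py <- c(0, cumsum(y))
  pxy <- c(0, cumsum(grid * y)); pxx <- c(0, cumsum(grid * grid))
  starts <- seq_len(n - nw + 1L)
  sx <- px[starts + nw] - px[starts]
  sy <- py[starts + nw] - py[starts]
  sxy <- pxy[starts + nw] - pxy[starts]
  sxx <- pxx[starts + nw] - pxx[starts]
  slopes <- (sxy - sx * sy / nw) / (sxx - sx^2 / nw)
  max(slopes)
}

#' Calibrate the grayscale-to-modulus conversion factor
#'
#' Iteratively adjusts the conversion factor until the mean error between
#' measured and model-predicted stiffness over a development set is
#' minimised. The default objective is the mean absolute percentage error
#' (golden-section search); `objective = "signed"` instead finds the root
#' of the mean signed percentage error by bisection, which exists and is
#' unique because predicted stiffness is monotone increasing in the
#' conversion factor.
#'
#' @param devSet list of development specimens: either cohort records from
#'   [generateCohort()] or `list(masks, image, measured, cementType)`
#'   entries.
#' @param objective `"mape"` (mean absolute percentage error) or
#'   `"signed"` (mean signed percentage error root).
#' @param bracket length-2 search bracket on the conversion factor; the
#'   mean signed error must change sign across it.
#' @param tolRel relative tolerance on the fitted factor.
#' @param mat a [MaterialTable] for the fixed materials.
#' @param usePreAugmentation take the pre-augmentation state of cohort
#'   records (the fractured models the calibration is defined on).
#' @return a [CalibrationResult].
#' @export
calibrateAlpha <- function(devSet, objective = c("mape", "signed"),
                           bracket = c(0.05, 5), tolRel = 1e-3,
                           mat = materialTable(),
                           usePreAugmentation = FALSE) {
  objective <- match.arg(objective)
  set <- .asSpecimenSet(devSet, usePreAugmentation)
  if (!length(set)) stop("development set is empty")
  meas <- vapply(set, `[[`, numeric(1), "measured")
  if (any(!is.finite(meas)) || any(meas <= 0))
    stop("every development specimen needs a positive measured stiffness")
  mid <- mean(bracket)
  ps <- lapply(set, function(e)
    .prepareScalable(e$masks, e$image, mat, alpha = mid,
                     cementType = e$cementType, scalePart = "bone"))
  predAll <- function(a) vapply(ps, .predictAt, numeric(1), m = a)
  trace <- new.env()
  trace$tab <- list()
  signedErr <- function(a) mean(100 * (predAll(a) - meas) / meas)
  objFun <- function(a) {
    v <- if (objective == "mape") mean(abs(100 * (predAll(a) - meas) / meas))
    else abs(signedErr(a))
    trace$tab[[length(trace$tab) + 1L]] <- c(alpha = a, objective = v)
    v
  }
  sLo <- signedErr(bracket[1L]); sHi <- signedErr(bracket[2L])
  if (!(sLo < 0 && sHi > 0))
    stop(sprintf(paste0("bracket [%g, %g] does not contain the optimum ",
                        "(mean signed errors %.1f%%, %.1f%%); widen it"),
                 bracket[1L], bracket[2L], sLo, sHi))
  if (objective == "signed") {
    root <- stats::uniroot(function(a) { v <- signedErr(a)
      trace$tab[[length(trace$tab) + 1L]] <- c(alpha = a, objective = abs(v))
      v }, bracket, tol = tolRel * mid)
    alphaHat <- root$root
  } else {
    gr <- (sqrt(5) - 1) / 2
    a <- bracket[1L]; b <- bracket[2L]
    c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
    fc <- objFun(c1); fd <- objFun(d1)
    while ((b - a) > tolRel * (a + b) / 2) {
      if (fc < fd) {
        b <- d1; d1 <- c1; fd <- fc
        c1 <- b - gr * (b - a); fc <- objFun(c1)
      } else {
        a <- c1; c1 <- d1; fc <- fd
        d1 <- a + gr * (b - a); fd <- objFun(d1)
      }
    }
    alphaHat <- (a + b) / 2
  }
  pred <- predAll(alphaHat)
  per <- data.frame(id = vapply(set, `[[`, character(1), "id"),
                    predicted = pred, measured = meas,
                    pctError = 100 * (pred - meas) / meas)
  objVal <- if (objective == "mape") mean(abs(per$pctError)) else
    abs(mean(per$pctError))
  tr <- as.data.frame(do.call(rbind, trace$tab))
  new("CalibrationResult", alphaHat = alphaHat, objective = objective,
      objectiveValue = objVal, perSpecimen = per, trace = tr)
}

#' @rdname stiffness
setMethod("stiffness", "CalibrationResult", function(x) x@alphaHat)

#' @describeIn calibrateAlpha fitted conversion factor accessor.
#' @param x a [CalibrationResult].
#' @export
alphaHat <- function(x) x@alphaHat

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(paste0("CalibrationResult: alphaHat %.4f MPa/a.u. (%s = ",
                     "%.3f%% over %d specimens, %d evaluations)\n"),
              object@alphaHat, object@objective, object@objectiveValue,
              nrow(object@perSpecimen), nrow(object@trace)))
})

#' Validate a fitted conversion factor on held-out specimens
#'
#' Applies the fitted factor to a validation set, computes per-specimen
#' percentage errors `100 (pred - meas) / meas`, their mean absolute
#' value, Lin's concordance between measured and predicted stiffness, and
#' the Bland-Altman agreement (experimental minus finite-element).
#'
#' @param valSet validation specimens (as in [calibrateAlpha()]).
#' @param alphaHat fitted conversion factor (MPa per grayscale unit).
#' @param mat a [MaterialTable].
#' @param usePreAugmentation as in [calibrateAlpha()].
#' @return list with `perSpecimen` (data.frame), `meanAbsPctError`,
#'   `ccc`, `blandAltman`.
#' @export
validateAlpha <- function(valSet, alphaHat, mat = materialTable(),
                          usePreAugmentation = FALSE) {
  stopifnot(alphaHat > 0)
  set <- .asSpecimenSet(valSet, usePreAugmentation)
  pred <- vapply(set, function(e)
    specimenStiffness(e$masks, e$image, mat, cementType = e$cementType,
                      alpha = alphaHat), numeric(1))
  meas <- vapply(set, `[[`, numeric(1), "measured")
  per <- data.frame(id = vapply(set, `[[`, character(1), "id"),
                    predicted = pred, measured = meas,
                    pctError = 100 * (pred - meas) / meas)
  list(perSpecimen = per, meanAbsPctError = mean(abs(per$pctError)),
       ccc = linCCC(meas, pred), blandAltman = blandAltman(meas, pred))
}

#' Fracture-gap modulus sensitivity study
#'
#' Solves one specimen over a strictly descending sequence of gap moduli.
#' The plateau is the first modulus at which the stiffness change from
#' the previous (larger) value falls below `undetectableTolRel`; the
#' recommended working value is three orders of magnitude below the
#' plateau, so that more severe fracture patterns remain unaffected.
#'
#' @param specimen one specimen (cohort record or `list(masks, image, ...)`).
#' @param eGapGPa strictly descending gap moduli (GPa), at least three.
#' @param mat a [MaterialTable].
#' @param alpha conversion factor for the bone; defaults to `mat@alpha`.
#' @param undetectableTolRel relative stiffness-change tolerance defining
#'   "undetectable".
#' @param usePreAugmentation as in [calibrateAlpha()].
#' @return a [SensitivityTable].
#' @export
gapSensitivity <- function(specimen, eGapGPa = 10^seq(-3, -9, by = -1),
                           mat = materialTable(), alpha = NULL,
                           undetectableTolRel = 1e-3,
                           usePreAugmentation = FALSE) {
  if (length(eGapGPa) < 3L || any(diff(eGapGPa) >= 0))
    stop("eGapGPa must be a strictly descending sequence of length >= 3")
  e <- .asSpecimenSet(list(specimen), usePreAugmentation)[[1L]]
  alpha <- alpha %||% mat@alpha
  ps <- .prepareScalable(e$masks, e$image, mat, alpha = alpha,
                         cementType = e$cementType, scalePart = "gap")
  k <- vapply(eGapGPa, function(eg) .predictAt(ps, eg * 1000), numeric(1))
  change <- abs(diff(k)) / k[-length(k)]
  hit <- which(change < undetectableTolRel)
  if (!length(hit))
    stop("no plateau found over the sequence: ",
         paste(signif(eGapGPa, 3), collapse = ", "))
  plateau <- eGapGPa[hit[1L] + 1L]
  new("SensitivityTable",
      table = data.frame(eGapGPa = eGapGPa, stiffnessNPerMm = k),
      plateauEGapGPa = plateau, recommendedEGapGPa = plateau / 1000)
}

setMethod("show", "SensitivityTable", function(object) {
  cat(sprintf(paste0("SensitivityTable: plateau at E_gap = %.3g GPa, ",
                     "recommended %.3g GPa (%d solves)\n"),
              object@plateauEGapGPa, object@recommendedEGapGPa,
              nrow(object@table)))
})

#' Virtual cement-swap augmentation study
#'
#' For every augmented specimen, the cement region is assigned the PMMA
#' modulus and then the CaP modulus and the model re-solved; the fractured
#' baseline reassigns the cement region to the fracture-gap modulus, so
#' the stiffness gain isolates the cement's contribution on identical
#' geometry. The gains are correlated (Pearson, two-tailed) with the
#' percentage fracture fill computed from the masks (cement volume over
#' cement-plus-residual-fracture volume).
#'
#' @param specimens augmented specimens (cohort records or
#'   `list(masks, image, ...)` entries).
#' @param mat a [MaterialTable].
#' @param alpha conversion factor; defaults to `mat@alpha`.
#' @return an [AugmentationStudyResult].
#' @export
virtualAugmentation <- function(specimens, mat = materialTable(),
                                alpha = NULL) {
  alpha <- alpha %||% mat@alpha
  set <- .asSpecimenSet(specimens)
  rows <- list()
  for (e in set) {
    cemVox <- sum(specimenMask(e$masks, "cement"))
    fracVox <- sum(specimenMask(e$masks, "fracture"))
    if (cemVox + fracVox == 0L) {
      warning(sprintf("specimen %s has no fracture void; skipped", e$id))
      next
    }
    ps <- .prepareScalable(e$masks, e$image, mat, alpha = alpha,
                           cementType = e$cementType, scalePart = "cement")
    kPMMA <- .predictAt(ps, mat@ECementPMMA)
    kCaP <- .predictAt(ps, mat@ECementCaP)
    kFrac <- .predictAt(ps, mat@EGap)
    rows[[length(rows) + 1L]] <- data.frame(
      id = e$id, percentFill = 100 * cemVox / (cemVox + fracVox),
      stiffnessFractured = kFrac, stiffnessPMMAModulus = kPMMA,
      stiffnessCaPModulus = kCaP, gainPMMA = kPMMA - kFrac,
      gainCaP = kCaP - kFrac)
  }
  if (!length(rows)) stop("no usable augmented specimens")
  per <- do.call(rbind, rows)
  corRow <- function(cement, gain) {
    ok <- nrow(per) >= 3L && stats::var(per$percentFill) > 0 &&
      stats::var(gain) > 0
    if (ok) {
      pc <- pearsonCor(per$percentFill, gain)
      data.frame(cement = cement, r = pc$r, p = pc$p, n = pc$n)
    } else data.frame(cement = cement, r = NA_real_, p = NA_real_,
                      n = nrow(per))
  }
  new("AugmentationStudyResult", perSpecimen = per,
      correlations = rbind(corRow("PMMA", per$gainPMMA),
                           corRow("CaP", per$gainCaP)))
}

setMethod("show", "AugmentationStudyResult", function(object) {
  cat(sprintf("AugmentationStudyResult: %d specimens\n",
              nrow(object@perSpecimen)))
  print(object@correlations, row.names = FALSE)
})
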