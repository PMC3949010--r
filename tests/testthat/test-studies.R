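test_that("windowed gradient extraction recovers known curve slopes", {
  d <- seq(0, 2, by = 0.01)
  expect_equal(stiffnessFromCurve(data.frame(d, 2500 * d)), 2500,
               tolerance = 1e-9)
  ## quadratic toe (0-0.5 mm) then linear slope 3000 N/mm
  toe <- 0.5; k <- 3000
  load <- ifelse(d <= toe, k * d^2 / (2 * toe), k * toe / 2 + k * (d - toe))
  curve <- data.frame(displacement_mm = d, load_N = load)
  est <- stiffnessFromCurve(curve, windowMm = 0.6)
  ## brute-force oracle: least-squares slope over every 0.6 mm window of
  ## the raw samples
  bf <- max(vapply(which(d <= max(d) - 0.6), function(i) {
    sel <- d >= d[i] & d <= d[i] + 0.6 + 1e-12
    unname(stats::coef(stats::lm(load[sel] ~ d[sel]))[2])
  }, numeric(1)))
  expect_equal(est, bf, tolerance = 1e-6)
  expect_equal(est, k, tolerance = 1e-6)
  short <- curve[curve$displacement_mm <= 0.4, ]
  expect_error(stiffnessFromCurve(short), "smaller than")
})

test_that("calibration recovers the generating conversion factor at zero noise", {
  coh <- generateCohort(0, 3, 0, 0, baseSpec = tinySpec(), seed = 14L,
                        alphaTrue = 0.5, noiseSdRel = 0)
  cal <- calibrateAlpha(coh, objective = "mape")
  expect_lt(abs(alphaHat(cal) - 0.5) / 0.5, 0.005)
  expect_true(all(diff(range(cal@trace$alpha)) > 0))
  ## single noiseless specimen: essentially exact fit
  cal1 <- calibrateAlpha(coh[1], objective = "signed", tolRel = 1e-5)
  expect_lt(max(abs(cal1@perSpecimen$pctError)), 0.1)
  ## the signed-error mode agrees with the MAPE mode here
  cal2 <- calibrateAlpha(coh, objective = "signed")
  expect_lt(abs(alphaHat(cal2) - alphaHat(cal)) / alphaHat(cal), 0.01)
})

test_that("calibration objective is unimodal along the recorded trace", {
  coh <- generateCohort(0, 3, 0, 0, baseSpec = tinySpec(), seed = 15L,
                        alphaTrue = 0.5, noiseSdRel = 0.05)
  cal <- calibrateAlpha(coh, objective = "mape")
  tr <- cal@trace[order(cal@trace$alpha), ]
  ## objective decreases towards alphaHat and increases after it
  below <- tr$objective[tr$alpha <= alphaHat(cal)]
  above <- tr$objective[tr$alpha >= alphaHat(cal)]
  expect_true(all(diff(below) <= 1e-8))
  expect_true(all(diff(above) >= -1e-8))
})

test_that("an unattainable bracket is rejected with advice", {
  coh <- generateCohort(0, 2, 0, 0, baseSpec = tinySpec(), seed = 16L,
                        alphaTrue = 0.5, noiseSdRel = 0)
  expect_error(calibrateAlpha(coh, bracket = c(2, 5)), "widen")
})

test_that("in-sample noiseless validation is near-perfect", {
  coh <- generateCohort(0, 3, 0, 0, baseSpec = tinySpec(), seed = 17L,
                        alphaTrue = 0.5, noiseSdRel = 0)
  val <- validateAlpha(coh, alphaHat = 0.5)
  expect_lt(val$meanAbsPctError, 0.2)
  expect_gt(val$ccc, 0.99)
  expect_lt(abs(val$blandAltman$meanDiff),
            0.01 * mean(val$perSpecimen$measured))
})

test_that("gap modulus set to the bone modulus reproduces the intact model", {
  ## uniform bone grayscale; assigning the crack the same modulus as the
  ## surrounding bone must erase it
  base <- tinySpec(boneGraySd = 0, seed = 21L)
  crack <- midCrack(base, tilt = c(0, 0))
  phFrac <- generatePhantom(tinySpec(boneGraySd = 0,
                                     fracturePlanes = crack, seed = 21L))
  phIntact <- generatePhantom(base)
  alpha <- 0.5
  eBone <- alpha * base@boneGrayMean                       # MPa
  matSame <- materialTable(alpha = alpha, EGapGPa = eBone / 1000)
  kFrac <- specimenStiffness(truthMasks(phFrac), specimenImage(phFrac),
                             matSame, alpha = alpha)
  kIntact <- specimenStiffness(truthMasks(phIntact),
                               specimenImage(phIntact), alpha = alpha)
  expect_equal(kFrac, kIntact, tolerance = 1e-8)
})

test_that("stiffness decreases monotonically as the gap softens to a plateau", {
  spec <- tinySpec(fracturePlanes = midCrack(tinySpec()), seed = 22L)
  ph <- generatePhantom(spec)
  entry <- list(masks = truthMasks(ph), image = specimenImage(ph))
  sens <- gapSensitivity(entry, eGapGPa = 10^seq(-1, -9, by = -1),
                         alpha = 0.5)
  k <- sens@table$stiffnessNPerMm
  expect_true(all(diff(k) <= 1e-9 * k[-length(k)]))
  expect_equal(sens@recommendedEGapGPa, sens@plateauEGapGPa / 1000)
  expect_error(gapSensitivity(entry, eGapGPa = c(1e-3, 1e-2, 1e-1)),
               "descending")
  expect_error(gapSensitivity(entry, eGapGPa = c(1, 0.9, 0.8),
                              undetectableTolRel = 1e-12), "plateau")
})

test_that("virtual augmentation honours cement-modulus monotonicity", {
  coh <- generateCohort(0, 0, 2, 2, baseSpec = tinySpec(), seed = 23L,
                        simulateMeasurements = FALSE)
  res <- virtualAugmentation(coh, alpha = 0.5)
  ps <- res@perSpecimen
  expect_identical(nrow(ps), 4L)
  expect_true(all(ps$stiffnessPMMAModulus >= ps$stiffnessCaPModulus))
  expect_true(all(ps$gainPMMA >= ps$gainCaP))
  expect_true(all(ps$gainCaP >= -1e-6 * ps$stiffnessFractured))
})

test_that("a zero-fill specimen gains nothing from the cement swap", {
  spec <- tinySpec(fracturePlanes = midCrack(tinySpec()), seed = 24L)
  ph <- generatePhantom(spec)                 # fractured, no cement
  res <- virtualAugmentation(list(list(masks = truthMasks(ph),
                                       image = specimenImage(ph))),
                             alpha = 0.5)
  ps <- res@perSpecimen
  expect_identical(ps$percentFill, 0)
  expect_equal(ps$stiffnessPMMAModulus, ps$stiffnessFractured,
               tolerance = 1e-9)
  expect_equal(ps$stiffnessCaPModulus, ps$stiffnessFractured,
               tolerance = 1e-9)
})

test_that("stiffness gain rises with percent fill across a graded series", {
  base <- tinySpec()
  crack <- midCrack(base, radiusMm = 0.75 * base@bodyRadiusMm)
  entries <- lapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(f) {
    ph <- generatePhantom(tinySpec(fracturePlanes = crack,
                                   cementLabel = "PMMA", fillFraction = f,
                                   seed = 31L))
    list(masks = truthMasks(ph), image = specimenImage(ph))
  })
  res <- virtualAugmentation(entries, alpha = 0.5)
  ps <- res@perSpecimen
  expect_true(all(diff(ps$percentFill) > 0))
  expect_true(all(diff(ps$gainPMMA) > 0))
  cors <- res@correlations
  expect_true(all(cors$r > 0))
  expect_lt(cors$p[cors$cement == "PMMA"], 0.05)
})

test_that("specimens without any void are skipped with a warning", {
  ph <- generatePhantom(tinySpec(seed = 25L))    # intact
  entryIntact <- list(masks = truthMasks(ph), image = specimenImage(ph))
  expect_warning(expect_error(virtualAugmentation(list(entryIntact)),
                              "no usable"), "skipped")
})
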