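test_that("an intact spec yields no fracture and a full-fill spec no residual void", {
  ph <- generatePhantom(smallSpec(seed = 2L))
  expect_identical(ph@truthFractureVolumeMm3, 0)
  expect_false(any(specimenMask(truthMasks(ph), "fracture")))

  crack <- midCrack(smallSpec())
  phOpen <- generatePhantom(smallSpec(fracturePlanes = crack, seed = 2L))
  phFull <- generatePhantom(smallSpec(fracturePlanes = crack, seed = 2L,
                                      cementLabel = "PMMA",
                                      fillFraction = 1))
  ## full fill: cement occupies the open phantom's void voxel-for-voxel
  expect_identical(specimenMask(truthMasks(phFull), "cement"),
                   specimenMask(truthMasks(phOpen), "fracture"))
  expect_false(any(specimenMask(truthMasks(phFull), "fracture")))
})

test_that("phantom generation is deterministic in the seed", {
  spec <- smallSpec(fracturePlanes = midCrack(smallSpec()), seed = 31L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(imageData(specimenImage(a)), imageData(specimenImage(b)))
  expect_identical(maskLabels(truthMasks(a)), maskLabels(truthMasks(b)))
  spec2 <- spec; spec2@seed <- 32L
  c <- generatePhantom(spec2)
  expect_false(identical(imageData(specimenImage(a)),
                         imageData(specimenImage(c))))
})

test_that("truth masks partition the grid and cement stays inside the void", {
  spec <- smallSpec(fracturePlanes = midCrack(smallSpec()),
                    cementLabel = "CaP", fillFraction = 0.36, seed = 12L)
  ph <- generatePhantom(spec)
  tm <- truthMasks(ph)
  comps <- c("bone", "fracture", "cement", "cap_lower", "cap_upper",
             "marker")
  tot <- Reduce(`+`, lapply(comps, function(cp) specimenMask(tm, cp)))
  expect_true(all(tot <= 1))                       # disjoint by construction
  ## cement + residual fracture = the pre-fill void
  voidVox <- ph@truthFractureVolumeMm3 / spec@voxelMm^3
  expect_equal(sum(specimenMask(tm, "cement")) +
                 sum(specimenMask(tm, "fracture")), voidVox)
  ## fill quantisation within one voxel of the requested fraction
  expect_lte(abs(sum(specimenMask(tm, "cement")) -
                   spec@fillFraction * voidVox), 1)
  ## grayscale plateaus sit where the masks say
  g <- imageData(specimenImage(ph))
  expect_true(all(g[specimenMask(tm, "cement")] == spec@cementGray))
  expect_true(all(g[specimenMask(tm, "fracture")] == 0))
  expect_true(all(g[specimenMask(tm, "bone")] >= spec@grayFloor))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(smallSpec(bodyRadiusMm = 20), "fit")
  expect_error(smallSpec(capThicknessMm = 15), "grid height")
  expect_error(smallSpec(fillFraction = 1.3), "fillFraction")
  expect_error(generatePhantom(smallSpec(cementLabel = "PMMA",
                                         fillFraction = 0.5)),
               "no fracture")
})

test_that("simulated measurements are exact at zero noise and seeded", {
  spec <- tinySpec(fracturePlanes = midCrack(tinySpec()), seed = 5L)
  ph <- generatePhantom(spec)
  m0 <- simulateMeasurement(ph, alphaTrue = 0.5, noiseSdRel = 0, seed = 1L)
  expect_identical(stiffness(m0), m0@feStiffnessNPerMm)
  m1 <- simulateMeasurement(ph, alphaTrue = 0.5, noiseSdRel = 0.05,
                            seed = 9L, feStiffnessNPerMm = m0@feStiffnessNPerMm)
  m2 <- simulateMeasurement(ph, alphaTrue = 0.5, noiseSdRel = 0.05,
                            seed = 9L, feStiffnessNPerMm = m0@feStiffnessNPerMm)
  expect_identical(stiffness(m1), stiffness(m2))
  expect_false(identical(stiffness(m1), stiffness(m0)))
  ## synthetic curve: monotone, toe then linear, max gradient = stiffness
  expect_false(is.unsorted(m0@curve$load_N))
  expect_equal(stiffnessFromCurve(m0@curve), stiffness(m0),
               tolerance = 1e-6)
})

test_that("Monte-Carlo mean of noisy measurements matches the FE value", {
  spec <- tinySpec(fracturePlanes = midCrack(tinySpec()), seed = 6L)
  ph <- generatePhantom(spec)
  m0 <- simulateMeasurement(ph, alphaTrue = 0.5, noiseSdRel = 0, seed = 1L)
  fe <- m0@feStiffnessNPerMm
  draws <- vapply(1:200, function(s)
    stiffness(simulateMeasurement(ph, 0.5, noiseSdRel = 0.05, seed = s,
                                  curve = FALSE, feStiffnessNPerMm = fe)),
    numeric(1))
  expect_lt(abs(mean(draws) - fe) / fe, 0.01)
})

test_that("cohorts have the requested composition", {
  expect_identical(generateCohort(0, 0, 0, 0, baseSpec = tinySpec()),
                   list())
  coh <- generateCohort(1, 5, 6, 6, baseSpec = smallSpec(), seed = 2L,
                        simulateMeasurements = FALSE)
  expect_length(coh, 18L)
  arms <- vapply(coh, `[[`, character(1), "arm")
  expect_identical(as.integer(table(arms)[c("intact", "fractured", "PMMA",
                                            "CaP")]), c(1L, 5L, 6L, 6L))
  hasCem <- vapply(coh, function(e)
    any(specimenMask(truthMasks(e$specimen), "cement")), logical(1))
  expect_identical(sum(hasCem), 12L)
  ## augmented records carry a cement-free pre-augmentation twin of the
  ## same geometry and grayscale field
  aug <- coh[arms %in% c("PMMA", "CaP")]
  expect_true(all(vapply(aug, function(e) !is.null(e$preSpecimen),
                         logical(1))))
  e <- aug[[1L]]
  preBone <- specimenMask(truthMasks(e$preSpecimen), "bone")
  postAll <- specimenMask(truthMasks(e$specimen), "bone")
  expect_identical(preBone, postAll)
  gPre <- imageData(specimenImage(e$preSpecimen))
  gPost <- imageData(specimenImage(e$specimen))
  expect_identical(gPre[preBone], gPost[preBone])
})

test_that("cohort fill fractions draw around the PMMA/CaP study targets", {
  coh <- generateCohort(0, 0, 12, 12, baseSpec = smallSpec(), seed = 77L,
                        simulateMeasurements = FALSE)
  arms <- vapply(coh, `[[`, character(1), "arm")
  fills <- vapply(coh, `[[`, numeric(1), "targetFillFraction")
  ## sample means within 3 SE of the 0.53 / 0.36 targets
  expect_lt(abs(mean(fills[arms == "PMMA"]) - 0.53),
            3 * 0.055 / sqrt(12))
  expect_lt(abs(mean(fills[arms == "CaP"]) - 0.36),
            3 * 0.125 / sqrt(12))
  expect_true(all(fills >= 0.05 & fills <= 0.95))
})
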