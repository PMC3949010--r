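test_that("downsampling preserves constants and computes block means", {
  img <- VoxelImage(array(7.5, c(4, 4, 4)), 0.5)
  out <- downsampleImage(img, 1)
  expect_equal(dim(imageData(out)), c(2L, 2L, 2L))
  expect_true(all(abs(imageData(out) - 7.5) < 1e-12))

  a <- withSeed(5L, array(stats::runif(64), c(4, 4, 4)))
  out2 <- downsampleImage(VoxelImage(a, 1), 2)
  ## independent oracle: aggregate means over the 2x2x2 blocks directly
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    expect_equal(imageData(out2)[i, j, k],
                 mean(a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                        (2 * k - 1):(2 * k)]), tolerance = 1e-12)
  ## volume-weighted global mean is conserved
  expect_equal(mean(imageData(out2)), mean(a), tolerance = 1e-10)
  expect_error(downsampleImage(VoxelImage(a, 1), 0.5), ">=")
})

test_that("downsampling composes: factor 2 then 2 equals factor 4", {
  a <- withSeed(6L, array(stats::runif(8^3), c(8, 8, 8)))
  img <- VoxelImage(a, 1)
  twice <- downsampleImage(downsampleImage(img, 2), 4)
  once <- downsampleImage(img, 4)
  expect_equal(imageData(twice), imageData(once), tolerance = 1e-8)
})

test_that("downsampling handles non-integer ratios by fractional overlap", {
  ## 3 voxels of size 1 -> 2 voxels of size 1.5:
  ## out1 = (v1 + 0.5 v2)/1.5, out2 = (0.5 v2 + v3)/1.5
  a <- array(0, c(3, 1, 1)); a[, 1, 1] <- c(3, 6, 12)
  out <- downsampleImage(VoxelImage(a, 1), c(1.5, 1, 1))
  expect_equal(as.numeric(imageData(out)), c((3 + 3) / 1.5, (3 + 12) / 1.5))
})

test_that("threshold segmentation windows behave as half-open intervals", {
  img <- VoxelImage(array(100, c(3, 3, 3)), 1)
  expect_true(all(segmentThreshold(img, 50, 150)))
  expect_false(any(segmentThreshold(img, 150, 200)))
  expect_false(any(segmentThreshold(img, 100 + 1e-9, 200)))
  expect_true(all(segmentThreshold(img, 100)))          # hi defaults to Inf
  expect_error(segmentThreshold(img, 10, 5), "lo")
})

test_that("segmentation recovers the phantom's truth masks exactly", {
  spec <- smallSpec(fracturePlanes = midCrack(smallSpec()),
                    cementLabel = "PMMA", fillFraction = 0.5, seed = 4L)
  ph <- generatePhantom(spec)
  segm <- suppressMessages(
    segmentSpecimen(specimenImage(ph), segmentationWindows(spec)))
  tm <- truthMasks(ph)
  for (comp in c("bone", "cement", "cap_lower", "cap_upper", "marker",
                 "fracture"))
    expect_identical(specimenMask(segm, comp), specimenMask(tm, comp),
                     label = comp)
})

test_that("shift-based morphology matches the brute-force definition", {
  for (kern in c(2L, 3L)) {
    off <- seq_len(kern) - 1L - ((kern - 1L) %/% 2L)
    for (s in 1:3) {
      m <- withSeed(40L + s, array(stats::runif(7^3) < 0.35, c(7, 7, 7)))
      expect_identical(dilateMask(m, kern), bruteDilate(m, off))
      expect_identical(erodeMask(m, kern), bruteErode(m, off))
      expect_identical(closeMask(m, kern), bruteClose(m, kern))
    }
  }
})

test_that("fracture extraction recovers a one-voxel slit exactly", {
  dm <- c(8L, 8L, 9L)
  bone <- array(TRUE, dm)
  bone[, , 5] <- FALSE                       # 1-voxel planar slit
  frac <- extractFractureMask(bone, kernelPx = 2L)
  slit <- array(FALSE, dm); slit[, , 5] <- TRUE
  expect_identical(frac, slit)
  ## matches the brute-force morphological oracle
  expect_identical(frac, bruteClose(bone, 2L) & !bone)
  ## closing of a solid block is itself
  expect_false(any(extractFractureMask(array(TRUE, dm), 2L)))
})

test_that("gaps thicker than the kernel closes are flagged and omitted", {
  dm <- c(8L, 8L, 10L)
  bone <- array(TRUE, dm)
  bone[2:7, 2:7, 5:6] <- FALSE               # interior 2-voxel-thick gap
  roi <- array(TRUE, dm)
  expect_message(frac <- extractFractureMask(bone, 2L, bodyROI = roi),
                 "uncaptured")
  expect_identical(frac, bruteClose(bone, 2L) & !bone)
  ## the un-closable core is omitted from the mask
  expect_false(all(frac[2:7, 2:7, 5:6]))
  ## kernel 3 closes the 2-voxel gap completely, and nothing is flagged
  expect_message(frac3 <- extractFractureMask(bone, 3L, bodyROI = roi), NA)
  expect_true(all(frac3[2:7, 2:7, 5:6]))
})

test_that("fracture mask is always disjoint from bone and small components drop", {
  for (s in 1:3) {
    bone <- withSeed(60L + s, array(stats::runif(8^3) < 0.5, c(8, 8, 8)))
    frac <- suppressMessages(extractFractureMask(bone, 2L))
    expect_false(any(frac & bone))
  }
  bone <- array(TRUE, c(8, 8, 9)); bone[, , 5] <- FALSE
  expect_message(
    frac <- extractFractureMask(bone, 2L, minComponentVox = 100L),
    "removed")
  expect_false(any(frac))
})

test_that("mask volumes and percent fill follow their closed forms", {
  m <- array(FALSE, c(5, 5, 5))
  expect_identical(maskVolume(m, 1), 0)
  m[1:10] <- TRUE
  expect_identical(maskVolume(m, 1), 10)
  expect_equal(maskVolume(m, c(1, 2, 0.5)), 10)
  expect_identical(percentFill(10, 10), 100)
  expect_identical(percentFill(5, 10), 50)
  expect_equal(percentFill(5, 10), percentFill(5 * 3.2, 10 * 3.2))
  expect_error(percentFill(5, 0), "positive")
  expect_warning(p <- percentFill(12, 10), "100")
  expect_identical(p, 100)
})

test_that("fracture scoring counts cells as specified", {
  dm <- c(8L, 8L, 6L)
  bone <- array(TRUE, dm)
  none <- array(FALSE, dm)
  s0 <- fractureScore(none, bone, gridCells = c(4, 4), nSlices = 3,
                      includeThreshold = 0.1)
  expect_identical(s0@normalizedScore, 0)
  expect_false(s0@included)
  s2 <- fractureScore(bone, bone, gridCells = c(4, 4), nSlices = 3)
  expect_identical(s2@normalizedScore, 1)
  expect_true(s2@included)
  ## half the 16 cells fully fractured on every slice -> 8*2/(2*16) = 0.5
  half <- array(FALSE, dm); half[1:4, , ] <- TRUE
  sh <- fractureScore(half, bone, gridCells = c(4, 4), nSlices = 3)
  expect_identical(sh@normalizedScore, 0.5)
  expect_error(fractureScore(none, none, nSlices = 3), "no bone")
})

test_that("marker localisation returns physical centroids", {
  m <- array(FALSE, c(9, 9, 9))
  m[3, 5, 7] <- TRUE
  expect_equal(locateMarker(m, 2), c(2 * 2.5, 2 * 4.5, 2 * 6.5))
  ## digitised sphere: centroid within half a voxel of the true centre
  ctr <- c(4.7, 5.2, 4.9)
  cc <- expand.grid(x = 1:9 - 0.5, y = 1:9 - 0.5, z = 1:9 - 0.5)
  sph <- array(colSums((t(as.matrix(cc)) - ctr)^2) <= 2.5^2, c(9, 9, 9))
  expect_lt(max(abs(locateMarker(sph, 1) - ctr)), 0.5)
  expect_error(locateMarker(array(FALSE, c(3, 3, 3)), 1), "empty")
})

test_that("body region fills interior cavities", {
  bone <- array(FALSE, c(9, 9, 9))
  bone[2:8, 2:8, 2:8] <- TRUE
  bone[4:6, 4:6, 4:6] <- FALSE             # internal cavity
  roi <- bodyRegion(bone, closePx = 3L)
  expect_true(all(roi[4:6, 4:6, 4:6]))
})
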