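test_that("one-way ANOVA reproduces the hand-worked three-group example", {
  ## groups {1,2,3},{2,3,4},{3,4,5}: SSB = 6, SSW = 6, F = (6/2)/(6/6) = 3
  an <- oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(an$F, 3)
  expect_identical(c(an$dfBetween, an$dfWithin), c(2L, 6L))
  expect_equal(an$p, stats::pf(3, 2, 6, lower.tail = FALSE))
})

test_that("ANOVA agrees with aov and is affine-invariant", {
  groups <- withSeed(9L, lapply(c(5, 7, 6), function(n) stats::rnorm(n)))
  an <- oneWayAnova(groups)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(seq_along(groups), lengths(groups))))
  ref <- anova(stats::aov(y ~ g, df))
  expect_equal(an$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(an$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
  shifted <- lapply(groups, function(g) 4.2 + 3 * g)
  expect_equal(oneWayAnova(shifted)$F, an$F, tolerance = 1e-10)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  x <- withSeed(3L, stats::rnorm(8)); y <- withSeed(4L, stats::rnorm(6, 1))
  an <- oneWayAnova(list(x, y))
  tt <- tTestUnpaired(x, y)
  expect_equal(an$F, tt$t^2, tolerance = 1e-12)
  expect_equal(an$p, tt$p, tolerance = 1e-12)
})

test_that("degenerate ANOVA inputs are flagged", {
  expect_warning(an <- oneWayAnova(list(c(1, 1), c(2, 2))), "infinite")
  expect_identical(an$F, Inf)
  expect_identical(an$p, 0)
  expect_error(oneWayAnova(list(c(1, 1), c(1, 1))), "zero")
  expect_error(oneWayAnova(list(1, c(1, 2))), "two observations")
})

test_that("studentized-range critical value matches published tables", {
  ## q(k = 3, df = 10, alpha = 0.05) = 3.877 in standard tables
  expect_lt(abs(stats::qtukey(0.95, 3, 10) - 3.877), 0.01)
  tk <- tukeyKramer(list(c(1, 2, 3), c(2, 3, 4), c(10, 11, 12)),
                    alpha = 0.05)
  expect_equal(tk$qCrit, stats::qtukey(0.95, 3, 6), tolerance = 1e-12)
})

test_that("identical groups yield no significant Tukey-Kramer pairs", {
  g <- withSeed(10L, stats::rnorm(6))
  tk <- tukeyKramer(list(g + stats::rnorm(6, 0, 1e-6), g, g + 1e-6))
  expect_false(any(tk$pairs$significant))
})

test_that("balanced Tukey-Kramer reduces to classical Tukey HSD", {
  groups <- withSeed(11L, lapply(1:4, function(i) stats::rnorm(6, i / 2)))
  tk <- tukeyKramer(groups, alpha = 0.05)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(seq_along(groups), each = 6)))
  hsd <- stats::TukeyHSD(stats::aov(y ~ g, df))$g
  ## same pairwise p values (HSD rows are ordered j > i pairs)
  key <- paste(tk$pairs$j, tk$pairs$i, sep = "-")
  expect_equal(unname(hsd[key, "p adj"]), tk$pairs$p, tolerance = 1e-8)
})

test_that("Tukey-Kramer with two groups matches the pooled t decision", {
  for (s in 1:5) {
    g <- withSeed(500L + s, list(stats::rnorm(5), stats::rnorm(7, 0.8)))
    tk <- tukeyKramer(g, alpha = 0.05)
    tt <- tTestUnpaired(g[[1]], g[[2]])
    expect_equal(tk$pairs$q, abs(tt$t) * sqrt(2), tolerance = 1e-10)
    expect_identical(tk$pairs$significant, tt$p < 0.05)
  }
})

test_that("pooled t test reproduces the worked example and degenerate cases", {
  tt <- tTestUnpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-12)   # -3.674
  expect_identical(tt$df, 4L)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
  same <- c(2, 2, 2)
  expect_identical(tTestUnpaired(same, same)$p, 1)
  expect_warning(tz <- tTestUnpaired(c(1, 1), c(2, 2)), "infinite")
  expect_identical(tz$p, 0)
})

test_that("Pearson correlation matches its direct-formula oracle", {
  expect_equal(pearsonCor(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearsonCor(1:5, -(1:5))$r, -1)
  pc <- pearsonCor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(pc$r, 0.8, tolerance = 1e-12)
  expect_equal(pc$t, 0.8 * sqrt(3 / (1 - 0.64)), tolerance = 1e-12) # 2.309
  ref <- stats::cor.test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(pc$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearsonCor(c(1, 1, 1), 1:3), "variance")
})

test_that("Lin's concordance follows the 1/n-moment formula", {
  x <- c(1, 3, 5, 7)
  expect_equal(linCCC(x, x), 1)
  y <- c(2, -1, 1, -2)
  expect_equal(linCCC(y, -y), -1)          # zero means, s_xy = -s_x^2
  ## direct evaluation with biased moments: 2*1.625/(1.25+2.1875+0.0625)
  expect_equal(linCCC(c(1, 2, 3, 4), c(1, 2, 3, 5)), 3.25 / 3.5,
               tolerance = 1e-12)
  expect_error(linCCC(c(2, 2), c(3, 3)), "constant")
  ## random vectors against an inline oracle
  for (s in 1:5) {
    v <- withSeed(700L + s, list(stats::rnorm(9), stats::rnorm(9, 1, 2)))
    mx <- mean(v[[1]]); my <- mean(v[[2]])
    oracle <- 2 * mean((v[[1]] - mx) * (v[[2]] - my)) /
      (mean((v[[1]] - mx)^2) + mean((v[[2]] - my)^2) + (mx - my)^2)
    expect_equal(linCCC(v[[1]], v[[2]]), oracle, tolerance = 1e-12)
  }
})

test_that("concordance is attenuated relative to Pearson and symmetric", {
  worst <- 0
  for (s in 1:1000) {
    v <- withSeed(2000L + s, list(stats::rnorm(8), stats::rnorm(8, 1, 2)))
    ccc <- linCCC(v[[1]], v[[2]])
    r <- stats::cor(v[[1]], v[[2]])
    expect_lte(abs(ccc), abs(r) + 1e-12)
    expect_equal(ccc, linCCC(v[[2]], v[[1]]), tolerance = 1e-12)
    worst <- max(worst, abs(ccc) - abs(r))
  }
  expect_lte(worst, 1e-12)
})

test_that("Bland-Altman limits follow mean +/- 1.96 sample SD", {
  x <- c(3, 4, 5)
  ba0 <- blandAltman(x, x)
  expect_identical(ba0$meanDiff, 0)
  expect_identical(ba0$sdDiff, 0)
  expect_identical(c(ba0$loaLow, ba0$loaHigh), c(0, 0))
  ba1 <- blandAltman(x, x - 5)
  expect_identical(ba1$meanDiff, 5)
  expect_identical(ba1$sdDiff, 0)
  ## direct-formula oracle: d = (-1, 1, -1), mean -1/3, sd 2/sqrt(3)
  ba <- blandAltman(c(10, 12, 14), c(11, 11, 15))
  expect_equal(ba$meanDiff, -1 / 3, tolerance = 1e-12)
  expect_equal(ba$sdDiff, stats::sd(c(-1, 1, -1)), tolerance = 1e-12)
  expect_equal(ba$loaHigh - ba$loaLow, 2 * 1.96 * ba$sdDiff)
  expect_equal(ba$table$mean, c(10.5, 11.5, 14.5))
  expect_error(blandAltman(1:3, 1:4), "equal length")
})

test_that("p values live in [0,1] and decrease in the statistic magnitude", {
  x <- c(1, 2, 3, 4)
  ps <- vapply(c(0.5, 1, 2, 4), function(d)
    tTestUnpaired(x, x + d)$p, numeric(1))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(all(diff(ps) < 0))
})
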