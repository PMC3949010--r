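## Group-comparison and agreement statistics used by the study analyses.
## ANOVA, the unpaired t test and Pearson's correlation are computed from
## the textbook sums-of-squares formulas so that degenerate inputs (zero
## within-group variance with unequal means) can be flagged explicitly;
## studentized-range quantiles/tails come from R's ptukey/qtukey.

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA from sums of squares; the null
#' hypothesis is that all group means are equal. Zero within-group
#' variance with unequal means is reported as `F = Inf`, `p = 0` with
#' `degenerate = TRUE`.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `dfBetween`, `dfWithin`, `p`, `groupMeans`,
#'   `groupNs`, `MSW`, `degenerate`.
#' @export
oneWayAnova <- function(groups) {
  groups <- lapply(groups, as.numeric)
  k <- length(groups)
  ns <- lengths(groups)
  if (k < 2L) stop("need at least two groups")
  if (any(ns < 2L)) stop("every group needs at least two observations")
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssb + ssw <= 0) stop("total variance is zero")
  dfb <- k - 1L
  dfw <- N - k
  if (ssw == 0) {
    warning("zero within-group variance with unequal means; F is infinite")
    return(list(F = Inf, dfBetween = dfb, dfWithin = dfw, p = 0,
                groupMeans = means, groupNs = ns, MSW = 0, degenerate = TRUE))
  }
  Fstat <- (ssb / dfb) / (ssw / dfw)
  list(F = Fstat, dfBetween = dfb, dfWithin = dfw,
       p = stats::pf(Fstat, dfb, dfw, lower.tail = FALSE),
       groupMeans = means, groupNs = ns, MSW = ssw / dfw, degenerate = FALSE)
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range post hoc test valid for unequal group sizes:
#' `q_ij = |m_i - m_j| / sqrt((MSW/2) (1/n_i + 1/n_j))`, compared against
#' the studentized-range quantile `q(k, N - k, 1 - alpha)`. With equal
#' group sizes this reduces to the classical Tukey HSD.
#'
#' @param groups list of numeric vectors (as [oneWayAnova()]).
#' @param alpha familywise significance level.
#' @return list with `pairs` (data.frame: i, j, meanDiff, q, p,
#'   significant), `qCrit`, `alpha`, and the underlying `anova` result.
#' @export
tukeyKramer <- function(groups, alpha = 0.05) {
  an <- oneWayAnova(groups)
  k <- length(groups)
  if (an$degenerate)
    stop("zero within-group variance; studentized range undefined")
  qc <- stats::qtukey(1 - alpha, k, an$dfWithin)
  pr <- utils::combn(k, 2L)
  res <- data.frame(i = pr[1L, ], j = pr[2L, ])
  res$meanDiff <- an$groupMeans[res$i] - an$groupMeans[res$j]
  se <- sqrt((an$MSW / 2) * (1 / an$groupNs[res$i] + 1 / an$groupNs[res$j]))
  res$q <- abs(res$meanDiff) / se
  res$p <- stats::ptukey(res$q, k, an$dfWithin, lower.tail = FALSE)
  res$significant <- res$q > qc
  list(pairs = res, qCrit = qc, alpha = alpha, anova = an)
}

#' Unpaired two-sample t test (pooled variance)
#'
#' Classical equal-variance unpaired t test. With zero pooled variance the
#' result is `t = 0, p = 1` for equal means, and a flagged infinite `t`
#' with `p = 0` otherwise.
#'
#' @param x,y numeric vectors with at least two observations each.
#' @param twoTailed logical; two-tailed p value (default) or upper tail of
#'   `|t|` halved appropriately.
#' @return list with `t`, `df`, `p`, `meanDiff`, `degenerate`.
#' @export
tTestUnpaired <- function(x, y, twoTailed = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("both samples need at least two observations")
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  md <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (md == 0) return(list(t = 0, df = df, p = 1, meanDiff = 0,
                             degenerate = TRUE))
    warning("zero pooled variance with unequal means; t is infinite")
    return(list(t = sign(md) * Inf, df = df, p = 0, meanDiff = md,
                degenerate = TRUE))
  }
  tstat <- md / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(t = tstat, df = df, p = if (twoTailed) 2 * p else p, meanDiff = md,
       degenerate = FALSE)
}

#' Pearson correlation with t-distributed significance test
#'
#' @param x,y numeric vectors, n >= 3, both with positive variance.
#' @param twoTailed logical; two-tailed p value (default).
#' @return list with `r`, `t`, `df`, `p`, `n`.
#' @export
pearsonCor <- function(x, y, twoTailed = TRUE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least three observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance; correlation undefined")
  r <- stats::cor(x, y)
  df <- n - 2L
  if (abs(r) >= 1) {
    tstat <- sign(r) * Inf
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- stats::pt(abs(tstat), df, lower.tail = FALSE)
    p <- if (twoTailed) 2 * p else p
  }
  list(r = r, t = tstat, df = df, p = p, n = n)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement with the 45-degree line through the origin:
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`, with biased
#' (1/n) moment estimators per Lin's original definition; implementations
#' using (n-1)-based variances differ slightly at small n.
#'
#' @param x,y numeric vectors of equal length, n >= 2, not both constant.
#' @return scalar concordance in \[-1, 1\].
#' @export
linCCC <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least two observations")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0)
    stop("both sequences are constant; concordance undefined")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d_i = x_i - y_i` (by convention experimental minus
#' finite-element), their mean and sample SD, limits of agreement
#' `mean +/- 1.96 SD`, and the (mean, difference) table for plotting.
#'
#' @param x,y numeric vectors of equal length, n >= 2.
#' @return list with `meanDiff`, `sdDiff`, `loaLow`, `loaHigh`, `table`
#'   (data.frame: mean, diff).
#' @export
blandAltman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least two observations")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  list(meanDiff = md, sdDiff = sdd, loaLow = md - 1.96 * sdd,
       loaHigh = md + 1.96 * sdd,
       table = data.frame(mean = (x + y) / 2, diff = d))
}
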