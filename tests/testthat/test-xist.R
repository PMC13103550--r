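test_that("dip statistic matches limiting cases and stays in its range", {
  expect_equal(dipStatistic(c(0, 0, 1, 1)), 0.25)
  expect_equal(dipStatistic(rep(c(0, 1), each = 50)), 0.25)
  expect_lt(dipStatistic(seq(0, 1, length.out = 1000)), 0.02)
  expect_error(dipStatistic(c(1, 2, 3)), "at least 4")
  expect_error(dipStatistic(rep(2, 10)), "identical")
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(4:200, 1))
    D <- dipStatistic(x)
    expect_gte(D, 1 / (2 * length(x)))
    expect_lte(D, 0.25)
  }
})

test_that("dip statistic agrees with the brute-force unimodal-CDF minimizer", {
  skip_if_not_installed("boot")
  set.seed(10)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    x <- switch(sample(3, 1),
                round(runif(n), 2),
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 4)),
                as.numeric(sample(0:3, n, replace = TRUE)))
    if (length(unique(x)) < 2) next
    expect_equal(dipStatistic(x), bruteDip(x), tolerance = 1e-6)
  }
})

test_that("dip test is deterministic given a seed and p respects its bounds", {
  x <- c(rnorm(20), rnorm(20, 6))
  t1 <- dipTest(x, n_mc = 500, seed = 42)
  t2 <- dipTest(x, n_mc = 500, seed = 42)
  expect_identical(t1$p.value, t2$p.value)
  expect_gte(t1$p.value, 1 / 501)
  expect_lte(t1$p.value, 1)
  # precomputed null table gives the same answer as fresh draws with that table
  null <- dipNullDistribution(40, 500, seed = 7)
  expect_equal(dipTest(x, null = null)$p.value,
               (1 + sum(null >= dipStatistic(x))) / 501)
})

test_that("SJ bandwidth is scale-equivariant and solves the plug-in equation", {
  set.seed(11)
  x <- rnorm(200)
  h <- as.numeric(sjBandwidth(x))
  # equivariance up to the binned-kernel discretization of the solver
  expect_equal(as.numeric(sjBandwidth(3 + 2.5 * x)), 2.5 * h,
               tolerance = 0.01)
  expect_error(sjBandwidth(rep(1, 10)), "zero variance")
  x2 <- rnorm(1000)
  expect_equal(as.numeric(sjBandwidth(x2)), sjSolveOracle(x2),
               tolerance = 0.1)
})

test_that("KDE curve is normalized on the standard grid", {
  trapz <- function(k) sum(diff(k$x) * (head(k$y, -1) + tail(k$y, -1)) / 2)
  k <- kdeCurve(0, 1)
  expect_equal(k$x[which.max(k$y)], 0, tolerance = 0.02)
  # single-point worst case: only the 3-bandwidth Gaussian tails are missed
  expect_equal(trapz(k), 1, tolerance = 3e-3)
  expect_true(all(k$y >= 0))
  set.seed(121)
  xs <- rnorm(100)
  expect_equal(trapz(kdeCurve(xs, sjBandwidth(xs))), 1, tolerance = 1e-3)
  set.seed(12)
  x <- c(rnorm(200, 0, 0.5), rnorm(200, 8, 0.5))
  k2 <- kdeCurve(x, sjBandwidth(x))
  expect_gte(length(dimorphix:::.localMaxima(k2$y)), 2)
})

test_that("trough threshold falls between the outer modes", {
  set.seed(13)
  x <- c(rnorm(500, 0, 0.4), rnorm(500, 5, 0.4))
  thr <- troughThreshold(kdeCurve(x, sjBandwidth(x)))
  expect_equal(thr, 2.5, tolerance = 0.35)
  expect_error(troughThreshold(kdeCurve(rnorm(500), 0.5)), "unimodal")
  x2 <- c(rnorm(54, 0, 1), rnorm(46, 6, 1))
  thr2 <- troughThreshold(kdeCurve(x2, sjBandwidth(x2)))
  expect_gt(thr2, 0); expect_lt(thr2, 6)
})

test_that("delta-delta-Ct normalization is anchored at sex-matched controls", {
  sex <- c("M", "M", "M", "M", "F", "F")
  disease <- c("HC", "HC", "SLE", "SLE", "HC", "SLE")
  ctr <- rep(20, 6)
  # male HC mean dCt = 5; samples 3 and 4 sit 1 cycle below/above
  ctt <- c(25, 25, 24, 26, 24, 23)
  rel <- normalizeQpcr(ctt, ctr, sex, disease)
  expect_equal(rel[1], 1)
  expect_equal(rel[3], 2)
  expect_equal(rel[4], 0.5)
  expect_error(normalizeQpcr(c(25, 25, 24, 26, 24, 23),
                             c(20, NA, 20, 20, 20, 20), sex, disease),
               "reference")
})

test_that("classification is affine-invariant and uses the recorded source", {
  set.seed(14)
  n <- 41
  lab <- rep(c("high", "low"), c(22, 19))
  vals <- ifelse(lab == "high", 9, 0) + rnorm(n, 0, 1.5)
  names(vals) <- sprintf("m%02d", 1:n)
  rna <- vals / 2 + 1  # affine image, same latent classes
  cls <- classifyXist(vals, rna)
  expect_true(all(cls$source == "qpcr"))
  expect_equal(setNames(cls$label, cls$sample)[names(vals)], setNames(lab, names(vals)))
  # affine transform of the values transforms the threshold covariantly
  cls2 <- classifyXist(3 + 2 * vals, rna)
  expect_equal(cls2$label, cls$label)
  # threshold transforms covariantly up to one 512-point grid step
  expect_lt(abs(attr(cls2, "threshold_qpcr") -
                  (3 + 2 * attr(cls, "threshold_qpcr"))), 0.06)
  # samples without qPCR fall back to the RNA-seq trough
  vals2 <- vals; vals2[1:3] <- NA
  cls3 <- classifyXist(vals2, rna)
  expect_equal(sum(cls3$source == "rnaseq"), 3)
  expect_equal(setNames(cls3$label, cls3$sample)[names(vals)],
               setNames(lab, names(vals)))
})

test_that("Levene/Brown-Forsythe test detects scale differences only", {
  x <- c(rnorm(100), rnorm(100))
  g <- rep(c("a", "b"), each = 100)
  same <- leveneVarianceTest(rep(c(1, 2, 3, 4), 2), rep(c("a", "b"), each = 4))
  set.seed(15)
  xx <- c(rnorm(100, 0, 1), rnorm(100, 0, 10))
  lv <- leveneVarianceTest(xx, g)
  expect_lt(lv$p.value, 1e-6)
  # location invariance
  lv2 <- leveneVarianceTest(xx + rep(c(0, 50), each = 100), g)
  expect_equal(lv$statistic, lv2$statistic, tolerance = 1e-10)
  # cross-check against the established implementation
  skip_if_not_installed("car")
  ref <- car::leveneTest(xx, as.factor(g), center = median)
  expect_equal(lv$statistic, ref[["F value"]][1], tolerance = 1e-8)
  expect_equal(lv$p.value, ref[["Pr(>F)"]][1], tolerance = 1e-8)
})
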