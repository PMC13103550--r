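mkNpx <- function(m) {
  dimnames(m) <- list(sprintf("a%02d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  m
}

test_that("LOD filter uses a strict detection fraction and FAIL flags", {
  m <- mkNpx(rbind(c(rep(1, 8), rep(-1, 2)),   # 8/10 above -> kept
                   c(rep(1, 7), rep(-1, 3)),   # 7/10 -> dropped
                   rep(1, 10)))
  lod <- setNames(rep(0, 3), rownames(m))
  kept <- filterNpxByLod(m, lod)
  expect_setequal(rownames(kept), c("a01", "a03"))
  # exactly 75 of 100 detected -> dropped (strict >)
  m2 <- mkNpx(matrix(c(rep(1, 75), rep(-1, 25)), 1, 100))
  expect_equal(nrow(filterNpxByLod(m2, c(a01 = 0))), 0)
  m3 <- mkNpx(matrix(c(rep(1, 76), rep(-1, 24)), 1, 100))
  expect_equal(nrow(filterNpxByLod(m3, c(a01 = 0))), 1)
  # FAIL-flagged measurements count as missing (not above LOD)
  flags <- matrix("PASS", 1, 100, dimnames = dimnames(m3))
  flags[1, 1:2] <- "FAIL"
  expect_equal(nrow(filterNpxByLod(m3, c(a01 = 0), flags)), 0)
  expect_error(filterNpxByLod(m, lod[1:2]), "missing LOD")
  # idempotence
  again <- filterNpxByLod(kept, lod)
  expect_equal(featureValues(again), featureValues(kept))
})

test_that("low-expression sample exclusion uses a strict 4-SD rule", {
  m <- mkNpx(matrix(5, 20, 10))
  expect_length(excludeLowExpressionSamples(m + rnorm(200, 0, 1e-8)), 0)
  set.seed(1)
  m2 <- mkNpx(matrix(rnorm(20 * 30, 5, 1), 20, 30))
  sm <- colMeans(m2)
  m2[, 3] <- m2[, 3] - 10 * sd(sm)        # far outlier
  expect_equal(excludeLowExpressionSamples(m2), "s03")
  # a sample sitting exactly at the threshold is retained (strict <)
  base <- mkNpx(matrix(rep(c(0, 10, 10, 10, 10), each = 5), 5, 5))
  sm <- colMeans(base)
  kExact <- (mean(sm) - min(sm)) / sd(sm)
  expect_length(excludeLowExpressionSamples(base, k_sd = kExact), 0)
  expect_equal(excludeLowExpressionSamples(base, k_sd = kExact - 1e-6), "s01")
  expect_error(excludeLowExpressionSamples(base[, 1:2]), "3 samples")
})

test_that("low-count filter implements the CPM cutoff / smallest group rule", {
  cnt <- matrix(10, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  cnt2 <- rbind(cnt, matrix(round(1e6 - 40), 1, 6,
                            dimnames = list("filler", colnames(cnt))))
  groups <- rep(c("a", "b"), c(3, 3))
  kept <- filterLowCounts(cnt2, groups)
  expect_true(all(paste0("g", 1:4) %in% kept))   # CPM 10 >= cutoff 10 everywhere
  cnt2["g1", ] <- 0
  expect_false("g1" %in% filterLowCounts(cnt2, groups))
  cnt2["g2", ] <- c(100, 0, 0, 0, 0, 0)          # expressed in 1 < smallest group 3
  expect_false("g2" %in% filterLowCounts(cnt2, groups))
  expect_error(filterLowCounts(cnt2, rep("a", 6)), "2 groups")
  # idempotence
  kept2 <- filterLowCounts(cnt2[kept <- filterLowCounts(cnt2, groups), ], groups)
  expect_setequal(kept2, kept)
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantileNormalize(m)
  expect_equal(unname(qn), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  same <- cbind(x = c(3, 1, 2), y = c(3, 1, 2))
  expect_equal(quantileNormalize(same), same)
  set.seed(2)
  r <- matrix(rnorm(200), 40, 5)
  qr_ <- quantileNormalize(r)
  sorted <- apply(qr_, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))  # shared multiset
  expect_equal(quantileNormalize(qr_), qr_, tolerance = 1e-12)  # projection
  expect_equal(quantileNormalize(r[, 1, drop = FALSE]), r[, 1, drop = FALSE])
})

test_that("log-CPM matches its defining formula", {
  cnt <- matrix(c(100, 1e6 - 100, 0, 1e6), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lc <- featureValues(logCpm(cnt))
  expect_equal(lc["g1", "s1"], 6.6511, tolerance = 1e-4)
  expect_equal(lc["g1", "s2"], -0.99999, tolerance = 1e-4)
  eq <- matrix(50, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_true(all(abs(featureValues(logCpm(eq)) -
                        featureValues(logCpm(eq))[1, 1]) < 1e-12))
  expect_error(logCpm(matrix(-1, 1, 1, dimnames = list("g", "s"))), "negative")
})

test_that("precision weights track the mean-variance trend", {
  set.seed(3)
  n <- 40; G <- 300
  design <- cbind(1, rep(0:1, each = n / 2))
  mu <- runif(G, 2, 10)
  hom <- matrix(rnorm(G * n, mu, 1), G, n,
                dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  w <- voomWeights(hom, design)
  expect_true(all(w > 0))
  expect_lt(sd(w) / mean(w), 0.2)
  # variance decreasing in mean -> weights increasing in mean
  het <- matrix(rnorm(G * n, mu, rep(3 / sqrt(mu), n)), G, n,
                dimnames = dimnames(hom))
  w2 <- voomWeights(het, design)
  expect_gt(cor(mu, rowMeans(w2), method = "spearman"), 0.8)
  expect_warning(voomWeights(hom[1:10, ], design), "unit weights")
})

test_that("region summarization averages covered sites", {
  sm <- matrix(c(0.2, 0.6, 0.4), 3, 2,
               dimnames = list(NULL, c("s1", "s2")))
  pos <- data.frame(chromosome = "1", pos = c(10, 20, 500))
  regions <- data.frame(gene_id = c("r1", "r2", "r3"),
                        chromosome = "1",
                        start = c(0, 400, 1000), end = c(100, 600, 1100))
  out <- featureValues(summarizeMethylationRegions(sm, pos, regions))
  expect_equal(unname(out["r1", "s1"]), 0.4)    # mean of 0.2, 0.6
  expect_equal(unname(out["r2", "s1"]), 0.4)    # single site
  expect_true(all(is.na(out["r3", ])))
  expect_error(summarizeMethylationRegions(
    sm, data.frame(chromosome = "1", pos = c(20, 10, 500)), regions),
    "sorted")
})

test_that("sex QC flags karyotype-discordant coverage ratios", {
  d <- matrix(30, 3, 23, dimnames = list(c("m_ok", "m_xxy", "f_xo"),
                                         c(as.character(1:22), "X")))
  d["m_ok", "X"] <- 15; d["m_xxy", "X"] <- 30; d["f_xo", "X"] <- 15
  rep <- sexQcReadDepth(d, c("M", "M", "F"))
  expect_equal(rep$flag, c("pass", "anomalous", "anomalous"))
  expect_error(sexQcReadDepth(d[, 1:22, drop = FALSE], c("M", "M", "F")),
               "missing X")
})
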