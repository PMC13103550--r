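mk4cell <- function(means, nPer = 5, sd = 0, G = 1) {
  sex <- rep(c("F", "F", "M", "M"), each = nPer)
  dis <- rep(c("HC", "SLE", "HC", "SLE"), each = nPer)
  mu <- rep(means[c(1, 2, 3, 4)], each = nPer)  # F_HC, F_SLE, M_HC, M_SLE
  m <- matrix(rep(mu, each = G), G, 4 * nPer,
              dimnames = list(sprintf("g%03d", 1:G),
                              sprintf("s%02d", 1:(4 * nPer))))
  if (sd > 0) m <- m + matrix(rnorm(length(m), 0, sd), G)
  list(x = m, sex = sex, disease = dis)
}

test_that("factorial coding recovers cell means exactly", {
  d <- mk4cell(c(0, 1, 0, 5))
  X <- makeFactorialDesign(d$sex, d$disease)
  fit <- fitFeatureModels(d$x, X)
  expect_equal(unname(fit$coefficients[1, ]), c(0, 0, 1, 4), tolerance = 1e-12)
  d0 <- mk4cell(c(1, 3, 2, 4))                   # parallel response: no interaction
  fit0 <- fitFeatureModels(d0$x, makeFactorialDesign(d0$sex, d0$disease))
  expect_equal(unname(fit0$coefficients[1, "sex_disease"]), 0, tolerance = 1e-12)
  # constant weights equal the unweighted fit
  set.seed(4)
  dn <- mk4cell(c(0, 1, 0, 5), sd = 1, G = 20)
  Xn <- makeFactorialDesign(dn$sex, dn$disease)
  w <- matrix(2.5, nrow(dn$x), ncol(dn$x))
  fw <- fitFeatureModels(dn$x, Xn, weights = w)
  fu <- fitFeatureModels(dn$x, Xn)
  expect_equal(fw$coefficients, fu$coefficients, tolerance = 1e-10)
  expect_error(fitFeatureModels(dn$x[, d$sex == "F"],
                                Xn[d$sex == "F", ]), "rank-deficient")
})

test_that("variance prior recovers scaled chi-square hyperparameters", {
  set.seed(5)
  d0 <- 8; s02 <- 2; df <- 10
  # per-feature variance from the scaled-inverse-chi-square prior, residual
  # variance from the sampling chi-square
  sigma2 <- s02 * d0 / rchisq(5000, d0)
  s2 <- sigma2 * rchisq(5000, df) / df
  prior <- estimateVariancePrior(s2, df)
  expect_lt(abs(prior$d0 - d0) / d0, 0.15)
  expect_lt(abs(prior$s02 - s02) / s02, 0.15)
  # agreement with the established empirical-Bayes fit
  lf <- limma::fitFDist(s2, df1 = df)
  expect_equal(prior$d0, lf$df2, tolerance = 0.02)
  expect_equal(prior$s02, lf$scale, tolerance = 0.02)
  # zero-spread limit
  pc <- estimateVariancePrior(rep(3, 100), df = 10)
  expect_equal(pc$d0, Inf)
  expect_equal(pc$s02, 3, tolerance = 1e-9)
  expect_gt(estimateVariancePrior(runif(100, 1, 2), 10)$d0, 0)
})

test_that("moderated t matches its limiting cases and limma", {
  set.seed(6)
  d <- mk4cell(c(0, 0, 0, 0), nPer = 6, sd = 1, G = 200)
  X <- makeFactorialDesign(d$sex, d$disease)
  fit <- fitFeatureModels(d$x, X)
  cvec <- c(0, 0, 1, 1)  # male SLE - HC
  # d0 = 0 reproduces the ordinary t-test to machine precision
  tab0 <- moderatedT(fit, list(d0 = 0), cvec)
  ordinary <- vapply(seq_len(200), function(g) {
    est <- sum(fit$coefficients[g, ] * cvec)
    se <- sqrt(fit$s2[g] * drop(t(cvec) %*% fit$cov_unscaled %*% cvec))
    est / se
  }, 0)
  expect_equal(tab0$t, ordinary, tolerance = 1e-12)
  # d0 = Inf uses the prior variance everywhere
  tabI <- moderatedT(fit, list(d0 = Inf, s02 = 1.3), cvec)
  expect_equal(tabI$s2_post, rep(1.3, 200))
  # full moderation agrees with the reference empirical-Bayes pipeline
  prior <- estimateVariancePrior(fit$s2, fit$df)
  tab <- moderatedT(fit, prior, cvec)
  lfit <- limma::lmFit(d$x, X)
  lfit <- limma::contrasts.fit(lfit, cvec)
  eb <- limma::eBayes(lfit)
  expect_equal(tab$t, unname(eb$t[, 1]), tolerance = 1e-6)
  expect_equal(tab$p, unname(eb$p.value[, 1]), tolerance = 1e-6)
})

test_that("null moderated p-values are approximately uniform", {
  set.seed(7)
  d <- mk4cell(c(0, 0, 0, 0), nPer = 8, sd = 1, G = 5000)
  tabs <- runFactorialDE(d$x, d$sex, d$disease, moderate = TRUE)
  ks <- suppressWarnings(stats::ks.test(tabs$interaction$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment equals the reference step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(c(0.03, 0.4)), c(0.06, 0.4))
  set.seed(8)
  p <- runif(300)
  expect_equal(bhAdjust(p), refBH(p), tolerance = 1e-12)
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("significance calls combine FDR and fold-change thresholds", {
  tab <- data.frame(lfc = c(0.60, 0.58, 2.0), fdr = c(0.05, 0.01, 0.2))
  expect_equal(callSignificant(tab), c(TRUE, FALSE, FALSE))
})

test_that("Venn partition is exhaustive and direction-aware", {
  f <- data.frame(feature = paste0("g", 1:6),
                  lfc = c(1, -1, 2, 1, -2, 0.1),
                  significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  m <- data.frame(feature = paste0("g", 1:6),
                  lfc = c(1, -1, -2, 0.2, 2, 3),
                  significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  v <- vennPartition(f, m)
  expect_equal(sum(v), sum(f$significant | m$significant))
  expect_equal(unname(v["shared_up"]), 1)        # g1
  expect_equal(unname(v["shared_down"]), 1)      # g2
  expect_equal(unname(v["discordant"]), 2)       # g3, g5
  expect_equal(unname(v["female_only_up"]), 1)   # g4
  expect_equal(unname(v["male_only_up"]), 1)     # g6
  expect_error(vennPartition(f[1:5, ], m), "universe")
  # disjoint / identical significant sets
  m2 <- f; m2$significant <- !f$significant
  expect_equal(unname(vennPartition(f, m2)["shared_up"] +
                        vennPartition(f, m2)["shared_down"]), 0)
  expect_equal(unname(vennPartition(f, f)["discordant"]), 0)
})
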