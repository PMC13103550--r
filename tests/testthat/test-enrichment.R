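test_that("LFC ranking is a strict total order with the stated tie rules", {
  tab <- data.frame(feature = c("a", "b", "c"), lfc = c(2, 1, 3),
                    p = c(0.5, 0.5, 0.5))
  expect_equal(rankByLfc(tab)$gene, c("c", "a", "b"))
  tied <- data.frame(feature = c("a", "b"), lfc = c(1, 1), p = c(0.5, 0.01))
  expect_equal(rankByLfc(tied)$gene, c("b", "a"))
  dup <- data.frame(feature = c("a", "a"), lfc = c(1, 2), p = 0.5)
  expect_error(rankByLfc(dup), "duplicate")
})

test_that("enrichment score matches hand evaluation and brute force", {
  ranked <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                       score = c(3, 2, 1, 0.5))
  top <- gseaPreranked(ranked, list(s = "g1"), n_perm = 200, seed = 1,
                       min_size = 1)
  expect_equal(top$es, 1)
  bottom <- gseaPreranked(ranked, list(s = "g4"), n_perm = 200, seed = 1,
                          min_size = 1)
  expect_equal(bottom$es, -1)
  # running-sum implementation vs an independent full-cumsum recomputation
  set.seed(16)
  for (i in 1:50) {
    N <- sample(10:50, 1)
    sc <- sort(rnorm(N), decreasing = TRUE)
    genes <- sprintf("g%02d", 1:N)
    K <- sample(2:(N - 2), 1)
    inSet <- genes %in% sample(genes, K)
    r <- data.frame(gene = genes, score = sc)
    es <- gseaPreranked(r, list(s = genes[inSet]), n_perm = 10, seed = 1,
                        min_size = 1)$es
    expect_equal(es, bruteES(sc, inSet), tolerance = 1e-10)
  }
})

test_that("enrichment score agrees with the reference GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  N <- 80
  sc <- sort(rnorm(N, 0, 2), decreasing = TRUE)
  genes <- sprintf("g%02d", 1:N)
  set <- sample(genes, 12)
  mine <- gseaPreranked(data.frame(gene = genes, score = sc),
                        list(s = set), n_perm = 10, seed = 1)$es
  stats <- setNames(sc, genes)
  ref <- fgsea::calcGseaStat(stats, selectedStats = which(genes %in% set),
                             gseaParam = 1)
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("size-1 set permutation p matches exact enumeration (w = 0)", {
  set.seed(18)
  N <- 12
  sc <- sort(rnorm(N), decreasing = TRUE)
  genes <- sprintf("g%02d", 1:N)
  r <- data.frame(gene = genes, score = sc)
  # exact null: ES for the single gene at every possible position
  esAt <- vapply(1:N, function(pos) {
    inSet <- seq_len(N) == pos
    run <- cumsum(ifelse(inSet, 1, -1 / (N - 1)))
    run[which.max(abs(run))]
  }, 0)
  g <- gseaPreranked(r, list(s = genes[3]), weight_exponent = 0,
                     n_perm = 4000, seed = 5, min_size = 1)
  same <- esAt[sign(esAt) == sign(g$es)]
  pExact <- sum(abs(same) >= abs(g$es)) / N
  expect_equal(g$p, pExact, tolerance = 0.05)
})

test_that("degenerate all-zero scores fall back to the unweighted statistic", {
  r <- data.frame(gene = sprintf("g%02d", 1:20), score = rep(0, 20))
  expect_warning(g <- gseaPreranked(r, list(s = r$gene[1:6]), n_perm = 50,
                                    seed = 1), "weight_exponent = 0")
  expect_true(is.finite(g$es))
  expect_error(gseaPreranked(r[0, ], list(s = "g01")), "empty")
})

test_that("hypergeometric ORA is exact", {
  u <- sprintf("u%02d", 1:10)
  res <- hypergeometricOra(u[1:5], u[1:5], u)
  expect_equal(res$p.value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(hypergeometricOra(u[6:10], u[1:5], u)$p.value, 1)
  u4 <- u[1:4]
  res4 <- hypergeometricOra(u4[1:2], u4[c(1, 3)], u4)  # k=1, K=2, n=2, N=4
  expect_equal(res4$p.value, 5 / 6, tolerance = 1e-12)
  expect_error(hypergeometricOra(c(u, "zz"), u[1:2], u), "subset")
  # exhaustive agreement with combinatorial enumeration for small universes
  set.seed(19)
  for (N in 5:12) {
    un <- sprintf("x%02d", 1:N)
    for (rep in 1:5) {
      K <- sample(1:N, 1); n <- sample(1:N, 1)
      st <- sample(un, K); q <- sample(un, n)
      res <- hypergeometricOra(q, st, un)
      expect_equal(res$p.value, enumHyper(res$k, K, n, N), tolerance = 1e-12)
    }
  }
})

test_that("chromosome scan reports per-table families with BH monotonicity", {
  co <- smallCohortFixture()
  s <- co$samples
  pm <- logitMethylation(co$matrices$promoter_meth)
  de <- runFactorialDE(pm, s$sex, s$disease)
  sets <- buildChromosomeGeneSets(co$annotation_meth)
  scan <- chromosomeSilencingScan(
    list(pm.male = de$male_SLE_vs_HC, pm.female = de$female_SLE_vs_HC),
    sets, n_perm = 300, seed = 20)
  expect_true(all(c("table", "set", "es", "nes", "p", "fdr") %in% names(scan)))
  expect_true(all(abs(scan$es) <= 1))
  expect_true(all(sign(scan$nes) == sign(scan$es), na.rm = TRUE))
  expect_true(all(scan$p >= 1 / 301 & scan$p <= 1))
  # sets smaller than min_size are skipped
  expect_false("MT" %in% scan$set[lengths(sets["MT"]) < 5])
  # planted X hypermethylation scores positive in males only
  xm <- scan[scan$table == "pm.male" & scan$set == "X", ]
  expect_gt(xm$nes, 0)
  expect_lte(xm$fdr, 0.1)
})

test_that("X-linked fraction and XCI-panel summaries count correctly", {
  sets <- list(X = c("x1", "x2", "x3"), `1` = c("a1", "a2", "a3", "a4"))
  universe <- c(sets$X, sets$`1`)
  s <- xlinkedFractionSummary(c("x1", "x2", "a1"), sets, universe)
  expect_equal(s$k, 2); expect_equal(s$n, 3)
  expect_equal(s$fraction, 2 / 3)
  expect_equal(xlinkedFractionSummary(character(), sets, universe)$fraction,
               NA_real_)
  expect_error(xlinkedFractionSummary("x1", sets, universe, chromosome = "Y"),
               "absent")
  tab <- data.frame(feature = c("x1", "x2", "x3", "a1", "a2"),
                    lfc = c(-1, -0.3, 0.5, -2, 1),
                    fdr = c(0.01, 0.05, 0.01, 0.2, 0.01))
  xp <- xciPanelSummary(tab, panel = c("x1", "x2", "x3", "zz"))
  expect_equal(xp$n_panel_tested, 3)
  expect_equal(xp$n_down, 2)           # x1, x2: LFC < 0, FDR < 0.1
  expect_equal(xp$n_strong_down, 1)    # only x1 passes |FC| > 1.5
  expect_equal(xp$fraction_down, 2 / 3)
  expect_error(xciPanelSummary(tab, panel = "none"), "no panel genes")
  tabUp <- transform(tab, lfc = abs(lfc))
  expect_equal(xciPanelSummary(tabUp, c("x1", "x2", "x3"))$n_down, 0)
})
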