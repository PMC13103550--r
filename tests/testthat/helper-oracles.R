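# Independent oracles used by the unit and acceptance tests. Each recomputes
# a quantity by a route unrelated to the package implementation.

# Minimum over unimodal CDFs (convex part, optional atom at the mode, concave
# part; mode at any data value or midpoint) of sup|F_n - G|, solved as a small
# linear program per candidate mode (boot::simplex). Exact for tiny n.
bruteDip <- function(x) {
  x <- sort(x); n <- length(x)
  t <- unique(x); k <- length(t)
  cnt <- cumsum(tabulate(match(x, t), k))
  nodes <- data.frame(u = t, lo = cnt / n, hi = c(0, cnt[-k]) / n)
  if (k > 1) nodes <- rbind(nodes,
    data.frame(u = (t[-k] + t[-1]) / 2, lo = cnt[-k] / n, hi = cnt[-k] / n))
  nodes <- nodes[order(nodes$u), ]
  u <- nodes$u; lo <- nodes$lo; hi <- nodes$hi
  m <- length(u)
  best <- Inf
  for (j in seq_len(m)) {
    nv <- m + 2; R <- m + 1; D <- m + 2
    A1 <- list(); b1 <- c(); A2 <- list(); b2 <- c()
    le <- function(r, b) { A1[[length(A1) + 1]] <<- r; b1 <<- c(b1, b) }
    ge <- function(r, b) { A2[[length(A2) + 1]] <<- r; b2 <<- c(b2, b) }
    rw <- function(...) { r <- numeric(nv)
      for (p in list(...)) r[p[1]] <- r[p[1]] + p[2]; r }
    for (i in seq_len(m)) {
      if (i == j) {  # split mode node: var j = left limit, var R = right value
        le(rw(c(i, 1), c(D, -1)), hi[i]); ge(rw(c(i, 1), c(D, 1)), hi[i])
        le(rw(c(R, 1), c(D, -1)), lo[i]); ge(rw(c(R, 1), c(D, 1)), lo[i])
        le(rw(c(R, 1)), 1)
        ge(rw(c(R, 1), c(i, -1)), 0)
      } else {
        le(rw(c(i, 1), c(D, -1)), hi[i])
        ge(rw(c(i, 1), c(D, 1)), lo[i])
        le(rw(c(i, 1)), 1)
      }
    }
    rightVar <- function(i) if (i == j) R else i
    for (i in seq_len(m - 1)) {
      a <- if (i >= j) rightVar(i) else i
      b <- if (i + 1 > j) rightVar(i + 1) else i + 1
      ge(rw(c(b, 1), c(a, -1)), 0)
    }
    if (j > 2) for (i in 2:(j - 1)) {
      h1 <- u[i] - u[i - 1]; h2 <- u[i + 1] - u[i]
      ge(rw(c(i - 1, 1 / h1), c(i, -1 / h1 - 1 / h2), c(i + 1, 1 / h2)), 0)
    }
    if (j < m - 1) for (i in (j + 1):(m - 1)) {
      h1 <- u[i] - u[i - 1]; h2 <- u[i + 1] - u[i]
      le(rw(c(rightVar(i - 1), 1 / h1), c(rightVar(i), -1 / h1 - 1 / h2),
            c(rightVar(i + 1), 1 / h2)), 0)
    }
    obj <- numeric(nv); obj[D] <- -1
    s <- tryCatch(boot::simplex(a = obj, A1 = do.call(rbind, A1), b1 = b1,
                                A2 = do.call(rbind, A2), b2 = b2,
                                maxi = TRUE),
                  error = function(e) NULL)
    if (!is.null(s) && s$solved == 1) best <- min(best, s$soln[D])
  }
  best
}

# Naive full running-sum GSEA enrichment score (independent code path).
bruteES <- function(scores, inSet, w = 1) {
  N <- length(scores)
  hit <- inSet
  wv <- abs(scores)^w
  WR <- sum(wv[hit])
  Nm <- N - sum(hit)
  run <- cumsum(ifelse(hit, wv / WR, -1 / Nm))
  run[which.max(abs(run))]
}

# Reference BH step-up (independent of p.adjust).
refBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Exact hypergeometric upper tail by combinatorial enumeration.
enumHyper <- function(k, K, n, N) {
  kk <- max(0, n + K - N):min(K, n)
  probs <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(probs[kk >= k])
}

# Independent Sheather-Jones solve-the-equation bandwidth (Gaussian kernel),
# following the plug-in construction with normal-scale pilot bandwidths.
sjSolveOracle <- function(x) {
  n <- length(x)
  lam <- min(sd(x), IQR(x) / 1.349)
  phi4 <- function(u) (u^4 - 6 * u^2 + 3) * dnorm(u)
  phi6 <- function(u) (u^6 - 15 * u^4 + 45 * u^2 - 15) * dnorm(u)
  dif <- outer(x, x, "-")
  TD <- function(b) -sum(phi6(dif / b)) / (n * (n - 1) * b^7)
  SD <- function(a) sum(phi4(dif / a)) / (n * (n - 1) * a^5)
  a <- 0.920 * lam * n^(-1 / 7)
  b <- 0.912 * lam * n^(-1 / 9)
  RK <- 1 / (2 * sqrt(pi))
  alpha2 <- function(h) 1.357 * (SD(a) / TD(b))^(1 / 7) * h^(5 / 7)
  f <- function(h) (RK / (n * SD(alpha2(h))))^(1 / 5) - h
  uniroot(f, c(0.01 * lam, 2 * lam), tol = 1e-8)$root
}

# shared small synthetic cohort (computed once per test run)
smallCohortFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateCohort(cohortSpec(
        n_genes = 600, n_meth_features = 600, n_proteins = 300,
        protein_x_count = 20, seed = 421))
    cache
  }
})
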