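#' Hartigan dip statistic
#'
#' Maximum difference between the empirical distribution function and the
#' closest unimodal distribution function, computed by the iterative
#' greatest-convex-minorant / least-concave-majorant algorithm on the sorted
#' sample. The statistic lies in [1/(2n), 1/4].
#'
#' @param x numeric vector, n >= 4, finite, not all identical.
#' @return the dip statistic D (scalar).
#' @examples
#' dipStatistic(c(0, 0, 1, 1))  # two-point mass limit: 0.25
#' @export
dipStatistic <- function(x) {
  if (length(x) < 4) stop("need at least 4 observations")
  .assertNumeric(x, "x")
  x <- sort(x)
  n <- length(x)
  if (x[1] == x[n]) stop("all values identical")

  # mn[j]: previous touch point of the greatest convex minorant through 1..j
  mn <- integer(n); mn[1] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  # mj[k]: next touch point of the least concave majorant through k..n
  mj <- integer(n); mj[n] <- n
  for (k in (n - 1):1) {
    mj[k] <- k + 1L
    repeat {
      mjk <- mj[k]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[k] - x[mjk]) * (mjk - mjmjk) <
          (x[mjk] - x[mjmjk]) * (k - mjk)) break
      mj[k] <- mjmjk
    }
  }

  low <- 1L; high <- n
  dip <- 1.0  # in units of counts; final statistic is dip / (2n)
  repeat {
    # GCM touch points on [low, high], from high down to low
    gcm <- integer(0); i <- 1L; gcm[1] <- high
    while (gcm[i] > low) { gcm[i + 1L] <- mn[gcm[i]]; i <- i + 1L }
    l_gcm <- i; ig <- i
    # LCM touch points on [low, high], from low up to high
    lcm <- integer(0); i <- 1L; lcm[1] <- low
    while (lcm[i] < high) { lcm[i + 1L] <- mj[lcm[i]]; i <- i + 1L }
    l_lcm <- i; ih <- i

    # largest separation between the two fits
    d <- 0
    if (l_gcm != 2L || l_lcm != 2L) {
      ix <- l_gcm - 1L; iv <- 2L
      repeat {
        gcmix <- gcm[ix]; lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv - 1L }
        } else {
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else {
      d <- 1
    }
    if (d < dip) break

    # max deviation of the ECDF above the minorant on [low, gcm corner]
    dip_l <- 0
    if (ig < l_gcm) for (j in ig:(l_gcm - 1L)) {
      max_t <- 1
      jb <- gcm[j + 1L]; je <- gcm[j]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        for (jj in (jb + 1L):je) {
          t <- (jj - jb + 1) - (x[jj] - x[jb]) * C
          if (t > max_t) max_t <- t
        }
      }
      if (max_t > dip_l) dip_l <- max_t
    }
    # max deviation of the ECDF below the majorant on [lcm corner, high]
    dip_u <- 0
    if (ih < l_lcm) for (j in ih:(l_lcm - 1L)) {
      max_t <- 1
      jb <- lcm[j]; je <- lcm[j + 1L]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        for (jj in jb:(je - 1L)) {
          t <- (je - jj + 1) - (x[je] - x[jj]) * C
          if (t > max_t) max_t <- t
        }
      }
      if (max_t > dip_u) dip_u <- max_t
    }

    dipnew <- max(dip_l, dip_u)
    if (dipnew > dip) dip <- dipnew
    if (low == gcm[ig] && high == lcm[ih]) break
    low <- gcm[ig]
    high <- lcm[ih]
  }
  dip / (2 * n)
}

#' Monte-Carlo null distribution of the dip statistic
#'
#' Dip statistics of \code{n_mc} uniform(0, 1) samples of size n. The null
#' distribution depends only on n, so a table can be computed once and shared
#' across many tests of samples of the same size (see \code{\link{dipTest}}).
#'
#' @param n sample size.
#' @param n_mc number of Monte-Carlo draws (default 10000).
#' @param seed optional RNG seed.
#' @return numeric vector of \code{n_mc} null dip statistics.
#' @export
dipNullDistribution <- function(n, n_mc = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_mc), function(i) dipStatistic(runif(n)), 0)
}

#' Monte-Carlo dip test of unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution, with p-value
#' \code{(1 + #\{null D >= observed D\}) / (n_mc + 1)} against uniform
#' reference samples of the same size.
#'
#' @param x numeric sample (n >= 4).
#' @param n_mc number of null draws (default 10000; ignored when \code{null}
#'   is supplied).
#' @param seed optional RNG seed for the null draws.
#' @param null optional precomputed null distribution from
#'   \code{\link{dipNullDistribution}} for \code{length(x)}.
#' @return object of class \code{"dipTest"}: list with \code{statistic},
#'   \code{p.value}, \code{n}, \code{n_mc}, \code{seed}.
#' @export
dipTest <- function(x, n_mc = 10000, seed = NULL, null = NULL) {
  D <- dipStatistic(x)
  if (is.null(null)) null <- dipNullDistribution(length(x), n_mc, seed)
  p <- (1 + sum(null >= D)) / (length(null) + 1)
  structure(list(statistic = D, p.value = p, n = length(x),
                 n_mc = length(null), seed = seed),
            class = "dipTest")
}

#' @export
print.dipTest <- function(x, ...) {
  cat("Hartigan dip test (Monte-Carlo)\n")
  cat(sprintf("  D = %.5f, n = %d, p = %.4g (%d null draws)\n",
              x$statistic, x$n, x$p.value, x$n_mc))
  invisible(x)
}

#' Sheather-Jones plug-in bandwidth
#'
#' Solve-the-equation plug-in bandwidth with Gaussian kernels and pilot
#' estimation of derivatives. If the fixed-point equation has no root in the
#' search bracket, Silverman's rule of thumb is returned instead and flagged
#' via the \code{"fallback"} attribute.
#'
#' @param x numeric sample, n >= 5, positive standard deviation.
#' @return bandwidth h (attribute \code{fallback} = TRUE when Silverman's rule
#'   was used).
#' @export
sjBandwidth <- function(x) {
  .assertNumeric(x, "x")
  if (length(x) < 5) stop("need at least 5 observations")
  if (sd(x) == 0) stop("zero variance")
  h <- tryCatch(bw.SJ(x, method = "ste"),
                error = function(e) {
                  structure(bw.nrd0(x), fallback = TRUE)
                })
  if (is.null(attr(h, "fallback"))) attr(h, "fallback") <- FALSE
  h
}

#' Gaussian kernel density on the standard grid
#'
#' Density evaluated on 512 equally spaced points spanning the data range
#' extended by 3 bandwidths on both sides; the trapezoid integral is ~1.
#'
#' @param x numeric sample.
#' @param h bandwidth (> 0), e.g. from \code{\link{sjBandwidth}}.
#' @return object of class \code{"kdeCurve"}: list with \code{x} (grid),
#'   \code{y} (density), \code{bandwidth}.
#' @export
kdeCurve <- function(x, h) {
  if (h <= 0) stop("bandwidth must be positive")
  d <- density(x, bw = h, kernel = "gaussian", n = 512,
               from = min(x) - 3 * h, to = max(x) + 3 * h)
  structure(list(x = d$x, y = d$y, bandwidth = h), class = "kdeCurve")
}

# indices of strict local maxima of a vector
.localMaxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y > c(y[-1], -Inf))
}

#' Trough threshold of a bimodal density
#'
#' Location of the minimum density strictly between the leftmost and rightmost
#' strict local maxima of the curve (the "trough"); ties broken leftmost.
#' A curve with fewer than two modes is an error.
#'
#' @param curve a \code{"kdeCurve"} (or list with \code{x}, \code{y}).
#' @return threshold (grid location of the trough).
#' @export
troughThreshold <- function(curve) {
  peaks <- .localMaxima(curve$y)
  if (length(peaks) < 2) stop("unimodal input: fewer than 2 density modes")
  lo <- min(peaks); hi <- max(peaks)
  inner <- (lo + 1L):(hi - 1L)
  curve$x[inner[which.min(curve$y[inner])]]
}

#' Relative expression from qPCR Ct values
#'
#' Delta-delta-Ct normalization: \code{dCt = Ct_target - Ct_reference};
#' relative expression is \code{2^-(dCt - mean dCt of the sex-matched healthy
#' controls)}, so a healthy-control-average sample has relative expression 1.
#'
#' @param ct_target,ct_reference paired Ct values (NA allowed in target;
#'   missing reference for a non-missing target is an error).
#' @param sex per-sample sex labels ("F"/"M").
#' @param disease per-sample disease labels ("HC"/"SLE").
#' @return numeric vector of relative expression values (NA where target NA).
#' @export
normalizeQpcr <- function(ct_target, ct_reference, sex, disease) {
  stopifnot(length(ct_target) == length(ct_reference),
            length(sex) == length(ct_target),
            length(disease) == length(ct_target))
  if (any(!is.na(ct_target) & is.na(ct_reference)))
    stop("missing reference Ct for a measured sample")
  dct <- ct_target - ct_reference
  out <- rep(NA_real_, length(dct))
  for (s in unique(sex)) {
    hc <- sex == s & disease == "HC" & !is.na(dct)
    if (!any(hc)) stop("no sex-matched healthy controls for sex ", s)
    sel <- sex == s & !is.na(dct)
    out[sel] <- 2^(-(dct[sel] - mean(dct[hc])))
  }
  out
}

#' Classify samples into XIST-high and XIST-low
#'
#' Primary threshold: trough of the SJ-bandwidth KDE of the qPCR values (log2
#' scale recommended). Samples lacking a qPCR measurement are classified by an
#' independent SJ-KDE trough on the RNA-seq values. Intended for the male SLE
#' cohort; the function itself is generic.
#'
#' @param qpcr named numeric vector (NA = missing) of qPCR-based expression.
#' @param rnaseq named numeric vector of RNA-seq expression for the same
#'   samples (used for samples missing qPCR).
#' @return object of class \code{"xistClassification"}: data.frame with
#'   sample, value, source ("qpcr"/"rnaseq"), label ("high"/"low"); attributes
#'   \code{threshold_qpcr} and \code{threshold_rnaseq} (NA when unused).
#' @export
classifyXist <- function(qpcr, rnaseq) {
  ids <- names(qpcr)
  if (is.null(ids)) stop("qpcr values must be named by sample")
  if (!all(ids %in% names(rnaseq)) && anyNA(qpcr))
    stop("rnaseq values needed for samples missing qPCR")
  useQ <- !is.na(qpcr)
  thrQ <- thrR <- NA_real_
  label <- setNames(character(length(ids)), ids)
  src <- setNames(character(length(ids)), ids)
  if (any(useQ)) {
    thrQ <- troughThreshold(kdeCurve(qpcr[useQ], sjBandwidth(qpcr[useQ])))
    label[useQ] <- ifelse(qpcr[useQ] > thrQ, "high", "low")
    src[useQ] <- "qpcr"
  }
  if (any(!useQ)) {
    r <- rnaseq[names(rnaseq) %in% ids]
    thrR <- troughThreshold(kdeCurve(r, sjBandwidth(r)))
    miss <- ids[!useQ]
    label[miss] <- ifelse(rnaseq[miss] > thrR, "high", "low")
    src[miss] <- "rnaseq"
  }
  out <- data.frame(sample = ids,
                    value = ifelse(useQ, qpcr, rnaseq[ids]),
                    source = unname(src), label = unname(label),
                    stringsAsFactors = FALSE)
  attr(out, "threshold_qpcr") <- thrQ
  attr(out, "threshold_rnaseq") <- thrR
  class(out) <- c("xistClassification", "data.frame")
  out
}

#' Brown-Forsythe (median-centered) Levene variance test
#'
#' One-way ANOVA F-test on the absolute deviations from the group centers
#' (medians by default), testing equality of spread across groups.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups, each n >= 2).
#' @param center centering function (default \code{median}).
#' @return list with \code{statistic} (W), \code{df}, \code{p.value}.
#' @export
leveneVarianceTest <- function(values, groups, center = median) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("each group needs n >= 2")
  z <- abs(values - ave(values, g, FUN = center))
  if (all(tapply(z, g, var) == 0)) {
    k <- nlevels(g)
    return(list(statistic = 0, df = c(k - 1, length(z) - k), p.value = 1))
  }
  a <- anova(lm(z ~ g))
  list(statistic = a[["F value"]][1], df = a[["Df"]], p.value = a[["Pr(>F)"]][1])
}
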