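#' Factorial sex-by-disease design matrix
#'
#' Columns: intercept, sex (female = 0, male = 1), disease (HC = 0, SLE = 1)
#' and their interaction. With this coding the interaction coefficient equals
#' ([Male SLE - Male HC] - [Female SLE - Female HC]).
#'
#' @param sex character/factor "F"/"M" per sample.
#' @param disease character/factor "HC"/"SLE" per sample.
#' @return model matrix with columns intercept, sex, disease, sex_disease.
#' @export
makeFactorialDesign <- function(sex, disease) {
  s <- as.numeric(sex == "M")
  d <- as.numeric(disease == "SLE")
  X <- cbind(intercept = 1, sex = s, disease = d, sex_disease = s * d)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: cohort is missing at least one sex x disease cell")
  X
}

#' Per-feature (weighted) least-squares fits
#'
#' Ordinary or precision-weighted least squares for every feature against a
#' common design. Residual variances of exactly zero are floored at 1e-12
#' before any downstream moderation.
#'
#' @param x OmicsMatrix or matrix of responses (features x samples); for
#'   methylation, values are expected logit-transformed upstream.
#' @param design model matrix (samples x coefficients), full column rank.
#' @param weights optional positive weight matrix, same shape as \code{x}.
#' @return list with \code{coefficients} (features x coefficients), \code{s2}
#'   (residual variances), \code{df} (residual df, shared), \code{cov_unscaled}
#'   (per-feature list of (X'WX)^-1 when weighted, single matrix otherwise),
#'   \code{design}.
#' @export
fitFeatureModels <- function(x, design, weights = NULL) {
  m <- .asMatrixInput(x)
  X <- as.matrix(design)
  n <- ncol(m)
  stopifnot(nrow(X) == n)
  r <- qr(X)$rank
  if (r < ncol(X)) stop("rank-deficient design")
  if (n <= r) stop("need more samples than design rank")
  dfres <- n - r
  G <- nrow(m)
  if (is.null(weights)) {
    XtXi <- chol2inv(chol(crossprod(X)))
    B <- m %*% X %*% XtXi                       # features x p
    fitted <- B %*% t(X)
    res <- m - fitted
    s2 <- rowSums(res^2) / dfres
    cov_unscaled <- XtXi
  } else {
    W <- .asMatrixInput(weights)
    stopifnot(identical(dim(W), dim(m)), all(W > 0))
    B <- matrix(NA_real_, G, ncol(X))
    s2 <- numeric(G)
    cov_unscaled <- vector("list", G)
    for (g in seq_len(G)) {
      w <- W[g, ]
      Xw <- X * w
      XtWXi <- chol2inv(chol(crossprod(X, Xw)))
      beta <- drop(XtWXi %*% crossprod(Xw, m[g, ]))
      resid <- m[g, ] - drop(X %*% beta)
      B[g, ] <- beta
      s2[g] <- sum(w * resid^2) / dfres
      cov_unscaled[[g]] <- XtWXi
    }
  }
  dimnames(B) <- list(rownames(m), colnames(X))
  s2 <- pmax(s2, 1e-12)
  names(s2) <- rownames(m)
  list(coefficients = B, s2 = s2, df = dfres, cov_unscaled = cov_unscaled,
       design = X)
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf))
.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Empirical-Bayes variance prior by moment matching
#'
#' Fits a scaled inverse chi-square prior to the per-feature residual
#' variances by matching moments of log s^2 (digamma/trigamma equations).
#' When the empirical spread of log s^2 does not exceed the spread expected
#' from the residual degrees of freedom alone, the prior df is infinite.
#'
#' @param s2 numeric vector of residual variances (>= 30 features).
#' @param df residual degrees of freedom (scalar).
#' @return list with \code{d0} (prior df, possibly Inf) and \code{s02}
#'   (prior variance).
#' @export
estimateVariancePrior <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  if (length(s2) < 30) stop("need at least 30 features")
  if (all(s2 <= 0)) stop("all residual variances are zero")
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  if (var(z) == 0) return(list(d0 = Inf, s02 = s2[1]))
  e <- z - digamma(df / 2) + log(df / 2)
  excess <- var(e) - trigamma(df / 2)
  if (excess <= 0) {
    # no excess spread beyond sampling noise: infinite prior df; the prior
    # variance is then the plain average (the unbiased scale estimate)
    return(list(d0 = Inf, s02 = mean(s2)))
  }
  d0 <- 2 * .trigammaInverse(excess)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated t-statistics for a contrast
#'
#' Posterior variance \code{(d0 s0^2 + df s^2) / (d0 + df)}; the t statistic is
#' the contrast estimate over its posterior standard error and is referred to a
#' t distribution on \code{d0 + df} degrees of freedom (two-sided p).
#' \code{d0 = 0} reproduces the ordinary t-test; \code{d0 = Inf} uses the prior
#' variance for every feature.
#'
#' @param fits result of \code{\link{fitFeatureModels}}.
#' @param prior list with \code{d0}, \code{s02}
#'   (see \code{\link{estimateVariancePrior}}); use \code{list(d0 = 0)} for the
#'   unmoderated test.
#' @param contrast numeric contrast vector over design columns.
#' @return data.frame: feature, lfc, t, p, s2_post.
#' @export
moderatedT <- function(fits, prior, contrast) {
  cvec <- as.numeric(contrast)
  stopifnot(length(cvec) == ncol(fits$coefficients))
  est <- drop(fits$coefficients %*% cvec)
  if (is.list(fits$cov_unscaled)) {
    sefac <- sqrt(vapply(fits$cov_unscaled,
                         function(V) drop(t(cvec) %*% V %*% cvec), 0))
  } else {
    sefac <- rep(sqrt(drop(t(cvec) %*% fits$cov_unscaled %*% cvec)),
                 length(est))
  }
  d0 <- prior$d0
  pooled <- length(fits$s2) * fits$df   # cap: total residual df in the data
  if (is.infinite(d0)) {
    s2post <- rep(prior$s02, length(est))
    dft <- pooled
  } else if (d0 == 0) {
    s2post <- fits$s2
    dft <- fits$df
  } else {
    s2post <- (d0 * prior$s02 + fits$df * fits$s2) / (d0 + fits$df)
    dft <- min(d0 + fits$df, pooled)
  }
  tstat <- est / (sqrt(s2post) * sefac)
  p <- 2 * pt(abs(tstat), df = dft, lower.tail = FALSE)
  data.frame(feature = rownames(fits$coefficients), lfc = est, t = tstat,
             p = p, s2_post = s2post, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotonicity enforced); wraps
#' \code{stats::p.adjust(method = "BH")} after validating the input range.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of adjusted p-values (q-values), each in [p, 1].
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Significance calls from FDR and fold-change thresholds
#'
#' A feature is significant iff FDR <= \code{fdr_max} and
#' |LFC| > log2(\code{fc_min}).
#'
#' @param table data.frame with columns \code{lfc} and \code{fdr}.
#' @param fdr_max FDR threshold (default 0.1).
#' @param fc_min fold-change threshold on the linear scale (default 1.5).
#' @return logical vector of significance flags.
#' @export
callSignificant <- function(table, fdr_max = 0.1, fc_min = 1.5) {
  table$fdr <= fdr_max & abs(table$lfc) > log2(fc_min)
}

#' Contrast table for one named contrast
#'
#' Convenience wrapper: moderated t, BH adjustment and significance calls.
#'
#' @inheritParams moderatedT
#' @param name contrast name recorded in the table.
#' @param fdr_max,fc_min thresholds for \code{\link{callSignificant}}.
#' @return data.frame: feature, contrast, lfc, t, p, fdr, significant.
#' @export
contrastTable <- function(fits, prior, contrast, name,
                          fdr_max = 0.1, fc_min = 1.5) {
  tab <- moderatedT(fits, prior, contrast)
  tab$fdr <- bhAdjust(tab$p)
  tab$contrast <- name
  tab$significant <- callSignificant(tab, fdr_max, fc_min)
  tab[, c("feature", "contrast", "lfc", "t", "p", "fdr", "significant")]
}

#' Run the three factorial contrasts on one modality
#'
#' Fits per-feature factorial models, estimates the variance prior and returns
#' the female SLE-vs-HC, male SLE-vs-HC and interaction contrast tables.
#'
#' @param x responses (OmicsMatrix or matrix); methylation should be
#'   logit-transformed (see \code{\link{logitMethylation}}).
#' @param sex,disease per-sample labels ("F"/"M", "HC"/"SLE").
#' @param weights optional precision weights.
#' @param fdr_max,fc_min significance thresholds.
#' @param moderate use the empirical-Bayes prior (default TRUE); FALSE uses
#'   ordinary t-tests.
#' @return named list of contrast tables: \code{female_SLE_vs_HC},
#'   \code{male_SLE_vs_HC}, \code{interaction}.
#' @export
runFactorialDE <- function(x, sex, disease, weights = NULL,
                           fdr_max = 0.1, fc_min = 1.5, moderate = TRUE) {
  X <- makeFactorialDesign(sex, disease)
  fits <- fitFeatureModels(x, X, weights)
  prior <- if (moderate) estimateVariancePrior(fits$s2, fits$df) else list(d0 = 0)
  contrasts <- list(
    female_SLE_vs_HC = c(0, 0, 1, 0),
    male_SLE_vs_HC   = c(0, 0, 1, 1),
    interaction      = c(0, 0, 0, 1))
  out <- lapply(names(contrasts), function(nm)
    contrastTable(fits, prior, contrasts[[nm]], nm, fdr_max, fc_min))
  names(out) <- names(contrasts)
  out
}

#' Subgroup contrasts within males (XIST-high / XIST-low / HC)
#'
#' One-way three-level model on male samples; returns the XIST-high vs HC,
#' XIST-low vs HC and high-vs-low contrast tables through the same moderation
#' machinery as the factorial analysis.
#'
#' @param x responses restricted to male samples (features x samples).
#' @param group character per male sample: "HC", "high" or "low".
#' @param weights optional precision weights.
#' @param fdr_max,fc_min significance thresholds.
#' @param moderate use the empirical-Bayes prior (default TRUE).
#' @return named list of contrast tables: \code{high_vs_HC}, \code{low_vs_HC},
#'   \code{high_vs_low}.
#' @export
runSubgroupDE <- function(x, group, weights = NULL,
                          fdr_max = 0.1, fc_min = 1.5, moderate = TRUE) {
  stopifnot(all(group %in% c("HC", "high", "low")))
  X <- cbind(intercept = 1,
             high = as.numeric(group == "high"),
             low = as.numeric(group == "low"))
  if (qr(X)$rank < 3) stop("need samples in all three male groups")
  fits <- fitFeatureModels(x, X, weights)
  prior <- if (moderate) estimateVariancePrior(fits$s2, fits$df) else list(d0 = 0)
  contrasts <- list(high_vs_HC = c(0, 1, 0), low_vs_HC = c(0, 0, 1),
                    high_vs_low = c(0, 1, -1))
  out <- lapply(names(contrasts), function(nm)
    contrastTable(fits, prior, contrasts[[nm]], nm, fdr_max, fc_min))
  names(out) <- names(contrasts)
  out
}

#' Logit-transform methylation fractions for differential analysis
#'
#' Fractions are clamped to [1e-4, 1 - 1e-4] before the transform; "fold
#' change" thresholds for methylation apply on this scale.
#'
#' @param x methylation OmicsMatrix or matrix of fractions in [0, 1].
#' @return matrix of logits.
#' @export
logitMethylation <- function(x) {
  m <- .asMatrixInput(x)
  out <- .logit(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Venn partition of sex-specific significance calls
#'
#' Exhaustive, mutually exclusive partition of features by significance and
#' direction in the two sexes. "Shared" requires significance in both sexes
#' with concordant LFC sign; features significant in both with opposite signs
#' are counted as discordant.
#'
#' @param female,male contrast tables (same feature universe) with columns
#'   \code{feature}, \code{lfc}, \code{significant}.
#' @return named integer vector: female_only_up, female_only_down,
#'   male_only_up, male_only_down, shared_up, shared_down, discordant.
#' @export
vennPartition <- function(female, male) {
  if (!setequal(female$feature, male$feature) ||
      nrow(female) != nrow(male))
    stop("mismatched feature universes")
  male <- male[match(female$feature, male$feature), ]
  fs <- female$significant; ms <- male$significant
  fup <- female$lfc > 0; mup <- male$lfc > 0
  c(female_only_up   = sum(fs & !ms & fup),
    female_only_down = sum(fs & !ms & !fup),
    male_only_up     = sum(ms & !fs & mup),
    male_only_down   = sum(ms & !fs & !mup),
    shared_up        = sum(fs & ms & fup & mup),
    shared_down      = sum(fs & ms & !fup & !mup),
    discordant       = sum(fs & ms & (fup != mup)))
}
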