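#' Filter protein assays by limit of detection
#'
#' Measurements flagged FAIL are set missing first; an assay is kept iff the
#' fraction of samples strictly above its LOD is strictly greater than
#' \code{min_frac} ("more than 75\% of samples").
#'
#' @param npx protein NPX \linkS4class{OmicsMatrix} (or matrix), assays in rows.
#' @param lod named numeric vector of per-assay LODs (NPX units); every assay
#'   present in \code{npx} must have one.
#' @param flags optional character matrix (same shape as the data) of
#'   "PASS"/"FAIL" measurement QC flags.
#' @param min_frac detection-fraction threshold (default 0.75, strict).
#' @return OmicsMatrix restricted to kept assays (FAIL values set to NA).
#' @export
filterNpxByLod <- function(npx, lod, flags = NULL, min_frac = 0.75) {
  m <- .asMatrixInput(npx)
  if (is.null(names(lod)) || !all(rownames(m) %in% names(lod)))
    stop("missing LOD for assay(s): ",
         paste(head(setdiff(rownames(m), names(lod))), collapse = ", "))
  if (any(!is.finite(lod[rownames(m)]))) stop("LOD must be finite")
  if (!is.null(flags)) {
    stopifnot(identical(dim(flags), dim(m)))
    m[flags != "PASS"] <- NA
  }
  above <- sweep(m, 1, lod[rownames(m)], ">")
  above[is.na(above)] <- FALSE
  keep <- rowMeans(above) > min_frac
  out <- m[keep, , drop = FALSE]
  if (is(npx, "OmicsMatrix")) npx[keep, ] else OmicsMatrix(out, "protein_npx")
}

#' Identify low-expression outlier samples
#'
#' A sample is excluded iff its mean NPX across assays falls strictly below
#' the cohort mean minus \code{k_sd} cohort standard deviations of the
#' per-sample means.
#'
#' @param npx protein NPX OmicsMatrix or matrix.
#' @param k_sd number of standard deviations (default 4).
#' @return character vector of excluded sample ids (possibly empty).
#' @export
excludeLowExpressionSamples <- function(npx, k_sd = 4) {
  m <- .asMatrixInput(npx)
  if (ncol(m) < 3) stop("need at least 3 samples")
  sm <- colMeans(m, na.rm = TRUE)
  s <- sd(sm)
  if (!is.finite(s)) stop("cannot compute cohort SD")
  if (s == 0) return(character())
  colnames(m)[sm < mean(sm) - k_sd * s]
}

#' Filter lowly-expressed count features
#'
#' Simplified expression filter: the CPM cutoff is
#' \code{min_count / (median library size in millions)}; a feature is kept iff
#' the number of samples with CPM at or above the cutoff is at least the
#' smallest group size.
#'
#' @param counts count OmicsMatrix or matrix.
#' @param groups factor/character of group labels, one per sample.
#' @param min_count minimum count at the median library size (default 10).
#' @return character vector of kept feature ids.
#' @export
filterLowCounts <- function(counts, groups, min_count = 10) {
  m <- .asMatrixInput(counts)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(m))
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  lib <- colSums(m)
  if (any(lib <= 0)) stop("library sizes must be positive")
  cutoff <- min_count / (median(lib) / 1e6)
  cpm <- sweep(m, 2, lib, "/") * 1e6
  minGroup <- min(table(droplevels(groups)))
  rownames(m)[rowSums(cpm >= cutoff) >= minGroup]
}

#' Quantile-normalize the columns of a matrix
#'
#' After normalization every column shares the same sorted multiset (the
#' across-column mean of order statistics); ties within a column receive the
#' mean of their reference quantiles. Single-column input is returned
#' unchanged. Delegates to \code{limma::normalizeQuantiles}.
#'
#' @param x numeric matrix or OmicsMatrix without missing values.
#' @return matrix of the same shape.
#' @export
quantileNormalize <- function(x) {
  m <- .asMatrixInput(x)
  if (anyNA(m)) stop("missing values not allowed")
  if (ncol(m) < 2) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Log2 counts-per-million
#'
#' \code{log2((count + prior) / (libsize + 2 * prior) * 1e6)}, the log-CPM core
#' of the voom transform.
#'
#' @param counts count OmicsMatrix or matrix.
#' @param prior prior count (default 0.5).
#' @param lib optional library sizes (default column sums).
#' @return \code{rna_logexpr} OmicsMatrix.
#' @export
logCpm <- function(counts, prior = 0.5, lib = NULL) {
  m <- .asMatrixInput(counts)
  if (any(m < 0)) stop("negative counts")
  if (is.null(lib)) lib <- colSums(m)
  if (any(lib <= 0)) stop("library sizes must be positive")
  out <- log2(sweep(m + prior, 2, lib + 2 * prior, "/") * 1e6)
  OmicsMatrix(out, "rna_logexpr")
}

#' Precision weights from the mean-variance trend
#'
#' Fits a lowess trend of sqrt residual standard deviation against mean
#' log-expression (per feature) and returns per-observation weights equal to
#' the inverse fourth power of the interpolated trend, floored at a small
#' positive constant. With fewer than 50 features no trend is fit and unit
#' weights are returned with a warning.
#'
#' @param logexpr log-expression OmicsMatrix or matrix.
#' @param design model matrix (samples x coefficients).
#' @param span lowess span (default 0.5).
#' @return matrix of positive weights, same shape as \code{logexpr}.
#' @export
voomWeights <- function(logexpr, design, span = 0.5) {
  m <- .asMatrixInput(logexpr)
  design <- as.matrix(design)
  n <- ncol(m)
  if (n - qr(design)$rank <= 0) stop("no residual degrees of freedom")
  if (nrow(m) < 50) {
    warning("fewer than 50 features; returning unit weights")
    return(matrix(1, nrow(m), ncol(m), dimnames = dimnames(m)))
  }
  fit <- limma::lmFit(m, design)
  mu <- rowMeans(m)
  sq <- sqrt(fit$sigma)
  ok <- is.finite(sq) & is.finite(mu)
  lo <- lowess(mu[ok], sq[ok], f = span)
  trend <- approx(lo$x, lo$y, xout = m, rule = 2)$y
  w <- 1 / pmax(trend, 1e-4)^4
  matrix(w, nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Summarize site-level methylation over regions
#'
#' The value of a region is the mean of site-level methylation fractions whose
#' position lies in \code{[start, end)} on the region's chromosome; regions
#' with no covered site are NA.
#'
#' @param site_meth numeric matrix of site methylation fractions
#'   (sites x samples).
#' @param site_positions data.frame with columns \code{chromosome}, \code{pos}
#'   (0-based), rows aligned to \code{site_meth}; must be position-sorted
#'   within each chromosome.
#' @param regions data.frame with \code{gene_id}, \code{chromosome},
#'   \code{start}, \code{end} (e.g. from \code{\link{buildPromoterRegions}}).
#' @param modality modality tag of the returned matrix
#'   (default "promoter_meth").
#' @return OmicsMatrix of region-level methylation (regions x samples).
#' @export
summarizeMethylationRegions <- function(site_meth, site_positions, regions,
                                        modality = "promoter_meth") {
  stopifnot(nrow(site_meth) == nrow(site_positions))
  for (ch in unique(site_positions$chromosome)) {
    p <- site_positions$pos[site_positions$chromosome == ch]
    if (is.unsorted(p)) stop("sites must be position-sorted within chromosome ", ch)
  }
  out <- matrix(NA_real_, nrow(regions), ncol(site_meth),
                dimnames = list(regions$gene_id, colnames(site_meth)))
  for (i in seq_len(nrow(regions))) {
    sel <- site_positions$chromosome == regions$chromosome[i] &
      site_positions$pos >= regions$start[i] &
      site_positions$pos < regions$end[i]
    if (any(sel))
      out[i, ] <- colMeans(site_meth[sel, , drop = FALSE])
  }
  OmicsMatrix(out, modality)
}

#' Sex QC from per-chromosome read depths
#'
#' Compares each sample's X/autosome mean-coverage ratio with the ratio
#' expected from its reported sex (0.5 for males, 1.0 for females) and flags
#' samples deviating by more than \code{tol}. An XXY male (ratio near 1) and an
#' XO female (ratio near 0.5) are both flagged anomalous.
#'
#' @param depths numeric matrix of mean coverage, samples x chromosomes, with
#'   autosome columns named "1".."22" and an "X" column.
#' @param reported_sex character vector ("F"/"M"), one per sample.
#' @param tol flag tolerance on the ratio (default 0.25).
#' @return data.frame: sample_id, ratio, expected, flag ("pass"/"anomalous").
#' @export
sexQcReadDepth <- function(depths, reported_sex, tol = 0.25) {
  depths <- as.matrix(depths)
  stopifnot(length(reported_sex) == nrow(depths))
  if (!"X" %in% colnames(depths)) stop("missing X coverage")
  auto <- intersect(colnames(depths), as.character(1:22))
  if (!length(auto)) stop("no autosomal coverage columns")
  autoMean <- rowMeans(depths[, auto, drop = FALSE])
  if (any(autoMean <= 0)) stop("autosomal coverage must be positive")
  ratio <- depths[, "X"] / autoMean
  expected <- ifelse(reported_sex == "M", 0.5, 1.0)
  data.frame(sample_id = rownames(depths), ratio = unname(ratio),
             expected = expected,
             flag = ifelse(abs(ratio - expected) > tol, "anomalous", "pass"),
             stringsAsFactors = FALSE)
}
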