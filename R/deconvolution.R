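#' Transcripts-per-million normalization
#'
#' Per sample: length-normalized rates \code{count / length} rescaled to sum
#' to one million.
#'
#' @param counts count OmicsMatrix or matrix (genes x samples).
#' @param lengths named numeric vector of gene lengths in bases (every gene in
#'   \code{counts} must have one, > 0).
#' @return TPM matrix (columns sum to 1e6).
#' @export
tpmNormalize <- function(counts, lengths) {
  m <- .asMatrixInput(counts)
  if (is.null(names(lengths)) || !all(rownames(m) %in% names(lengths)))
    stop("missing gene length(s)")
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  rate <- m / len
  tot <- colSums(rate)
  if (any(tot == 0)) stop("all-zero sample(s): ",
                          paste(colnames(m)[tot == 0], collapse = ", "))
  sweep(rate, 2, tot, "/") * 1e6
}

.sharedGenes <- function(expr, ref) {
  shared <- intersect(rownames(expr), rownames(ref))
  if (!length(shared)) stop("empty gene intersection between mixture and reference")
  if (length(shared) < ncol(ref))
    stop("need at least as many shared genes as cell types")
  shared
}

#' Non-negative least-squares deconvolution
#'
#' Per sample, solves min ||R w - y||^2 subject to w >= 0 on the shared-gene
#' intersection (Lawson-Hanson NNLS via \code{pracma::lsqnonneg}), then
#' renormalizes the weights to proportions summing to 1.
#'
#' @param expr mixture expression matrix (genes x samples), TPM scale.
#' @param ref reference profile matrix (genes x cell types), TPM scale.
#' @return list of class \code{"proportionEstimate"}: \code{proportions}
#'   (samples x cell types), \code{method}, \code{raw} (pre-normalization
#'   weights).
#' @export
deconvolveNnls <- function(expr, ref) {
  expr <- as.matrix(expr); ref <- as.matrix(ref)
  shared <- .sharedGenes(expr, ref)
  R <- ref[shared, , drop = FALSE]
  raw <- t(apply(expr[shared, , drop = FALSE], 2, function(y)
    pracma::lsqnonneg(R, y)$x))
  colnames(raw) <- colnames(ref)
  props <- raw / pmax(rowSums(raw), .Machine$double.eps)
  structure(list(proportions = props, method = "nnls", raw = raw),
            class = "proportionEstimate")
}

#' Ordinary least-squares deconvolution
#'
#' Unconstrained per-sample least squares; negative weights are clipped to 0
#' and the remainder renormalized (raw coefficients are also returned).
#'
#' @inheritParams deconvolveNnls
#' @return \code{"proportionEstimate"} list (see \code{\link{deconvolveNnls}}).
#' @export
deconvolveOls <- function(expr, ref) {
  expr <- as.matrix(expr); ref <- as.matrix(ref)
  shared <- .sharedGenes(expr, ref)
  R <- ref[shared, , drop = FALSE]
  if (qr(R)$rank < ncol(R)) stop("collinear reference columns")
  raw <- t(qr.solve(R, expr[shared, , drop = FALSE]))
  colnames(raw) <- colnames(ref)
  clipped <- pmax(raw, 0)
  props <- clipped / pmax(rowSums(clipped), .Machine$double.eps)
  structure(list(proportions = props, method = "ols", raw = raw),
            class = "proportionEstimate")
}

#' Benchmark deconvolution estimates against flow cytometry
#'
#' Pearson correlation per mapped cell type on the overlapping samples; the
#' selection score of a (reference, method) pair is the mean of the B-cell and
#' NK-cell correlations, the pair with the highest score wins and ties are
#' broken by the B-cell correlation. Pairs with constant estimates (undefined
#' correlation) are excluded with a warning.
#'
#' @param estimates named list of \code{"proportionEstimate"} objects, one per
#'   (reference, method) pair.
#' @param flow data.frame/matrix of flow proportions with sample rownames.
#' @param mapping named character vector mapping estimate cell-type columns to
#'   flow columns; the first element is treated as B cells, the second as NK
#'   (default \code{c(B = "B", NK = "NK")}).
#' @param min_overlap minimum number of shared samples (default 10).
#' @return list of class \code{"deconvBenchmark"}: \code{table} (data.frame
#'   pair, r_B, r_NK, score), \code{selected} (name of the winning pair).
#' @export
benchmarkDeconvolution <- function(estimates, flow,
                                   mapping = c(B = "B", NK = "NK"),
                                   min_overlap = 10) {
  stopifnot(length(mapping) >= 2)
  flow <- as.matrix(flow)
  rows <- lapply(names(estimates), function(nm) {
    est <- estimates[[nm]]$proportions
    shared <- intersect(rownames(est), rownames(flow))
    if (length(shared) < min_overlap)
      stop("fewer than ", min_overlap, " overlapping samples for ", nm)
    ct <- names(mapping)
    if (!all(ct %in% colnames(est)) || !all(mapping %in% colnames(flow)))
      stop("no mappable cell types for ", nm)
    r <- vapply(seq_along(mapping), function(i) {
      e <- est[shared, ct[i]]; f <- flow[shared, mapping[i]]
      if (sd(e) == 0 || sd(f) == 0) NA_real_ else cor(e, f)
    }, 0)
    data.frame(pair = nm, r_B = r[1], r_NK = r[2],
               score = mean(r[1:2]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  bad <- !is.finite(tab$score)
  if (any(bad)) {
    warning("excluding pair(s) with undefined correlation: ",
            paste(tab$pair[bad], collapse = ", "))
    tab_ok <- tab[!bad, , drop = FALSE]
  } else tab_ok <- tab
  if (!nrow(tab_ok)) stop("no pair with a defined benchmark score")
  o <- order(-tab_ok$score, -tab_ok$r_B)
  structure(list(table = tab, selected = tab_ok$pair[o[1]]),
            class = "deconvBenchmark")
}
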