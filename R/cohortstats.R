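#' Default type I interferon signature genes
#' @export
IFN_SIGNATURE_GENES <- c("MX1", "OAS3", "LY6E", "USP18", "IFI44", "DDX60")

#' Interferon signature score
#'
#' Per-gene z-score across samples, then per-sample mean of the available gene
#' z-scores. Genes absent from the matrix or with zero variance are dropped
#' (and reported); if no signature gene remains the call is an error.
#'
#' @param logexpr log-expression OmicsMatrix or matrix (genes x samples).
#' @param genes signature gene ids (default the 6-gene type I IFN panel).
#' @return named numeric vector of per-sample scores; attribute
#'   \code{genes_used} records the genes that entered the score.
#' @export
ifnSignature <- function(logexpr, genes = IFN_SIGNATURE_GENES) {
  m <- .asMatrixInput(logexpr)
  present <- intersect(genes, rownames(m))
  if (!length(present)) stop("none of the signature genes are present")
  sub <- m[present, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  use <- sds > 0
  if (!any(use)) stop("all signature genes constant across samples")
  z <- (sub[use, , drop = FALSE] - rowMeans(sub[use, , drop = FALSE])) /
    sds[use]
  score <- colMeans(z)
  attr(score, "genes_used") <- present[use]
  score
}

#' Spearman rank correlation
#'
#' Average ranks for ties; p-value from the t approximation on rho.
#'
#' @param x,y paired numeric vectors (>= 4 complete pairs).
#' @return list with \code{rho}, \code{p.value}, \code{n}.
#' @export
spearmanCorr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 4) stop("need at least 4 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) stop("zero rank variance")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = sum(ok))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when the smaller group has at most 10 observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with \code{U} (rank-sum statistic of \code{a}), \code{p.value}
#'   and \code{exact} (logical).
#' @export
wilcoxonRankSum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 10 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value, exact = exact)
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction; sets a warning flag when any expected count
#' is below 5. A zero row or column margin is an error.
#'
#' @param tab contingency table (matrix, 2x2 or larger).
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{low_expected} (logical flag).
#' @export
chisqTest <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero margin")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, low_expected = any(ct$expected < 5))
}

#' Clinical screen of numeric and categorical variables between two groups
#'
#' Wilcoxon rank-sum per numeric variable and chi-square per categorical
#' variable; BH correction within each test family separately. Variables with
#' fewer than 2 non-missing values in either group are skipped and logged in
#' the \code{skipped} attribute.
#'
#' @param data data.frame of clinical variables (rows = samples).
#' @param group two-level factor/character over rows of \code{data}.
#' @param numeric_vars,categorical_vars column names to screen.
#' @return data.frame (ScreenTable): variable, test, family, statistic, p,
#'   fdr; attribute \code{skipped}.
#' @export
clinicalScreen <- function(data, group, numeric_vars = character(),
                           categorical_vars = character()) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2) stop("group must have exactly 2 levels")
  skipped <- character()
  rows <- list()
  for (v in numeric_vars) {
    x <- data[[v]]
    n1 <- sum(is.finite(x[g == levels(g)[1]]))
    n2 <- sum(is.finite(x[g == levels(g)[2]]))
    if (n1 < 2 || n2 < 2) { skipped <- c(skipped, v); next }
    w <- wilcoxonRankSum(x[g == levels(g)[1]], x[g == levels(g)[2]])
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, test = "wilcoxon", family = "numeric",
      statistic = w$U, p = w$p.value, stringsAsFactors = FALSE)
  }
  for (v in categorical_vars) {
    x <- data[[v]]
    ok <- !is.na(x)
    if (sum(ok & g == levels(g)[1]) < 2 || sum(ok & g == levels(g)[2]) < 2) {
      skipped <- c(skipped, v); next
    }
    tab <- table(g[ok], x[ok])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) { skipped <- c(skipped, v); next }
    cs <- chisqTest(tab)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, test = "chisq", family = "categorical",
      statistic = cs$statistic, p = cs$p.value, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), test = character(),
               family = character(), statistic = numeric(), p = numeric(),
               stringsAsFactors = FALSE)
  out$fdr <- NA_real_
  for (fam in unique(out$family))
    out$fdr[out$family == fam] <- bhAdjust(out$p[out$family == fam])
  if (length(skipped)) message("skipped variable(s): ",
                               paste(skipped, collapse = ", "))
  attr(out, "skipped") <- skipped
  out
}

#' Spearman screen of a feature against a covariate table
#'
#' Per-covariate Spearman correlation of a feature (e.g. XIST expression) with
#' BH correction within the screen family; optionally stratified (one row per
#' stratum x covariate, BH within each stratum).
#'
#' @param feature named numeric vector (e.g. per-sample expression).
#' @param covariates data.frame of numeric covariates, rows aligned to
#'   \code{feature}.
#' @param strata optional stratification labels (e.g. sex) aligned to
#'   \code{feature}; NULL = pooled.
#' @param min_n minimum complete pairs per covariate (default 4; fewer are
#'   skipped).
#' @return data.frame: stratum, variable, rho, n, p, fdr.
#' @export
correlateFeaturesWithCovariates <- function(feature, covariates, strata = NULL,
                                            min_n = 4) {
  if (is.null(strata)) strata <- rep("all", length(feature))
  rows <- list()
  for (s in unique(strata)) {
    sel <- strata == s
    part <- list()
    for (v in names(covariates)) {
      x <- feature[sel]; y <- covariates[[v]][sel]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_n || sd(rank(x[ok])) == 0 || sd(rank(y[ok])) == 0)
        next
      sc <- spearmanCorr(x, y)
      part[[length(part) + 1]] <- data.frame(
        stratum = s, variable = v, rho = sc$rho, n = sc$n, p = sc$p.value,
        stringsAsFactors = FALSE)
    }
    if (length(part)) {
      d <- do.call(rbind, part)
      d$fdr <- bhAdjust(d$p)
      rows[[length(rows) + 1]] <- d
    }
  }
  if (!length(rows)) stop("no testable covariates")
  do.call(rbind, rows)
}
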