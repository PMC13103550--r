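#' Rank features by log fold change
#'
#' Descending LFC; ties broken by ascending p-value, then lexicographic
#' feature id, so the order is a strict total order.
#'
#' @param contrast_table data.frame with columns \code{feature}, \code{lfc}
#'   and (optionally) \code{p}.
#' @return data.frame \code{gene}, \code{score} in ranking order.
#' @export
rankByLfc <- function(contrast_table) {
  if (anyDuplicated(contrast_table$feature)) stop("duplicate feature ids")
  p <- if ("p" %in% names(contrast_table)) contrast_table$p else
    rep(0, nrow(contrast_table))
  o <- order(-contrast_table$lfc, p, contrast_table$feature)
  data.frame(gene = contrast_table$feature[o], score = contrast_table$lfc[o],
             stringsAsFactors = FALSE)
}

# weighted Kolmogorov-Smirnov running-sum enrichment score, evaluated only at
# hit boundaries (equivalent to the full running sum); returns the signed
# maximum deviation and the index of the extremum hit
.esStat <- function(absw, pos, n_total) {
  K <- length(pos)
  Nm <- n_total - K
  w <- absw[pos]
  W <- sum(w)
  cw <- cumsum(w) / W
  miss <- (pos - seq_len(K)) / Nm         # misses accumulated before hit i
  peak <- cw - miss                        # running sum just after hit i
  valley <- c(0, cw[-K]) - miss            # just before hit i
  maxp <- max(peak, 0)
  minv <- min(valley, 0)
  if (maxp >= -minv) {
    list(es = maxp, at = if (maxp > 0) which.max(peak) else 0L)
  } else {
    list(es = minv, at = -which.min(valley))
  }
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted running-sum statistic on a ranked list: hits increment by
#' |score|^w normalized over in-set scores, misses decrement by 1/(N - Nh);
#' ES is the signed maximum deviation. The null is gene-label permutation
#' (random sets of the same size); NES divides ES by the mean |null ES| of the
#' same sign, the permutation p is one-sided with the add-one rule, and FDR is
#' BH across reported sets.
#'
#' @param ranked data.frame from \code{\link{rankByLfc}} (columns gene, score,
#'   descending).
#' @param sets named list of gene-id vectors.
#' @param weight_exponent weight w on |score| (default 1). If all scores are 0
#'   with w > 0 the statistic degenerates; the function falls back to w = 0
#'   with a warning.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional RNG seed.
#' @param min_size,max_size set-size bounds after intersecting with the ranked
#'   universe; sets outside are skipped.
#' @return data.frame: set, size, es, nes, p, fdr, leading_edge
#'   (comma-separated gene ids up to the ES extremum).
#' @export
gseaPreranked <- function(ranked, sets, weight_exponent = 1, n_perm = 10000,
                          seed = NULL, min_size = 5, max_size = 5000) {
  if (!nrow(ranked)) stop("empty ranked list")
  if (anyDuplicated(ranked$gene)) stop("duplicate gene ids in ranked list")
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(ranked)
  genes <- ranked$gene
  if (all(ranked$score == 0) && weight_exponent > 0) {
    warning("all scores zero; falling back to weight_exponent = 0")
    weight_exponent <- 0
  }
  absw <- abs(ranked$score)^weight_exponent
  idx <- lapply(sets, function(s) which(genes %in% s))
  sizes <- lengths(idx)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (!any(keep))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), fdr = numeric(),
                      leading_edge = character(), stringsAsFactors = FALSE))
  idx <- idx[keep]
  res <- lapply(names(idx), function(nm) {
    pos <- sort(idx[[nm]])
    K <- length(pos)
    obs <- .esStat(absw, pos, N)
    nullES <- vapply(seq_len(n_perm), function(b)
      .esStat(absw, sort(sample.int(N, K)), N)$es, 0)
    same <- if (obs$es >= 0) nullES[nullES >= 0] else nullES[nullES < 0]
    nes <- if (length(same) && mean(abs(same)) > 0)
      obs$es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (n_perm + 1)
    le <- if (obs$at > 0) genes[pos[seq_len(obs$at)]]
    else if (obs$at < 0) genes[pos[(-obs$at):K]]
    else character()
    data.frame(set = nm, size = K, es = obs$es, nes = nes, p = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bhAdjust(out$p)
  out[, c("set", "size", "es", "nes", "p", "fdr", "leading_edge")]
}

#' Hypergeometric over-representation test
#'
#' Exact upper-tail probability of observing at least the seen overlap between
#' a query gene list and a gene set within a universe.
#'
#' @param query character vector of query gene ids (subset of universe).
#' @param set character vector of gene-set members.
#' @param universe character vector of all tested gene ids.
#' @return list: k (overlap), K (set size in universe), n (query size),
#'   N (universe size), p.value.
#' @export
hypergeometricOra <- function(query, set, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  set <- intersect(unique(set), universe)
  k <- length(intersect(query, set))
  K <- length(set)
  n <- length(query)
  N <- length(universe)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p.value = p)
}

#' Chromosome-level silencing scan across modalities
#'
#' One preranked GSEA per contrast table against the chromosome/PAR gene sets.
#' Ranking is by LFC (descending), so for methylation a positive NES means
#' enrichment of hypermethylation, while for transcripts/proteins a negative
#' NES means enrichment of downregulation; this convention is recorded in the
#' \code{direction_note} attribute of the result.
#'
#' @param contrast_tables named list of contrast tables (name them e.g.
#'   \code{"promoter_meth.male_SLE_vs_HC"}).
#' @param chromosome_sets named list from
#'   \code{\link{buildChromosomeGeneSets}} (or any GMT sets).
#' @param n_perm,seed,min_size,weight_exponent passed to
#'   \code{\link{gseaPreranked}}; sets below \code{min_size} in a modality are
#'   skipped (absent from the output).
#' @return data.frame with a \code{table} column plus the
#'   \code{\link{gseaPreranked}} columns; FDR is BH across the chromosome sets
#'   within each table.
#' @export
chromosomeSilencingScan <- function(contrast_tables, chromosome_sets,
                                    n_perm = 1000, seed = NULL, min_size = 5,
                                    weight_exponent = 1) {
  stopifnot(length(names(contrast_tables)) == length(contrast_tables))
  res <- lapply(names(contrast_tables), function(nm) {
    ranked <- rankByLfc(contrast_tables[[nm]])
    g <- gseaPreranked(ranked, chromosome_sets,
                       weight_exponent = weight_exponent, n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else
                         .deriveSeed(seed, nm),
                       min_size = min_size)
    if (nrow(g)) cbind(table = nm, g, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, res)
  attr(out, "direction_note") <-
    "positive NES = enrichment at the top of the LFC ranking (hypermethylation for methylation modalities); negative NES = enrichment of downregulation"
  out
}

#' Fraction of significant features that are X-linked
#'
#' Counts members of one chromosome set among a significant feature list and
#' tests enrichment against the tested universe with the hypergeometric law.
#'
#' @param significant character vector of significant feature ids (one stated
#'   direction, e.g. hypermethylated).
#' @param chromosome_sets named list of chromosome gene sets.
#' @param universe all tested feature ids of the modality.
#' @param chromosome which set to count (default "X").
#' @return list: k, n, fraction (NA when \code{significant} is empty),
#'   p.value.
#' @export
xlinkedFractionSummary <- function(significant, chromosome_sets, universe,
                                   chromosome = "X") {
  xset <- intersect(chromosome_sets[[chromosome]], universe)
  if (!length(xset))
    stop("chromosome set ", chromosome, " absent from the universe")
  if (!length(significant))
    return(list(k = 0L, n = 0L, fraction = NA_real_, p.value = NA_real_))
  ora <- hypergeometricOra(significant, xset, universe)
  list(k = ora$k, n = ora$n, fraction = ora$k / ora$n, p.value = ora$p.value)
}

#' Silencing summary over an X-inactivation gene panel
#'
#' Among panel genes present in the tested universe, counts genes
#' downregulated at the FDR threshold (LFC < 0, FDR < fdr_max) and the subset
#' that additionally passes the fold-change threshold.
#'
#' @param contrast_table contrast table (feature, lfc, fdr).
#' @param panel character vector of panel gene ids.
#' @param fdr_max,fc_min thresholds (defaults 0.1 and 1.5).
#' @return list: n_panel_tested, n_down, n_strong_down, fraction_down,
#'   fraction_strong_down.
#' @export
xciPanelSummary <- function(contrast_table, panel, fdr_max = 0.1,
                            fc_min = 1.5) {
  tab <- contrast_table[contrast_table$feature %in% panel, ]
  if (!nrow(tab)) stop("no panel genes in the tested universe")
  down <- tab$lfc < 0 & tab$fdr < fdr_max
  strong <- down & abs(tab$lfc) > log2(fc_min)
  list(n_panel_tested = nrow(tab), n_down = sum(down),
       n_strong_down = sum(strong),
       fraction_down = sum(down) / nrow(tab),
       fraction_strong_down = sum(strong) / nrow(tab))
}
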