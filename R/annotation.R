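#' Gene annotation, promoter windows and chromosome gene sets
#'
#' Coordinates are 0-based, half-open everywhere in this package. The TSS of a
#' gene is \code{start} on the + strand and \code{end - 1} on the - strand.
#'
#' @name annotation
NULL

#' Default pseudoautosomal intervals (GRCh38)
#'
#' PAR1 and PAR2 on X and Y as 0-based half-open intervals. Genes whose TSS
#' falls inside one of these intervals are assigned to the "PAR" gene set
#' instead of "X"/"Y".
#'
#' @return data.frame with columns \code{chromosome}, \code{start}, \code{end}.
#' @examples
#' grch38ParIntervals()
#' @export
grch38ParIntervals <- function() {
  data.frame(
    chromosome = c("X", "X", "Y", "Y"),
    start = c(10000L, 155701382L, 10000L, 56887902L),
    end   = c(2781479L, 156030895L, 2781479L, 57217415L),
    stringsAsFactors = FALSE)
}

.validateParIntervals <- function(par) {
  stopifnot(all(c("chromosome", "start", "end") %in% names(par)))
  if (!all(par$chromosome %in% c("X", "Y")))
    stop("PAR intervals must be on X or Y")
  if (any(par$start >= par$end)) stop("PAR intervals need start < end")
  for (ch in unique(par$chromosome)) {
    p <- par[par$chromosome == ch, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)]))
      stop("PAR intervals overlap within chromosome ", ch)
  }
  invisible(par)
}

#' Read a GTF-lite gene annotation table
#'
#' Tab-separated file with header columns \code{gene_id}, \code{chromosome},
#' \code{start}, \code{end}, \code{strand} (0-based half-open span). The TSS is
#' derived as \code{start} for + strand genes and \code{end - 1} for - strand
#' genes. Genes on non-canonical chromosomes are rejected.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns gene_id, chromosome, start, end, strand, tss.
#' @export
readGeneAnnotation <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start", "end", "strand")
  if (!all(need %in% names(d)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  makeGeneAnnotation(d[, need])
}

#' Build/validate a gene annotation table
#'
#' @param d data.frame with gene_id, chromosome, start, end, strand (and
#'   optionally tss, which is recomputed).
#' @return validated annotation data.frame with a \code{tss} column.
#' @export
makeGeneAnnotation <- function(d) {
  d$chromosome <- as.character(d$chromosome)
  d$strand <- as.character(d$strand)
  if (anyDuplicated(d$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(head(unique(d$gene_id[duplicated(d$gene_id)])), collapse = ", "))
  if (!all(d$chromosome %in% .CHROMOSOMES))
    stop("unknown chromosome label(s): ",
         paste(head(setdiff(unique(d$chromosome), .CHROMOSOMES)), collapse = ", "))
  if (!all(d$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(d$start < 0) || any(d$end <= d$start))
    stop("gene spans must satisfy 0 <= start < end")
  d$tss <- ifelse(d$strand == "+", d$start, d$end - 1L)
  rownames(d) <- NULL
  d
}

#' Derive promoter windows around each TSS
#'
#' A promoter spans \code{upstream} bases in the anti-transcription direction
#' and \code{downstream} bases starting at the TSS, so every unclipped region
#' has length \code{upstream + downstream}. Coordinates are clipped at 0.
#'
#' @param annotation annotation data.frame from \code{\link{readGeneAnnotation}}.
#' @param upstream,downstream window sizes in bp (defaults 2000 and 200).
#' @return data.frame gene_id, chromosome, start, end, strand.
#' @examples
#' ann <- makeGeneAnnotation(data.frame(
#'   gene_id = c("a", "b"), chromosome = "X",
#'   start = c(10000, 8000), end = c(12000, 10001), strand = c("+", "-")))
#' buildPromoterRegions(ann)
#' @export
buildPromoterRegions <- function(annotation, upstream = 2000L, downstream = 200L) {
  if (upstream < 0 || downstream < 0) stop("window sizes must be non-negative")
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - upstream,
                  annotation$tss - downstream + 1L)
  end <- ifelse(plus, annotation$tss + downstream,
                annotation$tss + upstream + 1L)
  data.frame(gene_id = annotation$gene_id,
             chromosome = annotation$chromosome,
             start = pmax(start, 0L), end = end,
             strand = annotation$strand, stringsAsFactors = FALSE)
}

#' Partition genes into chromosome gene sets with a PAR set
#'
#' Every annotated gene is assigned to exactly one set: "PAR" if its TSS lies
#' inside a pseudoautosomal interval, otherwise its chromosome label. PAR genes
#' appear in neither "X" nor "Y".
#'
#' @param annotation annotation data.frame.
#' @param par PAR intervals (data.frame chromosome/start/end, 0-based
#'   half-open); defaults to the GRCh38 PARs.
#' @return named list of gene-id character vectors; names are chromosome labels
#'   plus "PAR". Empty sets are kept.
#' @export
buildChromosomeGeneSets <- function(annotation, par = grch38ParIntervals()) {
  .validateParIntervals(par)
  inPar <- rep(FALSE, nrow(annotation))
  for (i in seq_len(nrow(par))) {
    inPar <- inPar | (annotation$chromosome == par$chromosome[i] &
                        annotation$tss >= par$start[i] &
                        annotation$tss < par$end[i])
  }
  lab <- ifelse(inPar, "PAR", annotation$chromosome)
  sets <- split(annotation$gene_id, factor(lab, levels = c(.CHROMOSOMES, "PAR")))
  lapply(sets, as.character)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' \code{name <TAB> description <TAB> member ...}. Duplicate or blank set names
#' are an error.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 2L
  if (any(bad)) stop("malformed GMT line(s): need name, description, members")
  nms <- vapply(parts, `[[`, "", 1L)
  if (any(!nzchar(nms))) stop("blank set name in GMT")
  if (anyDuplicated(nms)) stop("duplicate set names in GMT: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' Inverse of \code{\link{readGmt}} up to member order; write-then-read
#' preserves set membership exactly.
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, members)
    paste(c(nm, desc, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Write regions as BED3+name
#'
#' Chromosome, start, end (0-based half-open, as BED expects) and the gene id
#' as the name column; no header.
#'
#' @param regions data.frame with chromosome, start, end, gene_id (e.g. from
#'   \code{\link{buildPromoterRegions}}).
#' @param path output path.
#' @export
writeBedRegions <- function(regions, path) {
  write.table(regions[, c("chromosome", "start", "end", "gene_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a feature matrix as TSV
#'
#' TSV with feature ids in the first column and a header row of sample ids.
#'
#' @param path file path.
#' @param modality modality tag for the returned \linkS4class{OmicsMatrix}.
#' @return \code{readFeatureMatrix}: an OmicsMatrix.
#' @export
readFeatureMatrix <- function(path, modality) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  OmicsMatrix(m, modality)
}

#' @rdname readFeatureMatrix
#' @param x OmicsMatrix or matrix to write.
#' @export
writeFeatureMatrix <- function(x, path) {
  m <- .asMatrixInput(x)
  d <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
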