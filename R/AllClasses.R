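#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx aov coef cor cor.test density lm lowess mad median
#'   model.matrix p.adjust pchisq phyper plogis pnorm pt qlogis quantile rbinom
#'   rlnorm rnbinom rnorm runif sd setNames var wilcox.test chisq.test bw.SJ
#'   bw.nrd0 rgamma anova
#' @importFrom utils read.delim write.table head tail
NULL

.MODALITIES <- c("promoter_meth", "gene_meth", "rna_counts", "rna_logexpr",
                 "protein_npx")

.CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT")

#' OmicsMatrix: a feature-by-sample matrix for one modality
#'
#' Thin extension of \linkS4class{SummarizedExperiment} carrying a single
#' assay (\code{"values"}) plus a modality tag that fixes the value-scale
#' semantics: methylation modalities hold region-level fractions in [0, 1],
#' \code{rna_counts} holds non-negative read counts, \code{rna_logexpr} and
#' \code{protein_npx} hold log2-scale values.
#'
#' @slot modality one of \code{"promoter_meth"}, \code{"gene_meth"},
#'   \code{"rna_counts"}, \code{"rna_logexpr"}, \code{"protein_npx"}.
#' @export
setClass("OmicsMatrix",
         contains = "SummarizedExperiment",
         representation(modality = "character"))

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    msg <- c(msg, paste("modality must be one of:",
                        paste(.MODALITIES, collapse = ", ")))
  v <- SummarizedExperiment::assay(object)
  if (nrow(v) > 0 && (is.null(rownames(v)) || anyDuplicated(rownames(v))))
    msg <- c(msg, "feature ids must be unique and non-null")
  if (ncol(v) > 0 && (is.null(colnames(v)) || anyDuplicated(colnames(v))))
    msg <- c(msg, "sample ids must be unique and non-null")
  fin <- v[!is.na(v)]
  if (length(object@modality) == 1L && object@modality %in% .MODALITIES) {
    if (object@modality %in% c("promoter_meth", "gene_meth") &&
        length(fin) && (min(fin) < 0 || max(fin) > 1))
      msg <- c(msg, "methylation values must lie in [0, 1]")
    if (object@modality == "rna_counts" && length(fin) &&
        (min(fin) < 0 || any(!is.finite(fin))))
      msg <- c(msg, "counts must be non-negative and finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix with feature row names and sample column names.
#' @param modality modality tag (see \linkS4class{OmicsMatrix}).
#' @param sampleData optional data.frame of per-sample annotation, rows aligned
#'   to the columns of \code{values}.
#' @return An \linkS4class{OmicsMatrix}.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' om <- OmicsMatrix(m, "rna_counts")
#' modality(om)
#' @export
OmicsMatrix <- function(values, modality, sampleData = NULL) {
  values <- as.matrix(values)
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(values))
  } else {
    stopifnot(nrow(sampleData) == ncol(values))
    S4Vectors::DataFrame(sampleData, row.names = colnames(values))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values), colData = cd)
  new("OmicsMatrix", se, modality = modality)
}

#' @rdname OmicsMatrix
#' @param object,x an OmicsMatrix.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname OmicsMatrix
#' @export
setMethod("modality", "OmicsMatrix", function(x) x@modality)

#' @rdname OmicsMatrix
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname OmicsMatrix
#' @export
setMethod("featureValues", "OmicsMatrix",
          function(x) SummarizedExperiment::assay(x, "values"))

setMethod("show", "OmicsMatrix", function(object) {
  cat("OmicsMatrix [", object@modality, "]: ",
      nrow(object), " features x ", ncol(object), " samples\n", sep = "")
})

# keep the modality tag across [ subsetting
setMethod("[", c("OmicsMatrix", "ANY", "ANY"), function(x, i, j, ..., drop = FALSE) {
  se <- callNextMethod()
  new("OmicsMatrix", se, modality = x@modality)
})
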