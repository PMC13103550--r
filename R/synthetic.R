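#' Specification of a synthetic multi-omic cohort
#'
#' Defaults mirror the structure of a large SLE trial cohort: a 4-cell
#' sex-by-disease design (679 female SLE, 77 female HC, 41 male SLE, 7 male
#' HC), bimodal XIST expression in male SLE (54\% high mode, modes separated
#' by 6 within-mode SDs, mean male interaction LFC 4.71), X-chromosome
#' hypermethylation confined to male SLE, modest X-transcript downregulation
#' in SLE of both sexes, shared interferon-gene upregulation, and a protein
#' panel with sparse X coverage (66 of 2434 assays).
#'
#' @param n_F_SLE,n_F_HC,n_M_SLE,n_M_HC cell sizes (>= 1).
#' @param n_genes,n_meth_features,n_proteins per-modality feature counts (the
#'   two methylation matrices share the gene universe of the RNA matrix when
#'   \code{n_meth_features == n_genes}).
#' @param x_fraction,y_fraction,mt_fraction,n_par_genes chromosome composition
#'   of the gene universe.
#' @param protein_x_count number of X-linked protein assays.
#' @param interaction_lfc planted sex-by-disease interaction LFC of the
#'   XIST-like transcript (mean over the male SLE mixture).
#' @param pi_high fraction of male SLE samples in the XIST-high mode.
#' @param delta_sd separation of the two XIST modes in within-mode SDs.
#' @param delta_meth logit-scale hypermethylation shift applied to affected X
#'   features in male SLE.
#' @param f_x_meth fraction of (non-PAR) X methylation features affected.
#' @param x_down_lfc,f_x_down log2 downshift applied in SLE (both sexes) to a
#'   fraction of X transcripts.
#' @param ifn_lfc upshift of interferon genes in SLE (both sexes).
#' @param n_ifn_extra additional unnamed interferon-module genes.
#' @param protein_sle_lfc,n_protein_sle shared SLE protein shift and count.
#' @param n_protein_interaction,protein_interaction_lfc proteins with a
#'   male-SLE-only shift.
#' @param nb_dispersion negative-binomial dispersion of RNA counts.
#' @param meth_sd,npx_sd Gaussian noise SDs (logit / NPX log2 scale).
#' @param lib_size_mean,lib_size_cv log-normal library-size model.
#' @param qpcr_slope,qpcr_intercept,ct_sd qPCR calibration
#'   (Ct = intercept - slope * log2 expression + noise).
#' @param n_missing_qpcr male SLE samples lacking qPCR (classified via
#'   RNA-seq).
#' @param lod_fail_fraction fraction of protein assays with an elevated LOD
#'   (detected in < 75\% of samples).
#' @param flag_fail_fraction fraction of protein measurements flagged FAIL.
#' @param n_xxy,n_xo planted karyotype anomalies (XXY male, XO female).
#' @param n_clinical_null numbers of pure-noise numeric clinical variables.
#' @param noise global noise multiplier; 0 gives the deterministic mean field
#'   (counts are then non-integer expectations and latent classes are assigned
#'   deterministically).
#' @param seed RNG seed.
#' @return validated list of class \code{"cohortSpec"}.
#' @export
cohortSpec <- function(n_F_SLE = 679, n_F_HC = 77, n_M_SLE = 41, n_M_HC = 7,
                       n_genes = 5000, n_meth_features = 5000,
                       n_proteins = 2434,
                       x_fraction = 0.05, y_fraction = 0.01,
                       mt_fraction = 0.005, n_par_genes = 20,
                       protein_x_count = 66,
                       interaction_lfc = 4.71, pi_high = 0.54, delta_sd = 6,
                       delta_meth = 1.0, f_x_meth = 0.5,
                       x_down_lfc = -0.4, f_x_down = 0.5,
                       ifn_lfc = 2.0, n_ifn_extra = 24,
                       protein_sle_lfc = 1.2, n_protein_sle = 30,
                       n_protein_interaction = 10,
                       protein_interaction_lfc = 1.0,
                       nb_dispersion = 0.1, meth_sd = 0.5, npx_sd = 0.5,
                       lib_size_mean = 3e6, lib_size_cv = 0.3,
                       qpcr_slope = 1, qpcr_intercept = 35, ct_sd = 0.15,
                       n_missing_qpcr = 3,
                       lod_fail_fraction = 0.08, flag_fail_fraction = 0.01,
                       n_xxy = 1, n_xo = 1,
                       n_clinical_null = 12,
                       noise = 1, seed = 1) {
  spec <- as.list(environment())
  with(spec, {
    stopifnot(n_F_SLE >= 1, n_F_HC >= 1, n_M_SLE >= 1, n_M_HC >= 1,
              pi_high > 0, pi_high < 1, delta_sd > 0,
              f_x_meth >= 0, f_x_meth <= 1, f_x_down >= 0, f_x_down <= 1,
              noise >= 0, n_genes >= 20)
  })
  class(spec) <- "cohortSpec"
  spec
}

# deterministic cell-type reference: 5 leukocyte populations with marker genes
.CELL_TYPES <- c("B", "NK", "T_CD4", "T_CD8", "Neutrophils")

.simulateAnnotation <- function(spec) {
  nfeat <- max(spec$n_genes, spec$n_meth_features)
  n_special <- 8L  # 6 IFN genes + IFI44L + XIST
  aut <- as.character(1:22)
  pAut <- rep((1 - spec$x_fraction - spec$y_fraction - spec$mt_fraction) / 22,
              22)
  chrom <- sample(c(aut, "X", "Y", "MT"), nfeat, replace = TRUE,
                  prob = c(pAut, spec$x_fraction, spec$y_fraction,
                           spec$mt_fraction))
  if (spec$x_fraction <= 0)
    stop("infeasible spec: no X features (the XIST-like transcript and the ",
         "planted X effects need X-chromosome genes)")
  nRna <- min(spec$n_genes, nfeat)
  # force workable minima of non-PAR X genes inside the RNA block (the first
  # nRna features form the transcript universe) and across the annotation
  forceX <- function(block, minX) {
    xiB <- intersect(which(chrom == "X"), block)
    if (length(xiB) < minX) {
      pool <- intersect(which(chrom %in% aut), block)
      chrom[sample(pool, minX - length(xiB))] <<- "X"
    }
  }
  forceX(seq_len(nRna), min(40, max(10, round(nRna / 8))))
  forceX(seq_len(nfeat), spec$n_par_genes + 60)
  ids <- sprintf("g%05d", seq_len(nfeat))
  # name the planted genes inside the RNA block (autosomal IFN panel +
  # X-linked XIST)
  ifn <- c(IFN_SIGNATURE_GENES, "IFI44L")
  autIdx <- intersect(which(chrom %in% aut), seq_len(nRna))
  ids[autIdx[seq_along(ifn)]] <- ifn
  xIdx <- which(chrom == "X")
  xistIdx <- intersect(xIdx, seq_len(nRna))[1]
  ids[xistIdx] <- "XIST"
  lenChrom <- c(setNames(rep(1.5e8, 22), aut),
                X = 156040895, Y = 57227415, MT = 16569)
  hiTss <- ifelse(chrom == "X", 1.5e8,
                  ifelse(chrom == "Y", 5.5e7,
                         pmax(lenChrom[chrom] - 2e5, 1.5e4)))
  loTss <- ifelse(chrom %in% c("X", "Y"), 3e6, 1)
  tss <- round(loTss + runif(nfeat) * (hiTss - loTss))
  # PAR genes: a random subset of non-XIST X genes gets a TSS inside PAR1
  if (spec$n_par_genes > 0) {
    parIdx <- sample(setdiff(xIdx, xistIdx), spec$n_par_genes)
    tss[parIdx] <- round(runif(length(parIdx), 2e4, 2.7e6))
  }
  strand <- sample(c("+", "-"), nfeat, replace = TRUE)
  glen <- round(rlnorm(nfeat, log(2e4), 0.8))
  start <- ifelse(strand == "+", tss, pmax(tss + 1 - glen, 0))
  end <- ifelse(strand == "+", tss + glen, tss + 1)
  makeGeneAnnotation(data.frame(
    gene_id = ids, chromosome = chrom, start = start, end = end,
    strand = strand, stringsAsFactors = FALSE))
}

#' Simulate a multi-omic cohort with planted effect structure
#'
#' Generates RNA-seq counts (negative binomial around a cell-type mixture
#' baseline), promoter and gene methylation (logit-normal fractions), a
#' protein NPX panel with per-assay LODs and QC flags, qPCR Ct values, flow
#' proportions and clinical variables, together with the ground truth needed
#' by recovery tests. Deterministic given the spec's seed.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return list with elements \code{matrices} (named list of
#'   \linkS4class{OmicsMatrix}: rna_counts, promoter_meth, gene_meth,
#'   protein_npx), \code{samples} (sample table), \code{annotation},
#'   \code{lod}, \code{flags}, \code{reference} (generating cell-type
#'   profile), \code{gene_lengths}, and \code{truth} (planted values; consumed
#'   only by tests and benchmarks).
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  noise <- spec$noise

  ## ---- samples --------------------------------------------------------
  cells <- c(F_SLE = spec$n_F_SLE, F_HC = spec$n_F_HC,
             M_SLE = spec$n_M_SLE, M_HC = spec$n_M_HC)
  nS <- sum(cells)
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(nS)),
    sex = rep(c("F", "F", "M", "M"), cells),
    disease = rep(c("SLE", "HC", "SLE", "HC"), cells),
    stringsAsFactors = FALSE)
  samples$group <- paste(samples$sex, samples$disease, sep = "_")
  rownames(samples) <- samples$sample_id
  karyo <- ifelse(samples$sex == "F", "XX", "XY")
  mSle <- which(samples$group == "M_SLE")
  fSle <- which(samples$group == "F_SLE")
  if (spec$n_xxy > 0) karyo[mSle[seq_len(min(spec$n_xxy, length(mSle)))]] <- "XXY"
  if (spec$n_xo > 0) karyo[fSle[seq_len(min(spec$n_xo, length(fSle)))]] <- "XO"

  ## ---- annotation and gene sets ---------------------------------------
  ann <- .simulateAnnotation(spec)
  geneIds <- ann$gene_id[seq_len(spec$n_genes)]
  annRna <- ann[seq_len(spec$n_genes), ]
  sets <- buildChromosomeGeneSets(annRna)
  xGenes <- setdiff(sets$X, "XIST")
  if (spec$f_x_meth > 0 && !length(xGenes)) stop("infeasible spec: no X features")

  ## ---- XIST latent and classes ----------------------------------------
  deltaHigh <- spec$interaction_lfc / spec$pi_high
  sdWithin <- deltaHigh / spec$delta_sd
  nHigh <- if (noise == 0) round(spec$pi_high * length(mSle)) else
    rbinom(1, length(mSle), spec$pi_high)
  zHigh <- integer(nS)
  zHigh[mSle[seq_len(nHigh)]] <- 1L
  xistBase <- ifelse(samples$sex == "F", 8, 3.3)
  fSdXist <- ifelse(samples$disease == "SLE", 1.5, 0.8)  # variance excess in F SLE
  xistLatent <- xistBase +
    ifelse(samples$sex == "F", rnorm(nS, 0, fSdXist * noise),
           zHigh * deltaHigh + rnorm(nS, 0, sdWithin * noise))

  ## ---- cell-type mixture baseline -------------------------------------
  nG <- spec$n_genes
  baseLog <- rnorm(nG, 4, 1.5)
  boost <- matrix(0, nG, length(.CELL_TYPES),
                  dimnames = list(geneIds, .CELL_TYPES))
  markers <- sample(nG, round(0.2 * nG))
  boost[cbind(markers, sample(length(.CELL_TYPES), length(markers),
                              replace = TRUE))] <- 3
  refLinear <- 2^(baseLog + boost)
  # equalize per-cell-type total length-normalized output (equal mRNA
  # content), so bulk TPM is linear in the mixing proportions
  geneLen <- pmax(annRna$end - annRna$start, 1)
  rateTot <- colSums(refLinear / geneLen)
  refLinear <- sweep(refLinear, 2, rateTot, "/") * mean(rateTot)
  alpha <- c(B = 0.10, NK = 0.05, T_CD4 = 0.20, T_CD8 = 0.15,
             Neutrophils = 0.50)
  eta <- matrix(log(alpha), nS, 5, byrow = TRUE,
                dimnames = list(samples$sample_id, .CELL_TYPES))
  eta <- eta + matrix(rnorm(nS * 5, 0, 0.3 * noise), nS, 5)
  isF <- samples$sex == "F"
  zx <- (xistLatent - mean(xistLatent[isF])) /
    max(sd(xistLatent[isF]), 1e-8)
  eta[isF, "Neutrophils"] <- eta[isF, "Neutrophils"] - 0.6 * zx[isF]
  props <- exp(eta) / rowSums(exp(eta))

  ## ---- RNA expression field -------------------------------------------
  mixLog <- log2(refLinear %*% t(props))      # genes x samples
  sle <- samples$disease == "SLE"
  male <- samples$sex == "M"
  ifnGenes <- intersect(c(IFN_SIGNATURE_GENES,
                          sprintf("g%05d", 9:(8 + spec$n_ifn_extra))), geneIds)
  xDown <- sample(xGenes, round(spec$f_x_down * length(xGenes)))
  shift <- matrix(0, nG, nS, dimnames = list(geneIds, samples$sample_id))
  shift[ifnGenes, sle] <- shift[ifnGenes, sle] + spec$ifn_lfc
  shift[xDown, sle] <- shift[xDown, sle] + spec$x_down_lfc
  muLog <- mixLog + shift
  muLog["XIST", ] <- xistLatent
  libs <- if (noise == 0) rep(spec$lib_size_mean, nS) else {
    sdlog <- sqrt(log(1 + spec$lib_size_cv^2))
    rlnorm(nS, log(spec$lib_size_mean) - sdlog^2 / 2, sdlog)
  }
  q <- 2^muLog
  mu <- sweep(q, 2, libs / colSums(q), "*")
  counts <- if (noise == 0) mu else
    matrix(rnbinom(nG * nS, mu = mu, size = 1 / spec$nb_dispersion), nG, nS,
           dimnames = dimnames(mu))

  ## ---- methylation ----------------------------------------------------
  nM <- spec$n_meth_features
  methIds <- ann$gene_id[seq_len(nM)]
  annMeth <- ann[seq_len(nM), ]
  methSets <- buildChromosomeGeneSets(annMeth)
  xMeth <- setdiff(methSets$X, "XIST")
  xAffected <- sample(xMeth, round(spec$f_x_meth * length(xMeth)))
  maleSleCol <- male & sle
  mkMeth <- function(baseCenter) {
    baseLogit <- rnorm(nM, baseCenter, 1)
    m <- matrix(baseLogit, nM, nS, dimnames = list(methIds, samples$sample_id))
    m[xAffected, maleSleCol] <- m[xAffected, maleSleCol] + spec$delta_meth
    shared <- intersect(c("IFI44L", "IFI44"), methIds)
    m[shared, sle & male] <- m[shared, sle & male] - 1.5 * spec$delta_meth
    m[shared, sle & !male] <- m[shared, sle & !male] - 0.75 * spec$delta_meth
    m <- m + matrix(rnorm(nM * nS, 0, spec$meth_sd * noise), nM, nS)
    .invlogit(m)
  }
  promoterMeth <- mkMeth(-2)
  geneMeth <- mkMeth(0)

  ## ---- proteins -------------------------------------------------------
  nP <- spec$n_proteins
  annX <- annRna$gene_id[annRna$chromosome == "X"]
  protX <- sample(setdiff(annX, "XIST"),
                  min(spec$protein_x_count, length(annX) - 1))
  protOther <- sample(setdiff(geneIds, c(annX, "XIST")), nP - length(protX))
  protIds <- paste0("P_", c(protX, protOther))
  protBase <- rnorm(nP, 3, 2)
  protein <- matrix(protBase, nP, nS,
                    dimnames = list(protIds, samples$sample_id))
  protSle <- sample(nP, min(spec$n_protein_sle, nP))
  protein[protSle, sle] <- protein[protSle, sle] + spec$protein_sle_lfc
  protInter <- sample(setdiff(seq_len(nP), protSle),
                      min(spec$n_protein_interaction, nP))
  interSign <- rep(c(1, -1), length.out = length(protInter))
  protein[protInter, maleSleCol] <- protein[protInter, maleSleCol] +
    interSign * spec$protein_interaction_lfc
  protein <- protein + matrix(rnorm(nP * nS, 0, spec$npx_sd * noise), nP, nS)
  lod <- setNames(protBase - 3, protIds)
  lowDetect <- sample(nP, round(spec$lod_fail_fraction * nP))
  lod[lowDetect] <- protBase[lowDetect] + 0.7
  flags <- matrix("PASS", nP, nS, dimnames = dimnames(protein))
  nFail <- round(spec$flag_fail_fraction * nP * nS * (noise > 0))
  if (nFail > 0) flags[sample(nP * nS, nFail)] <- "FAIL"

  ## ---- qPCR -----------------------------------------------------------
  ctXist <- spec$qpcr_intercept - spec$qpcr_slope * xistLatent +
    rnorm(nS, 0, spec$ct_sd * noise)
  ctGapdh <- 20 + rnorm(nS, 0, spec$ct_sd * noise)
  if (spec$n_missing_qpcr > 0) {
    missQ <- rev(mSle)[seq_len(min(spec$n_missing_qpcr, length(mSle)))]
    ctXist[missQ] <- NA
  }

  ## ---- flow + clinical -------------------------------------------------
  flow <- props[, c("B", "NK", "T_CD4", "T_CD8", "Neutrophils")] +
    matrix(rnorm(nS * 5, 0, 0.01 * noise), nS, 5)
  flow <- pmax(flow, 0)
  colnames(flow) <- paste0("flow_", colnames(flow))
  activity <- as.numeric(sle) + rnorm(nS, 0, 1 * noise)
  zH <- zHigh
  clin <- data.frame(
    sledai_2k = 6 + 3 * activity + 1.6 * zH + rnorm(nS, 0, 2 * noise),
    igg = 12 + 2 * zH + 0.5 * activity + rnorm(nS, 0, 2 * noise),
    alk_phos = 70 + 16 * zH + rnorm(nS, 0, 15 * noise),
    mobility_score = 2 - 0.8 * zH + rnorm(nS, 0, 0.8 * noise),
    disease_duration = pmax(8 - 4 * zH + rnorm(nS, 0, 3 * noise), 0))
  for (i in seq_len(spec$n_clinical_null))
    clin[[sprintf("clin_null%02d", i)]] <- rnorm(nS)
  clin$apl_status <- ifelse(runif(nS) < 0.2 + 0.3 * zH, "positive", "negative")
  clin$cat_null1 <- sample(c("a", "b"), nS, replace = TRUE)
  clin$cat_null2 <- sample(c("x", "y", "z"), nS, replace = TRUE)

  samples <- cbind(samples,
                   karyotype = karyo,
                   ct_xist = ctXist, ct_gapdh = ctGapdh,
                   as.data.frame(flow), clin)

  ## ---- ground truth ----------------------------------------------------
  trueLfcRna <- data.frame(feature = geneIds,
                           female_SLE_vs_HC = 0, male_SLE_vs_HC = 0,
                           interaction = 0, stringsAsFactors = FALSE,
                           row.names = geneIds)
  trueLfcRna[ifnGenes, c("female_SLE_vs_HC", "male_SLE_vs_HC")] <- spec$ifn_lfc
  trueLfcRna[xDown, c("female_SLE_vs_HC", "male_SLE_vs_HC")] <-
    trueLfcRna[xDown, c("female_SLE_vs_HC", "male_SLE_vs_HC")] + spec$x_down_lfc
  trueLfcRna["XIST", "male_SLE_vs_HC"] <- spec$interaction_lfc
  trueLfcRna["XIST", "interaction"] <- spec$interaction_lfc
  trueLfcMeth <- data.frame(feature = methIds,
                            female_SLE_vs_HC = 0, male_SLE_vs_HC = 0,
                            interaction = 0, stringsAsFactors = FALSE,
                            row.names = methIds)
  trueLfcMeth[xAffected, c("male_SLE_vs_HC", "interaction")] <- spec$delta_meth
  shared <- intersect(c("IFI44L", "IFI44"), methIds)
  trueLfcMeth[shared, "male_SLE_vs_HC"] <- -1.5 * spec$delta_meth
  trueLfcMeth[shared, "female_SLE_vs_HC"] <- -0.75 * spec$delta_meth
  trueLfcMeth[shared, "interaction"] <- -0.75 * spec$delta_meth

  xciPanel <- setdiff(sets$X, "XIST")
  xciPanel <- xciPanel[seq_len(min(253, length(xciPanel)))]

  truth <- list(
    xist_class = setNames(ifelse(zHigh[mSle] == 1, "high", "low"),
                          samples$sample_id[mSle]),
    xist_latent = setNames(xistLatent, samples$sample_id),
    karyotype = setNames(karyo, samples$sample_id),
    cell_props = props,
    x_affected_meth = xAffected,
    x_down_genes = xDown,
    ifn_genes = ifnGenes,
    protein_interaction = protIds[protInter],
    true_lfc = list(rna = trueLfcRna, meth = trueLfcMeth),
    xci_panel = xciPanel,
    lib_sizes = setNames(libs, samples$sample_id),
    chromosome_sets = sets)

  list(matrices = list(
         rna_counts = OmicsMatrix(counts, "rna_counts", samples),
         promoter_meth = OmicsMatrix(promoterMeth, "promoter_meth", samples),
         gene_meth = OmicsMatrix(geneMeth, "gene_meth", samples),
         protein_npx = OmicsMatrix(protein, "protein_npx", samples)),
       samples = samples,
       annotation = annRna,
       annotation_meth = annMeth,
       lod = lod, flags = flags,
       reference = {  # per-cell-type expected TPM profile
         len <- annRna$end - annRna$start
         rate <- refLinear / len
         sweep(rate, 2, colSums(rate), "/") * 1e6
       },
       gene_lengths = setNames(annRna$end - annRna$start, annRna$gene_id),
       truth = truth)
}

#' Simulate per-sample per-chromosome read depths
#'
#' X (and Y) mean coverage scales with the sex-chromosome copy number of the
#' sample's karyotype (XY ~ 0.5x autosomal, XX/XXY ~ 1x, XO ~ 0.5x), with
#' multiplicative log-normal noise.
#'
#' @param karyotype named character vector ("XX", "XY", "XXY", "XO") per
#'   sample, e.g. \code{truth$karyotype} from \code{\link{simulateCohort}}.
#' @param base_depth autosomal mean coverage (default 30).
#' @param cv coefficient of variation of the noise (0 = exact ratios).
#' @param seed optional RNG seed.
#' @return matrix samples x chromosomes ("1".."22", "X", "Y").
#' @export
simulateReadDepths <- function(karyotype, base_depth = 30, cv = 0.03,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xCopies <- c(XX = 2, XY = 1, XXY = 2, XO = 1)[karyotype]
  yCopies <- c(XX = 0, XY = 1, XXY = 1, XO = 0)[karyotype]
  if (anyNA(xCopies)) stop("unknown karyotype label")
  nS <- length(karyotype)
  chroms <- c(as.character(1:22), "X", "Y")
  d <- matrix(base_depth, nS, 24, dimnames = list(names(karyotype), chroms))
  d[, "X"] <- base_depth * xCopies / 2
  d[, "Y"] <- base_depth * yCopies / 2
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    d <- d * matrix(rlnorm(nS * 24, -sdlog^2 / 2, sdlog), nS, 24)
  }
  d
}
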