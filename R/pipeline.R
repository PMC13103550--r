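#' Pipeline configuration
#'
#' Collects every threshold the analysis uses, the simulation spec (or input
#' paths) and the output directory. Can be written/read as YAML.
#'
#' @param outdir output directory for stage TSVs and the run manifest.
#' @param seed master seed; each stage derives its own seed from it.
#' @param sim list of \code{\link{cohortSpec}} arguments (a synthetic cohort
#'   is generated when \code{inputs} is NULL).
#' @param inputs optional named list of input paths (\code{rna_counts},
#'   \code{promoter_meth}, \code{gene_meth}, \code{protein_npx},
#'   \code{samples}, \code{annotation}, \code{depths}); overrides \code{sim}.
#' @param fdr_max,fc_min significance thresholds (0.1, 1.5).
#' @param lod_frac LOD detection fraction (0.75, strict).
#' @param min_count low-count filter threshold (10).
#' @param npx_outlier_sd low-expression sample exclusion (4 SDs).
#' @param sexqc_tol X/autosome ratio tolerance (0.25).
#' @param promoter_upstream,promoter_downstream promoter window (2000, 200).
#' @param n_perm GSEA permutations per set in the chromosome scan (1000).
#' @param n_mc Monte-Carlo draws for the dip test (10000).
#' @param use_voom_weights carry precision weights into the RNA fits (TRUE).
#' @param methylation_scale "logit" (default) or "log2" fold-change scale for
#'   methylation fractions.
#' @param ifn_rule "zscore" (default) or "mean" aggregation for the IFN score.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(outdir = tempfile("dimorphix_run_"), seed = 1,
                           sim = list(), inputs = NULL,
                           fdr_max = 0.1, fc_min = 1.5, lod_frac = 0.75,
                           min_count = 10, npx_outlier_sd = 4,
                           sexqc_tol = 0.25,
                           promoter_upstream = 2000,
                           promoter_downstream = 200,
                           n_perm = 1000, n_mc = 10000,
                           use_voom_weights = TRUE,
                           methylation_scale = c("logit", "log2"),
                           ifn_rule = c("zscore", "mean")) {
  cfg <- as.list(environment())
  cfg$methylation_scale <- match.arg(methylation_scale)
  cfg$ifn_rule <- match.arg(ifn_rule)
  stopifnot(cfg$fdr_max > 0, cfg$fdr_max <= 1, cfg$fc_min >= 1,
            cfg$lod_frac > 0, cfg$lod_frac < 1, cfg$n_perm >= 100)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with \code{\link{pipelineConfig}} fields.
#' @return a \code{"pipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.methTransform <- function(m, scale) {
  if (scale == "logit") logitMethylation(m) else log2(pmax(.asMatrixInput(m), 1e-4))
}

.writeStage <- function(obj, outdir, name) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full sex-dimorphism analysis
#'
#' Executes the stages in fixed order: cohort (simulate or load), read-depth
#' sex QC, protein QC, RNA preprocessing (count filter, log-CPM, quantile
#' normalization, precision weights), methylation transform, factorial
#' differential analysis with Venn partitions, XIST bimodality testing and
#' classification, male subgroup contrasts, chromosome/PAR silencing scan with
#' X-linked fraction and XCI-panel summaries, IFN signature correlation,
#' deconvolution benchmark, and clinical screens. Rerunning with the same
#' config is bit-identical.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisible list with all stage results and \code{manifest}; stage
#'   tables and the JSON manifest are written under \code{config$outdir}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("dimorphix")),
                   seed = config$seed, stages = list())
  files <- character()
  note <- function(stage, ...) {
    info <- list(...)
    manifest$stages[[stage]] <<- info
    message(sprintf("[%s] %s", stage,
                    paste(names(info), unlist(info), sep = "=", collapse = " ")))
  }

  ## 1 cohort ------------------------------------------------------------
  if (is.null(config$inputs)) {
    simArgs <- config$sim
    if (is.null(simArgs$seed)) simArgs$seed <- .deriveSeed(config$seed, "cohort")
    cohort <- simulateCohort(do.call(cohortSpec, simArgs))
    depths <- simulateReadDepths(cohort$truth$karyotype,
                                 seed = .deriveSeed(config$seed, "depths"))
  } else {
    inp <- config$inputs
    cohort <- list(
      matrices = list(
        rna_counts = readFeatureMatrix(inp$rna_counts, "rna_counts"),
        promoter_meth = readFeatureMatrix(inp$promoter_meth, "promoter_meth"),
        gene_meth = readFeatureMatrix(inp$gene_meth, "gene_meth"),
        protein_npx = readFeatureMatrix(inp$protein_npx, "protein_npx")),
      samples = read.delim(inp$samples, stringsAsFactors = FALSE),
      annotation = readGeneAnnotation(inp$annotation),
      truth = NULL)
    rownames(cohort$samples) <- cohort$samples$sample_id
    depths <- as.matrix(read.delim(inp$depths, row.names = 1,
                                   check.names = FALSE))
    cohort$gene_lengths <- setNames(cohort$annotation$end - cohort$annotation$start,
                                    cohort$annotation$gene_id)
  }
  samples <- cohort$samples
  note("cohort", n_samples = nrow(samples),
       n_genes = nrow(cohort$matrices$rna_counts))

  ## 2 sex QC ------------------------------------------------------------
  sexqc <- sexQcReadDepth(depths[samples$sample_id, , drop = FALSE],
                          samples$sex, tol = config$sexqc_tol)
  keep <- sexqc$sample_id[sexqc$flag == "pass"]
  dropN <- nrow(samples) - length(keep)
  samples <- samples[keep, ]
  cohort$matrices <- lapply(cohort$matrices, function(m) m[, keep])
  files["sex_qc"] <- .writeStage(sexqc, config$outdir, "sex_qc")
  note("sex_qc", excluded = dropN, kept = length(keep))

  ## 3 protein QC --------------------------------------------------------
  npx <- cohort$matrices$protein_npx
  nIn <- nrow(npx)
  if (!is.null(cohort$flags)) {
    npx <- filterNpxByLod(npx, cohort$lod,
                          cohort$flags[, keep, drop = FALSE],
                          min_frac = config$lod_frac)
  }
  lowS <- excludeLowExpressionSamples(npx, k_sd = config$npx_outlier_sd)
  if (length(lowS)) npx <- npx[, setdiff(colnames(npx), lowS)]
  note("protein_qc", assays_in = nIn, assays_kept = nrow(npx),
       assays_filtered = nIn - nrow(npx), samples_excluded = length(lowS))

  ## 4 RNA preprocessing -------------------------------------------------
  counts <- cohort$matrices$rna_counts
  keptG <- filterLowCounts(counts, samples$group, min_count = config$min_count)
  counts <- counts[keptG, ]
  logexpr <- featureValues(logCpm(counts))
  logexpr <- quantileNormalize(logexpr)
  design <- makeFactorialDesign(samples$sex, samples$disease)
  weights <- if (config$use_voom_weights)
    voomWeights(logexpr, design) else NULL
  note("rna_preprocess", features_in = nrow(cohort$matrices$rna_counts),
       features_kept = length(keptG),
       features_filtered = nrow(cohort$matrices$rna_counts) - length(keptG))

  ## 5 methylation transform ---------------------------------------------
  promoterT <- .methTransform(cohort$matrices$promoter_meth,
                              config$methylation_scale)
  geneT <- .methTransform(cohort$matrices$gene_meth, config$methylation_scale)
  note("methylation_transform", scale = config$methylation_scale)

  ## 6 factorial DE ------------------------------------------------------
  deInputs <- list(rna = list(x = logexpr, w = weights),
                   promoter_meth = list(x = promoterT, w = NULL),
                   gene_meth = list(x = geneT, w = NULL),
                   protein_npx = list(x = featureValues(npx), w = NULL))
  de <- lapply(deInputs, function(z)
    runFactorialDE(z$x, samples$sex, samples$disease, weights = z$w,
                   fdr_max = config$fdr_max, fc_min = config$fc_min))
  venn <- lapply(de, function(tabs)
    vennPartition(tabs$female_SLE_vs_HC, tabs$male_SLE_vs_HC))
  for (mod in names(de)) {
    tab <- do.call(rbind, de[[mod]])
    files[paste0("de_", mod)] <- .writeStage(tab, config$outdir,
                                             paste0("de_", mod))
  }
  vennTab <- data.frame(modality = rep(names(venn), each = 7),
                        partition = unlist(lapply(venn, names)),
                        count = unlist(venn), row.names = NULL)
  files["venn"] <- .writeStage(vennTab, config$outdir, "venn")
  note("factorial_de",
       sig_interaction = sum(vapply(de, function(t) sum(t$interaction$significant), 0)))

  ## 7 XIST classification -----------------------------------------------
  maleSle <- samples$sample_id[samples$sex == "M" & samples$disease == "SLE"]
  femaleSle <- samples$sample_id[samples$sex == "F" & samples$disease == "SLE"]
  # single-gene analyses use plain log-CPM (quantile normalization maps values
  # onto shared order statistics, which distorts extreme-ranked genes)
  xistRna <- featureValues(logCpm(counts))["XIST", ]
  rel <- normalizeQpcr(samples$ct_xist, samples$ct_gapdh, samples$sex,
                       samples$disease)
  names(rel) <- samples$sample_id
  qpcrLog <- log2(rel)
  nullTab <- dipNullDistribution(length(maleSle), config$n_mc,
                                 seed = .deriveSeed(config$seed, "dipnull"))
  dipQ <- dipTest(qpcrLog[maleSle][!is.na(qpcrLog[maleSle])],
                  n_mc = config$n_mc, seed = .deriveSeed(config$seed, "dipq"))
  dipR <- dipTest(xistRna[maleSle], null = nullTab)
  dipF <- dipTest(xistRna[femaleSle], n_mc = config$n_mc,
                  seed = .deriveSeed(config$seed, "dipf"))
  cls <- classifyXist(qpcrLog[maleSle], xistRna)
  lev <- leveneVarianceTest(xistRna[samples$sex == "F"],
                            samples$disease[samples$sex == "F"])
  files["xist_classification"] <- .writeStage(cls, config$outdir,
                                              "xist_classification")
  note("xist", dip_p_qpcr = signif(dipQ$p.value, 3),
       dip_p_rnaseq = signif(dipR$p.value, 3),
       dip_p_female = signif(dipF$p.value, 3),
       n_high = sum(cls$label == "high"), n_low = sum(cls$label == "low"),
       levene_p = signif(lev$p.value, 3))

  ## 8 subgroup DE -------------------------------------------------------
  maleIds <- samples$sample_id[samples$sex == "M"]
  maleGroup <- ifelse(samples[maleIds, "disease"] == "HC", "HC",
                      cls$label[match(maleIds, cls$sample)])
  subgroupInputs <- list(rna = logexpr, promoter_meth = promoterT,
                         gene_meth = geneT, protein_npx = featureValues(npx))
  subde <- lapply(subgroupInputs, function(x) {
    cols <- intersect(maleIds, colnames(x))
    runSubgroupDE(x[, cols, drop = FALSE],
                  maleGroup[match(cols, maleIds)],
                  fdr_max = config$fdr_max, fc_min = config$fc_min)
  })
  for (mod in names(subde))
    files[paste0("subgroup_de_", mod)] <-
      .writeStage(do.call(rbind, subde[[mod]]), config$outdir,
                  paste0("subgroup_de_", mod))
  note("subgroup_de", n_high = sum(maleGroup == "high"),
       n_low = sum(maleGroup == "low"))

  ## 9 chromosome silencing scan -----------------------------------------
  ann <- cohort$annotation
  sets <- buildChromosomeGeneSets(ann)
  scanTables <- list()
  for (mod in c("promoter_meth", "gene_meth", "rna")) {
    scanTables[[paste0(mod, ".female_SLE_vs_HC")]] <- de[[mod]]$female_SLE_vs_HC
    scanTables[[paste0(mod, ".high_vs_HC")]] <- subde[[mod]]$high_vs_HC
    scanTables[[paste0(mod, ".low_vs_HC")]] <- subde[[mod]]$low_vs_HC
  }
  scan <- chromosomeSilencingScan(scanTables, sets, n_perm = config$n_perm,
                                  seed = .deriveSeed(config$seed, "scan"))
  files["chromosome_scan"] <- .writeStage(scan, config$outdir,
                                          "chromosome_scan")
  hyperFrac <- lapply(c(high = "high_vs_HC", low = "low_vs_HC"), function(cn) {
    tab <- subde$promoter_meth[[cn]]
    sig <- tab$feature[tab$significant & tab$lfc > 0]
    xlinkedFractionSummary(sig, sets, tab$feature)
  })
  xci <- if (!is.null(cohort$truth))
    xciPanelSummary(subde$rna$high_vs_HC, cohort$truth$xci_panel,
                    config$fdr_max, config$fc_min) else NULL
  note("silencing_scan", n_tables = length(scanTables),
       x_frac_high = signif(hyperFrac$high$fraction, 3),
       x_frac_low = signif(hyperFrac$low$fraction, 3))

  ## 10 IFN signature ----------------------------------------------------
  ifn <- if (config$ifn_rule == "zscore") ifnSignature(logexpr) else {
    present <- intersect(IFN_SIGNATURE_GENES, rownames(logexpr))
    colMeans(logexpr[present, , drop = FALSE])
  }
  ifnCor <- lapply(c(F = "F", M = "M"), function(s) {
    ids <- samples$sample_id[samples$sex == s & samples$disease == "SLE"]
    spearmanCorr(xistRna[ids], ifn[ids])
  })
  note("ifn", rho_female = signif(ifnCor$F$rho, 3),
       rho_male = signif(ifnCor$M$rho, 3))

  ## 11 deconvolution ----------------------------------------------------
  deconv <- NULL
  if (!is.null(cohort$reference)) {
    tpm <- tpmNormalize(featureValues(cohort$matrices$rna_counts),
                        cohort$gene_lengths)
    set.seed(.deriveSeed(config$seed, "deconv"))
    shuf <- cohort$reference[sample(nrow(cohort$reference)), ]
    rownames(shuf) <- rownames(cohort$reference)
    refs <- list(generating = cohort$reference, shuffled = shuf,
                 noised = cohort$reference *
                   matrix(2^rnorm(length(cohort$reference), 0, 2),
                          nrow(cohort$reference)))
    est <- list()
    for (rn in names(refs)) {
      est[[paste0(rn, ".nnls")]] <- deconvolveNnls(tpm, refs[[rn]])
      est[[paste0(rn, ".ols")]] <- deconvolveOls(tpm, refs[[rn]])
    }
    flow <- as.matrix(samples[, paste0("flow_", c("B", "NK"))])
    colnames(flow) <- c("B", "NK")
    deconv <- suppressWarnings(benchmarkDeconvolution(est, flow))
    files["deconvolution"] <- .writeStage(deconv$table, config$outdir,
                                          "deconvolution")
    note("deconvolution", selected = deconv$selected)
  }

  ## 12 clinical screens -------------------------------------------------
  numVars <- grep("^(sledai|igg|alk|mobility|disease_dur|clin_null)",
                  names(samples), value = TRUE)
  catVars <- grep("^(apl_status|cat_null)", names(samples), value = TRUE)
  clsLab <- setNames(cls$label, cls$sample)
  pairs <- list(
    high_vs_femaleSLE = c(maleSle[clsLab[maleSle] == "high"], femaleSle),
    low_vs_femaleSLE = c(maleSle[clsLab[maleSle] == "low"], femaleSle),
    high_vs_low = maleSle)
  screens <- lapply(names(pairs), function(pn) {
    ids <- pairs[[pn]]
    grp <- if (pn == "high_vs_low") clsLab[ids] else
      ifelse(samples[ids, "sex"] == "M", "male", "female")
    s <- clinicalScreen(samples[ids, ], grp, numVars, catVars)
    cbind(pair = pn, s)
  })
  screenTab <- do.call(rbind, screens)
  corTab <- correlateFeaturesWithCovariates(
    xistRna[c(maleSle, femaleSle)],
    samples[c(maleSle, femaleSle),
            c(numVars, paste0("flow_", c("B", "NK", "Neutrophils")))],
    strata = samples[c(maleSle, femaleSle), "sex"])
  files["clinical_screen"] <- .writeStage(screenTab, config$outdir,
                                          "clinical_screen")
  files["xist_correlations"] <- .writeStage(corTab, config$outdir,
                                            "xist_correlations")
  note("clinical_screen", n_tests = nrow(screenTab))

  manifest$files <- as.list(unname(vapply(files, basename, "")))
  manifest$digests <- as.list(tools::md5sum(unlist(files)))
  names(manifest$digests) <- basename(names(manifest$digests))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(samples = samples, de = de, subgroup_de = subde, venn = venn,
                 sexqc = sexqc, classification = cls, dip = list(
                   qpcr = dipQ, rnaseq = dipR, female = dipF),
                 levene = lev, scan = scan, xlinked_fraction = hyperFrac,
                 xci_panel = xci, ifn = ifn, ifn_cor = ifnCor,
                 deconvolution = deconv, screens = screenTab,
                 correlations = corTab, manifest = manifest,
                 outdir = config$outdir))
}
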