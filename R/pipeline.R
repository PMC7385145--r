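#' Assemble and validate a pipeline configuration
#'
#' All randomness in the pipeline flows from the single `seed` through
#' named per-stage substreams, so individual stages are independently
#' reproducible.
#'
#' @param genotypes path to a genotype file (VCF or TSV), or NULL to
#'   simulate inputs
#' @param format genotype file format, see [readGenotypes]
#' @param map optional marker map TSV path
#' @param phenotypes path to a long-format phenotype TSV, or NULL to
#'   simulate
#' @param alignments optional named character vector of per-gene FASTA
#'   alignment paths for the diversity stage
#' @param qc list of QC thresholds: mafMin, maxMissing, maxHet
#' @param gwas list: variant, nPcs, fdrQ
#' @param predictCfg list: models, nFolds, nCycles, hGrid, bayesb (control
#'   list for [bayesbFitPredict])
#' @param sim list of generator settings used when `genotypes` is NULL:
#'   nLines, nMarkers, nChromosomes, nSubpops, fst, nQtl, h2Target,
#'   nEnvironments
#' @param seed master seed
#' @param outDir run directory to create
#' @return list of class `PipelineConfig`
#' @export
pipelineConfig <- function(genotypes = NULL, format = "auto", map = NULL,
                           phenotypes = NULL, alignments = NULL,
                           qc = list(), gwas = list(), predictCfg = list(),
                           sim = list(), seed = 1, outDir = "grainQG_run") {
  cfg <- list(
    genotypes = genotypes, format = format, map = map,
    phenotypes = phenotypes, alignments = alignments,
    qc = utils::modifyList(
      list(mafMin = 0.05, maxMissing = 0.05, maxHet = 0.05), qc),
    gwas = utils::modifyList(
      list(variant = "pc_g", nPcs = 3, fdrQ = 0.20), gwas),
    predictCfg = utils::modifyList(
      list(models = c("gblup", "bayesb", "rkhs"), nFolds = 5, nCycles = 5,
           hGrid = 0.5 * c(1 / 5, 1, 5),
           bayesb = list(nIter = 2000, burnIn = 500, thin = 2)), predictCfg),
    sim = utils::modifyList(
      list(nLines = 300, nMarkers = 2000, nChromosomes = 5, nSubpops = 2,
           fst = 0.05, nQtl = 50, h2Target = 0.9, nEnvironments = 4),
      sim),
    seed = seed, outDir = outDir)
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname pipelineConfig
#' @param cfg a `PipelineConfig`
#' @export
validatePipelineConfig <- function(cfg) {
  for (f in c("genotypes", "map", "phenotypes")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config error: ", f, " path does not exist: ", cfg[[f]])
  }
  if (!is.null(cfg$genotypes) && is.null(cfg$phenotypes))
    stop("config error: genotypes given but phenotype path missing")
  for (a in cfg$alignments) if (!file.exists(a))
    stop("config error: alignment path does not exist: ", a)
  with(cfg$qc, stopifnot(mafMin >= 0, mafMin <= 1, maxMissing >= 0,
                         maxHet >= 0))
  stopifnot(cfg$gwas$variant %in% c("naive", "pc", "g", "pc_g"))
  invisible(TRUE)
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[names(cfg) != "outDir"],
                              auto_unbox = TRUE, force = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orders the stages QC -> PCA/LD -> heritability/BLUEs -> GWAS -> p_G ->
#' genomic prediction (-> diversity when alignments are given), writing
#' each stage's output as TSV into the run directory together with a
#' manifest and a log. Every output carries the seed and a config hash in
#' `#` header lines. A stage failure stops with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param cfg a [pipelineConfig] object
#' @return the run directory path, invisibly; stage results as a list
#' @export
runPipeline <- function(cfg) {
  validatePipelineConfig(cfg)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(cfg)
  meta <- c(seed = cfg$seed, config_hash = hash)
  logPath <- file.path(cfg$outDir, "pipeline.log")
  logLine <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = logPath, append = TRUE)
  stage <- function(name, expr) {
    logLine("stage", name, "start")
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logLine("stage", name, "done")
    out
  }
  results <- list()

  inputs <- stage("input", {
    if (is.null(cfg$genotypes)) {
      s <- cfg$sim
      geno <- simulateGenotypes(
        s$nLines, s$nMarkers, nChromosomes = s$nChromosomes,
        nSubpops = s$nSubpops, fst = s$fst,
        seed = subSeed(cfg$seed, "genotypes"))
      sim <- simulateTrait(geno, nQtl = s$nQtl, h2Target = s$h2Target,
                           nEnvironments = s$nEnvironments,
                           seed = subSeed(cfg$seed, "trait"))
      writeGenotypesTsv(geno, file.path(cfg$outDir, "genotypes_input.tsv"),
                        file.path(cfg$outDir, "map_input.tsv"), meta)
      writePhenotypes(sim$pheno, file.path(cfg$outDir, "phenotypes.tsv"),
                      meta)
      list(geno = geno, pheno = sim$pheno, truth = sim$truth)
    } else {
      list(geno = readGenotypes(cfg$genotypes, cfg$format, cfg$map),
           pheno = readPhenotypes(cfg$phenotypes), truth = NULL)
    }
  })

  qc <- stage("qc", qcFilter(inputs$geno, cfg$qc$mafMin, cfg$qc$maxMissing,
                             cfg$qc$maxHet))
  writeGenotypesTsv(qc$geno, file.path(cfg$outDir, "genotypes_qc.tsv"),
                    NULL, meta)
  writeTsv(as.data.frame(unclass(qc$report)),
           file.path(cfg$outDir, "qc_report.tsv"), meta)
  results$qc <- qc

  pca <- stage("pca", pcaGenotypes(qc$geno, k = min(10, ncol(qc$geno) - 1)))
  writeTsv(cbind(line = rownames(pca$scores), as.data.frame(pca$scores)),
           file.path(cfg$outDir, "pca_scores.tsv"), meta)
  writeTsv(data.frame(component = seq_along(pca$propVar),
                      propVar = pca$propVar),
           file.path(cfg$outDir, "pca_propvar.tsv"), meta)
  results$pca <- pca

  ld <- stage("ld", ldDecayProfile(qc$geno))
  writeTsv(ld$decay, file.path(cfg$outDir, "ld_decay.tsv"), meta)
  results$ld <- ld

  traits <- unique(inputs$pheno$trait)
  grm <- stage("grm", computeGRM(qc$geno))
  results$traits <- list()
  for (tr in traits) {
    vc <- stage(paste0("h2:", tr),
                fitVarianceComponents(inputs$pheno, tr))
    H2 <- heritability(vc)
    blues <- stage(paste0("blues:", tr), computeBlues(inputs$pheno, tr))
    writeTsv(data.frame(trait = tr, sigma2G = vc$sigma2G,
                        sigma2E = vc$sigma2E, sigma2e = vc$sigma2e,
                        nEnvironments = vc$nEnvironments, H2 = H2),
             file.path(cfg$outDir, paste0("heritability_", tr, ".tsv")),
             meta)
    writeTsv(data.frame(genotype = names(blues), blue = blues),
             file.path(cfg$outDir, paste0("blues_", tr, ".tsv")), meta)

    gw <- stage(paste0("gwas:", tr),
                runGwas(blues, qc$geno, variant = cfg$gwas$variant,
                        nPcs = cfg$gwas$nPcs, grm = grm, pca = pca))
    gw$fdrFlag <- fdrAdjust(gw$p, cfg$gwas$fdrQ)
    writeTsv(gw, file.path(cfg$outDir, paste0("gwas_", tr, ".tsv")), meta)

    mta <- gw[!is.na(gw$fdrFlag) & gw$fdrFlag,
              c("marker", "p", "beta"), drop = FALSE]
    pg <- stage(paste0("pg:", tr),
                genotypicVarianceExplained(blues, qc$geno, mta, H2))
    writeTsv(data.frame(trait = tr, nMTA = pg$z, R2 = pg$R2,
                        R2adj = pg$R2adj, totalPg = pg$totalPg),
             file.path(cfg$outDir, paste0("pg_", tr, ".tsv")), meta)

    pc <- cfg$predictCfg
    cv <- stage(paste0("predict:", tr),
                crossValidate(blues, qc$geno, models = pc$models,
                              nFolds = pc$nFolds, nCycles = pc$nCycles,
                              H2 = H2, seed = subSeed(cfg$seed, "cv"),
                              grm = grm, hGrid = pc$hGrid,
                              bayesbControl = pc$bayesb))
    writeTsv(cv$folds, file.path(cfg$outDir, paste0("cv_folds_", tr,
                                                    ".tsv")), meta)
    writeTsv(cv$summary, file.path(cfg$outDir, paste0("cv_summary_", tr,
                                                      ".tsv")), meta)
    results$traits[[tr]] <- list(vc = vc, H2 = H2, blues = blues,
                                 gwas = gw, pg = pg, cv = cv)
  }

  if (!is.null(cfg$alignments)) {
    alns <- lapply(cfg$alignments, readAlignmentFasta)
    names(alns) <- names(cfg$alignments)
    div <- stage("diversity", diversityReport(alns))
    writeTsv(div, file.path(cfg$outDir, "diversity.tsv"), meta)
    results$diversity <- div
  }

  writeTsv(data.frame(
    key = c("seed", "config_hash", "qc_mafMin", "qc_maxMissing",
            "qc_maxHet", "gwas_variant", "gwas_nPcs", "fdr_q"),
    value = c(cfg$seed, hash, cfg$qc$mafMin, cfg$qc$maxMissing,
              cfg$qc$maxHet, cfg$gwas$variant, cfg$gwas$nPcs,
              cfg$gwas$fdrQ)),
    file.path(cfg$outDir, "manifest.tsv"), meta)
  logLine("pipeline complete")
  results$outDir <- cfg$outDir
  invisible(results)
}
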