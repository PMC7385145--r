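#' Simulate inbred-panel SNP genotypes with block LD and weak structure
#'
#' Generates fully inbred dosages (0/2) for a diversity panel. Subpopulation
#' allele frequencies follow a Balding-Nichols model: for ancestral
#' frequency p and divergence F, subpopulation frequencies are drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F); at F = 0 all subpopulations share the
#' ancestral frequency. Linkage disequilibrium arises from a
#' founder-haplotype mosaic: each line copies alleles along a chromosome
#' from a small pool of founder haplotypes, switching founders between
#' adjacent markers with probability 1 - exp(-d/L), where d is the cM gap
#' and L is calibrated so that blocks span `blockSize` markers on average.
#'
#' @param nLines number of inbred lines (>= 2)
#' @param nMarkers total number of SNP markers (>= 1)
#' @param nChromosomes number of chromosomes markers are spread over
#' @param chromLengthCM genetic length of each chromosome in cM
#' @param blockSize mean number of markers per LD block
#' @param nSubpops number of subpopulations
#' @param fst divergence parameter in \[0, 1)
#' @param mafMin lower bound on the ancestral minor allele frequency, in
#'   (0, 0.5]
#' @param nFounders founder haplotypes per subpopulation and chromosome
#' @param hetRate fraction of calls set to heterozygous (dosage 1); only
#'   used to exercise the QC heterozygosity filter
#' @param missingRate fraction of calls set missing
#' @param seed integer seed; same seed gives bit-identical output
#' @return A [GenotypeData] with line subpopulations in `colData` and
#'   monomorphic markers flagged in `rowData$monomorphic`.
#' @examples
#' gd <- simulateGenotypes(nLines = 20, nMarkers = 100, seed = 1)
#' gd
#' @export
simulateGenotypes <- function(nLines, nMarkers, nChromosomes = 3,
                              chromLengthCM = 150, blockSize = 10,
                              nSubpops = 1, fst = 0, mafMin = 0.1,
                              nFounders = 8, hetRate = 0, missingRate = 0,
                              seed = NULL) {
  if (nLines < 2) stop("invalid config: nLines must be >= 2")
  if (nMarkers < 1) stop("invalid config: nMarkers must be >= 1")
  if (fst < 0 || fst >= 1) stop("invalid config: fst must lie in [0, 1)")
  if (mafMin <= 0 || mafMin > 0.5)
    stop("invalid config: mafMin must lie in (0, 0.5]")
  if (nSubpops < 1) stop("invalid config: nSubpops must be >= 1")
  withSeed(seed, {
    chrom <- sort(rep_len(seq_len(nChromosomes), nMarkers))
    chromNames <- paste0("chr", chrom)
    cM <- numeric(nMarkers)
    for (c in seq_len(nChromosomes)) {
      idx <- which(chrom == c)
      cM[idx] <- sort(runif(length(idx), 0, chromLengthCM))
    }
    subpop <- rep_len(seq_len(nSubpops), nLines)
    p0 <- runif(nMarkers, mafMin, 1 - mafMin)
    # subpop-specific frequencies, Balding-Nichols
    pk <- matrix(p0, nrow = nMarkers, ncol = nSubpops)
    if (fst > 0 && nSubpops > 1) {
      for (s in seq_len(nSubpops))
        pk[, s] <- rbeta(nMarkers, p0 * (1 - fst) / fst,
                         (1 - p0) * (1 - fst) / fst)
    }
    dos <- matrix(0, nrow = nMarkers, ncol = nLines)
    for (c in seq_len(nChromosomes)) {
      idx <- which(chrom == c)
      m <- length(idx)
      spacing <- chromLengthCM / max(m, 1)
      L <- blockSize * spacing
      gaps <- diff(cM[idx])
      pSwitch <- c(1, 1 - exp(-gaps / L))  # first marker always draws anew
      for (s in seq_len(nSubpops)) {
        founders <- matrix(
          rbinom(m * nFounders, 1, rep(pk[idx, s], nFounders)),
          nrow = m, ncol = nFounders)
        for (i in which(subpop == s)) {
          sw <- runif(m) < pSwitch
          fid <- sample.int(nFounders, sum(sw), replace = TRUE)
          cur <- fid[cumsum(sw)]
          dos[idx, i] <- 2 * founders[cbind(seq_len(m), cur)]
        }
      }
    }
    if (hetRate > 0) {
      flip <- runif(length(dos)) < hetRate
      dos[flip] <- 1
    }
    if (missingRate > 0) {
      miss <- runif(length(dos)) < missingRate
      dos[miss] <- NA_real_
    }
    rownames(dos) <- sprintf("m%05d", seq_len(nMarkers))
    colnames(dos) <- sprintf("L%04d", seq_len(nLines))
    map <- data.frame(marker = rownames(dos), chrom = chromNames, cM = cM,
                      bp = as.numeric(round(cM * 1e6) + 1))
    gd <- GenotypeData(dos, map)
    SummarizedExperiment::colData(gd)$subpop <- paste0("pop", subpop)
    mono <- apply(dos, 1, function(z) {
      z <- z[!is.na(z) & z != 1]
      length(unique(z)) < 2
    })
    SummarizedExperiment::rowData(gd)$monomorphic <- mono
    gd
  })
}

#' Simulate a multi-environment trait with known genetic architecture
#'
#' Generates per-environment phenotypes y_ij = mu + g_i + E_j + e_ij where
#' the genetic value g_i is the sum of additive QTL effects on centered
#' dosages plus optional epistatic products. The residual variance is
#' solved so that the entry-mean (plot-level) heritability
#' Var(g) / (Var(g) + sigma2_e / nE) equals `h2Target`.
#'
#' @param geno a [GenotypeData]; QTL are sampled from its markers
#' @param nQtl number of additive QTL
#' @param h2Target target heritability on the entry-mean basis, in \[0, 1\]
#' @param nEnvironments number of environments (>= 1)
#' @param effectSd scale of the additive effects: the standard deviation
#'   for `effectDist = "gaussian"`, the common magnitude for `"equal"`
#' @param effectDist additive effect-size distribution: `"gaussian"`
#'   (default, small-to-medium effects) or `"equal"` (all effects of equal
#'   magnitude with random sign; the canonical sparse large-effect
#'   architecture)
#' @param envSd standard deviation of random environment main effects
#' @param epistaticPairs optional data.frame with columns `qtl1`, `qtl2`
#'   (indices into the sampled QTL) and `effect`; contributions are
#'   products of the two centered dosages
#' @param mu grand intercept on the trait scale
#' @param trait trait name recorded in the phenotype table
#' @param seed integer seed
#' @return list with `pheno` (long-format data.frame: genotype,
#'   environment, trait, value) and `truth` (class `SimTruth`: QTL markers
#'   and effects, true genetic values, realized heritability, residual
#'   variance used).
#' @examples
#' gd <- simulateGenotypes(30, 200, seed = 1)
#' sim <- simulateTrait(gd, nQtl = 5, h2Target = 0.8, nEnvironments = 4,
#'                      seed = 2)
#' head(sim$pheno)
#' @export
simulateTrait <- function(geno, nQtl, h2Target, nEnvironments = 4,
                          effectSd = 1, effectDist = c("gaussian", "equal"),
                          envSd = 1, epistaticPairs = NULL,
                          mu = 10, trait = "simTrait", seed = NULL) {
  stopifnot(is(geno, "GenotypeData"))
  effectDist <- match.arg(effectDist)
  if (h2Target < 0 || h2Target > 1) stop("h2Target must lie in [0, 1]")
  if (nEnvironments < 1) stop("nEnvironments must be >= 1")
  withSeed(seed, {
    W <- dosagesLxM(geno)
    if (any(is.na(W))) stop("genotypes must be imputed before simulateTrait")
    n <- nrow(W)
    g <- numeric(n)
    qtlIdx <- integer(0); eff <- numeric(0)
    if (nQtl > 0) {
      poly <- which(apply(W, 2, var) > 0)
      if (length(poly) < nQtl)
        stop("fewer polymorphic markers than requested QTL")
      qtlIdx <- sort(sample(poly, nQtl))
      eff <- if (effectDist == "equal")
        effectSd * sample(c(-1, 1), nQtl, replace = TRUE)
      else rnorm(nQtl, 0, effectSd)
      X <- scale(W[, qtlIdx, drop = FALSE], center = TRUE, scale = FALSE)
      g <- drop(X %*% eff)
    }
    epiEff <- numeric(0)
    if (!is.null(epistaticPairs) && nrow(epistaticPairs) > 0) {
      if (nQtl == 0) stop("epistatic pairs declared without QTL")
      if (any(epistaticPairs$qtl1 > nQtl | epistaticPairs$qtl2 > nQtl |
              epistaticPairs$qtl1 < 1 | epistaticPairs$qtl2 < 1))
        stop("epistatic pair indexes an undeclared QTL")
      X <- scale(W[, qtlIdx, drop = FALSE], center = TRUE, scale = FALSE)
      epiEff <- epistaticPairs$effect
      for (l in seq_len(nrow(epistaticPairs)))
        g <- g + epiEff[l] * X[, epistaticPairs$qtl1[l]] *
          X[, epistaticPairs$qtl2[l]]
    }
    vg <- var(g)
    if (vg == 0 && h2Target > 0)
      stop("infeasible: zero genetic variance with h2Target > 0")
    sigma2e <- if (h2Target == 0) {
      if (vg > 0) stop("infeasible: h2Target = 0 with nonzero genetic variance")
      1
    } else if (h2Target == 1) 0 else {
      vg * (1 - h2Target) / h2Target * nEnvironments
    }
    envEff <- rnorm(nEnvironments, 0, envSd)
    lines <- rownames(W)
    envs <- sprintf("env%02d", seq_len(nEnvironments))
    e <- rnorm(n * nEnvironments, 0, sqrt(sigma2e))
    pheno <- data.frame(
      genotype = rep(lines, times = nEnvironments),
      environment = rep(envs, each = n),
      trait = trait,
      value = mu + rep(g, times = nEnvironments) +
        rep(envEff, each = n) + e)
    realized <- if (vg == 0 && var(e) == 0) 0 else
      vg / (vg + var(e) / nEnvironments)
    truth <- structure(list(
      qtlMarkers = colnames(W)[qtlIdx], qtlEffects = eff,
      epistaticPairs = epistaticPairs, epistaticEffects = epiEff,
      trueGeneticValues = setNames(g, lines), envEffects = envEff,
      sigma2e = sigma2e, mu = mu, h2Target = h2Target,
      realizedH2 = realized), class = "SimTruth")
    list(pheno = pheno, truth = truth)
  })
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth:", length(x$qtlMarkers), "QTL; realized H2 =",
      round(x$realizedH2, 3), "\n")
  invisible(x)
}

#' Simulate a coding-sequence alignment with a mutation ledger
#'
#' Builds a reference CDS of `nCodons` sense codons (no internal stops) and
#' introduces `nMutations` point mutations, at most one per codon, each
#' carried by a random non-empty subset of the non-reference sequences.
#' Every mutation is classified synonymous or nonsynonymous by standard
#' codon-table lookup and recorded in a ledger, so downstream diversity
#' statistics can be checked against known truth. Sequence 1 is the
#' unmutated reference.
#'
#' @param nSeqs number of sequences (>= 2)
#' @param nCodons CDS length in codons (>= 1)
#' @param nMutations number of mutated codon sites; must not exceed `nCodons`
#' @param seed integer seed
#' @return list with `alignment` (a [Biostrings::DNAStringSet]), `ledger`
#'   (data.frame: site, codon, refBase, altBase, refAA, altAA, type,
#'   carriers), and the implied `nSynonymous` / `nNonsynonymous` counts.
#' @examples
#' sim <- simulateCdsAlignment(6, 50, 5, seed = 1)
#' sim$ledger
#' @export
simulateCdsAlignment <- function(nSeqs, nCodons, nMutations, seed = NULL) {
  if (nCodons < 1) stop("nCodons must be >= 1")
  if (nSeqs < 2) stop("nSeqs must be >= 2")
  if (nMutations > nCodons)
    stop("requested mutations exceed available sites (one per codon)")
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  withSeed(seed, {
    refCodons <- sample(sense, nCodons, replace = TRUE)
    seqs <- matrix(rep(unlist(strsplit(paste(refCodons, collapse = ""), "")),
                       nSeqs), nrow = nSeqs, byrow = TRUE)
    ledger <- NULL
    if (nMutations > 0) {
      mutCodon <- sort(sample.int(nCodons, nMutations))
      rows <- lapply(mutCodon, function(ci) {
        pos <- sample.int(3, 1)
        site <- (ci - 1) * 3 + pos
        refC <- refCodons[ci]
        refB <- substr(refC, pos, pos)
        altB <- sample(setdiff(c("A", "C", "G", "T"), refB), 1)
        altC <- refC
        substr(altC, pos, pos) <- altB
        carriers <- which(runif(nSeqs - 1) < 0.5) + 1L
        if (!length(carriers)) carriers <- sample(2:nSeqs, 1)
        data.frame(site = site, codon = ci, refBase = refB, altBase = altB,
                   refCodon = refC, altCodon = altC,
                   refAA = unname(code[refC]), altAA = unname(code[altC]),
                   type = if (code[refC] == code[altC]) "synonymous"
                          else "nonsynonymous",
                   carriers = paste(carriers, collapse = ","))
      })
      ledger <- do.call(rbind, rows)
      for (k in seq_len(nrow(ledger))) {
        carr <- as.integer(strsplit(ledger$carriers[k], ",")[[1]])
        seqs[carr, ledger$site[k]] <- ledger$altBase[k]
      }
    }
    aln <- Biostrings::DNAStringSet(apply(seqs, 1, paste, collapse = ""))
    names(aln) <- c("reference", sprintf("var%02d", seq_len(nSeqs - 1)))
    list(alignment = aln, ledger = ledger,
         nSynonymous = if (is.null(ledger)) 0L
                       else sum(ledger$type == "synonymous"),
         nNonsynonymous = if (is.null(ledger)) 0L
                          else sum(ledger$type == "nonsynonymous"))
  })
}
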