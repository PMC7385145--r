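#' Marker quality control and mean imputation
#'
#' Removes markers with minor allele frequency below `mafMin`, with more
#' than `maxMissing` missing calls, or with more than `maxHet` heterozygous
#' calls. Rates and allele frequencies are computed on observed calls
#' before imputation; heterozygous calls count toward the heterozygosity
#' rate and are treated as missing for frequency computation (the panel is
#' inbred). Remaining missing or heterozygous calls of surviving markers
#' are imputed with the marker's mean observed homozygous dosage, so
#' imputed dosages may be fractional.
#'
#' @param geno a [GenotypeData]
#' @param mafMin minimum minor allele frequency (inclusive: a marker at
#'   exactly `mafMin` is retained)
#' @param maxMissing maximum tolerated missing-call rate (exclusive: a rate
#'   strictly greater is removed)
#' @param maxHet maximum tolerated heterozygous-call rate (exclusive)
#' @return list with `geno` (filtered, fully imputed [GenotypeData]) and
#'   `report` (class `QCReport`)
#' @examples
#' gd <- simulateGenotypes(30, 200, missingRate = 0.02, seed = 1)
#' qc <- qcFilter(gd)
#' qc$report
#' @export
qcFilter <- function(geno, mafMin = 0.05, maxMissing = 0.05, maxHet = 0.05) {
  stopifnot(is(geno, "GenotypeData"))
  if (any(c(mafMin, maxMissing, maxHet) < 0) ||
      any(c(mafMin, maxMissing, maxHet) > 1))
    stop("thresholds must lie in [0, 1]")
  d <- dosages(geno)
  n <- ncol(d)
  isHet <- !is.na(d) & d == 1
  isMiss <- is.na(d)
  hetRate <- rowSums(isHet) / n
  missRate <- rowSums(isMiss) / n
  dHom <- d
  dHom[isHet] <- NA_real_
  nObs <- rowSums(!is.na(dHom))
  pAlt <- ifelse(nObs > 0, rowSums(dHom, na.rm = TRUE) / (2 * nObs), NA_real_)
  maf <- pmin(pAlt, 1 - pAlt)
  failMaf <- is.na(maf) | maf < mafMin
  failMiss <- missRate > maxMissing
  failHet <- hetRate > maxHet
  keep <- !(failMaf | failMiss | failHet)
  if (!any(keep)) stop("QC removed every marker")
  report <- structure(list(
    input = nrow(d),
    removedMaf = sum(failMaf),
    removedMissing = sum(failMiss & !failMaf),
    removedHet = sum(failHet & !failMaf & !failMiss),
    imputedCalls = sum((isHet | isMiss)[keep, ]),
    surviving = sum(keep)), class = "QCReport")
  dKeep <- dHom[keep, , drop = FALSE]
  mean_k <- rowMeans(dKeep, na.rm = TRUE)
  naIdx <- which(is.na(dKeep), arr.ind = TRUE)
  if (nrow(naIdx)) dKeep[naIdx] <- mean_k[naIdx[, 1]]
  out <- GenotypeData(dKeep, markerMap(geno))
  SummarizedExperiment::colData(out) <-
    SummarizedExperiment::colData(geno)
  list(geno = out, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf(paste0("QC: %d markers in; removed %d (MAF), %d (missing), ",
                     "%d (het); %d imputed calls; %d surviving\n"),
              x$input, x$removedMaf, x$removedMissing, x$removedHet,
              x$imputedCalls, x$surviving))
  invisible(x)
}

#' Linkage disequilibrium r-squared between two markers
#'
#' Squared Pearson correlation of the dosage vectors. For fully inbred
#' (0/2) data this equals the classical haplotype-frequency form
#' r2 = (p_ab - p_a p_b)^2 / (p_a(1-p_a) p_b(1-p_b)).
#'
#' @param geno a [GenotypeData]
#' @param markerA,markerB marker ids or indices
#' @return r-squared in \[0, 1\]; `NA` with a warning for a monomorphic
#'   marker
#' @export
ldR2 <- function(geno, markerA, markerB) {
  d <- dosages(geno)
  a <- d[markerA, ]; b <- d[markerB, ]
  ok <- !is.na(a) & !is.na(b)
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
    warning("monomorphic marker: r2 undefined")
    return(NA_real_)
  }
  cor(a[ok], b[ok])^2
}

#' LD decay profile against genetic distance
#'
#' Computes r-squared for all within-chromosome pairs of mapped markers up
#' to `maxDistanceCM` apart, and summarises the decay by binned medians.
#'
#' @param geno a [GenotypeData] (QC-passed recommended)
#' @param maxDistanceCM maximum genetic distance between pair members
#' @param binWidthCM width of the distance bins for the decay summary
#' @return list of class `LDResult` with `pairs` (data.frame: markerA,
#'   markerB, chrom, distanceCM, r2), `decay` (binned medians), and
#'   `nUnmapped` (markers excluded for missing map positions)
#' @export
ldDecayProfile <- function(geno, maxDistanceCM = 10, binWidthCM = 1) {
  map <- markerMap(geno)
  unmapped <- is.na(map$cM) | is.na(map$chrom)
  if (all(unmapped)) stop("no mapped markers")
  d <- dosages(geno)[!unmapped, , drop = FALSE]
  map <- map[!unmapped, , drop = FALSE]
  res <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    idx <- idx[order(map$cM[idx], map$marker[idx])]
    if (length(idx) < 2) next
    pos <- map$cM[idx]
    dd <- abs(outer(pos, pos, "-"))
    sel <- which(upper.tri(dd) & dd <= maxDistanceCM, arr.ind = TRUE)
    if (!nrow(sel)) next
    sub <- t(d[idx, , drop = FALSE])
    sds <- apply(sub, 2, sd)
    poly <- sds[sel[, 1]] > 0 & sds[sel[, 2]] > 0
    sel <- sel[poly, , drop = FALSE]
    if (!nrow(sel)) next
    r2 <- vapply(seq_len(nrow(sel)), function(k)
      cor(sub[, sel[k, 1]], sub[, sel[k, 2]])^2, numeric(1))
    res[[ch]] <- data.frame(
      markerA = map$marker[idx][sel[, 1]],
      markerB = map$marker[idx][sel[, 2]],
      chrom = ch, distanceCM = dd[sel], r2 = r2)
  }
  pairs <- do.call(rbind, res)
  if (is.null(pairs) || !nrow(pairs)) stop("no marker pairs within range")
  rownames(pairs) <- NULL
  bins <- cut(pairs$distanceCM,
              breaks = seq(0, maxDistanceCM + binWidthCM, by = binWidthCM),
              include.lowest = TRUE)
  decay <- data.frame(
    bin = levels(bins),
    midCM = seq(binWidthCM / 2, by = binWidthCM, length.out = nlevels(bins)),
    n = as.integer(table(bins)),
    medianR2 = as.numeric(tapply(pairs$r2, bins, median)))
  structure(list(pairs = pairs, decay = decay[decay$n > 0, ],
                 nUnmapped = sum(unmapped)), class = "LDResult")
}

#' @export
print.LDResult <- function(x, ...) {
  cat("LD decay:", nrow(x$pairs), "pairs;", x$nUnmapped,
      "unmapped markers excluded\n")
  print(x$decay, row.names = FALSE)
  invisible(x)
}

#' Principal component analysis of the dosage matrix
#'
#' SVD of the column-centered lines x markers matrix (each marker centered
#' at its mean dosage). Scores are the left singular vectors scaled by the
#' singular values; variance proportions are normalized squared singular
#' values, so they sum to 1 over all components.
#'
#' @param geno a [GenotypeData] with no missing calls (run [qcFilter] first)
#' @param k number of leading components to return (clipped with a warning
#'   when it exceeds the matrix rank bound)
#' @return list of class `PCAResult` with `scores` (lines x k),
#'   `propVar` (length k), and `propVarAll` over all components
#' @export
pcaGenotypes <- function(geno, k = 10) {
  W <- dosagesLxM(geno)
  if (any(is.na(W))) stop("missing calls present: impute before PCA")
  kmax <- min(nrow(W) - 1, ncol(W))
  if (k > kmax) {
    warning("k exceeds min(n, p); clipped to ", kmax)
    k <- kmax
  }
  Wc <- scale(W, center = TRUE, scale = FALSE)
  sv <- svd(Wc, nu = k, nv = 0)
  prop <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(W), paste0("PC", seq_len(k)))
  structure(list(scores = scores, propVar = prop[seq_len(k)],
                 propVarAll = prop), class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "lines;",
      "variance explained by shown PCs:",
      paste0(round(100 * x$propVar, 1), "%", collapse = " "), "\n")
  invisible(x)
}
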