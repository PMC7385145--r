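#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor cor.test median optimize pnorm pt qnorm rbeta rbinom
#'   rgamma rnorm runif sd setNames var anova as.formula coef ks.test lm
#'   p.adjust quantile rchisq
#' @importFrom utils read.delim write.table head
NULL

#' GenotypeData: SNP dosages with a marker map
#'
#' Container for a biallelic SNP genotype matrix of an inbred diversity
#' panel, following the SummarizedExperiment convention: markers as rows,
#' lines (varieties) as columns, and the marker map (chromosome, genetic
#' position in cM, optional physical position in bp) as `rowData`. Dosages
#' count copies of the alternate allele (0, 1, 2); `NA` marks missing calls.
#' After mean imputation dosages may be fractional, so validity only
#' requires values in \[0, 2\] or `NA`.
#'
#' @slot ... inherits all slots from [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!is.numeric(d))
      msg <- c(msg, "dosage assay must be numeric")
    else {
      rng <- suppressWarnings(range(d, na.rm = TRUE))
      if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
        msg <- c(msg, "dosages must lie in [0, 2] or be NA")
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "cM") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain marker map columns 'chrom' and 'cM'")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "marker (row) and line (column) names are required")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix of allele dosages, markers x lines, with
#'   marker ids as rownames and line ids as colnames. A lines x markers
#'   matrix is also accepted when `markersAsRows = FALSE`.
#' @param map data.frame with one row per marker and columns `marker`,
#'   `chrom`, `cM` and optionally `bp`. Markers present in `dosage` but
#'   absent from `map` are kept with `NA` map entries (flagged unmapped).
#' @param markersAsRows logical; orientation of `dosage`.
#' @return A [GenotypeData] object.
#' @examples
#' d <- matrix(c(0, 2, 2, 0, 0, 2), nrow = 3,
#'             dimnames = list(paste0("m", 1:3), c("L1", "L2")))
#' gd <- GenotypeData(d, data.frame(marker = paste0("m", 1:3),
#'                                  chrom = "1A", cM = c(0, 5, 10)))
#' gd
#' @export
GenotypeData <- function(dosage, map = NULL, markersAsRows = TRUE) {
  if (!markersAsRows) dosage <- t(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("m", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("line", seq_len(ncol(dosage)))
  storage.mode(dosage) <- "double"
  if (is.null(map)) {
    map <- data.frame(marker = rownames(dosage),
                      chrom = NA_character_, cM = NA_real_, bp = NA_real_)
  }
  if (!"bp" %in% colnames(map)) map$bp <- NA_real_
  stopifnot(all(c("marker", "chrom", "cM") %in% colnames(map)))
  idx <- match(rownames(dosage), map$marker)
  rd <- S4Vectors::DataFrame(
    chrom = as.character(map$chrom)[idx],
    cM = as.numeric(map$cM)[idx],
    bp = as.numeric(map$bp)[idx],
    row.names = rownames(dosage))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowData = rd)
  new("GenotypeData", se)
}

#' @describeIn GenotypeData dosage matrix, markers x lines
#' @param x,object a `GenotypeData` object
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeData dosage matrix oriented lines x markers, the
#'   orientation used by GWAS and prediction (n x p matrix W)
#' @export
dosagesLxM <- function(x) t(SummarizedExperiment::assay(x, "dosage"))

#' @describeIn GenotypeData marker map as a data.frame
#'   (marker, chrom, cM, bp)
#' @export
markerMap <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(marker = rownames(x), chrom = rd$chrom, cM = rd$cM, bp = rd$bp,
             row.names = NULL)
}

#' @describeIn GenotypeData marker identifiers
#' @export
markerNames <- function(x) rownames(x)

#' @describeIn GenotypeData line (variety) identifiers
#' @export
lineNames <- function(x) colnames(x)

setMethod("show", "GenotypeData", function(object) {
  d <- dosages(object)
  nmiss <- sum(is.na(d))
  mapped <- sum(!is.na(SummarizedExperiment::rowData(object)$cM))
  cat("GenotypeData:", nrow(object), "markers x", ncol(object), "lines\n")
  cat("  mapped markers:", mapped, "| missing calls:", nmiss, "\n")
  cat("  chromosomes:",
      paste(unique(stats::na.omit(
        SummarizedExperiment::rowData(object)$chrom)), collapse = " "), "\n")
})

# run expr under a temporary seed, restoring RNG state afterwards
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# derive a reproducible sub-seed for a named stage from a master seed,
# kept below 2^31 (R integers are 32-bit)
subSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435L + h) %% 2147483647)
}
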