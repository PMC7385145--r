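# TSV dialect used throughout: tab-separated, header row, '.' as missing
# token, UTF-8, '#'-prefixed metadata lines (seed and config hash).

#' Write a table in the package TSV dialect
#'
#' @param x data.frame
#' @param path output path
#' @param meta named character vector written as `# key=value` header lines
#'   (e.g. seed and config hash)
#' @return `path`, invisibly
#' @export
writeTsv <- function(x, path, meta = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), "=", meta), con)
  x <- as.data.frame(x)
  for (j in seq_along(x)) if (is.numeric(x[[j]]))
    x[[j]] <- ifelse(is.na(x[[j]]), ".", format(x[[j]], digits = 15,
                                                scientific = FALSE,
                                                trim = TRUE))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Read a table in the package TSV dialect
#'
#' @param path input path
#' @return data.frame (metadata lines in `attr(, "meta")`)
#' @export
readTsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  out <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                    na.strings = ".", stringsAsFactors = FALSE)
  attr(out, "meta") <- sub("^#\\s*", "", meta)
  out
}

#' Read a genotype matrix from VCF or TSV
#'
#' VCF: biallelic records only; multi-allelic records are skipped and
#' counted. GT fields are converted to alternate-allele dosages
#' (0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> NA). The map is populated from
#' CHROM/POS (bp); genetic positions come from `mapPath` when given.
#' TSV: markers x lines dosage matrix with a `marker` id column, '.' as
#' missing; the map is read from `mapPath` (columns marker, chrom, cM, bp).
#'
#' @param path genotype file
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension)
#' @param mapPath optional map TSV
#' @return a [GenotypeData]; for VCF the number of skipped multi-allelic
#'   records is in `attr(, "skippedMultiallelic")` of the metadata
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv"),
                          mapPath = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  map <- if (!is.null(mapPath)) readTsv(mapPath) else NULL
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", vcfR::getALT(v))
    nSkipped <- sum(multi)
    v <- v[!multi, ]
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dos[clean %in% c("0/0", "0")] <- 0
    dos[clean %in% c("0/1", "1/0")] <- 1
    dos[clean %in% c("1/1", "1")] <- 2
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    vmap <- data.frame(marker = rownames(gt), chrom = fix$CHROM,
                       cM = NA_real_, bp = as.numeric(fix$POS))
    if (!is.null(map)) {
      idx <- match(vmap$marker, map$marker)
      vmap$cM <- map$cM[idx]
    }
    gd <- GenotypeData(dos, vmap)
    S4Vectors::metadata(gd)$skippedMultiallelic <- nSkipped
    gd
  } else {
    tab <- readTsv(path)
    if (!"marker" %in% colnames(tab))
      stop("parse error: TSV dosage matrix needs a 'marker' column")
    dos <- as.matrix(tab[, setdiff(colnames(tab), "marker"), drop = FALSE])
    rownames(dos) <- tab$marker
    GenotypeData(dos, map)
  }
}

#' Write genotypes as a TSV dosage matrix plus map TSV
#'
#' @param geno a [GenotypeData]
#' @param path dosage TSV path
#' @param mapPath map TSV path (marker, chrom, cM, bp); skipped when NULL
#' @param meta metadata header lines, as in [writeTsv]
#' @export
writeGenotypesTsv <- function(geno, path, mapPath = NULL, meta = NULL) {
  d <- as.data.frame(dosages(geno))
  writeTsv(cbind(marker = markerNames(geno), d), path, meta)
  if (!is.null(mapPath)) writeTsv(markerMap(geno), mapPath, meta)
  invisible(path)
}

#' Write genotypes as VCF
#'
#' Chromosomes become contigs, positions are 1-based bp (markers without a
#' bp position get consecutive placeholder positions), REF/ALT are coded
#' A/C, and dosages become GT fields (0 -> 0/0, 1 -> 0/1, 2 -> 1/1,
#' NA -> ./.). Only unimputed integer dosages can be represented.
#'
#' @param geno a [GenotypeData] with integer dosages
#' @param path output VCF path
#' @export
writeGenotypesVcf <- function(geno, path) {
  d <- dosages(geno)
  if (any(!is.na(d) & !d %in% c(0, 1, 2)))
    stop("fractional (imputed) dosages cannot be written as VCF GT")
  map <- markerMap(geno)
  chrom <- ifelse(is.na(map$chrom), "chrUn", map$chrom)
  pos <- map$bp
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    bad <- is.na(pos[idx])
    if (any(bad)) pos[idx][bad] <- max(0, pos[idx][!bad]) + seq_len(sum(bad))
  }
  gtCode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  for (k in names(gtCode)) gt[!is.na(d) & d == as.numeric(k)] <- gtCode[k]
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", unique(chrom), ">"),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", lineNames(geno)), collapse = "\t"))
  body <- vapply(seq_len(nrow(d)), function(i)
    paste(c(chrom[i], format(pos[i], scientific = FALSE), map$marker[i],
            "A", "C", ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t"),
    character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read / write long-format phenotypes
#'
#' Long-format TSV with header columns genotype, environment, trait, value.
#'
#' @param path TSV path
#' @return data.frame with those four columns
#' @export
readPhenotypes <- function(path) {
  out <- readTsv(path)
  need <- c("genotype", "environment", "trait", "value")
  if (!all(need %in% colnames(out)))
    stop("parse error: phenotype TSV needs columns ",
         paste(need, collapse = ", "))
  out$value <- as.numeric(out$value)
  out
}

#' @rdname readPhenotypes
#' @param pheno long-format phenotype data.frame
#' @param meta metadata header lines
#' @export
writePhenotypes <- function(pheno, path, meta = NULL)
  writeTsv(pheno[, c("genotype", "environment", "trait", "value")], path,
           meta)

#' Read a FASTA alignment
#'
#' @param path FASTA file with equal-length aligned sequences
#' @return a [Biostrings::DNAStringSet]
#' @export
readAlignmentFasta <- function(path) {
  aln <- Biostrings::readDNAStringSet(path)
  if (length(unique(Biostrings::width(aln))) > 1)
    stop("sequences are not aligned (unequal lengths)")
  aln
}

#' @rdname readAlignmentFasta
#' @param aln a [Biostrings::DNAStringSet]
#' @export
writeAlignmentFasta <- function(aln, path) {
  Biostrings::writeXStringSet(aln, path)
  invisible(path)
}
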