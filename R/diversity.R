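.alnMatrix <- function(aln) {
  if (is(aln, "DNAStringSet") || is(aln, "BStringSet")) {
    if (length(unique(Biostrings::width(aln))) > 1)
      stop("sequences must all have the same length")
    m <- do.call(rbind, strsplit(as.character(aln), ""))
    rownames(m) <- names(aln)
  } else if (is.character(aln)) {
    if (length(unique(nchar(aln))) > 1)
      stop("sequences must all have the same length")
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln)
  } else if (is.matrix(aln)) m <- toupper(aln)
  else stop("unsupported alignment representation")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("alphabet must be {A,C,G,T,N,-}; found: ", paste(bad, collapse = " "))
  m
}

.unambiguous <- function(m) m %in% c("A", "C", "G", "T")

#' Count haplotypes in an alignment
#'
#' Number of distinct sequences under a missing-data-tolerant rule: two
#' sequences are compared only at sites where both carry an unambiguous
#' base (A/C/G/T); sequences indistinguishable under this rule collapse
#' into one haplotype (a sequence joins the first existing haplotype class
#' it is compatible with).
#'
#' @param aln alignment: a [Biostrings::DNAStringSet], character vector of
#'   equal-length sequences, or character matrix (sequences x sites)
#' @return haplotype count H >= 1
#' @export
countHaplotypes <- function(aln) {
  m <- .alnMatrix(aln)
  if (nrow(m) == 0) stop("zero sequences")
  ok <- matrix(.unambiguous(m), nrow(m))
  reps <- 1L  # row indices of haplotype representatives
  for (i in seq_len(nrow(m))[-1]) {
    matched <- FALSE
    for (r in reps) {
      comp <- ok[i, ] & ok[r, ]
      if (!any(m[i, comp] != m[r, comp])) { matched <- TRUE; break }
    }
    if (!matched) reps <- c(reps, i)
  }
  length(reps)
}

#' Nucleotide diversity (pi) per site
#'
#' Average over all unordered sequence pairs of the per-site difference
#' rate, counting only sites where both sequences carry an unambiguous
#' base (pairwise deletion of gaps and Ns). No multiple-hit correction is
#' applied (intra-species, low-divergence data).
#'
#' @inheritParams countHaplotypes
#' @return pi per site; `NA` with a warning if some pair has no comparable
#'   sites
#' @export
nucleotideDiversity <- function(aln) {
  m <- .alnMatrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  ok <- matrix(.unambiguous(m), n)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp)) {
      warning("pair with no comparable sites: pi undefined")
      return(NA_real_)
    }
    vals <- c(vals, sum(m[i, comp] != m[j, comp]) / sum(comp))
  }
  mean(vals)
}

#' Classify coding substitutions as synonymous or nonsynonymous
#'
#' Each variant codon observed in the alignment is compared, as a whole
#' codon, to the reference codon: if both translate to the same amino acid
#' the substitution is synonymous, otherwise nonsynonymous (so multi-hit
#' codons are classified by the whole-codon amino-acid comparison). Counts
#' are over distinct substitutions across the alignment, not per sequence.
#' Codons containing a gap or ambiguity in a sequence are skipped for that
#' sequence and tallied; a partial terminal codon is excluded with a
#' warning.
#'
#' @inheritParams countHaplotypes
#' @param referenceId id (name) or row index of the reference sequence
#' @param frame 0-based offset of the first complete codon
#' @return list of class `SubstitutionReport`: `SS`, `NS`, `perSite`
#'   (data.frame: codon, refCodon, altCodon, refAA, altAA, type, nCarriers),
#'   `skippedCodons`
#' @export
classifySubstitutions <- function(aln, referenceId = 1, frame = 0) {
  m <- .alnMatrix(aln)
  if (is.character(referenceId)) {
    referenceId <- match(referenceId, rownames(m))
    if (is.na(referenceId)) stop("reference sequence not found")
  }
  L <- ncol(m) - frame
  if (L < 3) stop("alignment too short for the given frame")
  nCodons <- L %/% 3
  if (L %% 3 != 0)
    warning("partial terminal codon excluded")
  code <- Biostrings::GENETIC_CODE
  ref <- m[referenceId, ]
  rows <- list()
  skipped <- 0L
  for (ci in seq_len(nCodons)) {
    idx <- frame + (ci - 1) * 3 + 1:3
    refCodon <- paste(ref[idx], collapse = "")
    if (!all(.unambiguous(ref[idx]))) { skipped <- skipped + 1L; next }
    variants <- apply(m[-referenceId, idx, drop = FALSE], 1, paste,
                      collapse = "")
    usable <- vapply(strsplit(variants, ""),
                     function(b) all(.unambiguous(b)), logical(1))
    if (any(!usable)) skipped <- skipped + 1L
    alt <- unique(variants[usable & variants != refCodon])
    for (ac in alt) {
      rows[[length(rows) + 1]] <- data.frame(
        codon = ci, refCodon = refCodon, altCodon = ac,
        refAA = unname(code[refCodon]), altAA = unname(code[ac]),
        type = if (code[refCodon] == code[ac]) "synonymous"
               else "nonsynonymous",
        nCarriers = sum(variants == ac))
    }
  }
  perSite <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(list(
    SS = if (is.null(perSite)) 0L else sum(perSite$type == "synonymous"),
    NS = if (is.null(perSite)) 0L else sum(perSite$type == "nonsynonymous"),
    perSite = perSite, skippedCodons = skipped),
    class = "SubstitutionReport")
}

#' @export
print.SubstitutionReport <- function(x, ...) {
  cat(sprintf("substitutions: %d synonymous, %d nonsynonymous (%d codons skipped)\n",
              x$SS, x$NS, x$skippedCodons))
  invisible(x)
}

#' Per-gene diversity report
#'
#' Convenience wrapper producing the haplotype count (H), synonymous (SS)
#' and nonsynonymous (NS) substitution counts, and nucleotide diversity
#' (Pi) for a set of gene alignments.
#'
#' @param alignments named list of alignments (one per gene)
#' @param referenceId reference sequence id or index, shared by all genes
#' @param frame 0-based reading-frame offset, recycled over genes
#' @return data.frame with columns gene, length, H, SS, NS, Pi
#' @export
diversityReport <- function(alignments, referenceId = 1, frame = 0) {
  if (is.null(names(alignments)))
    names(alignments) <- paste0("gene", seq_along(alignments))
  frame <- rep_len(frame, length(alignments))
  rows <- lapply(seq_along(alignments), function(i) {
    a <- alignments[[i]]
    cls <- classifySubstitutions(a, referenceId, frame[i])
    data.frame(gene = names(alignments)[i],
               length = ncol(.alnMatrix(a)),
               H = countHaplotypes(a),
               SS = cls$SS, NS = cls$NS,
               Pi = nucleotideDiversity(a))
  })
  do.call(rbind, rows)
}
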