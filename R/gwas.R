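#' VanRaden genomic relationship matrix
#'
#' G = Z Z' / (2 sum p_k (1 - p_k)) where Z is the dosage matrix with each
#' marker centered at twice its sample allele frequency (VanRaden method 1).
#' With frequencies estimated from the sample itself every row of G sums to
#' zero. Monomorphic markers contribute nothing to numerator or
#' denominator.
#'
#' @param geno a [GenotypeData] with no missing calls
#' @return n x n symmetric matrix with line ids as dimnames and the allele
#'   frequencies used for centering in `attr(, "alleleFreq")`
#' @export
computeGRM <- function(geno) {
  W <- dosagesLxM(geno)
  if (any(is.na(W))) stop("missing calls present: impute before computeGRM")
  pk <- colMeans(W) / 2
  denom <- 2 * sum(pk * (1 - pk))
  if (denom <= 0) stop("zero denominator: all markers are monomorphic")
  Z <- sweep(W, 2, 2 * pk)
  G <- tcrossprod(Z) / denom
  attr(G, "alleleFreq") <- pk
  G
}

# REML for y = X b + u + e, u ~ N(0, sigma2a * K), e ~ N(0, sigma2e * I),
# via the spectral decomposition of K (one-dimensional profile over
# delta = sigma2e / sigma2a).
.remlMixed <- function(y, X, eigK) {
  n <- length(y)
  q <- ncol(X)
  U <- eigK$vectors
  D <- pmax(eigK$values, 0)
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  profile <- function(logDelta) {
    delta <- exp(logDelta)
    w <- 1 / (D + delta)
    XtWX <- crossprod(Xt, Xt * w)
    b <- solve(XtWX, crossprod(Xt, yt * w))
    r <- yt - Xt %*% b
    rss <- sum(w * r^2)
    s2a <- rss / (n - q)
    ll <- -0.5 * ((n - q) * log(s2a) + sum(log(D + delta)) +
                    determinant(XtWX, logarithm = TRUE)$modulus)
    list(ll = as.numeric(ll), b = b, s2a = s2a, delta = delta)
  }
  opt <- optimize(function(ld) -profile(ld)$ll, interval = c(-12, 12),
                  tol = 1e-9)
  fit <- profile(opt$minimum)
  list(sigma2a = fit$s2a, sigma2e = fit$s2a * fit$delta, delta = fit$delta,
       beta = drop(fit$b), logLik = fit$ll, U = U, D = D)
}

# OLS marker scan by residualizing marker columns against covariates;
# assumes columns of X span the intercept. t-test with df = n - q - 1.
.markerScan <- function(y, X, M) {
  y <- as.numeric(y)
  M <- as.matrix(M)
  n <- length(y)
  q <- qr(X)
  yr <- qr.resid(q, y)
  Mr <- qr.resid(q, M)
  ssm <- colSums(Mr^2)
  scale0 <- colSums(M^2) + 1e-30
  estimable <- ssm / scale0 > 1e-10
  beta <- se <- tval <- p <- rep(NA_real_, ncol(M))
  df <- n - ncol(X) - 1
  xy <- colSums(Mr * yr)
  beta[estimable] <- xy[estimable] / ssm[estimable]
  rss <- sum(yr^2) - beta^2 * ssm
  s2 <- rss / df
  se[estimable] <- sqrt(s2[estimable] / ssm[estimable])
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  list(beta = beta, se = se, p = p, estimable = estimable)
}

#' Mixed-linear-model genome-wide association scan
#'
#' Tests each marker for association with the BLUEs under one of four
#' correction schemes: `naive` (multiple linear regression, no correction),
#' `pc` (the first `nPcs` principal components as fixed covariates), `g`
#' (polygenic random effect with covariance proportional to the genomic
#' relationship matrix), and `pc_g` (both). For the kinship variants the
#' polygenic variance components are estimated once per trait under the
#' no-marker model and reused for every marker test (P3D/EMMAX strategy);
#' `exactReml = TRUE` re-estimates them per marker instead. Wald t-tests
#' on the (whitened) marker regression; the naive variant is exactly the
#' ordinary-least-squares t-test.
#'
#' @param blues named numeric vector of BLUEs (names = line ids)
#' @param geno a QC-passed, imputed [GenotypeData]
#' @param variant one of `"naive"`, `"pc"`, `"g"`, `"pc_g"`
#' @param nPcs number of principal components for the `pc`/`pc_g` variants
#' @param grm optional precomputed GRM (from [computeGRM]); computed from
#'   `geno` when missing
#' @param pca optional precomputed `PCAResult` (from [pcaGenotypes])
#' @param exactReml re-estimate variance components for every marker
#'   (slower; default uses the P3D approximation)
#' @return data.frame of class `AssociationResult`: marker, chrom, cM, bp,
#'   beta, se, p, minusLog10P, estimable; variance components and the
#'   genomic inflation factor in attributes
#' @export
runGwas <- function(blues, geno, variant = c("pc_g", "g", "pc", "naive"),
                    nPcs = 3, grm = NULL, pca = NULL, exactReml = FALSE) {
  variant <- match.arg(variant)
  common <- intersect(names(blues), lineNames(geno))
  if (length(common) < 10)
    stop("too few lines shared between BLUEs and genotypes")
  geno <- geno[, common]
  y <- as.numeric(blues[common])
  M <- dosagesLxM(geno)
  if (any(is.na(M))) stop("missing calls present: impute before runGwas")
  n <- length(y)
  X <- matrix(1, n, 1)
  if (variant %in% c("pc", "pc_g") && nPcs > 0) {
    if (is.null(pca)) pca <- pcaGenotypes(geno, k = nPcs)
    X <- cbind(X, pca$scores[common, seq_len(nPcs), drop = FALSE])
  }
  vc <- NULL
  if (variant %in% c("g", "pc_g")) {
    if (is.null(grm)) grm <- computeGRM(geno)
    K <- grm[common, common]
    eigK <- eigen((K + t(K)) / 2, symmetric = TRUE)
    null <- .remlMixed(y, X, eigK)
    vc <- null[c("sigma2a", "sigma2e", "delta")]
    if (exactReml) {
      out <- .exactScan(y, X, M, eigK)
    } else {
      w <- 1 / sqrt(null$D + null$delta)
      Ut <- t(null$U)
      out <- .markerScan(w * (Ut %*% y), w * (Ut %*% X), w * (Ut %*% M))
    }
  } else {
    out <- .markerScan(y, X, M)
  }
  map <- markerMap(geno)
  res <- data.frame(marker = map$marker, chrom = map$chrom, cM = map$cM,
                    bp = map$bp, beta = out$beta, se = out$se, p = out$p,
                    minusLog10P = -log10(out$p), estimable = out$estimable)
  class(res) <- c("AssociationResult", "data.frame")
  attr(res, "variant") <- variant
  attr(res, "vc") <- vc
  attr(res, "lambdaGC") <- genomicInflation(res$p)
  res
}

.exactScan <- function(y, X, M, eigK) {
  p <- ncol(M)
  beta <- se <- pv <- rep(NA_real_, p)
  estimable <- rep(FALSE, p)
  for (j in seq_len(p)) {
    mj <- M[, j]
    Xa <- cbind(X, mj)
    if (qr(Xa)$rank < ncol(Xa)) next
    fit <- .remlMixed(y, Xa, eigK)
    w <- 1 / sqrt(fit$D + fit$delta)
    Ut <- t(fit$U)
    sc <- .markerScan(w * (Ut %*% y), w * (Ut %*% X),
                      w * (Ut %*% matrix(mj, ncol = 1)))
    beta[j] <- sc$beta; se[j] <- sc$se; pv[j] <- sc$p
    estimable[j] <- sc$estimable
  }
  list(beta = beta, se = se, p = pv, estimable = estimable)
}

#' Genomic inflation factor
#'
#' Median of the association chi-squared statistics divided by the median
#' of the null chi-squared(1) distribution; about 1 for a calibrated scan
#' and above 1 under inflation.
#'
#' @param p vector of P-values (NA allowed)
#' @return lambda_GC
#' @export
genomicInflation <- function(p) {
  p <- p[!is.na(p)]
  median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up FDR control: a P-value is flagged when its BH-adjusted value is
#' at most `q`.
#'
#' @param pvalues vector of P-values in (0, 1\]
#' @param q FDR level (the scan uses a liberal 0.20 by default)
#' @return logical vector of flags (empty input gives an empty vector)
#' @export
fdrAdjust <- function(pvalues, q = 0.20) {
  if (!length(pvalues)) return(logical(0))
  p.adjust(pvalues, method = "BH") <= q
}

#' Genotypic variance explained by marker-trait associations
#'
#' Fits all declared MTA simultaneously in a multiple linear regression of
#' the BLUEs on marker dosages, computes the adjusted coefficient of
#' determination R2_adj = R2 - (z/(N-z-1)) (1-R2) with z fitted markers
#' and N observations, and reports the total explained genotypic variance
#' p_G = (R2_adj / H2) x 100. Per-marker p_G apportions the total by each
#' marker's sequential sum of squares under the chosen entry order
#' (default: most significant first).
#'
#' @param blues named numeric vector of BLUEs
#' @param geno a [GenotypeData] containing the MTA markers
#' @param mta character vector of significant marker ids, or a data.frame
#'   with columns `marker`, `p` and optionally `beta` (used for ordering)
#' @param H2 broad-sense heritability of the trait (> 0)
#' @param order `"ascendingP"` (most significant entered first, default) or
#'   `"descendingP"`; ignored when no P-values are supplied
#' @return list of class `MTASet` with `totalPg`, `perMarker` (data.frame:
#'   marker, seqSS, pG), `R2`, `R2adj`, `z`, `N`
#' @export
genotypicVarianceExplained <- function(blues, geno, mta, H2,
                                       order = c("ascendingP", "descendingP")) {
  order <- match.arg(order)
  if (H2 <= 0) stop("H2 must be > 0")
  if (is.data.frame(mta)) {
    stopifnot("marker" %in% colnames(mta))
    o <- seq_len(nrow(mta))
    if ("p" %in% colnames(mta)) {
      bt <- if ("beta" %in% colnames(mta)) -abs(mta$beta) else 0
      o <- order(if (order == "ascendingP") mta$p else -mta$p, bt, mta$marker)
    }
    markers <- mta$marker[o]
  } else markers <- as.character(mta)
  if (!length(markers))
    return(structure(list(totalPg = 0, perMarker = NULL, R2 = 0, R2adj = 0,
                          z = 0, N = length(blues)), class = "MTASet"))
  missing <- setdiff(markers, markerNames(geno))
  if (length(missing)) stop("MTA absent from genotypes: ",
                            paste(missing, collapse = ", "))
  common <- intersect(names(blues), lineNames(geno))
  W <- dosagesLxM(geno[markers, common])
  y <- as.numeric(blues[common])
  N <- length(y)
  dat <- data.frame(y = y, W)
  colnames(dat) <- c("y", paste0("M", seq_along(markers)))
  fit <- lm(y ~ ., data = dat)
  z <- sum(!is.na(coef(fit))) - 1  # fitted markers (aliased ones drop out)
  if (N <= z + 1) stop("adjustment undefined: N must exceed z + 1")
  R2 <- summary(fit)$r.squared
  R2adj <- R2 - (z / (N - z - 1)) * (1 - R2)
  totalPg <- (R2adj / H2) * 100
  an <- anova(fit)
  ssTerms <- an[rownames(an) != "Residuals", "Sum Sq"]
  termNames <- rownames(an)[rownames(an) != "Residuals"]
  share <- ssTerms / sum(ssTerms)
  perMarker <- data.frame(
    marker = markers[match(termNames, paste0("M", seq_along(markers)))],
    seqSS = ssTerms, pG = totalPg * share, row.names = NULL)
  structure(list(totalPg = totalPg, perMarker = perMarker, R2 = R2,
                 R2adj = R2adj, z = z, N = N), class = "MTASet")
}

#' @export
print.MTASet <- function(x, ...) {
  cat(sprintf("MTA set: %d markers, N = %d, R2 = %.3f, R2adj = %.3f, total p_G = %.2f%%\n",
              x$z, x$N, x$R2, x$R2adj, x$totalPg))
  if (!is.null(x$perMarker)) print(x$perMarker, row.names = FALSE)
  invisible(x)
}
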