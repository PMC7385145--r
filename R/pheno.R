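#' Average correlation coefficients through Fisher's z transform
#'
#' Each correlation r is mapped to z = atanh(r) = 0.5 log((1+r)/(1-r)), the
#' z values are averaged, and the mean is back-transformed with tanh. This
#' gives a less biased average than the arithmetic mean of the r values.
#'
#' @param r numeric vector of correlation coefficients, each strictly
#'   inside (-1, 1)
#' @return the averaged correlation, inside (-1, 1)
#' @examples
#' averageCorrelation(c(0.5, 0.7))
#' @export
averageCorrelation <- function(r) {
  if (!length(r)) stop("empty correlation vector")
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("correlations must lie strictly inside (-1, 1)")
  tanh(mean(atanh(r)))
}

#' REML variance components of the two-way genotype/environment model
#'
#' Fits y_ij = mu + G_i + E_j + e_ij with genotype and environment random,
#' by REML, to per-environment adjusted entry means in long format.
#' Components are constrained non-negative (estimates on the boundary are
#' reported as 0 and flagged).
#'
#' @param pheno long-format data.frame with columns `genotype`,
#'   `environment`, `trait`, `value`
#' @param trait trait name to fit; defaults to the only trait present
#' @return list of class `VarianceComponents`: `sigma2G`, `sigma2E`,
#'   `sigma2e`, `nEnvironments`, `converged`, `boundary`
#' @export
fitVarianceComponents <- function(pheno, trait = NULL) {
  dat <- .traitSubset(pheno, trait)
  nE <- length(unique(dat$environment))
  if (nE < 2)
    stop("sigma2_E is inestimable with a single environment")
  if (length(unique(dat$genotype)) < 2)
    stop("at least two genotypes are required")
  if (max(table(dat$genotype, dat$environment)) < 1 ||
      nrow(dat) <= length(unique(dat$genotype)) + nE)
    stop("no replication structure: too few observations")
  fit <- lme4::lmer(value ~ (1 | genotype) + (1 | environment), data = dat,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2 <- setNames(vc$vcov, vc$grp)
  out <- list(sigma2G = unname(s2["genotype"]),
              sigma2E = unname(s2["environment"]),
              sigma2e = unname(s2["Residual"]),
              nEnvironments = nE,
              converged = length(fit@optinfo$conv$lme4) == 0,
              boundary = any(s2[c("genotype", "environment")] < 1e-10))
  class(out) <- "VarianceComponents"
  out
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat(sprintf("sigma2_G = %.4g, sigma2_E = %.4g, sigma2_e = %.4g (nE = %d)\n",
              x$sigma2G, x$sigma2E, x$sigma2e, x$nEnvironments))
  invisible(x)
}

#' Broad-sense heritability on the entry-mean basis
#'
#' H2 = sigma2_G / (sigma2_G + sigma2_e / nE): the share of the variance of
#' genotype means (over nE environments) attributable to genotypic variance.
#'
#' @param vc a `VarianceComponents` object, or the genotypic variance
#'   sigma2_G when the remaining arguments are given directly
#' @param sigma2e residual variance (ignored when `vc` is a
#'   `VarianceComponents`)
#' @param nE number of environments
#' @return heritability in \[0, 1\]
#' @examples
#' heritability(0.29, 0.24, nE = 8)  # 0.91 at two decimals
#' heritability(0.55, 0.22, nE = 3)  # 0.88
#' @export
heritability <- function(vc, sigma2e = NULL, nE = NULL) {
  if (inherits(vc, "VarianceComponents")) {
    sigma2G <- vc$sigma2G; sigma2e <- vc$sigma2e; nE <- vc$nEnvironments
  } else sigma2G <- vc
  if (any(c(sigma2G, sigma2e) < 0)) stop("variance components must be >= 0")
  den <- sigma2G + sigma2e / nE
  if (den <= 0) stop("zero denominator: sigma2_G + sigma2_e/nE must be > 0")
  sigma2G / den
}

#' Best linear unbiased estimations (BLUEs) across environments
#'
#' Genotype means estimated with genotype (and intercept) fixed and
#' environment random; the reported value is the predicted genotype mean
#' (intercept + genotype effect), so on balanced complete data each BLUE
#' equals the across-environment mean of that genotype.
#'
#' @inheritParams fitVarianceComponents
#' @return named numeric vector of BLUEs, one per genotype
#' @export
computeBlues <- function(pheno, trait = NULL) {
  dat <- .traitSubset(pheno, trait)
  nE <- length(unique(dat$environment))
  if (nE < 2) stop("at least two environments are required for BLUEs")
  dat$genotype <- factor(dat$genotype)
  fit <- lme4::lmer(value ~ 0 + genotype + (1 | environment), data = dat,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  b <- lme4::fixef(fit)
  setNames(as.numeric(b), sub("^genotype", "", names(b)))
}

#' Pearson correlations among traits with two-sided p-values
#'
#' @param blues matrix or data.frame of BLUEs, genotypes in rows and traits
#'   in columns
#' @return list with symmetric matrices `r` (diagonal 1) and `p`; constant
#'   traits produce `NA` entries with a warning
#' @export
traitCorrelations <- function(blues) {
  blues <- as.matrix(blues)
  k <- ncol(blues)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(colnames(blues), colnames(blues))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    ok <- stats::complete.cases(blues[, c(i, j)])
    if (sum(ok) < 3) stop("need >= 3 shared genotypes per trait pair")
    if (sd(blues[ok, i]) == 0 || sd(blues[ok, j]) == 0) {
      warning("constant trait vector: correlation undefined, reported NA")
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- cor.test(blues[ok, i], blues[ok, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p)
}

.traitSubset <- function(pheno, trait) {
  stopifnot(all(c("genotype", "environment", "trait", "value") %in%
                  colnames(pheno)))
  if (is.null(trait)) {
    tr <- unique(pheno$trait)
    if (length(tr) > 1) stop("multiple traits present; specify `trait`")
    trait <- tr
  }
  dat <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  if (!nrow(dat)) stop("no records for trait ", trait)
  if (anyDuplicated(dat[, c("genotype", "environment")]))
    stop("duplicate (genotype, environment) records for trait ", trait)
  dat
}
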