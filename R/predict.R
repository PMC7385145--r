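#' @useDynLib grainQG, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# mixed-model kernel predictor shared by GBLUP and RKHS: REML on the
# training block of K, then conditional-mean genetic values for all lines,
# g_hat = sigma2a * K[, train] V^{-1} (y - mu), V = sigma2a K_tr + sigma2e I
.kernelPredict <- function(y, K, trainIds, testIds, varComp = NULL) {
  Ktr <- K[trainIds, trainIds]
  n <- length(trainIds)
  if (is.null(varComp)) {
    eigK <- eigen((Ktr + t(Ktr)) / 2, symmetric = TRUE)
    fit <- .remlMixed(y, matrix(1, n, 1), eigK)
    varComp <- fit[c("sigma2a", "sigma2e")]
  }
  s2a <- varComp$sigma2a; s2e <- varComp$sigma2e
  V <- s2a * Ktr + diag(s2e, n)
  Vinv <- tryCatch(solve(V), error = function(e) {
    warning("singular mixed-model system: ridge-stabilized solve")
    solve(V + diag(1e-6 * mean(diag(V)) + 1e-12, n))
  })
  one <- rep(1, n)
  mu <- sum(Vinv %*% y) / sum(Vinv)
  gAll <- drop(s2a * K[, trainIds, drop = FALSE] %*% (Vinv %*% (y - mu)))
  list(predictions = setNames(mu + gAll[testIds], testIds), mu = mu,
       sigma2a = s2a, sigma2e = s2e,
       gHat = setNames(gAll, rownames(K)))
}

#' Genomic BLUP prediction
#'
#' Fits y = 1 mu + g + e on the training lines with g ~ N(0, G sigma2_a)
#' and e ~ N(0, I sigma2_e), estimating the variance components by REML on
#' the training data (via the spectral decomposition of the training block
#' of G), then predicts test-line genetic values as the conditional mean
#' given the training records. Equivalent to ridge regression on centered
#' marker dosages with penalty lambda = sigma2_e / sigma2_beta when G is
#' the VanRaden matrix built from those dosages.
#'
#' @param trainBlues named numeric vector of training BLUEs
#' @param grm genomic relationship matrix covering training and test lines
#' @param testIds line ids to predict
#' @param varComp optional list(sigma2a, sigma2e) to fix the variance
#'   components instead of estimating them
#' @return list of class `GblupModel` with `predictions` (named, test
#'   lines), `mu`, `sigma2a`, `sigma2e`, `gHat` (all lines in `grm`)
#' @export
gblupFitPredict <- function(trainBlues, grm, testIds, varComp = NULL) {
  trainIds <- intersect(names(trainBlues), rownames(grm))
  if (length(trainIds) < 2) stop("need at least 2 training lines in the GRM")
  if (!all(testIds %in% rownames(grm)))
    stop("test lines missing from the GRM")
  out <- .kernelPredict(as.numeric(trainBlues[trainIds]), grm,
                        trainIds, testIds, varComp)
  class(out) <- "GblupModel"
  out
}

#' @export
print.GblupModel <- function(x, ...) {
  cat(sprintf("GBLUP: mu = %.3f, sigma2_a = %.4g, sigma2_e = %.4g, %d predictions\n",
              x$mu, x$sigma2a, x$sigma2e, length(x$predictions)))
  invisible(x)
}

#' Gaussian kernel of marker profiles
#'
#' K_ij = exp(-h d2_ij / p) with d2_ij the squared Euclidean distance
#' between the dosage profiles of lines i and j over the p markers.
#'
#' @param geno a [GenotypeData] (imputed)
#' @param h bandwidth (> 0)
#' @return n x n kernel matrix with unit diagonal
#' @export
gaussianKernel <- function(geno, h) {
  if (h <= 0) stop("bandwidth h must be > 0")
  W <- dosagesLxM(geno)
  sq <- rowSums(W^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(W), 0)
  if (max(d2) == 0) stop("degenerate kernel: all marker distances are 0")
  exp(-h * d2 / ncol(W))
}

#' Reproducing-kernel Hilbert-space regression prediction
#'
#' Mixed-model prediction with a Gaussian kernel of marker distances in
#' place of the GRM (captures additive and epistatic signal). The
#' bandwidth is chosen from `hGrid` by an inner k-fold cross-validation on
#' the training set only, so no test information leaks into the choice.
#'
#' @param trainBlues named numeric vector of training BLUEs
#' @param geno a [GenotypeData] covering training and test lines
#' @param testIds line ids to predict
#' @param hGrid candidate bandwidths; default 0.5 x (1/5, 1, 5)
#' @param seed seed for the inner CV partition
#' @param innerFolds folds of the inner bandwidth CV
#' @return list of class `RkhsModel` with `predictions`, `chosenH`,
#'   `innerAccuracy` (mean inner-CV correlation per candidate), `mu`,
#'   `sigma2a`, `sigma2e`
#' @export
rkhsFitPredict <- function(trainBlues, geno, testIds,
                           hGrid = 0.5 * c(1 / 5, 1, 5), seed = NULL,
                           innerFolds = 5) {
  if (!length(hGrid) || any(hGrid <= 0)) stop("hGrid must be positive")
  trainIds <- intersect(names(trainBlues), lineNames(geno))
  if (!all(testIds %in% lineNames(geno)))
    stop("test lines missing from genotypes")
  kernels <- lapply(hGrid, function(h) gaussianKernel(geno, h))
  y <- as.numeric(trainBlues[trainIds])
  inner <- rep(NA_real_, length(hGrid))
  if (length(hGrid) > 1) {
    folds <- withSeed(seed, .makeFolds(length(trainIds), innerFolds))
    for (k in seq_along(hGrid)) {
      accs <- c()
      for (f in unique(folds)) {
        ho <- trainIds[folds == f]
        tr <- setdiff(trainIds, ho)
        if (length(ho) < 3) next
        pr <- .kernelPredict(y[match(tr, trainIds)], kernels[[k]], tr, ho)
        accs <- c(accs, cor(as.numeric(trainBlues[ho]), pr$predictions))
      }
      inner[k] <- mean(accs)
    }
    best <- which.max(inner)
  } else best <- 1L
  out <- .kernelPredict(y, kernels[[best]], trainIds, testIds)
  out$chosenH <- hGrid[best]
  out$innerAccuracy <- setNames(inner, paste0("h=", hGrid))
  class(out) <- "RkhsModel"
  out
}

#' @export
print.RkhsModel <- function(x, ...) {
  cat(sprintf("RKHS: chosen h = %g, mu = %.3f, %d predictions\n",
              x$chosenH, x$mu, length(x$predictions)))
  invisible(x)
}

#' BayesB whole-genome regression prediction
#'
#' Gibbs sampler for the spike-slab prior: each marker effect is zero with
#' probability 1 - pi and otherwise normal with its own variance following
#' a scaled inverse chi-squared prior (df `dfBeta`, scale `Sbeta`), giving
#' marker-specific shrinkage plus variable selection. The scale follows a
#' Gamma hyperprior and pi a Beta prior. Hyper-parameter defaults follow
#' the usual built-in rules: the scale is solved so the prior marker
#' variance accounts for a fraction `r2` of the phenotypic variance given
#' the prior inclusion probability `piPrior`. Markers are centered at
#' their training means. Predictions are intercept + dosages x
#' posterior-mean effects.
#'
#' @param trainBlues named numeric vector of training BLUEs
#' @param geno imputed [GenotypeData] covering training and test lines
#' @param testIds line ids to predict
#' @param nIter,burnIn,thin chain length, burn-in, thinning
#' @param piPrior prior mean proportion of non-zero effects (0 < pi0 < 1)
#' @param piCounts prior counts of the Beta prior on pi
#' @param dfBeta prior degrees of freedom of the marker variances (> 0)
#' @param r2 prior share of phenotypic variance attributed to markers,
#'   used to solve the scale Sbeta
#' @param fixPi fix pi at this value instead of sampling it (pi = 1 with
#'   `commonVariance = TRUE` degenerates to Bayesian ridge regression)
#' @param commonVariance share a single slab variance across markers
#' @param seed integer seed (same seed + config = identical predictions)
#' @return list of class `BayesBModel`: `predictions`, `markerEffects`
#'   (posterior means), `inclusionProb`, `mu`, `sigma2e`, `pi`
#' @export
bayesbFitPredict <- function(trainBlues, geno, testIds,
                             nIter = 12000, burnIn = 2000, thin = 5,
                             piPrior = 0.5, piCounts = 10, dfBeta = 5,
                             r2 = 0.5, fixPi = NULL, commonVariance = FALSE,
                             seed = NULL) {
  if (burnIn >= nIter) stop("burnIn must be smaller than nIter")
  if (dfBeta <= 0) stop("dfBeta must be > 0")
  if (is.null(fixPi) && (piPrior <= 0 || piPrior >= 1))
    stop("piPrior must lie strictly inside (0, 1)")
  trainIds <- intersect(names(trainBlues), lineNames(geno))
  if (!all(testIds %in% lineNames(geno)))
    stop("test lines missing from genotypes")
  W <- dosagesLxM(geno)
  if (any(is.na(W))) stop("missing calls present: impute before BayesB")
  ctr <- colMeans(W[trainIds, , drop = FALSE])
  Xtr <- sweep(W[trainIds, , drop = FALSE], 2, ctr)
  y <- as.numeric(trainBlues[trainIds])
  vy <- var(y)
  msx <- sum(apply(Xtr, 2, var))
  piIn <- if (is.null(fixPi)) piPrior else fixPi
  Sbeta0 <- vy * r2 * (dfBeta + 2) / max(msx * piIn, 1e-12)
  dfE <- 5
  Se <- vy * (1 - r2) * (dfE + 2)
  res <- withSeed(seed, .bayesbGibbs(
    y, Xtr, as.integer(nIter), as.integer(burnIn), as.integer(thin),
    dfBeta, Sbeta0, rGamma = 1.1, sGamma = 1.1 / Sbeta0,
    updateScale = TRUE, piInit = piIn, piCounts = piCounts,
    piPrior = piPrior, updatePi = is.null(fixPi),
    commonVariance = commonVariance, dfE = dfE, Se = Se))
  Xte <- sweep(W[testIds, , drop = FALSE], 2, ctr)
  pred <- setNames(drop(res$mu + Xte %*% res$beta), testIds)
  structure(list(predictions = pred,
                 markerEffects = setNames(res$beta, colnames(W)),
                 inclusionProb = setNames(res$inclProb, colnames(W)),
                 mu = res$mu, sigma2e = res$sigma2e, pi = res$pi,
                 sigma2b = res$sigma2b,
                 nSamples = res$nSamples), class = "BayesBModel")
}

#' @export
print.BayesBModel <- function(x, ...) {
  cat(sprintf("BayesB: mu = %.3f, pi = %.3f, %d posterior samples, %d predictions\n",
              x$mu, x$pi, x$nSamples, length(x$predictions)))
  invisible(x)
}

# balanced fold labels for n observations
.makeFolds <- function(n, k) sample(rep_len(seq_len(k), n))

#' Repeated k-fold cross-validation of genomic prediction models
#'
#' For each cycle the lines are randomly partitioned into `nFolds` subsets;
#' each subset in turn is predicted from the remaining ones. Prediction
#' accuracy per fold is the Pearson correlation between observed and
#' predicted values standardized by the square root of the broad-sense
#' heritability, r_GP = cor(y, yhat) / sqrt(H2). Variance components (and
#' the RKHS bandwidth) are re-estimated inside every training fold.
#'
#' @param blues named numeric vector of BLUEs for all lines
#' @param geno imputed [GenotypeData]
#' @param models subset of `c("gblup", "bayesb", "rkhs")`
#' @param nFolds folds per cycle (default 5)
#' @param nCycles number of repeated random partitions (the full study
#'   design uses 100)
#' @param H2 broad-sense heritability used for standardization (> 0)
#' @param seed master seed; each cycle derives its own partition from it
#' @param grm optional precomputed GRM for GBLUP
#' @param hGrid RKHS bandwidth grid
#' @param bayesbControl list of arguments passed on to [bayesbFitPredict]
#'   (chain length etc.)
#' @return list of class `PredictionCVResult` with `folds` (data.frame:
#'   model, cycle, fold, chosenH, accuracy), `summary` (pooled mean and sd
#'   per model), `perCycle` (per-cycle means)
#' @export
crossValidate <- function(blues, geno,
                          models = c("gblup", "bayesb", "rkhs"),
                          nFolds = 5, nCycles = 100, H2, seed = NULL,
                          grm = NULL, hGrid = 0.5 * c(1 / 5, 1, 5),
                          bayesbControl = list()) {
  models <- match.arg(models, c("gblup", "bayesb", "rkhs"),
                      several.ok = TRUE)
  if (H2 <= 0) stop("H2 must be > 0")
  ids <- intersect(names(blues), lineNames(geno))
  n <- length(ids)
  if (n < nFolds) stop("fewer lines than folds")
  geno <- geno[, ids]
  if (is.null(grm) && "gblup" %in% models) grm <- computeGRM(geno)
  rows <- list()
  for (cyc in seq_len(nCycles)) {
    cycSeed <- if (is.null(seed)) NULL else subSeed(seed, paste0("cv", cyc))
    folds <- withSeed(cycSeed, .makeFolds(n, nFolds))
    for (f in seq_len(nFolds)) {
      testIds <- ids[folds == f]
      trainIds <- setdiff(ids, testIds)
      if (length(testIds) < 3) {
        warning("fold with < 3 test lines skipped")
        next
      }
      yTest <- as.numeric(blues[testIds])
      for (m in models) {
        chosenH <- NA_real_
        pred <- switch(m,
          gblup = gblupFitPredict(blues[trainIds], grm, testIds)$predictions,
          bayesb = do.call(bayesbFitPredict, c(list(
            trainBlues = blues[trainIds], geno = geno, testIds = testIds,
            seed = if (is.null(cycSeed)) NULL else subSeed(cycSeed, m)),
            bayesbControl))$predictions,
          rkhs = {
            fit <- rkhsFitPredict(blues[trainIds], geno, testIds,
                                  hGrid = hGrid,
                                  seed = if (is.null(cycSeed)) NULL
                                         else subSeed(cycSeed, m))
            chosenH <- fit$chosenH
            fit$predictions
          })
        acc <- cor(yTest, pred) / sqrt(H2)
        rows[[length(rows) + 1]] <- data.frame(
          model = m, cycle = cyc, fold = f, chosenH = chosenH,
          accuracy = acc)
      }
    }
  }
  folds <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(folds, folds$model), function(d)
    data.frame(model = d$model[1], mean = mean(d$accuracy),
               sd = sd(d$accuracy), n = nrow(d))))
  rownames(summary) <- NULL
  perCycle <- stats::aggregate(accuracy ~ model + cycle, folds, mean)
  structure(list(folds = folds, summary = summary, perCycle = perCycle),
            class = "PredictionCVResult")
}

#' @export
print.PredictionCVResult <- function(x, ...) {
  cat("Cross-validation accuracy (pooled over cycles x folds):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
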