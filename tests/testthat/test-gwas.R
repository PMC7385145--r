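test_that("GRM matches hand evaluation on a 3-line toy and centers rows", {
  # lines x markers: L1=(0,2), L2=(2,0), L3=(2,2)
  d <- rbind(m1 = c(0, 2, 2), m2 = c(2, 0, 2))
  colnames(d) <- c("L1", "L2", "L3")
  G <- computeGRM(GenotypeData(d))
  # hand arithmetic: p = (2/3, 2/3); Z = W - 4/3; c = 2 * 2 * (2/9)
  W <- t(d); Z <- W - 4 / 3
  cden <- 2 * 2 * (2 / 3) * (1 / 3)
  expect_equal(unname(G), unname(tcrossprod(Z) / cden), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(G))), 1e-8)
})

test_that("GRM is invariant to marker order and monomorphic padding", {
  gd <- qcFilter(simulateGenotypes(40, 150, seed = 8))$geno
  G <- computeGRM(gd)
  # duplicated line gives identical rows/columns
  d <- dosages(gd); d2 <- cbind(d, dup = d[, 3])
  G2 <- computeGRM(GenotypeData(d2, markerMap(gd)))
  expect_equal(unname(G2[, "dup"]), unname(G2[, 3]), tolerance = 1e-12)
  # permutation of markers
  set.seed(9); perm <- sample(nrow(d))
  Gp <- computeGRM(GenotypeData(d[perm, ], markerMap(gd)[perm, ]))
  expect_equal(G, Gp, tolerance = 1e-12, ignore_attr = TRUE)
  # a monomorphic marker contributes nothing
  dm <- rbind(d, mono = rep(2, ncol(d)))
  Gm <- computeGRM(GenotypeData(dm))
  expect_equal(unname(G), unname(Gm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(computeGRM(GenotypeData(rbind(mono = rep(0, 5)))),
               "monomorphic")
})

test_that("naive GWAS equals the OLS t-test marker by marker", {
  fx <- simPanelTrait(nLines = 60, nMarkers = 80, nQtl = 5, seed = 10)
  b <- computeBlues(fx$pheno)
  gw <- runGwas(b, fx$geno, variant = "naive")
  W <- dosagesLxM(fx$geno)[names(b), ]
  for (j in c(1, 17, 53)) {
    ols <- summary(lm(b ~ W[, j]))$coefficients
    expect_equal(gw$beta[j], ols[2, 1], tolerance = 1e-10)
    expect_equal(gw$se[j], ols[2, 2], tolerance = 1e-10)
    expect_equal(gw$p[j], ols[2, 4], tolerance = 1e-10)
  }
  # pc variant equals OLS with the PCs as covariates
  pca <- pcaGenotypes(fx$geno, k = 3)
  gwp <- runGwas(b, fx$geno, variant = "pc", nPcs = 3, pca = pca)
  P <- pca$scores[names(b), 1:3]
  ols <- summary(lm(b ~ P + W[, 17]))$coefficients
  expect_equal(gwp$p[17], ols[5, 4], tolerance = 1e-10)
})

test_that("markers collinear with covariates are reported non-estimable", {
  fx <- simPanelTrait(nLines = 50, nMarkers = 60, nQtl = 3, seed = 11)
  b <- computeBlues(fx$pheno)
  W <- dosagesLxM(fx$geno)
  fakePca <- list(scores = matrix(scale(W[, 5], scale = FALSE),
                                  dimnames = list(rownames(W), "PC1")))
  gw <- runGwas(b, fx$geno, variant = "pc", nPcs = 1, pca = fakePca)
  expect_false(gw$estimable[5])
  expect_true(is.na(gw$p[5]))
  expect_true(all(gw$estimable[-5]))
})

test_that("P3D kinship model agrees with exact per-marker REML", {
  fx <- simPanelTrait(nLines = 50, nMarkers = 40, nQtl = 3, seed = 12)
  b <- computeBlues(fx$pheno)
  g1 <- runGwas(b, fx$geno, variant = "g")
  g2 <- runGwas(b, fx$geno, variant = "g", exactReml = TRUE)
  expect_gt(cor(-log10(g1$p), -log10(g2$p)), 0.99)
})

test_that("BH flags match the brute-force step-up and are monotone in q", {
  expect_identical(fdrAdjust(0.15, 0.2), TRUE)
  expect_identical(fdrAdjust(0.25, 0.2), FALSE)
  expect_identical(fdrAdjust(rep(1, 5), 0.2), rep(FALSE, 5))
  expect_identical(fdrAdjust(numeric(0)), logical(0))
  p <- c(0.01, 0.02, 0.04, 0.9)
  # brute-force step-up: largest k with p_(k) <= k q / m
  stepUp <- function(p, q) {
    m <- length(p); o <- order(p); ps <- p[o]
    k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
    flags <- rep(FALSE, m)
    if (is.finite(k)) flags[o[seq_len(k)]] <- TRUE
    flags
  }
  expect_identical(fdrAdjust(p, 0.2), stepUp(p, 0.2))
  set.seed(13)
  for (i in 1:10) {
    pr <- runif(20)^2
    expect_identical(fdrAdjust(pr, 0.1), stepUp(pr, 0.1))
    # lowering q never adds discoveries
    expect_true(all(fdrAdjust(pr, 0.05) <= fdrAdjust(pr, 0.1)))
  }
})

test_that("explained genotypic variance follows the adjusted-R2 formula", {
  fx <- simPanelTrait(nLines = 100, nMarkers = 200, nQtl = 3, h2 = 0.95,
                      seed = 14)
  b <- computeBlues(fx$pheno)
  H2 <- heritability(fitVarianceComponents(fx$pheno))
  empty <- genotypicVarianceExplained(b, fx$geno, character(0), H2)
  expect_equal(empty$totalPg, 0)
  gw <- runGwas(b, fx$geno, variant = "g")
  mta <- gw[fdrAdjust(gw$p) & gw$estimable, c("marker", "p", "beta")]
  pg <- genotypicVarianceExplained(b, fx$geno, mta, H2)
  # printed correction formula holds exactly for the returned quantities
  expect_equal(pg$R2adj,
               pg$R2 - (pg$z / (pg$N - pg$z - 1)) * (1 - pg$R2),
               tolerance = 1e-12)
  expect_equal(pg$totalPg, pg$R2adj / H2 * 100, tolerance = 1e-12)
  # per-marker shares apportion the total by sequential sums of squares
  expect_equal(sum(pg$perMarker$pG), pg$totalPg, tolerance = 1e-9)
  # most-significant-first entry order
  expect_equal(pg$perMarker$marker[1], mta$marker[which.min(mta$p)])
  expect_error(genotypicVarianceExplained(b, fx$geno, mta, 0), "H2")
  # degenerate N: 3 lines, 2 independent markers saturate the regression
  toy <- GenotypeData(rbind(m1 = c(0, 2, 2), m2 = c(2, 0, 2)))
  bt <- setNames(c(1.2, 0.7, 2.1), lineNames(toy))
  expect_error(genotypicVarianceExplained(bt, toy, c("m1", "m2"), 0.9),
               "adjustment undefined")
})
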