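test_that("Fisher-z averaging reproduces fixed points and the frozen oracle", {
  expect_equal(averageCorrelation(c(0.5, 0.5)), 0.5)
  expect_equal(averageCorrelation(0), 0)
  # frozen high-precision value of tanh((atanh 0.5 + atanh 0.7)/2)
  expect_equal(averageCorrelation(c(0.5, 0.7)), 0.6096117967977923,
               tolerance = 1e-12)
  expect_error(averageCorrelation(c(0.2, 1)), "inside")
  expect_error(averageCorrelation(numeric(0)), "empty")
})

test_that("averaged correlation lies between min and max of its inputs", {
  set.seed(42)
  for (i in 1:20) {
    r <- runif(sample(2:8, 1), -0.95, 0.95)
    rb <- averageCorrelation(r)
    expect_gte(rb, min(r) - 1e-12)
    expect_lte(rb, max(r) + 1e-12)
  }
})

test_that("REML matches the balanced-ANOVA method-of-moments estimators", {
  ph <- balancedPheno(n = 60, nE = 4, sdG = 1, sdE = 1.5, sdRes = 0.7,
                      seed = 8)
  vc <- fitVarianceComponents(ph)
  expect_true(vc$converged)
  # independent oracle: mean squares from the two-way additive ANOVA
  a <- anova(lm(value ~ genotype + environment, data = ph))
  msG <- a["genotype", "Mean Sq"]; msE <- a["environment", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  n <- 60; nE <- 4
  expect_equal(vc$sigma2e, mse, tolerance = 1e-3)
  expect_equal(vc$sigma2G, (msG - mse) / nE, tolerance = 1e-3)
  expect_equal(vc$sigma2E, (msE - mse) / n, tolerance = 1e-3)
})

test_that("REML detects absence of genotypic signal", {
  set.seed(9)
  n <- 300; nE <- 3
  ph <- data.frame(genotype = rep(sprintf("g%03d", 1:n), nE),
                   environment = rep(paste0("e", 1:nE), each = n),
                   trait = "t",
                   value = rep(rnorm(nE, 0, 2), each = n) + rnorm(n * nE))
  vc <- fitVarianceComponents(ph)
  total <- vc$sigma2G + vc$sigma2E + vc$sigma2e
  expect_lt(vc$sigma2G / total, 0.05)
})

test_that("variance-component fitting rejects degenerate designs", {
  ph <- balancedPheno(10, 3, 1, 1, 1)
  expect_error(fitVarianceComponents(ph[ph$environment == "e01", ]),
               "single environment")
  expect_error(fitVarianceComponents(ph, trait = "nope"), "no records")
  dup <- rbind(ph, ph[1, ])
  expect_error(fitVarianceComponents(dup), "duplicate")
})

test_that("heritability follows the entry-mean formula and its monotonicities", {
  expect_equal(round(heritability(0.29, 0.24, nE = 8), 2), 0.91)
  expect_equal(round(heritability(0.55, 0.22, nE = 3), 2), 0.88)
  expect_equal(heritability(1.7, 0, nE = 5), 1)
  expect_error(heritability(0, 0, nE = 4), "denominator")
  expect_error(heritability(-0.1, 0.2, nE = 4), ">= 0")
  # monotone in sigma2G and nE, decreasing in sigma2e
  grid <- seq(0.1, 2, 0.1)
  expect_false(is.unsorted(sapply(grid, heritability, sigma2e = 0.5,
                                  nE = 4)))
  expect_false(is.unsorted(sapply(2:10, function(k)
    heritability(0.5, 0.5, nE = k))))
  expect_false(is.unsorted(rev(sapply(grid, function(s)
    heritability(0.5, s, nE = 4)))))
})

test_that("BLUEs equal genotype means on balanced data and shift with location", {
  ph <- balancedPheno(n = 25, nE = 4, sdG = 1, sdE = 1, sdRes = 0.5,
                      seed = 3)
  b <- computeBlues(ph)
  means <- tapply(ph$value, ph$genotype, mean)
  expect_equal(b[names(means)], means, tolerance = 1e-8,
               ignore_attr = TRUE)
  ph2 <- ph; ph2$value <- ph2$value + 3.7
  expect_equal(computeBlues(ph2), b + 3.7, tolerance = 1e-8)
})

test_that("unbalanced BLUEs match an explicit mixed-model GLS solution", {
  ph <- balancedPheno(n = 3, nE = 3, sdG = 2, sdE = 1, sdRes = 0.5,
                      seed = 5)
  ph <- ph[-c(2, 7), ]  # 7 observations, 2 cells missing
  b <- computeBlues(ph)
  # oracle: GLS with V assembled from the lmer-estimated components
  fit <- lme4::lmer(value ~ 0 + genotype + (1 | environment), data = ph,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  s2E <- as.data.frame(lme4::VarCorr(fit))$vcov[1]
  s2e <- as.data.frame(lme4::VarCorr(fit))$vcov[2]
  Zg <- model.matrix(~ 0 + genotype, ph)
  Ze <- model.matrix(~ 0 + environment, ph)
  V <- s2E * tcrossprod(Ze) + s2e * diag(nrow(ph))
  gls <- solve(t(Zg) %*% solve(V) %*% Zg, t(Zg) %*% solve(V) %*% ph$value)
  expect_equal(unname(b[sort(unique(ph$genotype))]), as.numeric(gls),
               tolerance = 1e-6)
})

test_that("trait correlations reproduce hand-computed Pearson values", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 7)
  # hand oracle: explicit covariance-ratio arithmetic
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  blues <- cbind(t1 = x, t2 = y, t3 = x, t4 = -x)
  tc <- traitCorrelations(blues)
  expect_equal(tc$r["t1", "t2"], rHand, tolerance = 1e-12)
  expect_equal(tc$r["t1", "t3"], 1)
  expect_equal(tc$r["t1", "t4"], -1)
  expect_true(isSymmetric(tc$r))
  expect_equal(unname(diag(tc$r)), rep(1, 4))
  expect_equal(tc$p["t1", "t2"], cor.test(x, y)$p.value)
  # constant trait reported missing with a warning
  expect_warning(tc2 <- traitCorrelations(cbind(a = x, b = rep(1, 5))),
                 "constant")
  expect_true(is.na(tc2$r["a", "b"]))
})
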