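# small deterministic fixtures shared across test files

# hand-built 6-line x 3-marker panel used by the QC tests:
#   m1 (0,0,2,2,0,2)   passes all rules
#   m2 (0,0,2,NA,0,2)  1/6 missing = 16.7% > 5%
#   m3 (0,1,2,2,2,2)   1/6 het; homozygous mean dosage = 8/5 = 1.6
toyPanel <- function() {
  d <- rbind(m1 = c(0, 0, 2, 2, 0, 2),
             m2 = c(0, 0, 2, NA, 0, 2),
             m3 = c(0, 1, 2, 2, 2, 2))
  colnames(d) <- paste0("L", 1:6)
  GenotypeData(d, data.frame(marker = rownames(d), chrom = "1A",
                             cM = c(0, 5, 10)))
}

# QC-passed simulated panel with a simulated trait, memoised per options
simPanelTrait <- function(nLines = 100, nMarkers = 400, nQtl = 10,
                          h2 = 0.9, nE = 4, seed = 1, ...) {
  gd <- qcFilter(simulateGenotypes(nLines, nMarkers, seed = seed, ...))$geno
  sim <- simulateTrait(gd, nQtl = nQtl, h2Target = h2, nEnvironments = nE,
                       seed = seed + 1000)
  list(geno = gd, pheno = sim$pheno, truth = sim$truth)
}

# balanced long-format phenotype table with known components
balancedPheno <- function(n, nE, sdG, sdE, sdRes, mu = 10, seed = 1) {
  set.seed(seed)
  g <- rnorm(n, 0, sdG); E <- rnorm(nE, 0, sdE)
  e <- rnorm(n * nE, 0, sdRes)
  data.frame(genotype = rep(sprintf("g%03d", seq_len(n)), nE),
             environment = rep(sprintf("e%02d", seq_len(nE)), each = n),
             trait = "t",
             value = mu + rep(g, nE) + rep(E, each = n) + e)
}
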