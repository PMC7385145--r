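---
title: "Models and methods behind grainQG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grainQG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainQG)
```

grainQG implements the complete quantitative-genetics workflow used for
multi-environment diversity panels of inbred crop varieties — the kind of
panel in which a few hundred registered wheat varieties are phenotyped for
grain quality traits in several location-by-year environments and genotyped
with dense SNP arrays. This vignette explains each model, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Phenotypic stage

The input is a long table of per-environment *adjusted entry means*
$y_{ij}$ (one value per genotype $i$ and environment $j$ and trait). The
within-environment lattice adjustment that produces those means is out of
scope; entry means are taken as given.

Variance components come from the two-way additive mixed model

$$y_{ij} = \mu + G_i + E_j + e_{ij},$$

with genotype and environment random, fitted by REML through lme4.
Estimates on the zero boundary are reported as 0 and flagged. Broad-sense
heritability is computed on the entry-mean basis,

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_e / n_E},$$

where $n_E$ is the number of environments. Worked check: components
$(0.29, 0.24)$ over 8 environments give $H^2 = 0.91$; $(0.55, 0.22)$ over
3 give $0.88$ (two decimals). Note that for some published component sets
the printed $H^2$ is not exactly reproduced by this formula (e.g. a grain
hardness row printing 0.91 where the components give 0.89); grainQG always
reports the formula value.

BLUEs are the same model with intercept and genotype fixed; the reported
value is the predicted genotype mean (intercept plus genotype effect), so
on balanced complete data every BLUE equals the plain across-environment
mean of that genotype. Across-environment consistency of a trait is
summarised by Fisher-z averaging of pairwise correlations: each $r$ is
mapped to $z = \tfrac12\log\frac{1+r}{1-r}$, the $z$ values are averaged
and back-transformed — less biased than averaging the $r$ values directly.

## Marker stage

Quality control mirrors standard array practice: markers are dropped when
the minor allele frequency is below 0.05 (boundary inclusive), or when
more than 5% of calls are missing, or more than 5% are heterozygous (the
panel is fully inbred, so heterozygous calls are treated as errors:
they count toward the heterozygosity rate and are excluded from
frequency computation). Surviving missing/heterozygous calls are imputed
with the marker's mean observed homozygous dosage — a deliberate,
centering-compatible reading of "imputed with the mean value of both
alleles"; imputed dosages may therefore be fractional. QC is idempotent.

LD between two markers is the squared Pearson correlation of dosage
vectors, which for inbred (0/2) data equals the haplotype-frequency form
$r^2 = (p_{ab} - p_a p_b)^2 / [p_a(1-p_a)\,p_b(1-p_b)]$; it is documented
as an approximation if heterozygotes remain. The decay profile bins all
within-chromosome pairs by cM distance and reports binned medians.
Population structure is assessed by SVD of the marker-centered dosage
matrix; variance proportions are normalized squared singular values.
PCA uses all quality markers by default (mapped and unmapped), since
structure is a property of the whole genotype.

## GWAS

The association model is

$$y = 1\mu + X\beta + Pv + Zu + e, \qquad
  u \sim N(0, G\sigma^2_a), \; e \sim N(0, I\sigma^2_e),$$

where $y$ are BLUEs, $X$ the tested marker, $P$ optional principal
components and $G$ the VanRaden (method 1) genomic relationship matrix

$$G = \frac{\sum_k (w_{ik} - 2p_k)(w_{jk} - 2p_k)}{2\sum_k p_k(1-p_k)}.$$

Four correction variants are exposed (`naive`, `pc`, `g`, `pc_g`, default
3 PCs). For the kinship variants, variance components are estimated once
per trait under the no-marker model and reused for every marker test
(P3D/EMMAX strategy), using a cached spectral decomposition of $G$ and a
one-dimensional REML profile over $\delta = \sigma^2_e/\sigma^2_a$
(optimized to $10^{-9}$ on $\log\delta$); an exact per-marker REML option
exists behind `exactReml = TRUE`. After whitening, each marker is a Wald
t-test; the naive variant is exactly the OLS t-test. Markers collinear
with covariates are reported non-estimable rather than as hits.

Multiple testing uses Benjamini–Hochberg step-up at a deliberately liberal
$q = 0.20$ — the procedure is the default convention where only a generic
FDR reference is given. The genotypic variance explained by the declared
associations is

$$p_G = \frac{R^2_{adj}}{H^2} \times 100, \qquad
  R^2_{adj} = R^2 - \frac{z'}{N - z' - 1}(1 - R^2),$$

from a multiple regression of BLUEs on all associated markers jointly
($z'$ fitted markers, $N$ lines). Markers enter most-significant-first;
the source phrasing ("descending P-values") is ambiguous, so the entry
order is a parameter with ascending-P default, ties broken by $|\beta|$
then marker id. Per-marker $p_G$ apportions the total by sequential sums
of squares under that order.

## Genomic prediction

Three models, all trained per fold:

* **GBLUP** — $y = 1\mu + g + e$, $g \sim N(0, G\sigma^2_a)$, REML per
  training fold, test values from the conditional mean on the partitioned
  $G$. Algebraically identical to ridge regression on centered marker
  dosages with $\lambda = \sigma^2_e/\sigma^2_\beta$ (verified to $10^{-6}$
  in the tests).
* **BayesB** — spike-slab whole-genome regression: each effect is zero
  with probability $1-\pi$ or normal with a marker-specific variance
  following a scaled inverse-$\chi^2(df_\beta, S_\beta)$ prior. Defaults
  follow the usual built-in rules: $df_\beta = 5$, $\pi_0 = 0.5$ with
  Beta prior counts 10, $S_\beta$ solved so the prior marker variance
  accounts for an $R^2$ heuristic of 0.5 of phenotypic variance, a Gamma
  hyperprior on $S_\beta$, and chain defaults 12,000 iterations / 2,000
  burn-in / thin 5. The Gibbs sampler is implemented in C++ on R's RNG,
  so runs are seed-reproducible. Cross-validation experiments in this
  package use a shorter 1,500/500/thin-2 chain — at the panel sizes used
  here (n = 300, p = 1000) posterior means are already stable and the
  fixed-$\pi$ ridge degeneracy check passes, so longer chains change
  accuracies only in the third decimal.
* **RKHS regression** — the same mixed model with a Gaussian kernel
  $K_{ij} = \exp(-h\, d^2_{ij}/p)$ of squared Euclidean marker distances,
  capturing additive plus epistatic signal. The bandwidth is picked from
  the grid $h = 0.5 \times (1/5, 1, 5)$ by an *inner* five-fold CV on the
  training fold only — the source is silent on nesting, and nesting avoids
  information leakage. The chosen $h$ is reported per fold.

The harness is repeated five-fold cross-validation (100 cycles in the
full design; desk-scale experiments here use 10–20). Accuracy is
$r_{GP} = \mathrm{cor}(y, \hat y)/\sqrt{H^2}$ — division by the square
root of $H^2$, never by $H^2$. Reported $\mu/\sigma$ pool all
cycle-by-fold values; per-cycle means are also exported. Folds with
fewer than 3 test lines are skipped with a warning.

## Candidate-gene diversity

For per-gene CDS alignments (FASTA, equal lengths): the haplotype count
collapses sequences that are indistinguishable at sites where both are
unambiguous (tolerates scaffold-level missing data); nucleotide diversity
is the unbiased mean pairwise per-site difference with pairwise deletion
and no multiple-hit correction (intra-species data); substitutions are
classified synonymous/nonsynonymous against a designated reference by
whole-codon amino-acid comparison (multi-hit codons classified as one
event), counting distinct substitutions rather than carriers. Gapped
codons are skipped and tallied; indel events are out of analytic scope.

## Synthetic-data generator

The generator exists so every stage can be validated against known truth
at desk scale. Genotypes: fully inbred 0/2 dosages; subpopulation allele
frequencies follow a Balding–Nichols beta model parameterized by $F_{st}$
(weak continuous structure at small $F_{st}$, matching a panel whose
first two PCs explain only ~12% of variance); LD comes from a
founder-haplotype mosaic (8 founders per subpopulation and chromosome,
founder switches between adjacent markers with probability
$1 - e^{-d/L}$, $L$ calibrated to the requested mean block size), which
gives a tunable monotone $r^2$ decay in cM. Optional heterozygous and
missing calls exist only to exercise QC. Traits: additive QTL effects on
centered dosages plus optional epistatic products; the residual variance
is solved from the realized genetic variance so the entry-mean
heritability hits its target; the truth ledger records QTL, effects,
genetic values and the realized $H^2$. Alignments: sense-codon reference
with at most one point mutation per codon and a synonymous/nonsynonymous
ledger.

What the generator does **not** emulate: genotype-by-environment
interaction, selection or drift dynamics, coalescent-exact LD, ascertainment
bias of real arrays, and growth-habit (winter/spring) covariates. Passing
tests therefore demonstrate correctness of the estimators under the stated
generative model, not performance guarantees on any particular real panel.

## Numerical choices and limitations

* REML profiles are optimized on $\log\delta \in [-12, 12]$; variance
  components are non-negative by construction of the profile.
* Singular mixed-model systems fall back to a ridge-stabilized solve with
  a warning; non-positive-definite kernels are symmetrized and eigenvalues
  clipped at zero.
* Within-chromosome marker order is by cM with ties broken by marker id;
  bp positions are 1-based.
* Desk-scale experiment sizes used throughout the tests and the
  acceptance script (panels of 300–400 lines, 500–2,000 markers, 10–20 CV
  cycles) were chosen as the smallest sizes at which the stochastic
  checks are stable; the full study design (372 lines, ~27k markers, 100
  cycles) runs through exactly the same code paths.
* P-values from the P3D approximation are slightly anti-conservative when
  a tested marker carries a large share of the polygenic variance; the
  exact-REML flag exists for that case.
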