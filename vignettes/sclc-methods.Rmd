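---
title: "Multi-phenotype association testing from summary statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-phenotype association testing from summary statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclc)
```

## The problem

Genome-wide association studies (GWAS) of single traits publish, for every
SNP, a marginal effect estimate, its standard error, and usually a Z score
and p-value. Many clinically related phenotypes — for instance the disease
codes of one ICD chapter — are analysed trait by trait, yet a variant that
influences several of them at once may never reach genome-wide significance
in any single scan. Joint tests of the null hypothesis "this variant is
associated with none of the K phenotypes" can recover that power, and when
only summary statistics are available they must work from the per-SNP Z
score vector

$$Z = (Z_1, \dots, Z_K)^\top, \qquad Z_k = \hat\beta_k / \widehat{se}(\hat\beta_k),$$

whose null distribution is approximately $N(0, R)$ with $R$ the K×K
phenotype correlation matrix (including correlation induced by sample
overlap and other confounding).

This package implements the summary-statistic clustering linear combination
test (sCLC) together with five standard competitors (SSU, Hom, Wald,
PCFisher, aMAT), the LD-score-regression estimator of $R$, and a simulation
toolkit that reproduces the calibration and power experiments used to
validate the method.

## Estimating R from LD score regression intercepts

For phenotypes $s$ and $k$, the expected product of Z scores at SNP $j$
decomposes as

$$E(Z_{sj} Z_{kj}) = G_g\, l_j + \rho_{sk},$$

where $l_j$ is the LD score of SNP $j$ (obtainable from a reference panel),
the slope term $G_g$ carries the genetic covariance, and the intercept
$\rho_{sk}$ is the phenotypic correlation plus any confounding-induced
correlation. `estimate_R()` therefore regresses, across all SNPs, every
pairwise product $Z_s Z_k$ on the LD scores and keeps the intercept; the
univariate case ($s = k$, regressing $Z_k^2$ on $l$) supplies the diagonal.

Three post-processing rules matter:

* **Heritability filter.** The univariate slope implies a heritability
  proxy $\hat h^2 = \text{slope} \cdot M / \bar N$ (or the raw slope when no
  sample size is recorded). Phenotypes whose proxy falls outside $[0, 1]$
  by more than `h2_margin` (default 0.05) are excluded before $R$ is
  assembled. The margin exists because the proxy is a *point estimate*: a
  phenotype with true heritability 0 produces a negative estimate half the
  time, and a literal $[0,1]$ rule would discard half of all null
  phenotypes. Only estimates far outside the parameter space indicate a
  genuinely pathological fit. A non-positive univariate intercept likewise
  excludes the phenotype (a correlation matrix cannot be scaled by it).
* **Normalisation.** The raw univariate intercepts estimate
  $1 + $ confounding inflation, not exactly 1, so the assembled matrix is
  rescaled to unit diagonal ($D^{-1/2} \hat R\, D^{-1/2}$); raw intercepts
  are retained in the report for inspection.
* **PSD repair.** Intercepts are estimated entrywise, so the assembled
  matrix need not be positive definite. Eigenvalues below `psd_floor`
  (default `1e-8`) are clipped and the matrix re-normalised; the
  clip–renormalise pass is iterated because re-normalisation can push the
  smallest eigenvalue slightly back under the floor. Eigenvalue clipping
  is deterministic and adequate for the small violations intercept noise
  produces; a nearest-correlation iteration would add complexity without
  changing any downstream p-value materially.

The regression itself is unweighted ordinary least squares by default.
LDSC software often uses heteroscedasticity-motivated weights to sharpen
the *slope*; here the estimand is the *intercept*, the transparent baseline
is unweighted, and inverse-variance weights remain available via the
`weights` argument. A `max_zsq` cap (off by default) can exclude
large-statistic SNPs before the fit.

## The sCLC test

Given $R$, phenotypes are clustered agglomeratively on the dissimilarity
$D = 1 - R$ entrywise (negative correlations give $D \in (1, 2]$ and are
used as-is — strongly anticorrelated phenotypes are genuinely dissimilar
for the purpose of forming linear combinations with a common sign).
Cutting the tree at every height yields one nested partition for each
cluster count $L = 1, \dots, K$. For the K×L membership matrix $B$ of a
partition, with $W = B^\top R^{-1}$, the cluster-level statistic

$$T^{(L)} = (WZ)^\top (W R W^\top)^{-1} (WZ) \;\sim\; \chi^2_L
\quad \text{under } H_0$$

sums, in effect, an optimally weighted combination of the Z scores within
each cluster and a Wald-type quadratic form across clusters. Two algebraic
identities pin down the family's endpoints and are enforced by tests: at
$L = K$, $W R W^\top = R^{-1}$ and the form collapses to the Wald statistic
$Z^\top R^{-1} Z$; at $L = 1$ it equals the Hom statistic
$(e^\top R^{-1} Z)^2 / (e^\top R^{-1} e)$.

Because the best number of clusters is unknown, the K p-values
$p_1, \dots, p_K$ are aggregated with the Cauchy combination

$$T_{sCLC} = \frac{1}{K} \sum_{L=1}^{K} \tan\big((0.5 - p_L)\,\pi\big),
\qquad p \approx 0.5 - \arctan(T_{sCLC})/\pi .$$

Each transformed term is standard Cauchy under the null, and sums of
dependent Cauchy variables retain an approximately standard Cauchy *tail*,
so the combined p-value is accurate exactly where it matters — at
genome-wide thresholds.

### Numerical choices

* $p_L = 1$ exactly (statistic 0) breaks the tangent transform; p-values
  are clamped to $1 - 10^{-16}$. For $p_L < 10^{-15}$ the transform is
  replaced by its asymptote $1/(p_L \pi)$. Both are the standard ACAT
  stabilisations and preserve the Cauchy tail.
* Combined p-values are clipped into $[5 \times 10^{-324}, 1]$ and also
  reported as $-\log_{10} p$ computed in log space, so a genome scan never
  reports a bare 0 without its magnitude.
* $R^{-1}$ is applied through the Cholesky factor computed once per scan;
  if factorisation fails (e.g. duplicated phenotypes) the matrix is shrunk,
  $(1-\varepsilon) R + \varepsilon I$ with $\varepsilon = 10^{-6}$, with a
  warning — a genome scan must not crash mid-run.
* Chi-square survival functions are evaluated with `lower.tail = FALSE`
  (log-space internally where needed) rather than `1 - pchisq(...)`.

### Clustering determinism

The linkage is selectable (`average` default, `single`, `complete`);
average linkage (UPGMA) is the conventional choice for correlation-derived
distances. Tied merge distances are resolved by choosing the pair whose
(smallest member index, second smallest member index) is lexicographically
least, making the tree — and therefore every p-value — identical across
platforms and runs. The agglomeration is implemented in-package precisely
so this tie rule is guaranteed; on tie-free inputs it coincides with
`stats::hclust` + `cutree`, which the test suite verifies.

## The comparison tests

* **SSU**: $T = Z^\top Z$, whose null is the eigenvalue-weighted chi-square
  mixture $\sum c_i \chi^2_1$. It is approximated by $a\chi^2_d + b$ with
  $a = \sum c^3 / \sum c^2$, $b = \sum c - (\sum c^2)^2/\sum c^3$,
  $d = (\sum c^2)^3/(\sum c^3)^2$ (three-moment match; $d < K$ for
  correlated phenotypes). `weighted_chisq_pvalue()` provides the exact
  mixture tail as an oracle: Imhof's characteristic-function inversion via
  adaptive quadrature, falling back to Ruben's chi-square series — whose
  non-negative coefficients give a certified truncation bound — whenever
  the oscillatory integral cannot reach the requested `1e-8` absolute
  accuracy (typically $K \le 2$). The moment match is good to a few
  percent for p-values down to roughly $2\times 10^{-3}$ and then
  *undershoots* progressively: its tail decays at rate $e^{-q/2a}$ while
  the true mixture decays at $e^{-q/2c_1}$ with $c_1 > a$ whenever the
  eigenvalues are unequal. This is the mechanism behind SSU's inflated
  empirical type-I rates at small $\alpha$, and it means the approximation
  cannot stay within 10% of the exact tail at $p = 10^{-4}$ for any
  realistically heterogeneous spectrum.
* **Hom**: the single optimally weighted linear combination,
  $\chi^2_1$-distributed. With one cohort the sample-size weights cancel.
  Opposite-sign effects cancel *inside* the combination, so Hom's power
  collapses under sign-heterogeneous alternatives — reproduced as a power
  of exactly 0 in scenario 3 below.
* **Wald**: $Z^\top R^{-1} Z \sim \chi^2_K$, equivalently
  $\sum_m PC_m^2/\lambda_m$.
* **PCFisher**: Fisher's combination $-2\sum_m \log p_m \sim \chi^2_{2K}$
  of the two-sided p-values of the standardised principal components
  $PC_m/\sqrt{\lambda_m}$. Two-sided is the natural choice for an
  $N(0, \lambda_m)$ null with sign-free effects.
* **MAT/aMAT**: $T_\gamma = Z^\top R^+_\gamma Z$ with $R^+_\gamma$ the
  pseudoinverse truncated to the $m$ leading singular values satisfying
  $\sigma_1/\sigma_m \le \gamma$; the null is exactly $\chi^2_m$. The
  ratio condition uses $\le$ (a strict inequality would make $\gamma = 1$
  keep nothing; with $\le$ it keeps the top singular value's multiplicity).
  aMAT takes the minimum p-value over $\gamma \in \{1, 10, 30, 50\}$ and
  converts it through a Gaussian copula: the correlation of the
  probit-transformed MAT p-values is estimated once per $R$ from seeded
  null simulations (the MAT statistics are nested chi-square partial sums,
  so these simulations are cheap), and the minimum's tail probability
  under that multivariate normal is evaluated by a Genz-style sequential
  quasi-Monte Carlo routine. Two details keep it honest in the deep tail:
  MAT tests with equal truncation dimension are collapsed first (so the
  perfectly dependent limit returns min-p exactly), and the rectangle
  probability is decomposed into disjoint "first-crossing" terms with the
  tail coordinate ordered first, so the tiny factor
  $1 - \Phi(b)$ multiplies an $O(1)$ conditional estimate and relative
  accuracy survives at $p \sim 10^{-8}$ and far beyond. A genome scan
  evaluates the copula tail on a log-log grid (dense near moderate p,
  where the function bends) and interpolates monotonically, clipped to the
  Fréchet–Bonferroni envelope $[\min p,\ G \min p]$.

## The simulation study

Z score vectors are drawn from $N(\mu, R)$ via the Cholesky factor of $R$.
Two correlation structures are provided:

* `ar1_block_R(K, rho)` — four equal blocks, blocks 1 and 3 with entries
  $\rho^{|s-k|}$, blocks 2 and 4 with $(-\rho)^{|s-k|}$, default
  $\rho = 0.1$, K = 40. Taking the published "$-\rho^{|s-k|}$" literally
  would put $-1$ on the diagonal, which is not a correlation matrix; the
  AR(1)-with-negative-parameter reading is the unique interpretation with
  unit diagonal and is flagged here deliberately. Note two structural
  degeneracies of this matrix that are artefacts of its symmetry: all
  cross-block dissimilarities are exactly 1 (maximally tied for the
  clustering), and its leading eigenvalue has multiplicity 4 (one copy per
  block), which pins aMAT's $\gamma = 1$ truncation at $m = 4$.
* `synthetic_empirical_R()` — a documented synthetic stand-in for the
  sample correlation matrix of ~70 related disease phenotypes: clusters
  with graded within-cluster correlation (base levels 0.15–0.5, geometric
  decay 0.9 within a cluster), weak between-cluster correlation, released
  as the sample correlation of seeded normal draws. Unlike the block
  AR(1), no two dissimilarities are tied and the spectrum is simple, which
  is what an empirical matrix looks like.

Four effect-size scenarios cover same-direction graded effects
(scenario 1), half-null/half-affected (2), mixed-sign (3), and sparse (4).
Scenario 4 requires K divisible by 14 (it was designed for a 70-phenotype
setting; $70 = 14 \times 5$): with K = 40 the package raises an error
rather than guessing a rescaling.

**Replicate counts and effect sizes used by the packaged studies.** Type-I
studies default to $10^5$ null replicates — enough to resolve
$\alpha = 10^{-3}$ with a binomial standard error of $10^{-4}$ — and power
studies to $10^4$ replicates at the genome-wide $\alpha = 5\times 10^{-8}$.
The acceptance studies fix $\beta = 1.5$ for scenarios 1–3 on the 40-dim
block structure (a single matched effect size placing sCLC's scenario-3
power in the mid-range, around 0.66) and $\beta = 2.3$ for scenario 2 on
the 70-dim synthetic matrix (sCLC around 0.4). These were chosen once,
from the calibration sweeps, as the package's study conditions.

`ldsc_fixture()` generates summary statistics under the exact LDSC model:
LD scores from a long-tailed law ($1 + $ Gamma(2, 20), emulating common
variants' LD score distribution), and $Z_j \sim N(0, R_0 + l_j G)$
independently across SNPs, via the decomposition
$Z_j = A^\top \varepsilon + \sqrt{l_j}\, C^\top \eta$ with $A^\top A = R_0$,
$C^\top C = G$. The true intercept matrix is $R_0$ *by construction*, which
is what makes parameter recovery a meaningful test. Held fixed across SNP
counts, this law gives the expected $M^{-1/2}$ shrinkage of recovery error.

### What the generators do not emulate

Real summary statistics have linkage disequilibrium *between* SNPs (here
SNPs are independent given their LD score), binary phenotypes with
case-control imbalance (the saddlepoint-adjusted Z conversion is provided,
but fixtures draw Gaussian Z directly), allele-frequency-dependent power,
and population structure beyond what the LDSC intercept absorbs. Passing
tests therefore validate the statistical machinery — calibration,
identities, recovery, robustness — not end-to-end behaviour on a real
biobank. The real-data pipeline steps that surround the method (genotype
QC, SPA itself, clumping, annotation) are intentionally out of scope.

## Known limitations

* **Bulk conservatism of the Cauchy combination.** The combined sCLC
  p-value is slightly conservative in the middle of its distribution
  (Kolmogorov–Smirnov distance ≈ 0.03–0.04 from uniform at K = 40) because
  the per-L p-values are strongly dependent; the Cauchy approximation is a
  tail approximation. Tail calibration — the property the type-I tables
  report — holds, with a mild anti-conservative drift of a few percent
  relative (e.g. empirical rate ≈ 1.1–1.2 × 10⁻³ at α = 10⁻³), consistent
  with the published behaviour of ACAT-type combinations.
* **SSU's approximation region.** As derived above, the moment-matched SSU
  p-value is reliable for $p \gtrsim 2\times 10^{-3}$ and progressively
  anticonservative below; use `weighted_chisq_pvalue()` when exact SSU
  tails matter.
* **Tie-degenerate correlation structures.** On matrices with exactly tied
  dissimilarities (the block AR(1) is an extreme case), the hierarchical
  tree is decided by the tie-break rule, and *any* perturbation of $R$
  reshapes it, changing sCLC's partitions wholesale. On empirical
  (tie-free, graded) matrices the tree's power-relevant levels are stable;
  verified here by tree-held-fixed experiments in which the sCLC statistic
  itself moves by less than Monte-Carlo noise under perturbation.
* **Sensitivity to R estimation noise at δ = 10⁻⁴.** White noise of
  standard deviation 0.01 on a 70-dim correlation matrix is comparable to
  real LDSC intercept standard errors and is *not* uniformly negligible:
  methods sitting near their power threshold (often Wald/PCFisher, whose
  statistics weight the smallest eigenvalues of $R$) shift by 0.01–0.03
  absolute power, at or just beyond 3 binomial standard errors at 10⁴
  replicates. The qualitative power ordering across methods is preserved.
  At δ = 10⁻⁵ all six methods are stable well within Monte-Carlo noise.
* **Phenotypic, not genetic, clustering.** The tree is built from the
  phenotypic correlation matrix; clustering on an LDSC genetic correlation
  matrix is a natural variant and is deliberately not implemented here.
* Strand-ambiguous (A/T, C/G) SNPs are flagged, not resolved; multi-allelic
  handling and liftover belong to upstream tooling.
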