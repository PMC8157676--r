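---
title: "Window-based GWAS with WPPA: model, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based GWAS with WPPA: model, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery it
implements: the whole-genome regression model, how window posterior
probabilities of association (WPPA) are formed and thresholded, why SNP
density distorts them, the frequentist comparator, the synthetic-data
generator, and the numerical and design choices that were genuinely open.

## 1. Model

For `n` individuals and `p` biallelic markers coded as dosages 0/1/2,

$$y_i = \mu + \sum_{j=1}^{p} m_{ij}\,\alpha_j + e_i,
\qquad e_i \sim N(0, \sigma^2_e),$$

with a flat prior on the intercept and the BayesC$\pi$ mixture prior on
marker effects: each $\alpha_j$ is zero with probability $\pi$ and
$N(0, \sigma^2_\alpha)$ with probability $1-\pi$; $\pi$ has a Uniform(0,1)
prior, and both variances have scaled inverse chi-square priors.

Sampling is the standard single-site Gibbs scheme. For each locus the
inclusion indicator and effect are drawn jointly: the effect is
marginalized when computing the inclusion odds

$$\log\frac{\Pr(\delta_j = 1 \mid \cdot)}{\Pr(\delta_j = 0 \mid \cdot)}
 = \log\frac{1-\pi}{\pi}
 + \tfrac12\log\frac{\lambda}{c_j}
 + \frac{r_j^2}{2\sigma^2_e c_j},$$

with $\lambda = \sigma^2_e/\sigma^2_\alpha$,
$c_j = \mathbf{m}_j'\mathbf{m}_j + \lambda$ and
$r_j = \mathbf{m}_j'(\mathbf{e} + \mathbf{m}_j\alpha_j)$, after which an
included effect is drawn from $N(r_j/c_j,\ \sigma^2_e/c_j)$. Then
$\pi \mid \delta \sim \mathrm{Beta}(p-m+1,\ m+1)$ with $m=\sum_j\delta_j$
(uniform-prior conjugacy), and both variances are drawn from their scaled
inverse chi-square full conditionals. Genotype columns are centered
internally; the intercept absorbs the shift and every downstream variance
summary is shift-invariant, so results are unchanged while mixing improves.

**Hyperparameters.** The sampler's defaults are the conventions of the
whole-genome regression literature rather than estimates:
$\nu_\alpha = \nu_e = 4$; the residual scale is set so the prior mean of
$\sigma^2_e$ equals $(1-g)\,\mathrm{Var}(y)$ and the marker-effect scale so
the prior mean of $\sigma^2_\alpha$ equals
$g\,\mathrm{Var}(y) / \big((1-\pi_0)\sum_j 2f_j(1-f_j)\big)$ with
$\pi_0 = 0.5$, where $g$ is `genetic_variance_guess` (default 0.5, matching
the heritability used throughout the simulation study). Chains default to
5,000 sweeps with 1,000 burn-in and thinning 4 at desk scale — about 1,000
stored draws, enough for WPPA resolution of ~0.001 — and a seed is a
required argument everywhere randomness enters. $\pi$ is clipped to
$[10^{-8}, 1-10^{-8}]$ to avoid degenerate Bernoulli draws.

## 2. Windows, q_w and WPPA

Windows partition the markers either by physical span (`build_windows_bp`;
a marker at bp position $pos$ falls in window $\lfloor (pos-1)/\text{size}
\rfloor$ of its chromosome, i.e. intervals $[k\,\text{size}+1,
(k+1)\text{size}]$ with boundary markers in the lower window) or by fixed
SNP count (`build_windows_count`; never spanning chromosomes, trailing
remainder kept and flagged). Empty physical windows are omitted: `N` counts
testable windows only, which is the count that a threshold $1/N$ should
reflect.

For each stored draw, the window genotypic value is
$\mathbf{g}_w = \mathbf{M}_w \boldsymbol\alpha_w$, its variance is the
*population* variance $\sigma^2_{g_w} = \sum_i g_{w_i}^2/n - (\sum_i
g_{w_i}/n)^2$, and the window's share is $q_w = \sigma^2_{g_w}/\sigma^2_g$.
WPPA is the fraction of draws with $q_w$ **strictly** above the threshold
$T$ (ties do not count). In a draw where every effect is zero
($\sigma^2_g = 0$) all $q_w$ are set to 0, keeping sample counts equal
across windows; the alternative of skipping such draws was rejected for
that reason.

**Threshold schemes and the density artifact.** Under $T = 1/N$ the null
hypothesis is that every *window* explains an equal share of variance. A
window holding 600 of 4,000 SNPs explains ~15% of the variance under a
completely uniform, signal-free model — vastly above $1/N$ — so its WPPA
saturates regardless of the phenotype. The per-window scheme
$T_w = p_w/p$ restates the null as "every *SNP* explains an equal share",
which exactly absorbs the density effect; the fixed-count windows achieve
the same by construction. Changing the scheme never changes $q_w$, only the
exceedance probabilities.

Dense windows are flagged by the Tukey fence: SNP counts above
$Q_3 + 1.5(Q_3-Q_1)$, with quartiles computed by the default
linear-interpolation convention (`quantile` type 7) so that quartiles of 60
and 106 put the fence exactly at 175.

## 3. The frequentist comparator

`emmax_scan` implements the mixed-model windowed test. The null model
$y = \mu\mathbf{1} + u + \varepsilon$ with $u \sim N(0, \sigma^2_{poly} K)$
is fitted once by REML, where $K$ is the VanRaden method-1 genomic
relationship matrix $ZZ'/\sum_j 2f_j(1-f_j)$. REML maximizes over the
variance ratio by a one-dimensional bounded search (tolerance $10^{-8}$) on
the eigen-rotated representation, so a single decomposition of $K$ serves
the fit and every window test. Each window is then tested by generalized
least squares of $y$ on $[\mathbf{1}, \mathbf{M}_w]$ with
$\Sigma = \hat\sigma^2_{poly} K + \hat\sigma^2_{\varepsilon} I$ held fixed
— deliberately reproducing the EMMAX approximation in which the tested
window's SNPs also remain in $K$. The joint Wald statistic is referred to
$\chi^2$ with degrees of freedom equal to the rank of the
intercept-projected window design: $p_w$ for full-rank windows, fewer when
columns are collinear or $p_w \ge n$ (rank from an eigen-threshold of
$10^{-8}$ times the largest eigenvalue, pseudo-inverse statistic). A Wald
form was chosen because it is the GLS statistic consistent with the
$\chi^2(p_w)$ reference; under $\sigma^2_{poly}=0$ it reduces exactly to
the ordinary joint regression chi-square, which the tests exploit as an
oracle. Because the reference distribution's degrees of freedom grow with
$p_w$, dense windows are *not* favored — the property the frequentist test
gets right, and the package's tests check that $-\log_{10}p$ is
uncorrelated with $p_w$ under a structured null.

## 4. The synthetic panel generator

The generator emulates the structure that makes the density artifact
visible on real diversity panels: a few hundred individuals, thousands to
tens of thousands of SNPs, LD within windows, MAF ≥ 0.05, and a long right
tail of per-window SNP counts (a few windows several-fold denser than the
median).

Marker positions follow a piecewise-constant intensity — a baseline density
(default 75 SNPs/Mb) times a `fold` multiplier (default 8) inside hotspot
intervals aligned to whole-Mb boundaries, so dense 1 Mb windows exist
crisply by construction. Haplotypes come from a thresholded AR(1)-type
Gaussian copula: the latent field has adjacent-marker correlation
$\rho\,e^{-d/s}$ (defaults $\rho = 0.9$, $s = 100$ kb), and allele $j$ is 1
when the latent value exceeds $\Phi^{-1}(1-f_j)$ with
$f_j \sim U(0.05, 0.5)$; dosage is the sum of two independent haplotypes,
and columns whose realized MAF falls below the configured minimum are
dropped. This model was chosen over a coalescent simulator for speed and a
single interpretable decay parameter; it reproduces local LD and density
heterogeneity but *not* population structure, admixture, allele-frequency
spectra from demography, or long-range LD — so passing tests demonstrate
the windowing methodology, not robustness to confounding.

Phenotypes are additive: `n_qtl` QTL are drawn uniformly from the SNPs
outside dense windows (mirroring the design in which density-driven hits
are false by construction), effects are i.i.d. standard normal, and
residual variance is set to $\mathrm{Var}_{pop}(g)(1-h^2)/h^2$ — anchored
to the *realized* genetic variance on the fixed panel, which is how a
target heritability is usually imposed on fixed genotypes; `realized_h2`
is recorded so no test assumes exactness. The default study conditions are
$h^2 = 0.5$ with the QTL count scaled to the panel (10 QTL on the ~4,000
SNP desk panel, standing in for 90 on a 33,701-SNP panel).

## 5. Evaluation

A window is a true positive iff it contains at least one QTL; the score is
WPPA (each Bayesian scheme under its own threshold) or $-\log_{10}p$
(frequentist). Power is the partial area under the ROC up to a false
positive rate of 5%, with tied scores grouped into single ROC steps and
linear interpolation at the cap; the area is divided by
$0.05^2/2 = 0.00125$ so a random classifier scores exactly 1 and a perfect
one 40. For the fixed-count scheme the truth labels are recomputed on the
count-based windows, since different windows are tested. The experiment
runner simulates one panel, then per replicate draws a fresh phenotype and
runs all requested methods from one BayesC$\pi$ chain (the threshold
schemes share their posterior), recording rescaled pAUC5 per (method,
replicate) with distinct derived seeds.

Desk-scale defaults throughout — panel of 300 individuals, 4 × 10 Mb
chromosomes, ~4,000 SNPs, ~40 windows; 10 replicates; chains of 5,000
sweeps — were chosen so the full directional suite (permutation
diagnostics, power comparison, both calibration checks) completes in
minutes on one CPU while still leaving wide margins on every directional
assertion.

## 6. Numerical and interface choices

* Coordinates are 1-based bp; boundary membership is specified exactly so
  bucketing is bit-reproducible.
* Allele frequency is computed from dosage sums, MAF = min(f, 1−f), and
  ties at the MAF cutoff are retained (≥).
* Missing dosages are imputed to the column mean rounded to the nearest
  integer dosage (keeping the matrix 0/1/2-coded for the sampler) and
  counted in the load report; individuals missing the phenotype are
  dropped. MAF filtering is applied after sample alignment.
* PLINK input follows the bed convention that dosage counts the A1 (first
  bim) allele; only SNP-major files are supported.
* `reml_null` flags a non-identifiable ratio (all eigenvalues of K equal,
  e.g. K = I) with a warning and reports the boundary value 0.
* Permutation shuffles phenotype values against fixed sample order,
  preserving the value multiset exactly.
* Experiment replicates that fail are marked and skipped rather than
  aborting the run.

## 7. Known limitations

* No fixed effects or covariates beyond the intercept, no multi-trait
  models, and no alternative priors (point-normal only).
* The comparator re-uses null variance components for every window (the
  EMMAX approximation) and does not implement score or likelihood-ratio
  variants.
* The generator's LD is strictly local; conclusions about confounding by
  population structure are out of scope.
* Window construction is non-overlapping only; no sliding or LD-defined
  windows.
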