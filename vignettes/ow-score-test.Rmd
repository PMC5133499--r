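---
title: "The OW-score test: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The OW-score test: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owscore)
```

## The retrospective model

For pedigree $i$ with $n_i$ members, let $y_{ij}$ be a quantitative trait and
$g_{ij} = (g_{ij1}, \dots, g_{ijM})^T$ the minor-allele dosages of the $M$
variants in a genomic region. Given genotypes, the trait is modelled as
$y_{ij} \sim N(a + x_{ij}\beta, \sigma^2)$ with
$x_{ij} = \sum_m w_m g_{ijm}$ a weighted genotype burden. Instead of the
prospective likelihood of traits given genotypes, inference is based on the
*retrospective* likelihood $\prod_i \Pr(g_i \mid y_{i1}, \dots, y_{in_i})$:
traits are conditioned on, so any sampling of families based on trait values
(extreme probands, multiplex ascertainment) drops out of the likelihood. The
score test of $H_0\colon \beta = 0$ derived from it is

$$T(w) = U^2 / V, \qquad
U = \sum_{ij} (x_{ij}-\bar x)(y_{ij}-\bar y), \qquad
V = w^T \Sigma w \cdot \sum_i y_i^T \Phi_i y_i,$$

where $\Sigma$ is the covariance matrix of one individual's dosage vector,
estimated by the pooled sample covariance with divisor $N = \sum_i n_i$, and
$\Phi_i$ is twice the kinship matrix of pedigree $i$. The kinship term is what
accounts for relatedness: under the null, the variance of the score numerator
is proportional to $\sum_i y_i^T \Phi_i y_i$ rather than $\sum_{ij} y_{ij}^2$.

Rare variants in a region are treated as mutually uncorrelated, so $\Sigma$ is
replaced by its diagonal $\Sigma_0$. As a function of $w$, $T_0(w)$ is a
Rayleigh quotient maximised at $w = \Sigma_0^{-1}u$, with maximum

$$T_{\text{OW}} = u^T \Sigma_0^{-1} u \Big/ \sum_i y_i^T \Phi_i y_i
 = \sum_m \frac{u_m^2}{\sigma_{mm}} \Big/ \sum_i y_i^T \Phi_i y_i,$$

a sum of per-variant standardized score contributions. This is the OW-score
statistic (`ow_score_statistic()`). Because the weights are data-driven, the
statistic is no longer $\chi^2_1$; see the null approximation below. The
fixed-weight family (`weighted_score_statistic()`) retains the $\chi^2_1$
reference; Madsen–Browning weights
$w_m = 1/\sqrt{N \hat q_m (1-\hat q_m)}$ with the pseudocount frequency
$\hat q_m = (\sum_{ij} g_{ijm} + 1)/(2N+2)$ give the WS-score comparator.
Because no case/control split exists for a quantitative trait, $\hat q_m$ is
estimated from the full analyzed sample.

### Two-stage covariate adjustment

Covariates are removed before testing: the trait is regressed on an intercept
plus the covariates by ordinary least squares and the residuals are the
analysis trait (`adjust_covariates()`). Repeated measurements (e.g., a blood
pressure recorded at several exams) are averaged per individual first
(`average_repeated_measures()`), and time-varying covariates are averaged the
same way. Family structure is deliberately ignored at this stage: relatedness
enters only through $\Phi_i$ in the test's variance. Residuals are exactly
mean-zero and orthogonal to every covariate column; the adjustment is
idempotent. We do not rescale residuals to unit variance — both statistics are
invariant to affine changes of the trait scale.

One modelling choice deserves note: the quadratic form
$\sum_i y_i^T \Phi_i y_i$ is evaluated with the *centered, adjusted* trait.
The null moments of $u$ require mean-zero trait values, and using raw trait
values would make the variance depend on an arbitrary location shift. With
adjusted residuals the centering is a no-op, but it is applied defensively.

## Null distribution of the OW-score statistic

Under $H_0$, $u \sim N(0, \Sigma \cdot \sum_i y_i^T\Phi_i y_i)$
asymptotically, so $T_{\text{OW}}$ is a quadratic form — a mixture
$\sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the eigenvalues of
$\Sigma_0^{-1/2}\Sigma\,\Sigma_0^{-1/2}$. Two evaluations are provided:

* **Moment-matched scaled chi-square** (default): $\delta \chi^2_d$ with
  $\hat\mu_T = \mathrm{tr}(\hat\Sigma\hat\Sigma_0^{-1})$,
  $\hat\sigma^2_T = 2\,\mathrm{tr}\big((\hat\Sigma\hat\Sigma_0^{-1})^2\big)$,
  $\hat\delta = \hat\sigma^2_T/(2\hat\mu_T)$ and
  $\hat d = 2\hat\mu_T^2/\hat\sigma^2_T$. The identities
  $\delta d = \mu_T$ and $2\delta^2 d = \sigma^2_T$ hold by construction. The
  tail is evaluated on the log scale, so p-values remain reportable down to
  about $10^{-300}$.
* **Chi-square mixture cross-check** (`mixture_chisq_pvalue()`): Imhof's
  characteristic-function inversion. The oscillatory integral is evaluated in
  chunks of at most one oscillation (chunk length
  $\pi / \tfrac12(x + \sum_k\lambda_k)$) with iterated averaging of the
  alternating partial sums; requested absolute accuracy is $10^{-9}$, reliable
  for p-values down to roughly $10^{-8}$. Eigenvalues below $10^{-10}$ of the
  largest are truncated; a failed inversion falls back to the scaled
  chi-square fit with a warning. For diagonal or rank-one $\hat\Sigma$ the two
  methods agree exactly (to quadrature accuracy); a separate Satterthwaite
  variant would duplicate the two-moment fit and is not provided.

Monomorphic variants carry no information and would produce $0/0$ terms; they
are excluded from $u$, $\hat\Sigma$ and $\hat\Sigma_0$, and
`n_variants_used` records the effective $M$. A maximum-MAF filter is available
(`max_maf`) but off by default.

## Kinship

`kinship_matrix()` implements the standard recursion over a founders-first
topological order: founders are assumed mutually unrelated and non-inbred
($\phi(a,a) = 1/2$, $\phi(a,b) = 0$); for a non-founder $c$ with parents $p,
q$: $\phi(c,b) = (\phi(p,b)+\phi(q,b))/2$ and
$\phi(c,c) = 1/2 + \phi(p,q)/2$. Inbreeding loops recorded *within* the
pedigree are handled correctly by the recursion; the autosomal model only (the
sex field is carried but unused). Individuals referenced as parents without
their own record are inserted as founders with a warning, a common FAM-file
dialect. `gene_drop_kinship()` provides an independent Monte-Carlo check:
founder alleles are labelled uniquely and dropped through the pedigree, and
pairwise identity-by-descent frequencies estimate $\phi$.

When the analyzed sample is a subset of the pedigree (missing genotypes or
phenotypes), kinship is computed on the full pedigree and the $\Phi_i$ blocks
are then restricted to analyzed individuals, so relationships through
unretained connectors are preserved. Analysis is complete-case by default;
mean imputation of genotypes is available but off.

## The study simulator

`simulate_study()` generates synthetic pedigree studies for calibration and
power work. Defaults describe a realistic multi-pedigree family study of a
blood-pressure-like trait:

| parameter | default | meaning |
|---|---|---|
| `n_pedigrees` | 20 | families per study |
| template | 42 members, 4 generations | 2 founders, 4 children + spouses, 3 grandchildren each (one marries in), 4 great-grandchildren per couple |
| `M` | 100 | variants per region |
| `maf` | U(0.001, 0.05) | minor allele frequencies (rare) |
| `h2` | 0.3 | polygenic heritability |
| `sigma_total` | 10 | trait SD (mmHg-like) around the mean model |
| `intercept` | 80 | trait location |
| covariates | sex, age, 2 binary exposures | effects −2, 0.05/yr, 3, 1.5 |

Founder genotypes are two independent Bernoulli(MAF) allele draws
(Hardy–Weinberg); descendants receive one allele from each parent, chosen
uniformly per variant per meiosis (`gene_drop()`). The trait is
$y = a + X c + \sum_{\text{causal}} \beta_m g_m + \text{polygenic} +
\varepsilon$, with the polygenic component multivariate normal with covariance
$h^2\sigma^2\Phi_i$ per family and $\varepsilon$ iid
$N(0, (1-h^2)\sigma^2)$ — so $h^2 = 0$ recovers the plain
genotype-conditional normal model, and $h^2 > 0$ exercises the kinship term in
the test's variance. Variance explained by $\beta$ is additional to
$\sigma^2$ rather than carved out of it (power is monotone in $\beta$ either
way). Ascertainment can be simulated by keeping pedigrees whose proband — by
convention the first non-founder in pedigree order — exceeds a trait quantile.

What the simulator does **not** emulate: linkage disequilibrium and haplotype
structure (variants are unlinked and independent at the founder level),
site-frequency spectra of real sequence data, genotyping error, and population
stratification. Passing calibration and power checks on these synthetic
studies therefore demonstrates correctness of the statistic's bookkeeping
under the stated model, not performance on real sequence regions, whose LD
materially changes $\hat\Sigma$ (see the limitations below).

## Evaluation protocol

`run_calibration_study()` mirrors a per-gene null analysis: a fixed set of
pedigrees, a fixed set of simulated null genotype blocks, and repeated trait
replicates; covariates are regressed out per replicate and each test is
applied to each block, pooling one p-value per replicate × block. The
per-block covariance pieces are precomputed, which makes a
200-replicate × 100-block run (20,000 p-values) take seconds; a consistency
test asserts the fast path equals the end-to-end functions. The default
problem sizes — 200 × 50 for tests, 200 × 100 for the acceptance script — give
binomial Monte-Carlo standard errors of about 0.002 at $\alpha = 0.05$ and
0.0002–0.0003 at $\alpha = 0.001$. `run_power_study()` redraws founder
genotypes, covariates and traits per replicate, holding the region's MAF
vector (the "gene") fixed. `phi_mode = "identity"` deliberately omits the
kinship correction to demonstrate that the term is load-bearing: on
family-correlated null traits the rejection rate inflates far above nominal.

## Numerical choices

* Topological ordering by repeated founder-stripping; ties broken by input
  order, so results are deterministic for a given file.
* $\hat\Sigma$ uses divisor $N$ (not $N-1$), matching the estimator's
  definition; $\hat\delta$ and $\hat d$ are divisor-invariant.
* Cholesky factors of $\Phi_i$ for the polygenic draw get a $10^{-8}$ ridge
  only if the block is numerically semi-definite.
* All simulation randomness flows from explicit integer seeds; identical
  configuration + seed reproduces studies bitwise.
* Degenerate inputs are named errors, not NaNs: constant traits, all-monomorphic
  regions, rank-deficient covariate designs, empty sample intersections.

## Known limitations

* **Finite-sample conservatism on blocks of many independent rare variants.**
  $\hat\sigma^2_T = 2\,\mathrm{tr}((\hat\Sigma\hat\Sigma_0^{-1})^2)$ sums the
  squares of all $M(M-1)$ sample correlations. When the true cross-variant
  correlation is zero (unlinked variants) and $M$ is large relative to the
  effective sample size, pure sampling noise inflates this estimate —
  with $M = 100$ variants on ~840 related individuals, $\hat\delta$ fits
  around 1.3 where the independence truth is 1 — and for very rare variants
  the plug-in terms $u_m^2/\hat\sigma_{mm}$ are under-dispersed relative to
  $\chi^2_1$ because numerator and denominator are positively correlated
  through the family-clustered carrier counts. Both effects push the same
  way: on the default simulated design the empirical type-I error at
  $\alpha = 0.05$ is roughly half nominal (run `scripts/acceptance.R` to
  reproduce the rates), i.e., the test is *valid but conservative*. With few
  variants per region (e.g., $M \le 10$) or substantial true correlation
  (real-sequence LD, where the off-diagonal mass of $\Sigma$ is dominated by
  signal rather than noise), calibration is nominal — the package's own small-
  $M$ calibration tests confirm this. Users testing wide, LD-free panels
  should expect conservative p-values and may prefer the mixture p-value with
  a shrunken $\hat\Sigma$ pipeline upstream.
* The retrospective argument conditions on traits; covariate adjustment by
  unrelated-least-squares is a pragmatic two-stage choice, not a joint model.
* Qualitative (binary) traits and longitudinal phenotype modelling are out of
  scope; repeated measures are reduced to their mean.
* Founders are assumed unrelated and non-inbred; kinship is pedigree-based
  only (no genotype-based relatedness estimation), autosomes only.
* Multi-allelic VCF records are skipped rather than split; dosages are integer
  allele counts (no imputed fractional dosages on input, though mean
  imputation may introduce them internally).
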