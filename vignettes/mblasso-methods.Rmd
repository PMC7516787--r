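---
title: "Two-stage multi-locus association mapping with mblasso: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage multi-locus association mapping with mblasso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mblasso)
```

## The problem and the model

Genome-wide association studies for quantitative traits scan a panel of
`p` SNPs (often hundreds of thousands) typed in `n` individuals (often only
a few hundred) for loci affecting the trait. Single-locus scans test one SNP
at a time and pay a heavy multiple-testing price; multi-locus methods fit
many SNPs jointly, but ordinary high-dimensional regression breaks down when
`p` vastly exceeds `n`. `mblasso` implements a two-stage strategy for this
ultrahigh-dimensional regime.

The data model is the linear mixed genetic model

$$y = 1\mu + Q\alpha + X\beta + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2_e I),$$

where `y` is the length-`n` trait, `Q` an optional matrix of fixed effects
such as population-structure proportions, and `X` the `n x p` genotype
matrix with additive coding: the two homozygotes are 1 and -1, the
heterozygote 0.

**Stage 1 (screening).** The trait is first corrected for fixed effects:
$y' = y - Q\hat\alpha$ with $\hat\alpha$ from ordinary least squares of `y`
on `[1, Q]`. Two marginal association measures are then computed for every
SNP: the Pearson correlation $\omega_i$ and the mutual information
$\psi_i = I(X_i; y')$ between the three genotype states and the discretized
trait. For each measure, the top `n - 1` SNPs (ties included) enter a
SCAD-penalized regression; the SNPs with exactly nonzero SCAD effect form
the measure's *Type I* set. One ISIS iteration follows: the Type I
contribution is subtracted ($y'' = y' - X_I\hat\beta_I$, with the SCAD
estimates) and the screen-plus-SCAD step is repeated once on the remaining
SNPs, yielding the *Type II* set — SNPs individually uncorrelated with the
trait but jointly relevant. The candidate set `C` is the de-duplicated union
over both measures. Using two measures is the point of the method: mutual
information is sensitive to association shapes that depress a linear
correlation, so the union screens in loci a Pearson-only screen loses.

**Stage 2 (estimation and testing).** On the candidates, the package fits an
expectation–maximization Bayesian Lasso: per-effect normal priors
$\beta_j \sim N(0, \sigma^2_j)$ whose variances are estimated by EM and
collapse to zero for unsupported effects. Effects below $10^{-5}$ in
magnitude are dropped; the survivors are tested one at a time by a nested
likelihood-ratio test expressed as a LOD score,

$$\mathrm{LOD}_k = \frac{2\,(L_1 - L_0)}{2\ln 10},$$

with both likelihoods maximized (Gaussian, residual variance profiled out)
and the remaining effects refit under the null. A SNP is declared
significant when LOD $\ge$ 3, equivalent to a $\chi^2_1$ upper-tail
probability of about 2e-4. Stage 2 deliberately uses the *original* trait:
the hierarchical model estimates its own mean, and the screened correction
$y''$ exists only to rank candidates.

## Tunable parameters

| parameter | default | units / range | why this default |
|---|---|---|---|
| `lodThreshold` | 3 | LOD units | the conventional multi-locus call threshold; \(\approx\) p = 2e-4 |
| `bins` | `round(sqrt(n))` | count | histogram rule for the MI discretization |
| `smoothing` | 0 | pseudo-counts | empty cells use the \(0\log 0 = 0\) convention |
| `gamma` | 3.7 | > 2 | the standard SCAD shrinkage constant |
| `lambdaStrategy` | `"bic"` | `"bic"`/`"cv"` | deterministic, reproducible selection |
| `screenSize` | `"n-1"` | — | sure-independence screening size; `"n/logn"` available |
| `priorDf`, `priorScale` | -1, 0 | — | non-informative variance hyperprior (see below) |
| `dropTol` | 1e-5 | effect units | the stage-2 zero-effect rule |
| `emTol`, `emMaxIter` | 1e-8, 1000 | — | EM stopping rule |
| `scadTol`, `scadMaxIter` | 1e-7, 10000 | — | coordinate-descent stopping rule |

## Numerical and design choices

**SCAD solver.** Coordinate descent with the univariate SCAD thresholding
update, warm starts along a 100-point log-spaced penalty path from
$\lambda_{max}$ down to $0.001\lambda_{max}$, and active-set cycling
(compiled in C++). Columns and the response are standardized internally —
the SCAD problem is 2-homogeneous under joint scaling of `y` and
$\lambda$, so results are invariant to the trait's measurement scale — and
coefficients are returned on the original scale.

**Penalty selection.** The screened design has `n - 1` columns against `n`
observations, where a classical BIC always prefers the near-saturated
interpolating fit and raw path RSS under-rates sparse models (mid-path SCAD
coefficients are still shrunk). Three choices address this, each made once
and documented here: (i) the criterion is the extended BIC with the
adaptive weight $\gamma_E = \max(0,\ 1 - \log n / (2\log p))$, where `p` is
the *ambient panel size* the marginal screen searched, not the screened
column count — the screen is data-dependent, so the model-space
multiplicity it must guard against is the full panel; (ii) the criterion is
evaluated on the OLS-refit support of each path point; (iii) only solutions
with at most `n/2` nonzeros are eligible, and the empty model is always
compared explicitly. After selection, the coefficients reported are the
support's least-penalized SCAD solution (re-solved at the path minimum
restricted to the support): folded-concave penalties debias large effects
as the penalty decreases, and the ISIS correction step needs
close-to-unbiased estimates to reveal masked loci. Cross-validation
(`"cv"`, deterministic interleaved folds) is available but markedly more
liberal; with the nested-refit likelihood-ratio test downstream it admits
many spuriously correlated candidates and inflates false positives.

**EM Bayesian Lasso.** The variance-component update is
$\sigma^2_j \leftarrow (E[\beta_j^2\,|\,y] + \tau\omega)/(\tau + 3)$ under a
scaled inverse-chi-square $(\tau, \omega)$ hyperprior, with
$(\tau, \omega) = (-1, 0)$ by default — the non-informative choice of the
empirical-Bayes Lasso lineage. The resulting halving-type update drives the
variances of unsupported effects to zero geometrically, which is what makes
the $10^{-5}$ drop rule meaningful; a flat prior (reachable as
`priorDf = -2`) shrinks only at rate `1/t` and effectively retains
everything. The E-step uses the exact joint posterior evaluated through the
`n x n` marginal covariance $XDX' + \sigma^2_e I$, so zero variance
components need no inversion and candidate sets larger than `n` are handled.
Initialization is deterministic ($\mu = \bar y$, $\beta = 0$,
$\sigma^2_j = 1$, $\sigma^2_e = \mathrm{var}(y)$); variance components are
floored at 1e-12 as a box constraint, so the constrained EM keeps its
monotone observed-data log-posterior, which the fit records and the tests
assert sweep by sweep.

**Likelihood-ratio test.** Both hypotheses are maximized: under the null the
other retained effects and the mean are refit, making the test a proper
nested LR test; the alternative — freezing nuisance effects at their
alternative-model values — would not be a likelihood ratio between nested
maxima, so the nested refit is this package's choice. Singular retained
designs fall back to a ridge-stabilized solve with a warning.

**Fixed-effect correction.** The OLS correction includes an intercept but
subtracts only the covariate part, leaving the grand mean in the corrected
trait; stage 2 fits its own mean, and the model keeps the $1\mu$ term
separate from $Q\alpha$.

**Ties, degenerate inputs.** Screening keeps all SNPs tied at the cutoff, so
Type sets can exceed the nominal size. Constant SNP columns score zero with
a warning; a constant corrected trait is an error for Pearson screening and
carries zero mutual information. A constant raw trait yields the trivial
stage-2 fit ($\hat\mu$ = the constant, all effects zero). Missing genotypes
are rejected at validation unless column-mode imputation is requested;
individuals with missing trait values are dropped panel-wide.

## The simulation engine

`simulateScenario()` reproduces the package's reference study conditions:
199 individuals, 10,000 SNPs over five chromosomes (2,000 each), six QTNs at
allele frequency 0.30 with heritabilities 0.10, 0.05, 0.05, 0.15, 0.05,
0.05, overall mean 10 and residual variance 10. Effects are calibrated
through the variance-accounting identity
$V_P = (\sum_i h_i)V_P + \sigma^2_{pg} + \sigma^2_{epi} + \sigma^2_e$ and
$b_i = \sqrt{h_i V_P / (2f_i(1-f_i))}$. Scenario 2 adds a polygenic vector
$u \sim MVN(0, \sigma^2_{pg}K)$ with $\sigma^2_{pg} = 2$ (implied polygenic
heritability 0.092) and a VanRaden-style kinship $K = ZZ'/p$; scenario 3
adds three Hadamard-product epistatic pairs at non-QTN loci, each
contributing variance 1.25 (per-pair heritability 0.05), with the pair
effects scaled from the Hardy-Weinberg variance of the product column.

What the generator emulates — and what it does not. Genotypes are synthetic
Hardy-Weinberg draws with optional latent-AR(1) block LD (`ldRho`, off by
default). Real panels — plant accession collections especially — carry LD
structure, allele-frequency spectra and population stratification that a
synthetic panel does not reproduce. Passing tests on synthetic panels
therefore demonstrates the pipeline's statistical calibration (type-1
control, power ranking, effect-estimate accuracy) under the stated
architecture, not its behavior on structured real panels. The MI
discretization (equal-width bins, `round(sqrt(n))`) is one standard
histogram estimator; other discretizations can rank borderline SNPs
differently at the screening margin, which makes it the single largest
source of run-to-run divergence between MI implementations.

Problem sizes. The packaged tests and the acceptance script run the
reference conditions with the panel scaled to `p = 2000` SNPs and 100
replicates — about a minute end to end — which keeps per-replicate
behavior (set sizes, per-QTN power ordering, false-positive rate) in the
regime reported for the full 10,000-SNP, 1000-replicate study. Full-scale
runs are a matter of `simulateScenario(p = 10000)` and more replicates.

```{r quick-example, eval = FALSE}
sim <- simulateScenario(scenario = 1, n = 199, p = 2000, seed = 7)
res <- runMblasso(sim$genotypes, sim$phenotype)
significantSnps(res)
matchQtns(res, sim$truth, window = 1000)
```

## Known limitations

* The mutual-information estimator is histogram-based; k-nearest-neighbor
  or kernel estimators are out of scope.
* Exactly one ISIS iteration is performed, per the method's definition;
  multi-iteration screening is not implemented.
* Population structure is accepted as a covariate matrix; estimating it
  (ADMIXTURE-style) is out of scope, as is any polygenic random effect in
  the fitting model (it exists only in the simulator's scenario 2).
* PLINK ingestion covers the additive text export (`.raw`); binary `.bed`
  is not parsed.
* The Wald-test alternative to the LOD criterion is not implemented.
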