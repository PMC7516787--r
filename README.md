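# mblasso

Two-stage multi-locus genome-wide association mapping for quantitative
traits, combining **Pearson-correlation and mutual-information screening**
with **EM Bayesian Lasso** effect estimation and a **LOD likelihood-ratio
test**.

## Who this is for

Geneticists mapping quantitative trait nucleotides (QTNs) in panels where
the SNP count far exceeds the sample size (e.g. a few hundred accessions
against 10^5–10^6 SNPs), and methodologists benchmarking multi-locus GWAS
procedures on simulated architectures.

## The method

For trait `y`, optional fixed effects `Q` (e.g. population-structure
proportions), and genotypes `X` coded `{1, 0, -1}` (homozygotes ±1,
heterozygote 0), the model is

    y = 1·mu + Q·alpha + X·beta + e,     e ~ N(0, sigma2_e I).

**Stage 1 — screening.** After least-squares correction
`y' = y − Q·alpha_hat`, every SNP is scored by (a) Pearson correlation
`omega_i` and (b) mutual information `psi_i = I(X_i; y')` against the binned
trait. For each measure, the top `n − 1` SNPs enter a SCAD-penalized
regression (`gamma = 3.7`; penalty level chosen by an extended BIC over a
100-point path); the nonzero-effect SNPs are the measure's **Type I** set.
One ISIS iteration subtracts the fitted Type I contribution
(`y'' = y' − X_I beta_I`) and repeats the screen on the remaining SNPs,
reviving jointly-relevant, marginally-silent loci — the **Type II** set. The
candidate set `C` is the de-duplicated union over both measures.

**Stage 2 — estimation and testing.** On the original trait, an
expectation–maximization Bayesian Lasso (per-effect normal priors whose
variance components collapse to zero for unsupported effects) estimates the
candidate effects; effects below 1e-5 are dropped. Each survivor `k` is then
tested by a nested likelihood-ratio test reported as a LOD score,

    LOD_k = −2(L0 − L1) / (2 ln 10),    significant iff LOD_k ≥ 3,

where `L1`/`L0` are the maximized Gaussian log-likelihoods with and without
marker `k` (remaining effects refit under the null). LOD ≥ 3 corresponds to
a chi-square(1) upper tail of about 2e-4.

The package also ships the simulation engine for three phenotype
architectures (additive; + polygenic `u ~ MVN(0, sigma2_pg K)`;
+ Hadamard-product epistasis) with heritability-calibrated effect sizes, and
an evaluation suite (per-QTN power with the 1 kb matching rule, effect MSE,
type-1 error ratio).

## Worked example

```r
library(mblasso)

sim <- simulateScenario(scenario = 1, n = 199, p = 2000, seed = 7)
res <- runMblasso(sim$genotypes, sim$phenotype)
res
```

```
AssociationResult: 3 tested SNP(s), 3 significant at LOD >= 3
  stage sizes: k1=198, k2=2, k3=0, tau1=198, tau2=2, tau3=1, overlap=0.666666666666667, nu=3, retained=3
   snp_id chrom    pos   effect       lod      p_value significant
 snp01167     3 188230 2.610210 10.519639 3.397304e-12        TRUE
 snp00167     1  83995 1.728674  5.463305 5.278039e-07        TRUE
 snp01833     5 116840 1.267719  3.536989 5.439486e-05        TRUE
```

`k1..k3` / `tau1..tau3` are the Pearson / mutual-information screening set
sizes (screened, Type I, Type II), `nu` the candidate-union size, `effect`
the stage-2 shrinkage estimate on the trait scale. Matching calls to the
simulated truth with the 1 kb rule:

```r
mq <- matchQtns(res, sim$truth)
data.frame(chrom = sim$truth@qtnChrom, pos = sim$truth@qtnPos,
           true_effect = round(sim$truth@qtnEffects, 3),
           detected = mq$detected, estimate = round(mq$effects, 3))
```

```
  chrom    pos true_effect detected estimate
1     1  83995       2.081     TRUE    1.729
2     2  49087       1.471    FALSE       NA
3     3  16629       1.471    FALSE       NA
4     3 188230       2.548     TRUE    2.610
5     4 148321       1.471    FALSE       NA
6     5 116840       1.471     TRUE    1.268
```

This seed detects three of the six QTNs with zero false positives — the
strongest QTN (heritability 0.15, true effect 2.548) at LOD 10.5 — typical
single-replicate behavior for heritability-0.05 loci at n = 199.

Real data enter through `readGenotypes()` / `readPlinkRaw()`,
`readPhenotype()` and `readCovariates()`, with `mafFilter()`,
`logTransform()` and `dropMissingPhenotype()` for preprocessing; a thin
command-line wrapper with `run` / `simulate` / `evaluate` subcommands lives
at `inst/exec/mblasso.R`.

## Package layout

- `R/` — S4 classes (`GenotypeMatrix`, `ScreenResult`, `ScadFit`,
  `EmBlassoFit`, `SimTruth`, `AssociationResult`, ...), screening, stage-2
  EM, LOD testing, pipeline, simulator, evaluation.
- `src/` — C++ coordinate-descent SCAD solver.
- `vignettes/mblasso-methods.Rmd` — the model, its assumptions, all
  numerical choices and their rationale, and known limitations.
- `tests/testthat/` — unit, property and end-to-end calibration tests.
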