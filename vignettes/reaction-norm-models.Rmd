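---
title: "Disentangling genotype-covariate correlation from interaction with reaction norm models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling genotype-covariate correlation from interaction with reaction norm models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrnm)
```

## The problem

Many "environmental" modifiers of complex traits - smoking, alcohol use,
neuroticism - are themselves heritable. When a trait y and a covariate c
share genetic causes, two distinct phenomena are confounded in naive
analyses: *correlation* (pleiotropy: the same variants move both y and c)
and *interaction* (the genetic effects on y change with the level of c).
Their biological interpretations differ, and so do their implications for
intervention, so it matters to estimate them separately. A univariate
model that regresses genetic effects on c without modelling the y-c
covariance misattributes part of the correlation to interaction; an
additive model that ignores both absorbs the interaction variance into
its residual and so underestimates SNP heritability.

## The model family

For individual i with one record and unique covariate value c_i the full
model is

    y_i = alpha_i0 + alpha_i1 * c_i + tau_i0 + tau_i1 * c_i
    c_i = beta_i + eps_i

where (alpha_0, alpha_1) are random regression coefficients for the
genetic effect, with covariance K_y between coefficients and covariance
proportional to the genomic relationship matrix A across individuals, and
(tau_0, tau_1) are the corresponding residual coefficients with
between-individual covariance proportional to the identity. With the
polynomial basis Phi = [1, c] the trait's genetic covariance is
A * (Phi K_y Phi') (elementwise product) and its residual covariance is
the diagonal of Phi M_y Phi'. The bivariate ("multivariate reaction
norm") variants model y and c jointly and add K_yc = (cov(alpha_0, beta),
cov(alpha_1, beta)) and M_yc = (cov(tau_0, eps), cov(tau_1, eps)), which
is precisely what separates genotype-covariate correlation from
interaction. Because each individual has exactly one record, the
incidence matrices of the general formulation reduce to identities and
the whole joint covariance is assembled from Hadamard and diagonal
patterns in O(n^2) memory.

Model variants are declarative (`makeModel()`): each frees a subset of
the parameters, every null used in a likelihood-ratio test is nested in
its alternative by construction, and the covariance is *linear* in the
parameters, so each derivative matrix is a fixed pattern. The shipped
variants cover the additive models (GREML, bivariate MVGREML), the
univariate reaction norm models (genetic, residual, or both regressions),
the bivariate ones, and the two stratified comparison estimators:
RR-GREML (per-group residual variances, genetic random regression on the
group value) and GCI-GREML (a same-group kinship interaction component
with homogeneous residual variance and the interaction variance
constrained non-negative).

## Estimation

`fitReml()` maximises the REML log-likelihood
-0.5 (log|V| + log|X'V^-1X| + y'Py) by average information. The first
two iterations apply the EM recursion to the variance-type parameters
(covariances held at their starting zeros) - slow but monotone and safe
far from the optimum - after which full AI updates are taken with
step-halving whenever a proposal would decrease the likelihood or leave
the positive-definite cone. Default starting values split the phenotypic
variance equally over the free variances. Convergence requires the
likelihood gain to fall below `tol` (default 1e-4, adequate for
likelihood-ratio statistics read against chi-square thresholds of order
4-8) or the largest parameter move below 1e-6. Standard errors come from
the inverse AI matrix at the optimum.

Two estimation choices deserve comment:

* **Constraints.** Variance components are deliberately *unconstrained*
  (only positive-definiteness of V is enforced). Under a null with a
  true zero variance, constraining it at zero makes the LRT null
  distribution a chi-square mixture, deflating the nominal 5% test to
  roughly 3% and visibly bending the p-value distribution away from
  uniform; the unconstrained fit keeps the plain chi-square reference
  that the tests in this package (and the reference results they
  reproduce) rely on. The single exception is GCI-GREML, whose defining
  convention is to constrain its interaction variance to be
  non-negative - that model is therefore expected to test conservatively
  (near 0.034 rather than 0.05), and does.
* **Warm starts.** In all experiment loops the alternative fit starts
  from the null optimum mapped through the structural parameter
  correspondence, which both halves the iteration count and guarantees
  logL(H1) >= logL(H0) because iterations only ever accept
  non-decreasing likelihoods.

The covariate is centred and scaled before basis construction by default
(`standardize = TRUE`), matching how covariates are prepared in real
analyses; the stratified estimators represent each of their (by default
quartile) groups by the group mean of the standardized covariate.

## The generative simulator

`simulateFull()` draws (alpha_0, beta, alpha_1) with covariance
SigmaG (x) A - via an eigendecomposition square root of A with negative
eigenvalues clipped at zero, since sample GRMs are only near-PSD - and
(tau_0, eps, tau_1) with covariance SigmaR (x) I, then sets c = beta +
eps and y = alpha_0 + alpha_1 c + tau_0 + tau_1 c. The covariate enters
the product terms *raw* (variance 2 under the shipped designs, since
var(beta) = var(eps) = 1): this keeps the variance bookkeeping of the
inflation study self-consistent - var(alpha_1) = 0.25 contributes
0.25 * var(c) = 0.5 to var(y) = 2.5, i.e. a 10% share in the
var(alpha_1)/var(y) sense and a 1.5-fold inflation of an additive
model's residual; var(alpha_1) = 1 gives the 3-fold ceiling. Fitting, by
contrast, standardizes c by default; both behaviours are explicit flags.
All component vectors are retained, and y is their exact sum, which the
class validity enforces.

The shipped designs (`simPreset()`) are: the no-interaction,
no-correlation null; the genetic-interaction design
(var(alpha_1) = 0.25, cov(alpha_0, alpha_1) = 0.05); the
correlation-only design (cov(alpha_0, beta) = 0.5,
cov(tau_0, eps) = 0.3, no interaction); and the two inflation grids. On
the grids the coefficient covariance 0.05 applies where the interaction
variance is positive and drops to zero at the zero grid point (the
stated matrix would not be PSD there). Genotypes behind the GRM are
unlinked Hardy-Weinberg draws with uniform allele frequencies: linkage
disequilibrium is not simulated because every model here operates at the
covariance level, where only the relationship matrix enters. Passing
tests on such data therefore says nothing about LD-related artefacts,
genotyping error, ascertainment, or non-normal phenotypes - the RINT
utility exists precisely because real phenotypes are not Gaussian.

## Simulation experiments and their scale

`typeIErrorExperiment()`, `powerExperiment()` and
`inflationExperiment()` run replicate loops over one fixed GRM
(replicate r uses seed + r; the GRM square root is factored once).
Rejection proportions are computed over converged replicates with the
exclusion count reported, and the median-based inflation statistic
lambda accompanies every run.

The package's default scales are deliberately desk-sized: cohorts of
400-1,000 individuals with 4,000-5,000 simulated SNPs and 40-200
replicates, run in minutes on one core. Null rejection rates, p-value
uniformity and the residual-inflation folds are essentially invariant to
cohort size, and the power of the reaction norm test at a 10%
interaction share is already indistinguishable from 1 at these sizes, so
the desk scale reproduces those reference quantities faithfully. One
quantity is *not* size-invariant: the spurious interaction signal that a
univariate reaction norm model produces under pure genotype-covariate
correlation. Its noncentrality grows with cohort size and requires many
more markers than individuals (so that the GRM stays near the identity);
at n = 500/1,500 with 5,000 SNPs we measure spurious rejection of about
0.13/0.60, extrapolating to ~1 only at reference-cohort size
(n ~ 7,000, hundreds of thousands of SNPs). The direction of the
contrast - the univariate test rejects far in excess of its size while
the bivariate model stays calibrated - is reproduced at any scale; the
near-certain rejection rate itself is a full-scale phenomenon.

## Numerical choices and degenerate inputs

* Non-PD covariance proposals during fitting are handled by
  step-halving; a proposal chain that cannot improve the likelihood ends
  the fit, which is reported as converged only if the gradient is small.
* The AI system is solved with an escalating ridge when near-singular
  (confounded components, e.g. a GRM numerically close to the identity,
  leave the likelihood flat along a parameter combination).
* Monomorphic SNPs are dropped from the GRM with a warning (their
  standardization weight is undefined); relatedness pruning compares the
  signed GRM entry against the threshold and removes a random member of
  each offending pair, matching the convention of the cohort pipeline it
  mirrors, and is idempotent.
* A constant covariate cannot be standardized (error) or stratified
  (single stratum with a warning).
* Ties in the rank-based inverse normal transform share averaged ranks;
  the Blom offset (r - 3/8)/(n + 1/4) is used.
* The jackknife for the residual-variance difference test (RNM minus
  GREML, the Wald comparison used on real cohorts) deletes one of 50
  seeded random groups at a time and refits both models warm-started
  from the full-data optima; simulations show the jackknife SE tracks
  the replicate-to-replicate SD of the difference.

## Known limitations

Single records per individual (no repeated measures), polynomial order
k = 1 exercised throughout (the basis supports higher order, but no
shipped analysis validates it), at most two traits, no correlation
between the random effects of different covariates in the multiple-
covariate direction, and dense O(n^2)-memory / O(n^3)-time algebra - the
practical ceiling on one core is cohorts of a few thousand. Summary-
statistic methods are out of scope entirely.
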