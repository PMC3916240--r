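---
title: "Models and methods behind xcwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xcwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcwas)
```

# Why chromosome X needs its own association machinery

Outside the pseudoautosomal regions, males carry one X allele and
females two, and random X-chromosome inactivation (XCI) silences one of
the two female copies at most loci. If XCI is complete ("full dosage
compensation", FDC), a hemizygous male is biologically equivalent to a
homozygous female, which motivates the standard coding of male
genotypes as {0, 2} against female {0, 1, 2}. At a locus that escapes
XCI ("no dosage compensation", NDC) both female copies are active, so
on the {0,2} male scale the female per-allele effect is twice the male
one: $b_F = 2 b_M$. `xcwas` keeps this coding explicit everywhere: male
estimates carry a `male_coding` tag (`slope02` for {0,2}, `per_copy`
for {0,1}), and the functions that are sensitive to the convention
refuse mismatched tags instead of silently rescaling.

# Sex-stratified association and meta-analysis

`fit_additive()` is the simple linear regression of an
inverse-normal-transformed residual trait on coded dosage, with a
normal-approximation p-value from $z = \hat\beta/\mathrm{se}$. The
normal rather than t reference matches the large-sample score/Wald
behaviour of standard summary-statistic pipelines, which these outputs
are designed to feed; at the sample sizes where X-wide association is
meaningful the difference is negligible. Missing dosages are dropped
pairwise per SNP; fits require at least 10 complete pairs and positive
dosage variance.

Variant QC mirrors standard X-analysis practice: keep a variant when
female imputation info exceeds 0.4 *and* the female minor allele count
exceeds 3, both strictly. The female MAC for imputed (expected-count)
dosages is $\min(\sum d, 2n_F - \sum d)$ rounded to the nearest
integer; whether the original pipelines rounded expected counts is not
documented anywhere we know of, and rounding makes the count integral
and the filter reproducible.

`xwas_meta()` enforces the canonical order of operations: genomic
control within each cohort-by-sex stratum first (optional), then the
inverse-variance fixed-effects combination per sex across cohorts, then
the overall combination plus two sex-aware tests on the per-sex meta
results:

- sex-differentiated: $\chi^2 = z_F^2 + z_M^2$ on 2 df, which retains
  power when the sexes disagree in effect size;
- sex-heterogeneity: $Q = (b_F - b_M)^2/(\mathrm{se}_F^2 +
  \mathrm{se}_M^2)$ on 1 df, algebraically identical to two-group
  Cochran's Q.

SNPs present in fewer than two strata are dropped by default. Genomic
control estimates $\lambda$ as the median association $\chi^2_1$ over
its theoretical median `qchisq(0.5, 1)` $\approx 0.4549$ and divides
statistics by $\lambda$ only when $\lambda > 1$ — deflation is never
applied. When applied inside the meta pipeline the correction is
carried by inflating standard errors ($\mathrm{se} \to
\mathrm{se}\sqrt\lambda$) so that downstream inverse-variance weights
see it.

# The dosage-compensation Bayes factor

The core computation compares two priors on the pair of true effects
$(b_F, b_M)$, using the estimates and standard errors as an approximate
(normal) likelihood:

- FDC: $b_F \sim N(0, s^2)$, $b_M = b_F$;
- NDC: $b_F \sim N(0, s^2)$, $b_M = b_F/2$ (male effects on the
  slope02 scale).

The prior scale $s$ is set per SNP so that with 95% probability the
SNP explains less than 1% of the unit trait variance in females. Since
variance explained in females is $2p(1-p)b_F^2$, this is the quantile
equation $s = \sqrt{0.01/(2p(1-p))}/z_{0.975}$ with
$z_{0.975} = 1.959964$. For a zero-mean normal prior the two-sided
quantile solve and the direct probability solve coincide, so this
closed form is exact, and the three published posterior probabilities
reproduce under it (0.994, 0.069, 0.185 against printed 0.99, 0.07,
0.18) — that agreement is the package's acceptance check for this
module.

Because the prior is perfectly correlated (rank 1), marginalising the
shared effect is analytic: under male multiplier $c$ the estimates are
jointly normal, mean zero, covariance

$$\begin{pmatrix} s^2 + \mathrm{se}_F^2 & c\,s^2 \\ c\,s^2 & c^2 s^2 +
\mathrm{se}_M^2 \end{pmatrix},$$

with $c = 1$ (FDC) or $c = 1/2$ (NDC). We deliberately avoid Monte
Carlo integration here: the closed form is deterministic and the test
suite verifies it against 1-D numerical quadrature to $10^{-6}$ over a
thousand random parameter draws. Posterior probabilities use equal
prior model odds by default; `prior_ndc` exposes the prior as a
parameter. With null data ($\hat b = 0$) the Bayes factor reflects only
the difference in prior complexity, leaving the posterior strictly
between 0 and 1, and in the small-standard-error limit the posterior
is consistent (goes to 1 under data generated on the NDC line, to 0 on
the FDC line).

# Variance explained and sexual dimorphism

Under slope02 coding the genotype variance is $2P(1-P)$ in females and
$4P(1-P)$ in males, so variance explained on a unit-variance trait is
$2P(1-P)b_F^2$ and $4P(1-P)b_M^2$ respectively. The calculators take
sex-specific allele frequencies, because published tables print them
per sex and the distinction matters at the third decimal.

For a locus with *no* dosage compensation, a minor allele `a` at
frequency $f_a$ with per-copy effect $b$ in both sexes changes the male
mean by $f_a b$ and the female mean by $2 f_a b$, hence the sex
difference $m_M - m_F$ by $-f_a b$ relative to a population fixed for
the major allele. `per_copy_effect_combined()` produces the per-copy
$b$ in trait units by inverse-variance combination of the two sexes'
per-copy estimates times the trait standard deviation; it refuses
male input tagged `slope02` rather than doubling it silently.

# X-aware GREML

`make_grm()` standardises each SNP by its X-appropriate moments —
females $(x - 2p)/\sqrt{2p(1-p)}$, males $(x - p)/\sqrt{p(1-p)}$, with
$p$ the pooled allele frequency counting male chromosomes once — and
rescales male rows by $d_M = \sqrt2$, $1/\sqrt2$ or $1$ so that male
genetic variance is $2\times$, $0.5\times$ or $1\times$ the female
variance under FDC, NDC and EV. These scalings follow from the
genotype-variance argument above rather than from any single tool's
convention; the package's claim is parameter recovery on data simulated
under each model, which the test suite checks, not the reproduction of
any published cohort estimate (those require the original genotypes).
The EV model keeps a single residual variance for both sexes; per-sex
residual variances are a documented non-goal, consistent with traits
normalised to unit variance within sex.

`reml_fit()` is average-information REML with an intercept-only fixed
design by default. Numerical choices: variance components are floored
at $10^{-6}$ of the phenotypic variance to keep the covariance positive
definite; an AI step that leaves the feasible region is step-halved up
to 12 times and falls back to a single EM step if still infeasible;
convergence is a restricted-log-likelihood change below $10^{-8}$; SEs
come from the inverse AI matrix, with a delta-method SE for each
variance share. An unidentifiable model (e.g. a GRM numerically
proportional to the identity, aliased with the residual) yields a
result flagged `converged = FALSE` rather than an error, so pipelines
can log and continue. The boundary likelihood-ratio test of zero
genetic variance uses the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$
mixture, $p = \tfrac12 P(\chi^2_1 > LR)$; because a constrained fit
stopped at the boundary can sit marginally (order $10^{-3}$) below the
exact null optimum, the negative-LR fault tolerance defaults to 0.01.

Relatedness pruning is greedy: repeatedly drop the individual involved
in the most pairs above the threshold (ties towards the larger index)
until no pair exceeds it. Greedy removal is deterministic and
guarantees a valid (pairwise-clean) set; it does not claim the maximum
possible set, which would be an NP-hard independent-set problem with no
practical benefit here.

# The simulator, and what passing tests do and do not show

`simulate_genotypes()` draws unlinked SNPs: female genotypes
Binomial(2, MAF) (Hardy-Weinberg), male genotypes Bernoulli(MAF),
stored on the raw {0,1} scale. `simulate_phenotype()` adds genetic
values with a per-copy male multiplier of 2 (FDC), 1 (NDC) or
$\sqrt 2$ (EV) on the female per-allele scale plus Gaussian noise.
The EV generative convention is not uniquely pinned down by the
estimation model it mirrors; $\sqrt2$ is the choice that makes male and
female genetic variances equal, which is the property the EV GRM
assumes, and it is fixed once here. Default study conditions in the
tests — a few hundred to a few thousand individuals per sex, MAFs
0.05-0.5, unit residual variance, effects of 0.1-0.5 per allele — are
in the range where single-SNP power and REML identifiability are
realistic for cohort-scale X analyses; REML recovery uses n = 2000
samples and m = 1000 SNPs, and null calibration uses 10,000 simulated
SNPs.

Phenotype preparation follows sex-stratified GWAS practice:
`adjust_covariates()` takes OLS residuals on covariates within sex and
applies the rank-based inverse normal transform with Blom offsets,
$\Phi^{-1}((r - 3/8)/(n + 1/4))$, average ranks for ties. Plain
"inverse normal transformed" does not name an offset; Blom is the
common GWAS default and any offset choice changes nothing that these
analyses consume (the transform is rank-invariant). Constant input —
including residuals that are constant to machine precision, as happens
when a covariate duplicates the trait — is an error, since the
transform is undefined.

Because SNPs are simulated without linkage disequilibrium and without
relatedness structure, passing tests demonstrate the statistical
contracts of each stage (calibration, consistency, coding invariance,
parameter recovery) but not robustness to LD between causal and tested
variants, imputation error beyond an info column, or cryptic
relatedness — on real data those enter through the QC filters, the
genomic-control step and the pruning threshold.

# Limitations

- Partial escape from XCI (an escape fraction strictly between 0 and 1)
  is outside the model space: the comparison is FDC versus NDC only.
- The heterogeneity and sex-differentiated tests assume independent
  male and female strata (no shared samples).
- The REML implementation is dense ($O(n^3)$ per iteration) and
  practical to roughly $n \approx 10^4$ on one CPU.
- Mixed-model association (as opposed to variance estimation) and
  imputation itself are out of scope.
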