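---
title: "Joint Bayesian ancestry and association testing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian ancestry and association testing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmix)
```

## The problem

In a recently admixed cohort — African Americans being the canonical example —
each individual's genome is a mosaic of long segments inherited from the
parental populations. Two complementary genome-wide scans are possible:
*admixture mapping*, which regresses the phenotype on local ancestry (the
number of chromosome copies, 0/1/2, inherited from one parental population at
a marker), and *association mapping*, which regresses the phenotype on
genotype (0/1/2 copies of the minor allele). Because ancestry segments are
megabases long, an admixture scan involves a few hundred effectively
independent tests where an association scan involves hundreds of thousands.
A locus with an ancestry effect therefore needs far less evidence to stand
out in the admixture scan — and that evidence is informative about where
association signals are likely to be real.

`bmix` implements a joint Bayesian test that chains the two scans: the
posterior probability that a locus affects the phenotype, computed from
admixture mapping, becomes the prior probability for association mapping at
that same marker. Every marker passes through both stages unconditionally, so
there is no winner's curse from filtering on first-stage significance.

## The Bayesian model

For each marker let $H_1$ be the hypothesis that the locus affects the
phenotype. A 1-df Wald statistic $x$ from a generalized linear model is
scored under two densities: the central $\chi^2_1$ (null, $f_0$) and a
noncentral $\chi^2_1(\lambda)$ (alternative, $f_1$). The Bayes factor is the
density ratio $f_1(x)/f_0(x)$ and the posterior is

$$\Pr(H_1 \mid x) \;=\; \frac{\pi_1 f_1(x)}{\pi_1 f_1(x) + (1-\pi_1) f_0(x)}.$$

The calibration of the alternative follows classical power analysis: for a
two-tailed test at per-test level $\alpha$ and power $1-\beta$,

$$\lambda = \left(\Phi^{-1}(1-\alpha/2) + \Phi^{-1}(1-\beta)\right)^2 .$$

Two-tailed is the package default because Wald p-values from GLMs are
two-sided (the one-tailed variant is available via `tails = "one"`). Power
defaults to 0.8 and is configurable. The per-test level is the 0.05 budget
divided by the *effective* number of tests of the scan, and the prior
$\pi_1$ is 1 over that same effective number.

At $x = 0$ both df-1 densities diverge, but the ratio has the analytic limit
$e^{-\lambda/2}$, which `bayes_factor()` returns so that a completely null
statistic (p-value 1) still updates the prior by a finite, maximally
unfavourable factor. For df = 1 the ratio also has the closed form
$e^{-\lambda/2}\cosh\sqrt{\lambda x}$; the implementation evaluates the two
log-densities directly and the test suite uses the closed form as an
independent oracle. A prior of exactly 1 is not clipped: the posterior is 1
whatever the data, and the package warns that such a marker is no longer
updateable. Posterior probabilities above 0.5 — the point where the
posterior odds switch hypothesis — are called significant; a tie at exactly
0.5 is not significant.

`required_chisq_for_posterior()` inverts the posterior by bracketed
root-finding on the log Bayes factor (monotone in $x$; relative tolerance
below 1e-10, deterministic). Root-finding rather than the closed form keeps
the implementation honest for any df, and the closed form remains the test
oracle.

## Testing burdens from autocorrelation

The effective number of tests of each scan is estimated from the data
themselves. For every individual and chromosome, the ordered vector of local
ancestries (admixture scan) or minor-allele counts (association scan) is fit
with an autoregressive model — Yule–Walker estimation, order selected by AIC
up to `min(n-1, floor(10*log10(n)))` — and reduced to an effective sample
size

$$\mathrm{ESS} = \frac{n\,\widehat{\mathrm{Var}}(x)}{\hat\sigma^2/(1-\sum_i \hat\phi_i)^2},$$

the denominator being the AR spectral density at frequency zero. ESS values
are clamped to $[1, n]$: spectral estimates can overshoot on short series. A
constant chromosome (no ancestry switch) is defined to contribute exactly 1
effective test — it carries a single independent ancestry observation.
Missing values are mean-imputed within each (individual, chromosome)
sequence, and the imputation count is reported. Chromosome ESS values are
summed within individual and averaged across individuals
(`testing_burden()`).

Two remarks on deliberate choices. First, series shorter than 8 observations
cannot support an AR fit; they are treated as uncorrelated (ESS = length),
which only matters for toy inputs. Second, the AR fit is computed on
mean-centred series (the `stats::ar` default), since the mean level of an
ancestry sequence carries no information about its autocorrelation.

The package also counts ancestry switches (`count_switches()`) and converts
a genome-wide switch count into generations since admixture under a
hybrid-isolation model, $\hat g = S / (4\theta(1-\theta)L)$ for admixture
proportion $\theta$ and diploid map length $L$ Morgans.
`estimate_generations()` requires the map length explicitly — published maps
differ enough that silently defaulting one would present a guess as ground
truth.

## The six-step algorithm

`bmix()` runs, per marker $j$ with phenotype $y_i$, link $g$, local ancestry
$l_{ij}$, genotype $g_{ij}$ and global ancestry $G_i$ (local ancestry
averaged across all markers, rescaled to $[0,1]$):

1. **Admixture scan** — $g(E[y_i]) = \beta_0 + \beta_1 l_{ij} + \beta_2 G_i
   + \text{covariates}$; Wald p-value for $\beta_1 = 0$.
2. **Posterior conversion** — prior $1/N_{\mathrm{eff,admix}}$, ncp from
   $\alpha = 0.05/N_{\mathrm{eff,admix}}$.
3. **Stratified association** — within each stratum $k \in \{0,1,2\}$ of
   $l_{ij}$: $g(E[y_{ik}]) = \beta_{0k} + \beta_{1k} g_{ijk} + \beta_{2k}
   G_{ik} + \text{covariates}$. Stratification keeps genotype conditionally
   independent of local ancestry; adjusting for global ancestry controls
   confounding by genome-wide ancestry.
4. **Pooling** — inverse-variance fixed effects across usable strata.
5. **Association p-value** — $z = \hat\beta_{\text{pooled}}/\mathrm{se}$,
   two-sided normal.
6. **Posterior chaining** — the association posterior uses the marker's
   admixture posterior as its prior, with the association-scan ncp.

The chain is exactly the product-of-conditionals factorisation of the joint
probability of an ancestry effect and of association conditional on
ancestry; the test suite asserts the identity marker-wise to 1e-12.

Numerical and policy details:

* **Wald, not LRT** p-values throughout, matching what standard GLM output
  provides and what the step-5 z-statistic implies. Gaussian fits use
  t-based p-values with estimated dispersion (as `summary.glm` does),
  binomial fits use z-based ones.
* **Stratum eligibility**: at least 10 individuals and at least 2 distinct
  genotype values; otherwise the stratum is skipped with a recorded reason.
  Tiny strata produce unstable standard errors that corrupt the pooled
  weight. The threshold is configurable (`min_stratum`).
* **Missingness**: complete cases per marker.
* **Marker isolation**: a degenerate marker (constant ancestry,
  rank-deficient design, no usable stratum) yields a flagged `NA` row, never
  an aborted scan.
* **Genomic control**: $\lambda_{GC}$ of the association scan is reported in
  the metadata but never used to rescale statistics.
* Burdens are estimated once per dataset (not per marker) and can be
  overridden (`burdens =`) for simulation studies with known burdens.

## The power / sample-size trade-off

`sample_size_change()` quantifies what an admixture p-value buys: the
chained prior is computed, the association statistic achieving a joint
posterior of 0.5 is root-solved, and the change relative to the statistic
required under the uniform association prior is reported, treating required
sample size as proportional to the required $\chi^2$ statistic (noncentrality
grows linearly in $n$ at fixed effect size; the statistic is the observable
proxy the curve is defined on). Under the genome-wide calibration (burdens
368.8 and 345450.3 at power 0.8) a flat admixture result (p = 1) costs
+26.5% association sample size, the break-even point is at admixture
p = 0.31, and an admixture result at the Bayesian genome-wide significance
threshold — posterior 0.5, hence chained prior 0.5 — buys a 63.7% reduction.
We interpret "genome-wide significant admixture evidence" through the
posterior threshold that defines significance in this framework, not through
the Bonferroni-style level $0.05/368.8$ (where the admixture posterior is
0.58, and the implied reduction 65.0%).

## The simulator

`simulate_parental_freqs()` draws, per marker, an ancestral frequency from
Uniform(0.1, 0.9) and two parental frequencies from the Balding–Nichols
distribution $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ with $F = 0.12$,
mimicking West African / European differentiation. The bounded ancestral
support avoids monomorphic replicates; with this parameterisation the
pairwise Hudson FST between the parental populations equals $F$ in
expectation (asserted by simulation in the tests). Individual admixture
proportions are Beta with mean 0.8 and standard deviation 0.1 (a fixed-theta
mode exists for variance-controlled tests). Each chromosome copy draws its
ancestry Bernoulli($\theta_i$) and its allele from the matching parental
frequency, so genotype and local ancestry have exactly the conditional
dependence the stratified step relies on — within an ancestry stratum,
genotype is independent of $\theta$, which the tests check.

**Case-control generator.** Disease status follows
$\mathrm{logit}\,P(\text{case}) = \mathrm{logit}(0.1) + \ln(\Lambda)\,a +
\ln(R)\,g$ with ancestry odds ratio $\Lambda$ and allelic odds ratio $R$;
cohorts are rejection-sampled to 1500 cases and 1500 controls. The baseline
prevalence of 0.1 is a package choice (configurable); power at fixed odds
ratios is only weakly sensitive to it.

**Single-marker analyses omit the global-ancestry covariate.** With one
marker, global ancestry "averaged across markers" is exactly half the local
ancestry — perfectly collinear — so `bmix_single_marker()` and
`power_experiment()` fit no covariates. This is a structural fact of the
single-marker design, not a modelling preference.

**The MIX comparator.** The frequentist joint test used as the power
baseline exploits the fact that an allelic odds ratio $R$ *induces* an
ancestry odds ratio
$\Lambda(R) = (1 + (R-1)p_1)/(1 + (R-1)p_2)$ through the parental control
allele frequencies. `mix_score()` implements it as a 1-df Rao score test of
the joint null along the direction $(1, p_1 - p_2)$ — the tangent of the
induced curve at $R = 1$ — with nuisance parameters profiled out. Its null
calibration is unit-tested on its own, so power comparisons against the
joint Bayesian test cannot silently inherit a comparator bug. A constrained
profile-likelihood variant was prototyped and behaves nearly identically at
the operating points we report.

**Power experiment.** `power_experiment()` reruns the published comparison:
per odds-ratio cell, 2000 replicates (10,000 at full scale) of single-marker
cohorts with burdens fixed at 8.067 (admixture) and 6039 (association),
mimicking chromosome 22; the joint test calls a locus at joint posterior
above 0.5, MIX at $p < 0.05/6039$. With these conditions the admixture-arm
cells reproduce published values closely (the pure-ancestry cell
$\Lambda = 1.5$ lands near 0.65–0.70; the null cell is far below 0.005), while
cells driven by the genotype arm run substantially hotter than the published
table — the original experiment's disease model and frequency scheme are not
fully specified, and its per-replicate genotype information appears to be
two- to three-fold lower than this generator yields. We report what the
stated conditions produce rather than tuning unstated knobs toward published
cells; the qualitative structure (the Bayesian joint test dominates MIX in
every cell except a pure genotype effect, where MIX is slightly ahead; both
tests are calibrated under the null) reproduces.

**Confounding experiment.** `confounding_experiment()` makes the phenotype
depend only on an untested, strongly differentiated SNP, so the phenotype
tracks genome-wide ancestry $\theta$. The test SNP is then analysed
adjusting (a) for its local-ancestry call only, and (b) for global ancestry
estimated by averaging local ancestries over a background panel (default
400 markers, giving the estimate a standard error near 0.014). The reported
local-ancestry call and the genotype's latent copy origins are drawn
conditionally independently given $\theta$, reflecting that real
local-ancestry calls derive from marker windows and are imperfectly coupled
to the typed alleles. This decoupling is what makes the experiment
informative: under perfect coupling, conditioning on the true local ancestry
would block the confounding path entirely and both adjustments would be
indistinguishable. At 1000 individuals and 2000 replicates, local-only
adjustment rejects at roughly twice the nominal 5% level while
global-ancestry adjustment stays within binomial bounds; with the phenotype
effect set to zero both are nominal.

## What the simulations do and do not show

The generator reproduces the features the method's validity rests on:
Balding–Nichols differentiation at the target FST, Beta-distributed
admixture, the genotype–ancestry coupling that stratification exploits, and
a logistic disease model. It does **not** simulate recombination-map-aware
ancestry segments (each marker's ancestry is drawn independently given
$\theta$, appropriate for the single-marker experiments but not for
reproducing realistic switch spacing), genotyping error, or linkage
disequilibrium between markers. Passing tests therefore validate the
statistical machinery and its calibration, not the upstream local-ancestry
inference, which this package deliberately consumes rather than performs.

## Problem sizes used in the test suite

The packaged checks run the power grid at 2000 replicates for the directly
compared cells and 800 for the qualitative-ordering cells, the confounding
study at 2000 replicates, burden oracles at 5000-observation series, and
genomic control on $10^5$ null p-values. These sizes keep Monte-Carlo error
comfortably inside the stated tolerances while completing in minutes; all of
them are parameters, and the full-scale published sizes (10,000 replicates)
can be rerun by changing `n_reps`.

## Known limitations

* A marker whose admixture posterior reaches exactly 1 cannot be updated by
  association data (warned about, per the model).
* The effective-test estimator is sample-based: it reflects the markers
  observed, not all possible markers.
* AIC order selection retains a spurious low AR order on white noise with
  its usual positive probability; this leaves the spectral density at zero —
  the quantity that matters — essentially unbiased.
* Fixed-effects pooling assumes a common genotype effect across ancestry
  strata; heterogeneity shows up in the per-stratum detail table rather than
  in a random-effects variance.
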