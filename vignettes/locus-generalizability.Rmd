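---
title: "Methods: testing the cross-population generalizability of known risk loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing the cross-population generalizability of known risk loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`transloci` asks a replication question, not a discovery question. Given a
catalog of risk variants reported by earlier (mostly European-ancestry)
GWAS, and case-control genotype data from several other populations, it
quantifies three progressively weaker notions of transfer: (i) does the
index SNP itself associate with disease; (ii) does its estimated effect at
least point in the reported direction; (iii) does *some* correlated
variant in the region carry a signal, or does an aggregate score over all
reported alleles predict disease even when no single locus does. This
vignette records the models, the generator the package tests itself
against, the numerical choices, and what the synthetic results do and do
not establish.

## The association model

Within each case-control stratum the package fits, for one variant at a
time,

$$\operatorname{logit} P(D_i = 1) = \beta_0 + \beta\, g_i + \gamma'z_i,$$

where $g_i \in [0,2]$ is the effect-allele dosage (hard calls or imputed
dosages) and $z_i$ contains age, sex, BMI and the first 10 principal
components. Estimation is maximum likelihood via iteratively reweighted
least squares (`stats::glm.fit`), convergence at a coefficient change
below $10^{-8}$ or 50 iterations; inference on $\beta$ is a Wald test.
Wald (rather than likelihood-ratio) p-values match the convention of the
standard whole-genome tooling this workflow mirrors. Samples missing the
dosage are dropped for that variant only (per-variant complete case);
mean imputation is deliberately avoided. Fits showing separation
(runaway coefficients or standard errors, rank deficiency after removal
of constant covariates) are flagged unusable and excluded downstream with
a logged reason rather than contributing meaningless estimates.

Two filters precede fitting. A variant must have folded minor allele
frequency of at least 1% in a population (cases and controls pooled —
population-level frequency is what published exclusion lists refer to,
and pooling is the stabler estimate) to be analyzed in that population's
strata, and imputation INFO above 0.8 in a stratum to be analyzed there.

Principal components are computed per population — the analysis is
stratified, so the PCs should capture within-population structure — from a
random subset of 10,000 variants with MAF above 5% and call rate of at
least 95% (all eligible variants, with a warning, when fewer exist).
Columns are mean-imputed, standardized, and the unit-norm left singular
vectors taken in order of decreasing singular value.

## Pooling and directional consistency

Stratum estimates are pooled by fixed-effects inverse-variance weighting,
first over a population's strata and then across populations; a variant
enters the cross-population table only when observed in at least two
populations. Fixed-effects pooling is associative, so the two-stage
estimate equals a direct pool over all strata — the test suite asserts
this to $10^{-10}$. Cochran's Q and $I^2$ are reported but never used to
filter (heterogeneity across ancestries is a finding, not an artifact). A
sample-size-weighted z-combination is available behind a flag for users
who want the alternative convention; the effect-scale scheme is the
default because odds ratios from the meta-analysis are part of the output.

Each catalog index variant's pooled effect is oriented to the reported
risk allele (+1 when the effect allele is the risk allele, −1 when the
other allele is; strand complements are tried for non-palindromic pairs).
A/T and C/G pairs cannot be resolved by complement matching; they are
resolved only when both the observed effect-allele frequency and the
reported risk-allele frequency are below 0.40 — both alleles then being
minor, they must be the same physical allele — and are otherwise excluded
as ambiguous. The 0.40 cutoff is the conventional safeguard; reported
catalogs rarely state strand.

With $k$ of $n$ oriented effects positive, the consistency test is the
exact one-sided upper tail $P(X \ge k)$ for $X \sim \text{Binomial}(n,
1/2)$. The one-sided choice is deliberate: the question is whether *more*
loci than chance are consistent, and the published values this package
reproduces are one-sided tails. An oriented effect of exactly zero counts
as inconsistent (conservative; probability zero under continuous
estimates).

## Regional replication

For each region, proxies are all variants with $r^2 \ge 0.4$ to the index
SNP in a designated reference panel (the index included), $r^2$ being the
squared Pearson correlation of dosages — the composite estimator that
coincides with haplotype $D^2/(p_A p_a p_B p_b)$ on phased indicators.
The effective number of tests in the region is the number of greedy
pairwise tag-SNP bins at $r^2 \ge 0.8$ among variants with MAF above 1%:
repeatedly pick the variant covering the most untagged variants (itself
included), ties broken by higher MAF, then lower position, then
identifier — a deterministic rule, since the classic tagging tool does
not document its tie-break. A region replicates when the smallest proxy
p-value falls below $0.05/n_\text{tags}$. Proxy lookup and tag counting
take separate panel handles (published practice uses a European panel for
proxies and an African panel for tag counting); they may point at the
same matrix. Regions whose proxies are all filtered out are reported
"untestable", never "not replicated". Both thresholds are inclusive
($\ge$), matching the notation of the source conventions. The index SNP
is eligible for tag bins like any other variant.

## Genetic risk scores

Three unweighted allele-count definitions: the **base** score sums
risk-allele dosages over the catalog's index variants (one entry per
catalog row — correlated index pairs in one region are both kept, as in
the published analysis); **modified I** substitutes, within one
population, each replicated region's best proxy for its index variant;
**modified II** does the same from the cross-population meta-analysis.
"Regionally significant" means exactly the region call's
$p < 0.05/n_\text{tags}$ threshold. A substituted variant's risk allele
is whichever allele carried a positive oriented effect in the scope used.

Samples missing at least 20 score variants (a chip-level block, as when a
genotyping array lacks a fixed set of score SNPs) are excluded from score
analyses; residual sporadic missingness is imputed as twice the
within-population risk-allele frequency, the standard allele-score
practice. Dosages, not hard calls, are summed.

Score distributions are compared by Welch two-sample t-tests (cases vs
controls within population), and association with disease is tested
continuously (OR per risk allele) and by quartile, with cut-points from
the full analyzed within-population sample (controls-only cut-points are
a defensible alternative; the full sample is the default because the
published tables do not specify) and the lowest quartile as reference.
Tied cut-points — possible for very short scores — flag the quartile
model unusable rather than silently merging groups.

## Analytic power

For the two-sided level-$\alpha$ per-allele test at population risk-allele
frequency $p$ and odds ratio $R$: the expected control frequency is $p$,
the expected case frequency $p_1 = pR/(1-p+pR)$, the log-OR variance is
approximated by $1/(2n_1 p_1 q_1) + 1/(2n_0 p q)$ (two alleles per
person), and power is $\Phi(\lambda - z_{1-\alpha/2}) + \Phi(-\lambda -
z_{1-\alpha/2})$ with $\lambda = |\log R|/\text{sd}$. A
simulate-and-refit Monte-Carlo oracle (`mc_allele_power`) agrees with the
closed form within two percentage points across the tested grid. Exact
symmetry between risk and protective alleles holds under allele
relabeling — power$(p, R)$ = power$(1-p, 1/R)$ — which is how frequencies
above one half are folded; naive OR $\leftrightarrow$ 1/OR symmetry at
fixed $p$ holds only approximately, because the induced case-frequency
shift is asymmetric.

## The synthetic cohort generator

The generator exists so that every downstream stage has data with the
statistical structure the analysis assumes, under known truth.

* **Allele-frequency divergence.** Each variant has an ancestral
  frequency; population frequencies are drawn from the Balding–Nichols
  Beta law with mean $p$ and variance $F\,p(1-p)$. Defaults
  $F = (0.15, 0.08, 0.12)$ for the three populations give divergence of
  the order seen between continental groups and produce the realistic
  situation in which a locus is common in one population and near-absent
  in another. Only draws of exactly 0 or 1 are redrawn (bounded retries),
  so high-$F$ configurations legitimately concentrate near the
  boundaries.
* **LD.** Haplotypes come from a latent Gaussian with correlation
  $\exp(-d/L)$ in distance $d$ ($L$ = 100 kb by default), thresholded at
  each variant's frequency quantile. Thresholding attenuates correlation,
  so the latent correlation between each region's index and functional
  variants is calibrated by 1-D root finding (the bivariate normal
  orthant probability evaluated by quadrature) to hit the target $r^2$
  (default 0.9, the order reported for well-tagged functional variants).
  When diverged frequencies make the target unattainable, the generator
  warns and records the achieved value — this is exactly the
  trans-ethnic LD-difference phenomenon the analysis is designed around,
  not an error.
* **Phenotypes.** Disease labels follow a logistic model over the
  functional variants' log-odds plus age, BMI and sex terms (modest
  positive defaults for age and BMI, echoing observed case-control
  contrasts; all configurable). Risk terms enter centered so the baseline
  intercept pins the source prevalence whatever the number of effect
  variants. A source population of `source_multiplier` (default 1.6)
  times the target size is simulated and cases/controls are subsampled to
  hit each stratum's counts exactly, mimicking a cohort-nested
  case-control design rather than retrospective sampling formulas.
* **Study structure.** Defaults: three populations of ≈2,000 cases and
  3,500 controls each, six nested case-control strata per population (18
  overall, labels carrying a prior-condition tag used by the sensitivity
  filters), 65 regions of 30 variants with functional OR 1.12 (the mean
  reported index-SNP effect), a chip plan masking the index variants of
  the first 20 regions in 30% of the first and third populations'
  samples (the array-without-score-SNPs situation that motivates the
  GRS exclusion rule), per-variant/stratum INFO drawn from Beta(12, 1.2)
  (mean 0.91, roughly a tenth of draws below the 0.8 filter so the filter
  is exercised), and claims records for 74% of controls. Per-stratum
  sizes are population totals split evenly — published designs rarely
  state the full breakdown.
* **Alleles.** Synthetic variants never get palindromic allele pairs, so
  orientation is always resolvable in simulated catalogs; the palindrome
  rule is exercised by dedicated unit tests instead. The synthetic
  catalog's reported risk-allele frequency is the ancestral frequency
  (the discovery-panel stand-in).

What the generator does **not** emulate: recombination maps or coalescent
LD (pairwise $r^2$ is controlled, higher-order haplotype structure is
not), admixture and admixture LD, genotyping or imputation error beyond
the INFO labels (dosages are exact integer allele counts), departures
from Hardy–Weinberg equilibrium, relatedness, and case ascertainment from
claims codes (claims status is an independent label). Passing tests
therefore establish the *statistical* correctness of the pipeline —
calibration under the null, unbiased recovery of simulated effects,
agreement with independent implementations — not robustness to real-data
artifacts such as differential genotyping error between arrays.

## Numerical choices

Logistic fits: IRLS tolerance $10^{-8}$, 50 iterations; separation
flagged at $|\beta| > 15$ or $\text{se} > 100$; constant covariate
columns (single-sex strata) dropped before fitting. The latent
correlation matrix is repaired after the index–functional override by
eigenvalue clipping at $10^{-8}$ and diagonal renormalization. The
orthant probability uses adaptive quadrature with relative tolerance
$10^{-10}$, and the $r^2$ calibration root is found to $10^{-9}$. The
binomial tail is computed by `pbinom`, exact for these sizes; the test
suite checks it against brute-force summation for every $(k, n)$ with
$n \le 25$. Missing dosage is a plain `NA` throughout — no numeric
sentinel. Coordinates are 1-based inclusive, the VCF convention, in every
window.

## Scale of the shipped checks

The test suite runs the full pipeline on cohorts of 6–24 regions with
5–10 variants each and a few hundred samples per population, sizes chosen
so the whole suite completes in a few minutes while leaving Monte-Carlo
margins (binomial standard errors) several times smaller than the
asserted tolerances: 200 replicates for effect recovery at 2,000/4,000
cases/controls, 100 replicates for risk-score recovery at n = 6,000,
3,000 null fits for the type-I error check, and 50 end-to-end null runs
for the coin-flip consistency and false-replication checks. The
acceptance script's synthetic run uses 12 regions × 10 variants with
300/500 cases/controls per population.

## Known limitations

* The regional window is taken from the catalog entry (or index position
  ± 500 kb when absent); no recombination-informed boundaries.
* Power values are a normal approximation; exact unconditional power can
  differ by a point or two at small samples, which is why the
  Monte-Carlo oracle ships alongside.
* The palindromic-allele rule resolves only the both-minor case; a
  frequency contrast of the form 0.2 vs 0.8 is left ambiguous by design
  (conservative).
* No weighted or shrinkage polygenic scores, no haplotype tagging, no
  conditional regional analysis, and no random-effects or Bayesian
  trans-ethnic meta-analysis — the implemented estimators are the
  classical fixed-effects replication toolkit.
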