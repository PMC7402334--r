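---
title: "Methods: gene-wise variant burden and two-step extreme-phenotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-wise variant burden and two-step extreme-phenotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Antidepressant pharmacotherapy shows large, partly heritable variability in
outcome. A clinically useful question is not "who responds" in the abstract
but: among patients who show *poor early improvement* after two weeks of
treatment, who will still fail to reach remission at twelve weeks? gvburden
implements a two-step association design for exactly this contrast. The two
*concordant extremes* of the outcome range are compared — patients with
neither early improvement nor eventual remission (the `ER_neg_REM_neg`
group) versus patients with both (`ER_pos_REM_pos`) — because contrasting
extreme phenotypes concentrates the genetic signal available from a cohort
of modest size. Discordant patients are excluded from the association
steps.

The package takes SIFT/CADD-annotated variant calls (VCF or a flat
annotation table), a per-sample genotype dosage matrix, and longitudinal
Hamilton Depression Rating Scale (HAM-D) scores with covariates, and
produces gene-level screening statistics, variant-level follow-up
statistics, and a local gene-set over-representation analysis. Because
clinical sequencing cohorts of this kind are rarely public, a synthetic
cohort generator is a first-class module: every stage of the pipeline is
exercised end-to-end on data with known ground truth.

# Outcome definitions and their boundaries

* **Early improvement**: HAM-D reduction of at least 20% at week 2
  relative to baseline.
* **Remission**: HAM-D of at most 7 at week 12.

Both cuts are inclusive, and the 20% boundary is decided in exact integer
arithmetic — `(w0 - w2) * 5 >= w0` — so a 20 → 16 trajectory is early
improvement with no dependence on floating-point rounding. Eligibility
requires a baseline HAM-D of at least 14 (moderate depression); inclusion
in the outcome analysis additionally requires an observed score at week 1
or week 2 *and* at week 3, because without those visits neither outcome
can be anchored.

## Missing follow-up scores

Scores at weeks 6, 9 and 12 may be missing and are multiply imputed by
chained equations with predictive mean matching (PMM): each incomplete
week column is regressed on age, sex, baseline HAM-D, baseline HADS-A
anxiety and the current values of the other week columns; each missing
entry receives the *observed* score of a donor drawn from the five
nearest predicted values. PMM was chosen over a parametric normal draw
because it keeps imputations on the observed integer support of the
scale and is robust to the skewed, floor-bounded residuals typical of
symptom scores. Defaults are 5 imputations and 10 sweeps, which is ample
for three incomplete columns; both are configurable
(`imputation_config()`). Weeks 0–3 are never imputed.

Outcome labels are computed per imputation and pooled by majority vote on
each boolean, with exact ties resolved from the first imputation and
flagged. Label-level pooling (rather than pooling imputed scores) keeps
the nonlinear 20%/remission cuts honest: classifying the average of
imputations is not the same decision as averaging the classifications,
and the vote makes the pooling rule explicit and auditable.

# Gene-wise variant burden

For sample $i$ and gene $g$, let $S_{ig}$ be the set of *deleterious*
variants carried by $i$ in $g$ (dosage ≥ 1). The burden score is the
geometric mean of their SIFT scores,

$$\mathrm{GVB}_{ig} = \Big(\prod_{v \in S_{ig}} s_v\Big)^{1/|S_{ig}|},$$

with $\mathrm{GVB}_{ig} = 1$ when $S_{ig}$ is empty. Because SIFT scores
live in $[0,1]$ with smaller meaning more damaging, GVB is a
per-gene-per-sample summary in $(0,1]$: 1 means no predicted burden and
values near 0 mean heavy predicted functional impact.

Choices that the score definition leaves open, and the defaults here:

* **Deleteriousness cutoff** — SIFT < 0.7, following the burden-scoring
  methodology this score family derives from; SIFT's own "damaging" call
  (0.05) is available by configuration. The cutoff matters mostly for
  which common, mildly deleterious variants enter the product.
* **Zero floor** — a SIFT of exactly 0 is replaced by 0.001 so the
  geometric mean stays positive. Any variant with SIFT 0 otherwise
  collapses the whole product to 0 regardless of the rest of the gene.
* **Zygosity** — by default each carried variant counts once
  (`per_allele = FALSE`); weighting by allele dosage is supported. For a
  single homozygous variant the two conventions coincide (the geometric
  mean of $\{s, s\}$ is $s$), so cohort-level summaries rarely
  distinguish them.
* **Missing genotypes** — treated as non-carrier at scoring time; the
  upstream reader deliberately retains them as missing so each analysis
  decides.

# Step 1: gene-level screening

Within each stratum (total, male, female — sex-stratified runs are part of
the design because genetic effects on antidepressant response differ by
sex):

**Burden regression.** Logistic regression of extreme-group membership
(1 = `ER_neg_REM_neg`) on $1 - \mathrm{GVB}$ plus covariates. Regressing
on $1-\mathrm{GVB}$ orients the odds ratio so OR > 1 means more burden →
higher odds of non-remission. Covariates default to those differing
between the extreme groups at p < 0.05 in a univariate screen (Welch
t-test for numeric, chi-square for categorical), mirroring common
clinical-genetics practice; an explicit covariate list can be supplied
instead. The fit returns `NA` when the burden is constant, when a group
has fewer than 10 samples, or when the fit separates (detected by
non-convergence or exploding Wald standard errors) — these are reported
as `NA` rather than silently dropped, matching how such rows appear in
published result tables.

**SKAT-O.** The burden regression is blind to genes whose qualifying
variants are too rare to vary GVB between groups, so a rare-variant set
test complements it: the optimal sequence kernel association test on the
gene's variants with reference-panel allele frequency < 0.01 (cohort
frequency where no annotation is available). With score vector
$S = W G^\top (y - \hat\mu)$ from a covariate-only logistic null model and
weights $w_j = \mathrm{Beta}(\mathrm{MAF}_j; 1, 25)$ (the field's standard
up-weighting of the rarest variants), the statistic family is

$$Q_\rho = (1-\rho)\, S^\top S + \rho\, (\mathbf{1}^\top S)^2,$$

interpolating between the variance-component kernel statistic
($\rho = 0$) and the squared weighted burden score ($\rho = 1$). Each
$Q_\rho$ is a quadratic form in asymptotically normal scores, so its null
tail is a weighted mixture of 1-df chi-squares with weights given by the
eigenvalues of $R_\rho^{1/2} A R_\rho^{1/2}$, where $A$ is the null score
covariance and $R_\rho$ the compound-symmetry matrix. The optimal test
takes the minimum p over the grid
$\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$ and corrects it
with the one-dimensional integral that conditions on the shared
burden-direction chi-square (the Lee et al. construction); the final
p-value is clamped to its analytic envelope
$[\min_\rho p_\rho,\; |\mathrm{grid}| \cdot \min_\rho p_\rho]$ as a
numerical guardrail. Degenerate sets (a single variant, or perfectly
correlated variants) make every $Q_\rho$ the same burden chi-square; the
implementation detects this and returns the component p directly.

**Multiplicity.** Benjamini–Hochberg q-values are computed separately
within each stratum × test family (burden regression vs SKAT-O),
mirroring how the two q columns are reported side by side in this
literature; `NA` p-values stay `NA` and do not count toward the number of
tests. A gene becomes a *candidate* when either family's q falls below
the screening threshold, 0.25 by default — deliberately permissive, since
step 1 is a screen, not a final call.

## Tails of weighted chi-square mixtures

SKAT-O needs $P(\sum_k \lambda_k \chi^2_{1,k} > q)$ to high accuracy, both
per $\rho$ and inside the combination integral. The primary method here is
**Ruben's expansion**: the distribution is written as an infinite mixture
of central chi-squares,
$P(Q > q) = \sum_k c_k P(\chi^2_{m+2k} > q/\beta)$ with $\beta =
\min_k \lambda_k$, where the $c_k$ are a probability mass function
computed by an $O(Km)$ linear recurrence (compiled, in `src/ruben.cpp`)
and evaluated through the chi-square survival ladder. Its decisive
property is a *provable truncation bound*: stopping after $K$ terms
underestimates the tail by at most the mixture mass not yet accumulated,
so the implementation knows when its answer is good to tolerance.
Direct numerical inversion of the characteristic function (the
Imhof/Davies integral) is kept as a secondary route, and the Liu
moment-matching chi-square approximation as a last resort, flagged in the
result; generic quadrature on the oscillatory inversion integral is
unreliable precisely in the small-$m$ cases that dominate rare-variant
sets, which is why the series expansion leads.

Ruben's series converges geometrically at rate
$1 - \lambda_{\min}/\lambda_{\max}$, so near-zero eigenvalues (numerical
rank deficiency of the score covariance) would make it arbitrarily slow.
Eigenvalues whose running tail sum is below $10^{-4}$ of the
distribution's standard deviation are therefore dropped before the
expansion; the induced perturbation of the tail probability is far below
every tolerance used by the tests around it.

# Step 2: variant-level follow-up

Every variant in a candidate gene — rare and common, since published
variant tables of this design include both — is tested in the stratum
where the gene was selected, under the **dominant carrier model**: samples
are dichotomised as carriers (het + hom) versus homozygous reference,
giving a 2×2 table against the extreme groups. The table is tested with
the two-sided Fisher exact test; the reported odds ratio is the sample
cross-product ratio (with OR = ∞ when only the non-remission group has
carriers), and the 95% CI is the Woolf logit interval
$\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$, reported as
`NA` whenever a cell is zero. The carrier coding is not arbitrary: it is
the unique standard coding under which the published per-variant odds
ratios of this design are reproduced exactly from their printed genotype
counts, which the acceptance suite verifies against four such tables.

# Pathway over-representation

Candidate genes are tested against GMT gene-set collections with the
hypergeometric upper tail ($P(X \ge \text{overlap})$ over the collection's
universe), BH-adjusted across sets, significant at adjusted p < 0.05.
This is a deliberately local, offline stand-in for web-based enrichment
services: the decision rule matches, while rankings produced by hybrid
scores of such services are out of scope.

# The synthetic cohort generator

`simulate_cohort()` generates, from one seed with fixed substreams for
genotypes, phenotypes and missingness:

* **Genotypes**: per-variant alternate-allele frequencies drawn from a
  rare range (0.0005–0.01, 70% of variants) or a common range (0.01–0.3),
  dosages Hardy–Weinberg binomial(2, AF); the drawn AF is recorded as the
  reference-panel annotation. Defaults of 200 genes × 10 variants give a
  rare-heavy spectrum at a tractable scale.
* **Annotations**: SIFT from a mixture — deleterious
  (Uniform(0, 0.05), probability 0.3) or tolerated (Uniform(0.05, 1));
  CADD carried as annotation only.
* **Phenotypes**: a latent responder class with
  $P(\text{responder}) = \mathrm{logit}^{-1}(\alpha - \sum_g \beta_g
  (1-\mathrm{GVB}_g))$, where planted effects $\beta_g$ can be global or
  sex-specific. The intercept default, $\mathrm{logit}(0.426)$, together
  with a 78% partial-response rate among non-responders, places the
  marginal remission and early-improvement rates near the 42.6% / 83.3%
  observed in naturalistic antidepressant cohorts — these are modelling
  anchors, not constraints, and the extreme-group sizes are emergent.
  Trajectories follow
  $\text{score}_t = b\,(f + (1-f)e^{-rt})$ plus integer-rounded Gaussian
  noise: responders decay fast to a low plateau (remission range, early
  drop well above 20%), partial responders drop early but plateau above
  remission, flat non-responders do neither. Missingness is MCAR at 10%
  per visit, only after week 3.

What the generator does *not* emulate: linkage disequilibrium, population
stratification, a realistic site-frequency spectrum beyond the two
configured ranges, informative missingness, or covariate-outcome
confounding. Passing end-to-end tests therefore demonstrate that the
pipeline recovers effects of the stated size under clean sampling
assumptions — not that it is robust to the correlation structure of real
exomes.

# Validation scales and numerical choices

The test and acceptance suites run the pipeline at deliberately chosen
problem sizes: end-to-end parameter recovery uses cohorts of 1000 samples
× 200 genes with one planted gene of log-odds effect 1.5 over 50 seeded
replicates (selection expected in at least 80%), null calibration uses 15
replicates of the same scale with no planted effect, and SKAT-O type-I
error uses 2000 null simulations at n = 200 with 10 variants of MAF
0.01–0.05 — a range chosen so expected carrier counts put the asymptotic
score test in its regime of validity at that sample size. Tail
probabilities are computed to absolute tolerance 1e-8 (1e-6 inside the
combination integral); the permutation cross-check uses 100,000 label
permutations.

Other numerical decisions: the ρ = 1 grid point is handled in the 0.999
limit inside the combination integral (the integrand is otherwise
singular); the combination integral runs only over the region where its
integrand is non-zero; Wald CIs use z = 1.959964; imputed scores are
clamped to the HAM-D range [0, 52] and rounded.

# Configuration and orchestration

All thresholds surface in configuration objects (`gvb_params()`,
`rare_set_spec()`, `imputation_config()`, `sim_config()`) or the pipeline
run configuration. The run configuration file is YAML — a standard
key-value text format with a parser available everywhere R runs — and CLI
flags override it. Each pipeline stage writes a JSON manifest (input
hashes, seed, parameters) sufficient to replay the run; identical
configuration and seed give identical outputs.

# Known limitations

* SKAT-O is the standard asymptotic version; no small-sample moment
  adjustment is applied, so p-values at very sparse carrier counts are
  conservative.
* The burden regression reports Wald intervals; profile or exact
  intervals are not implemented.
* One gene symbol per variant: multi-transcript annotation is collapsed
  upstream.
* The generator's trajectory model is a two-parameter exponential with a
  plateau; real symptom courses (relapse, oscillation) are richer.
* Pooling outcome labels by majority vote is one defensible rule among
  several; it is exposed in configuration precisely because the design
  space is open.
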