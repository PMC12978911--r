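---
title: "Cluster-level analysis of stratified adherence trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-level analysis of stratified adherence trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtadhere)
```

## The problem

Treatment guidelines for uncomplicated gonorrhea recommend a single 1 g
intramuscular dose of ceftriaxone. Whether physicians follow that
recommendation can be audited from hospital prescription records, and
interventions to improve adherence are naturally evaluated by randomizing
*hospitals* (clusters), stratified by province, rather than individual
physicians or patients. `crtadhere` implements the complete statistical
workflow for such a trial: record-level eligibility filtering and
adherence adjudication, cluster-level summary inference with stratified
geometric-mean risk ratios and risk differences, covariate adjustment via
ratio residuals, sample-size design from a between-cluster coefficient of
variation, and a synthetic-trial generator so that every pipeline stage is
testable without access to any hospital data.

## Adjudication and eligibility

A prescription enters the analysis only if the patient was an adult,
not pregnant or lactating, received ceftriaxone, was not co-treated with
antibiotics for another infection, and had uncomplicated disease. The five
criteria are evaluated in that order and the first match is recorded as
the primary exclusion reason for the trial-profile tallies; all matching
reasons are also kept. The ordering is a reporting convention only — a
record is excluded if it matches *any* criterion, so the eligible set does
not depend on it.

Adherence of an eligible prescription is a deterministic function of its
ceftriaxone orders: exactly one order, one administration, 1000 mg, by the
intramuscular route. Anything else — a 2 g dose, a repeated schedule, an
intravenous route, a missing route — is a deviation. One genuine ambiguity
is a guideline-conforming ceftriaxone order accompanied by a second
antibiotic indicated for gonorrhea itself (co-treatment for *other*
infections triggers exclusion instead). The rule engine classifies this as
a deviation but flags the call (`ambiguous_extra_antibiotic`) so that a
reviewer can audit it; a second reviewer's calls can be supplied as an
override column, and disagreements are surfaced rather than silently
resolved.

## The estimator

Let $p_{ij}$ be the observed adherence proportion of cluster $i$ in
stratum $j$ at endline. Cluster-level summary analysis treats these, not
the individual prescriptions, as the units of inference — the standard
defence against between-cluster variation when clusters per arm are few.
Because cluster proportions are skewed, the analysis works with
$\ell_{ij} = \log p_{ij}$. The stratum effect

$$\hat\theta_j \;=\; \bar\ell_j^{\,I} - \bar\ell_j^{\,C}$$

is the log ratio of geometric mean risks between arms. Stratum estimates
are pooled with weights inversely proportional to their variances
$v_j = s^2 (1/c_{1j} + 1/c_{0j})$, giving

$$\widehat{\log RR} = \frac{\sum_j \hat\theta_j / v_j}{\sum_j 1/v_j},
\qquad SE = \Big(\sum_j 1/v_j\Big)^{-1/2},$$

with a two-sided t-test and confidence interval on
$\mathrm{df} = \sum_j (c_{1j} + c_{0j} - 2)$ degrees of freedom. The risk
difference analysis applies identical machinery to the untransformed
proportions.

Two numerical choices deserve comment.

**Variance pooling.** The within-arm scatter $s^2$ is pooled *across*
strata on the full $\sum_j (c_{1j}+c_{0j}-2)$ degrees of freedom, rather
than estimated separately per stratum. With two strata of nine clusters
per arm, per-stratum variances carry only 16 df each; weights estimated
from them are correlated with the stratum effects and the resulting test
is anti-conservative (simulation in the test suite puts its size near
7.5% at a nominal 5%). With the pooled $s^2$ the weights reduce to
cluster-count weights — still inversely proportional to the stratum
variances — and the test holds its nominal size in the same simulations.
This is the classical stratified (two-way ANOVA style) t-test.

**Continuity at the boundary.** A cluster with zero (or all) adherent
prescriptions has no finite log risk; such clusters substitute
$\tilde p = (o + 0.5)/(n + 1)$. The same adjusted count is used when
forming ratio residuals, which is what makes the intercept-only
adjustment identity below hold exactly, boundary clusters included.
Substitutions are counted and reported. Clusters with no eligible records
at all are dropped with a warning and a count; a stratum left with fewer
than two clusters in an arm is a hard error by default, because silently
merging strata changes the estimand (an explicit `small_stratum = "merge"`
folds it into the smallest other stratum). If every cluster in every arm
has an identical outcome the point estimate is still returned but SE and
p are reported as undefined rather than zero-divided.

## Covariate adjustment by ratio residuals

Individual-level covariates (stratum, the cluster's baseline adherence
proportion, patient sex and age, physician sex and department) are
adjusted for by fitting a logistic model to the individual endline data
*excluding the treatment arm*, predicting each cluster's expected adherent
count $e_i$ as the sum of fitted probabilities, and re-running the
cluster-level machinery on the ratio residuals $r_i = o_i / e_i$ (or
difference residuals $(o_i - e_i)/n_i$ for the risk-difference scale).
The model is an ordinary maximum-likelihood logistic fit; convergence is
verified on the score vector itself (max absolute component below
$10^{-8}$), separation is reported as an error naming the offending term,
and aliased terms are an error rather than a silent drop. Because the
intercept's score equation forces $\sum_i e_i = \sum_i o_i$, an
intercept-only model yields $r_i = \tilde p_i / \bar p$ and the adjusted
log risk ratio collapses to the unadjusted one — a machine-precision
identity the test suite checks on random synthetic trials, and a useful
canary for residual-computation bugs. Covariates that are constant in the
data at hand (a single-stratum trial, say) are dropped with a message.
The baseline cluster outcome enters as a cluster-constant numeric
covariate and patient age as numeric years; clusters with no baseline
records take their stratum's mean baseline proportion.

## Design calculations

Sample size uses the unmatched cluster-level formula in the
coefficient-of-variation tradition:

$$c = 1 + (z_{\alpha/2} + z_\beta)^2\,
\frac{\pi_0(1-\pi_0)/n + \pi_1(1-\pi_1)/n + k^2(\pi_0^2 + \pi_1^2)}
     {(\pi_0 - \pi_1)^2}$$

clusters per arm, where $k$ is the SD of true cluster proportions divided
by their mean, $n$ the expected usable individuals per cluster (the
anticipated fraction of illegible records is removed from $n$, not from
the cluster count), and the leading $+1$ compensates for estimating
between-cluster variation with few clusters. Standard-normal quantiles
are used, per convention. The returned integer count is floored at 2
clusters per arm (below that nothing is estimable); the unrounded formula
value is exposed as `c_exact`, which at $k = 0$ reduces to the classical
two-proportion individual-level size divided by $n$, plus one. Power for
a given cluster count inverts the same identity, and the two functions
round-trip. A `per_stratum` flag sizes each stratum separately — with
eight provinces and the formula's 9 clusters per arm this yields a 144
cluster allocation target; the package computes per-stratum targets but
does not claim the pooled formula itself outputs 144, since how
stratification entered that arithmetic is not fully determined.

Stratified 1:1 randomization (`allocate_clusters`) splits each province's
clusters evenly with a seeded sequence; generation and disclosure are
separate calls so the allocation can be concealed until assignment, and an
odd stratum either errors or sends the extra cluster to control under an
explicit rule.

## What the generator emulates — and what it does not

`generate_trial()` draws a latent true proportion per cluster,

$$p_i = \mathrm{clamp}\big(p_{\text{stratum}} \cdot G_i \cdot
RR^{\,[\text{arm} = I,\ \text{period} = \text{endline}]},\ \varepsilon,\
1 - \varepsilon\big), \qquad G_i \sim
\Gamma(k^{-2}, k^{-2}),$$

so the $G_i$ have mean 1 and coefficient of variation exactly $k$ — the
multiplicative-gamma choice matches how $k$ is defined in the sample-size
tradition (a CV of *true proportions*, not of their logits). The
intervention multiplies *risk* (matching the geometric-mean-ratio
estimand) while physician covariate effects act on the *odds* of
nonadherence (matching how factor analyses report them); the two scales
coexist and the truth record stores both. Physician effects are centered
on the covariate sampling frequencies so that they add prescription-level
heterogeneity without moving the cluster-level estimand off the
configured $RR$. Each prescription is then adherent with probability
$\mathrm{logit}^{-1}(\mathrm{logit}(p_i) + \text{physician offset})$, and
drug orders are written out accordingly: a guideline regimen for adherent
records, and a dose, schedule, route, or extra-antibiotic deviation
otherwise. Ineligible records are injected with exactly the attributes
that trigger each configured exclusion reason, and `corrupt_records()`
blanks required fields to emulate illegible prescriptions. Truncation of
$p_i$ at $1 - \varepsilon$ ($\varepsilon = 0.005$) is counted in the
truth record; with high baselines and large $k$ it introduces a small
downward bias in the realized geometric-mean ratio, which is why the
presets keep expected proportions comfortably inside the unit interval.

Three presets fix the study conditions used throughout the tests:
`four_province_trial` (baselines 4%, 49%, 72%, 77%; 9 clusters per arm
per stratum; ~100 prescriptions per cluster-period; $k = 0.1$;
generative $RR = 1.12$; roughly half of screened records ineligible; 10%
record loss), `yunnan_low_baseline` (a single 4% stratum lifted to ~19%),
and `null_trial` (two strata at 30% and 55%, $k = 0.25$, $RR = 1$, no
contamination — the clean null generator for calibration studies). The
null-trial baselines are the one free choice the conditions left open;
moderate and distinct values were picked once so the two strata have
genuinely different variances on the log scale.

The generator does *not* emulate: within-physician correlation of
prescriptions beyond shared covariates (an optional physician random
effect was considered and left out of the default, since no evidence
informs its size), seasonal or monthly trends, drug-name dialects beyond
the synonym list, Chinese-language free text, or partially legible
records (corruption is all-or-nothing per field). Passing tests therefore
demonstrate correctness of the *statistical machinery under the assumed
structure*, not robustness to real hospital-information-system noise.

Monte-Carlo study sizes used by the test suite and acceptance script —
2000 null trials for test size, 500 trials for estimand recovery, 100
trials for the adjustment identity — run the generator through its
summary-level path (`simulate_summaries()`), which draws the identical
latent clusters and binomial counts while skipping record-level
attributes that cannot affect cluster-level estimates; full
prescription-table trials are used wherever records, covariates or
adjudication matter.

## Known limitations

* The trial's own headline numbers (RR 1.12, 95% CI 0.93–1.35; a 5.5
  point mean difference) depend on unpublished hospital prescription
  data; the package reproduces the *methods*, and its simulations
  recover configured effects, but no claim is made about reproducing
  those estimates from real data.
* The approximate SE and df of the stratified t-test are a documented
  convention (pooled within-arm variance; $\sum_j (c_{1j}+c_{0j}-2)$ df);
  other defensible choices exist and small-sample behaviour differs
  between them.
* Inverse-variance pooling assumes the stratum effects share a common
  estimand; with qualitatively different stratum effects (a very low
  baseline province, say) the pooled estimate is a weighted average, not
  a law of nature, and per-stratum tables should be read alongside it.
* The logistic covariate model ignores within-cluster correlation by
  design — its only role is to produce expected counts for residuals, a
  point the cluster-level second stage is built to absorb.
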