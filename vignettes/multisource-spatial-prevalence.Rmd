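---
title: "Multi-source spatial prevalence estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source spatial prevalence estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`msprev` estimates small-area disease prevalence when cases are ascertained
by several incomplete, overlapping administrative lists. It was built around
the setting of multiple-sclerosis surveillance in 21 French departments,
where three sources — health insurance long-term-illness registers, a
neurologist network, and hospital discharge records — each see only part of
the case population, and no person-level linkage is available outside a few
registry regions. This vignette explains each stage of the method, the
choices that were genuinely open, and what the package's tests do and do not
establish.

## 1. Combining three sources with overlap shares

Write $a, b, c$ for the marginal counts of the three lists in one
(department, sex, age-class) cell and $N$ for the number of unique cases on
the union of the lists. The package defines a *share of overlap* as an
inclusive intersection count divided by the unique total:
$s_{ab} = |A \cap B| / N$, and likewise $s_{bc}$, $s_{ac}$,
$s_{abc} = |A \cap B \cap C| / N$. Inclusion–exclusion then gives the exact
identity

$$a + b + c \;=\; N\,(1 + s_{ab} + s_{bc} + s_{ac} - s_{abc}),$$

so `estimate_unique_cases()` returns
$N = (a+b+c) / (1 + s_{ab} + s_{bc} + s_{ac} - s_{abc})$.

The share semantics was the central open design question: with only printed
aggregate shares and department totals, several denominators (union,
source-sum, per-source) are conceivable, and applying the published
aggregate shares to published department totals does not reproduce the
published unique-case column under any of them — the original computation
used stratum-specific shares that were never printed. The union denominator
was chosen because it makes the estimator a closed-form inversion of
inclusion–exclusion and is *exactly* recoverable in simulation:
`shares_from_venn()` computes shares from the seven exclusive Venn cells of
a simulated triple-capture experiment, and the estimator applied to the
simulated marginals returns the simulated union count to numerical
precision. That identity is enforced by a 1,000-replicate test across
capture probabilities from 0.15 to 0.95 and log-linear pairwise dependence
from $-1.5$ to $1.5$.

Two catalogued share sets ship with the package: the regional aggregate set
(0.46, 0.23, 0.20, 0.12) applied to most departments and the Haute-Garonne
set (0.25, 0.28, 0.42, 0.17). The two published footnotes disagree on
whether 0.23 belongs to network–hospital or insurance–hospital, so both
orderings are catalogued (`lorraine_2008`, `lorraine_2008_alt`); the choice
does not affect the estimator (the divisor is symmetric in the pairwise
shares) but matters if shares are interpreted individually. Department-level
share sets for the other registry departments were never published, so
sensitivity analyses beyond the catalogued sets must supply their own
values.

Estimates are real-valued; the count likelihood needs integers, so a
half-to-even rounded copy is kept alongside (`unique_cases_int`). Rounding
happens at stratum level, before any aggregation, and the real-valued
numbers are authoritative for reporting. When inconsistent shares push an
estimate below the largest of the three marginals the row is flagged with a
warning rather than an error, since sampling noise in shares can legitimately
produce this.

## 2. Spatial autocorrelation of standardized prevalence ratios

Before modeling, the package tests whether neighbouring departments
resemble each other. Expected counts come from *internal indirect
standardization*: pooled stratum rates applied to each department's own
population structure, which conserves the observed total by construction
(checked to $10^{-9}$ on random tables). The standardized prevalence ratio
is $\mathrm{SPR}_d = 100\,O_d/E_d$.

Moran's I is computed on the SPR values — not raw counts — because the SPR
removes age–sex composition before the spatial question is asked:

$$I = \frac{n}{\sum_{ij} w_{ij}}
      \frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}
           {\sum_i (x_i-\bar x)^2}.$$

Weights are binary contiguity (1 when two departments share a border) by
default, the minimal reading of neighbourhood; row-standardized weights are
an option. The null reference uses the randomization assumption:
$E[I] = -1/(n-1)$ with the classic Cliff–Ord variance, and a two-sided
$p = 2(1-\Phi(|z|))$. A permutation test is also provided; its two-sided
region is defined by $|I - E[I]|$, i.e. deviations are centred at the null
expectation rather than at zero. This matters: the permutation null of I is
centred at $-1/(n-1)$, and taking $|I|$ uncentred systematically inflates
two-sided permutation p-values relative to the z-test (roughly twofold in
our lattice experiments). With centring, normal and permutation p-values
agree within a factor of two across signal strengths, which is the
method-agreement property the tests enforce.

## 3. The Bayesian negative-binomial BYM model

Counts $y_{ds}$ (department $d$, stratum $s$) are modeled as negative
binomial with mean $\mu_{ds} = P_{ds}\exp(\alpha + \beta^{sex}_s +
\beta^{age}_s + u_d + v_d)$ and variance $\mu + \mu^2/r$, where $P_{ds}$ is
the population denominator. Age and sex enter as fixed effects on the log
mean with the first sex and first age class as reference categories — the
mechanism of adjustment was unspecified in the source setting, and offsets
plus log-linear effects are the standard epidemiological choice. The
department effect is the Besag–York–Mollié convolution: unstructured
heterogeneity $u_d \sim N(0, \sigma_u^2)$ (the "global structure")
plus an intrinsic CAR field $v$ (the "local structure") in which
$v_d \mid v_{-d} \sim N(\bar v_{\partial d},\, \sigma_v^2/m_d)$ with $m_d$
the number of neighbours, subject to a sum-to-zero constraint. Both
components can be switched off independently.

"Non-informative" priors had to be concretized: Normal(0, 100) on
$\alpha$ and the $\beta$s, half-Normal(10) on $\sigma_u$ and $\sigma_v$,
Normal(0, 10) on $\log r$. All are overridable through
`build_model(priors = ...)`, and a numeric `fix_r` freezes the dispersion
(e.g. `1e6` as a practical Poisson limit). A caution from the test suite:
with only a handful of observations the dispersion is unidentified and a
wide prior on $\log r$ lets $r$ collapse, flattening the likelihood;
degenerate fixtures should fix $r$.

### Sampler

`run_mcmc()` is a Metropolis-within-Gibbs sweep: adaptive random-walk
updates for $\alpha$, each $\beta$, each $u_d$, each $v_d$ and $\log r$
(Robbins–Monro scaling toward 0.44 acceptance during burn-in), and
stepping-out slice updates for $\log\sigma_u$ and $\log\sigma_v$, whose full
conditionals are cheap one-dimensional densities
($\sigma^{-(k-1)}e^{-SS/2\sigma^2}$ times the half-Normal prior, with $k$
the effective dimension — for the intrinsic CAR, the rank of its precision,
i.e. nodes minus connected components).

Two structural moves were added after profiling mixing, both standard
remedies for the ridges this model contains:

* a likelihood-invariant translation $\alpha \to \alpha + \delta$,
  $u \to u - \delta$, accepted on the prior ratio alone, because the
  intercept and the mean of the unstructured field are only jointly
  identified;
* factor-block translations $\alpha \to \alpha + \delta$,
  $\beta^{age} \to \beta^{age} - \delta$ (and likewise for sex), which touch
  the likelihood only on the factor's reference rows — the reference age
  class carries few cases, so the intercept/age-profile ridge otherwise
  mixes very slowly.

Without these moves, split-$\hat R$ for $\alpha$ stayed near 1.8 on
20-second runs; with them it is at 1.00 and the intercept's credible
interval is well calibrated (see below).

The CAR field is recentred to sum zero over the connected nodes after every
sweep — the on-the-fly centring used by WinBUGS's `car.normal` — and
zero-degree departments ("islands", e.g. a department whose neighbours are
all outside the study) have $v_d$ pinned at 0 with a logged warning, keeping
the parameter vector aligned rather than silently dropping the CAR term.
Chains start from dispersed initial values; everything is bit-reproducible
given the seed.

Defaults are 2 chains of 20,000 iterations with 10,000 burn-in and thinning
by 5. Split-$\hat R$ and an initial-positive-sequence effective sample size
are reported per scalar parameter; the pipeline warns (but continues) when
any $\hat R$ exceeds 1.1, so a sensitivity sweep is never aborted by one
slow parameter.

### Derived quantities

Stratum rates $\theta_{ds} = \exp(\alpha + \beta + u_d + v_d)$ are
reconstructed per retained draw. Standardization is applied *per draw* and
then summarized, so credible intervals propagate posterior uncertainty
through the standardization step rather than standardizing a posterior
mean. Relative risks divide each department's directly standardized
prevalence by the unweighted mean over departments within the same draw; a
population-weighted mean was the alternative reading, and the unweighted
version was chosen because the reference is described as "the average of
the departments", a department-level not person-level average. Crude
(own-structure-weighted) rates are available via `summarize_fit(quantity =
"theta")`.

## 4. Direct standardization and reference populations

Directly standardized prevalence per 100,000 is
$P_d = 10^5 \sum_k w_k \theta_{dk}$ with normalized reference weights
$w_k$. Three references ship with the package:

* `european` — the 1976 European Standard Population (five-year bins,
  re-binned by lower-bound assignment to the configured classes, split
  evenly between sexes);
* `world` — the WHO World Standard 2000–2025, likewise;
* `french_2004` — an *approximate, synthetic* reconstruction of the French
  2004 age–sex margins, shipped so the pipeline runs end-to-end; a real
  census table should replace it in production via
  `read_reference_population()`.

The 1976 European standard (not the 2013 revision) matches the era of the
study setting. Re-binning conserves total weight exactly because source
bins nest inside the ten-year target classes; weights are normalized after
load, so pre-scaled tables (per-100,000, percent, raw counts) all work
identically.

The age classes themselves are a configurable list defaulting to ten-year
bins 0–9 … 80+. The original analysis never listed its age classes; ten-year
bins were chosen as the coarsest standard demographic binning that still
re-bins cleanly from the published five-year standard tables.

## 5. The synthetic-data generator

`simulate_truth()` draws the latent state of exactly the model above: an
intrinsic CAR field on the contiguity graph (sampled in the span of the
non-null eigenvectors of the graph Laplacian, recentred per component,
isolated nodes at zero), an unstructured Gaussian field, and log-linear
age–sex effects. Default hyperparameters describe a disease of roughly 150
cases per 100,000: baseline (female, 0–9) rate $5\times10^{-5}$, a
prevalence peak at ages 40–59 (log effects up to 4.1), a male rate about
half the female rate ($\beta = -0.7$), spatial sd 0.3 and unstructured sd
0.1 on the log scale. These are one-time choices of realistic magnitudes
for a chronic neurological disease, stated here and in every fixture
manifest.

`simulate_cases()` draws true cases binomially from stratum populations;
`simulate_capture()` assigns each case to one of the eight cells of a
2×2×2 log-linear capture table (independence margins times pairwise
interaction terms) and drops the never-captured cell, mirroring the fact
that real overlap shares describe observed lists only. The magnitude of
inter-source dependence in the real lists is unknown; the interaction
defaults are zero and tests sweep them over $\pm1.5$.

What the generator does *not* emulate: true census population margins (its
department sizes are log-normal around a target mean), coding errors and
false positives in administrative sources, temporal drift in overlap
between a prevalence date and the capture–recapture study years, and
spatial variation in capture probabilities. Passing tests therefore show
the estimator chain is internally exact and the sampler calibrated under
the model's own assumptions — not that those assumptions hold for any real
registry.

## 6. Problem sizes and numerical choices in the test suite

The suite runs on one CPU in a few minutes, with sizes chosen to keep the
statistical checks sharp at that budget: the calibration study uses 50
datasets simulated from the model on the 21-department graph (negative
binomial counts, dispersion 50, mean department population 400,000), each
fitted with 2 chains of 700 iterations after the ridge moves made short
chains honest; the requirement is 95% credible-interval coverage of the
intercept in at least 90% of replicates. The conjugate check fits a single
area in the Poisson limit ($r = 10^6$ fixed) against the closed-form
Gamma(150, $10^5$) posterior within three Monte-Carlo standard errors
(computed from the realized effective sample size). Moran's I is checked to
$10^{-12}$ against a brute-force double sum on 100 random graphs, and the
permutation p-value floor $1/(n_{perm}+1)$ is asserted exactly.

Other numerical conventions: degenerate SPR cells ($E = O = 0$) are flagged
`NA` rather than dropped; a zero-variance value vector is an error for
Moran's I (the index is undefined); true rates are clipped below 1 in the
generator and an error is raised if any rate reaches 0.5, which signals
implausible hyperparameters rather than a legitimate draw; ties in rank
comparisons use average ranks.

## 7. Known limitations

* The published unique-case column cannot be reproduced from published
  inputs (stratum-specific shares were never printed), so printed-number
  checks are restricted to the internal row/column sums of the published
  table and the Z-to-p conversion of the reported Moran deviate.
* Posterior numbers from the original analysis (prevalence range
  68.1–296.5 per 100,000, relative risks 0.5–2.1) are not desk-reproducible
  either: they require the non-deposited registry case lists, unpublished
  priors and MCMC settings, and exact census tables. The package's
  acceptance checks therefore validate internal consistency and calibration
  on synthetic data rather than chasing those values.
* The intrinsic CAR prior is improper and its sum-to-zero handling is the
  WinBUGS-style per-sweep recentring, not a hard constraint built into the
  proposal; with multiple graph components the field is centred over all
  connected nodes jointly.
* BYM's $u$/$v$ split is only weakly identified (their sum is what the data
  see); interpret $\sigma_u$ and $\sigma_v$ posteriors with care. The
  department totals $u_d + v_d$, the rates, and all derived prevalences are
  well identified.
* The three-source estimator assumes shares are transportable across
  departments (the homogeneity assumption of the original design); the
  sensitivity machinery quantifies the effect of swapping whole share sets
  but cannot detect department-specific violations.
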