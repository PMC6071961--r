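---
title: "Exact and asymptotic significance indices for small-sample contingency tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact and asymptotic significance indices for small-sample contingency tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabexact)
```

## The problem

Hypothesis tests in contingency tables are routinely carried out with
asymptotic chi-square reference distributions, yet much applied work —
clinical pilot studies, genotype counts for a rare locus, stratified case
series — produces tables whose margins are in the tens.  `tabexact`
computes, for one observed table, the whole family of significance indices
a practitioner might compare in that regime:

* the **exact LRT p-value**, an enumeration-based benchmark index;
* the **asymptotic LRT** and **Pearson chi-square** p-values;
* **Fisher's conditional exact test** (2 x 2 homogeneity);
* **Barnard's unconditional exact test** (2 x 2 homogeneity and
  Hardy-Weinberg);
* the **Full Bayesian Significance Test (FBST) e-value**, Monte Carlo and
  asymptotic.

Three null hypotheses are supported.  Under *homogeneity* the rows
$X_i \sim \mathrm{Multinomial}(n_{i\cdot}, \theta_{i1},\dots,\theta_{ic})$
are independent with fixed, known row totals, and the null states that all
rows share one column-probability vector.  Under *independence* the whole
table is a single multinomial of size $n_{\cdot\cdot}$ and the null factorises each
cell probability as $\theta_{ij} = \theta_{i\cdot}\theta_{\cdot j}$.  Under
*Hardy-Weinberg equilibrium (HWE)* the genotype counts $(x_1, x_2, x_3)$
of AA, Aa, aa follow a trinomial whose null manifold is
$(\theta^2,\, 2\theta(1-\theta),\, (1-\theta)^2)$ for an allele frequency
$\theta$.

## The exact LRT p-value

The LRT statistic is
$\lambda(x) = \sup_{\Theta_H} L / \sup_{\Theta} L \in (0, 1]$, with the
familiar closed forms (pooled column proportions for homogeneity, product
of marginal proportions for independence, the plug-in
$\hat\theta = (2x_1+x_2)/(2n)$ for HWE).  An exact p-value needs the
distribution of tables under the null, which depends on the nuisance
parameter.  The package eliminates it by *integration*: the null
likelihood is integrated against the uniform (flat) measure on the
relevant simplex, giving an unnormalised weight per table, e.g. for 2 x 2
homogeneity

$$
h(x_{11}, x_{21})
 = \binom{n_{1\cdot}}{x_{11}}\binom{n_{2\cdot}}{x_{21}}
   \binom{n_{1\cdot}+n_{2\cdot}}{x_{11}+x_{21}}^{-1}
   \frac{1}{n_{1\cdot}+n_{2\cdot}+1},
$$

and analogous log-gamma closed forms for $\ell \times c$ homogeneity,
independence and HWE.  Normalising the weights over the *complete
enumerated sample space* (fixed row margins, fixed grand total, or fixed
$n$ respectively) yields a genuine null distribution of tables, and

$$
p = \Pr\big(\lambda(X) \le \lambda(x_{\mathrm{obs}}) \mid H\big)
$$

is summed over the enumeration.  For 2 x 2 homogeneity the weights sum to
exactly 1 before normalisation; in general the sum is a fixed positive
constant ($1/(c-1)!$ for homogeneity, $1/((\ell-1)!(c-1)!)$ for
independence, 1 for HWE under this construction) which cancels, so every
p-value is invariant to rescaling of $h$ — a property the test suite
checks explicitly.

```{r}
tt <- ct_test(matrix(c(3, 7, 8, 2), 2, byrow = TRUE), "homogeneity", seed = 1)
tt
```

### Numerical choices

* All factorial ratios go through `lgamma`; sums of weights through
  log-sum-exp.  The benchmark scenario sizes ($n = 100$ margins) overflow
  double-precision factorials, so nothing is ever exponentiated before it
  has been normalised.
* $0\log 0 = 0$ and $0^0 = 1$ throughout, matching the limit of the
  likelihood.
* **Tie handling.**  The region $\{\lambda \le \lambda_{\mathrm{obs}}\}$
  uses a weak inequality with an absolute tolerance of $10^{-9}$ on the
  log scale: symmetric tables carry mathematically tied statistics whose
  floating-point images may differ in the last few ulps, and the tolerance
  keeps them inside the region on either side of the symmetry.
* **Enumeration order** is lexicographic in the row-major flattened count
  vector (row 1 most significant).  p-values do not depend on the order;
  fixing it makes scans and streams reproducible byte for byte.
* **Streaming.**  Exact p-values are accumulated in two passes over
  chunked enumerations (`space_apply()`), so the normalising constant and
  the region mass never require the space in memory.  The largest bundled
  scenario (3 x 3 independence at $n = 25$, about $1.39\times 10^7$
  tables) is reachable this way for a single observed table; the
  materialised whole-space scan refuses it by a memory guard.
* **Degenerate tables.**  Enumeration admits zero margins and $n = 0$
  (flagged on construction), but the index functions treat them as domain
  errors: the homogeneity model fixes the row totals as known positive
  sample sizes, so a zero row margin means an unobserved population, not
  $\lambda = 1$.

## The competing indices

*Asymptotic LRT*: $-2\log\lambda$ against the chi-square with
$\dim\Theta - \dim\Theta_H$ degrees of freedom ($(\ell-1)(c-1)$ for the
table hypotheses, 1 for HWE).  *Pearson*: the plain $X^2$ statistic, no
continuity correction anywhere (the comparison targets the uncorrected
test), same df; HWE uses the plug-in expected counts
$n(\hat\theta^2, 2\hat\theta(1-\hat\theta), (1-\hat\theta)^2)$ with df 1.
*Fisher*: conditional on both margins, two-sided by the
minimum-likelihood rule — the convention of `stats::fisher.test`, which is
the implementation; the suite carries an independent hypergeometric
summation oracle.  The sidedness rule is a dialect choice: the
minimum-likelihood convention is what standard software reports.

*Barnard*: the same $\lambda$-defined critical region as the exact
p-value, with the nuisance parameter eliminated by maximisation,
$p = \sup_{\theta\in[0,1]} \Pr(R \mid \theta)$ under the product-binomial
(homogeneity) or trinomial (HWE) null.  The profile is a polynomial in
$\theta$; the supremum is located on a 1001-point uniform grid (endpoints
evaluated as $0^0 = 1$ limits) followed by Brent refinement to $10^{-10}$
in the bracketing interval — deterministic, and verified against
million-point brute-force grids in the tests.  Consistent with the
binomial model, the null probability of a table uses the *pooled success
count* $x_{11} + x_{21}$ as the exponent of $\theta$.

*FBST*: with uniform (all-ones Dirichlet) priors — fixed, not
configurable, so the Bayesian index adds no information beyond the data —
the posterior is a product of independent Dirichlet$(x_i + 1)$
distributions.  The e-value is one minus the posterior probability of the
tangent set $T(x) = \{\theta : \pi(\theta\mid x) \ge \sup_{\Theta_H}
\pi(\theta\mid x)\}$.  The null supremum has a closed form (posterior
constants times the null kernel at the null MLE), checked against dense
grids over $\Theta_H$; the tangent-set probability is estimated by Monte
Carlo with a mandatory explicit seed, default $k = 10^5$ (binomial
standard error at most $0.5/\sqrt{k} \approx 0.0016$), and the indicator
comparison carries a $10^{-12}$ log-scale slack so the measure-zero
boundary cannot flip by rounding.  The asymptotic e-value uses the same
statistic with the *full* dimension $\dim\Theta$ as df, hence always
dominates the asymptotic p-value.

## Scans and power surfaces

`index_scan()` evaluates the indices for *every* table of a space (this is
not simulation — the whole sample space is visited), with the null
distribution built once and the exact p-values obtained from a single
shared sort.  `scan_scenarios()` catalogues ten benchmark settings
(homogeneity 2 x 2 at margins (30,30) and (100,100), 2 x 3 and 3 x 3;
independence 2 x 2, 2 x 3, 3 x 3; HWE at $n = 30$ and $n = 100$).

`power_surface()` maps $\mathrm{Power}(\theta_1, \theta_2) =
\Pr(\text{index} \le \alpha)$ for the frequentist indices over a parameter
grid, with the decision rule fixed at $\mathrm{index} \le 0.05$ by
default.  Ties at exactly $\alpha$ occur with positive probability for
discrete indices, so the weak inequality is fixed and documented rather
than left to chance.  Two evaluation modes share one per-space cache of
index values:

* `method = "exact"` sums the sampling probabilities of the rejecting
  tables — deterministic, and the oracle for
* `method = "mc"`, which draws `reps` tables per grid point
  (product-binomial or trinomial), with one sub-seed per grid point
  derived from the master seed so any execution order reproduces the
  surface.

The default grid places $G$ midpoints per axis, $\theta = (2i-1)/(2G)$:
equally spaced, symmetric, and strictly interior so no degenerate binomial
arises at $\theta \in \{0, 1\}$ (for HWE the grid is restricted to the
open simplex $\theta_1 + \theta_2 < 1$).

### What the Monte Carlo checks can and cannot show

A simultaneous comparison of MC and exact power across hundreds of grid
points multiplies small per-point tail probabilities into a sizeable
family-wise failure rate: at 500 replicates the per-point binomial
3-sigma event has probability up to ~1%, so over a 20 x 20 grid and five
indices a handful of exceedances is the *expected* behaviour of a correct
implementation.  Where the package's tests make per-point comparisons
they therefore use the conservative binomial bound $0.5/\sqrt{\mathrm{reps}}$
as the standard error; even so, a single-ulp-style guarantee at every
point is not attainable by any finite simulation, and isolated ~3-sigma
exceedances at interior-power points should be read as sampling noise,
not disagreement.  The definitive statement of MC/exact consistency is
the enumeration-exact surface itself.

## Simulated data versus real data

The generators used in tests and power studies draw from the exact model
classes under study (independent binomial rows, one multinomial, one
trinomial).  Real tables bring features these generators deliberately
omit — clustered sampling, misclassification, margins chosen after
peeking at the data — so passing tests certify the indices' mathematical
behaviour under the stated models, not robustness to violations of them.

## Design notes and limitations

* The independence weight is implemented as the uniform-prior integrated
  likelihood of the independence null (row-margin and column-margin
  Dirichlet integrals).  Under this construction the unnormalised weights
  over a sample space sum to $1/((\ell-1)!(c-1)!)$ — exactly 1 for the
  2 x 2 space at $n = 2$ — and, like every other constant, the sum cancels
  from all p-values.
* Problem sizes in the test suite are chosen to keep the full run in
  minutes: the brute-force Barnard oracle runs at $10^6$ grid points for
  selected tables (margins (8,8), HWE $n = 10$) and at $10^5$ points for
  all tables at margins (4,4); the streaming/oracle p-value sweep covers
  homogeneity margins through (6,6), independence totals through 6, and
  HWE through $n = 12$.
* Fisher's test is not extended beyond 2 x 2, Barnard's not beyond 2 x 2
  homogeneity and HWE, and no mid-p or continuity-corrected variants are
  offered: the package compares the plain indices.
* No decision rule is attached to the FBST e-value; it is reported as an
  evidence measure only, and no power surface is defined for it.
* Informative priors are out of scope; the uniform prior is part of the
  index's definition here.
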