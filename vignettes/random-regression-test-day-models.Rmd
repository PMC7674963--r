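---
title: "Random regression test-day models for milk yield: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random regression test-day models for milk yield: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkRRM)
```

## The model

A test-day record is one daily milk weight of one cow at one milk-recording
visit. `milkRRM` fits the single-trait, first-lactation random regression
test-day model

$$
y_{itklm} = HYS_l + AGE_m + DIM_t
          + \sum_{k=0}^{n_r} z_{tk}\, a_{ik}
          + \sum_{k=0}^{n_p} z_{tk}\, pe_{ik} + e_{itklm},
$$

where $y_{itklm}$ is the yield of cow $i$ at days in milk (DIM) $t$;
$HYS_l$ is the herd–year–season contemporary group (calving year and
calving season: Mar–May and Sep–Oct, Jun–Aug, Nov–Feb); $AGE_m$ one of four
calving-age classes (20–23, 24–27, 28–31, $\ge$32 months); $DIM_t$ a fixed
effect with one level per day 5..305 (301 levels); $a_{ik}$ and $pe_{ik}$
the additive-genetic and permanent-environment random regression
coefficients of cow $i$; and $z_{tk}$ the $k$-th normalized Legendre
polynomial evaluated at the standardized DIM
$x = 2(t - 5)/(305 - 5) - 1$. The polynomials are
$LP_k(x) = \sqrt{(2k+1)/2}\,P_k(x)$, orthonormal on $[-1, 1]$; orders
$n_r = n_p \in \{1,\dots,5\}$ are supported directly from their monomial
forms, higher orders through the Bonnet recurrence.

Across animals, $\mathrm{var}(\mathbf a) = \mathbf A \otimes \mathbf G$ with
$\mathbf A$ the pedigree numerator relationship matrix, and
$\mathrm{var}(\mathbf{pe}) = \mathbf I \otimes \mathbf P$. Residuals are
independent with variance either constant ("homogeneous") or specific to
ten DIM classes (5–34, 35–64, ..., 275–305; "heterogeneous"), handled by
weighting records with $w_i = \bar v / v_i$.

Derived quantities follow directly from the covariance functions:
$\sigma^2_g(t) = z_t' \mathbf G z_t$, $\sigma^2_{pe}(t) = z_t' \mathbf P z_t$,
$h^2(t)$ and repeatability as the corresponding variance ratios, daily
breeding values $z_t'\hat a_i$ and the 305-day breeding value
$\sum_{t=5}^{305} z_t'\hat a_i = u'\hat a_i$ with $u = \sum_t z_t$.

## Editing rules and fixed-effect coding

Records are kept when calving age lies in [20, 38] months, daily yield in
[5, 80] kg and DIM in [5, 305] (all bounds inclusive), and when the cow
retains at least three records *after* those scalar edits; the per-cow
count rule is applied last so that it is a property of the retained data.
Calving year, not test year, defines the year in herd–year–season, because
the seasons are calving seasons. The herd–year–season coding is a dense
re-indexing of the observed combinations.

## REML estimation

Variance components are estimated by restricted maximum likelihood on
Henderson's mixed-model equations scaled by $\mathbf R^{-1}$, so that the
inverse coefficient matrix is the prediction-error covariance of the
solutions. One iteration consists of:

1. a sparse simplicial Cholesky factorization of the coefficient matrix
   (Matrix/CHOLMOD) and solution of the equations;
2. the *selected inverse* of the coefficient matrix on the pattern of the
   factor, computed by the Takahashi recurrences in a compiled kernel;
   this yields every entry of $\mathbf C^{-1}$ at the structural nonzeros
   of $\mathbf C$, which is exactly what the exact first derivatives of
   the restricted likelihood require (the trace terms
   $\sum_{ij} (\mathbf A^{-1})_{ij}\, \mathbf C^{aa}_{ij}$ and
   $\mathrm{tr}(\boldsymbol\Omega \mathbf W \mathbf C^{-1}\mathbf W')$);
3. an update of $(\mathbf G, \mathbf P, v)$: plain EM for a short burn-in
   (3 iterations), then average-information (AI) steps, where the AI
   matrix costs one extra mixed-model solve per variance parameter.

AI steps are safeguarded: a proposed step is accepted only if it does not
decrease the restricted likelihood; otherwise Levenberg-style damping
($\lambda$ escalating from 0.1 to 1000 on the AI diagonal) bends the step
toward scaled gradient ascent, and as a last resort the iteration falls
back to the EM update, which can never decrease the likelihood. The path
is therefore monotone. $\mathbf G$ and $\mathbf P$ are kept positive
definite by eigenvalue flooring at $10^{-8}$ times their trace.
Convergence is declared when
$\max_i |\Delta\theta_i| / (|\theta_i| + 1) < 10^{-6}$ (configurable);
on well-posed data of the default scale the AI phase converges
quadratically in 10–20 iterations. On very small or weakly identified
data sets the optimum can lie on the positive-definiteness boundary, in
which case the damped steps reduce to a slow but monotone crawl along the
floor; the `history` slot of the fit records the full path.

The restricted likelihood itself is evaluated through the factorization,
$-2\log L = (n - r_X)\log 2\pi + \log|\mathbf C| + \log|\mathbf R| +
\log|\mathbf A \otimes \mathbf G| + \log|\mathbf I \otimes \mathbf P| +
y'\mathbf P y$, with $\log|\mathbf A| = \sum_i \log d_i$ available for free
from the Mendelian-sampling variances of the pedigree. All gradients are
unit-tested against central finite differences, and likelihood and BLUP
solutions against dense generalized-least-squares oracles on small
instances.

### Identifiability of the fixed effects

With full indicator sets for herd–year–season, age and DIM the fixed part
is rank-deficient (by at least two). Columns are processed in the order
HYS, AGE, DIM through a greedy incremental Cholesky of $X'X$; a column
whose pivot falls below $10^{-9}$ times the largest diagonal is constrained
to zero and removed. For connected data this reproduces the conventional
choice of constraining the last age class and the last observed DIM level,
and it degrades gracefully when small data sets carry additional
confounding. Estimable contrasts, variance components and breeding values
are unaffected by the choice of constraint; constrained levels are reported
with their fits.

### Heterogeneous residual variance

The ten class variances are not free parameters of the inner REML;
following the weighting scheme, the fit alternates (i) weighted REML with
the current weights, (ii) re-estimation of the class variances, and
(iii) recomputation of $w_i = \bar v / v_i$, until the class variances
change by less than 1% (at most `hetPasses` rounds; one round reproduces a
single-pass variant). The class variances are estimated by the
leverage-exact moment update
$$
v_i = \frac{\sum_{j \in i} \hat e_j^2 + \sum_{j \in i} h_j}{n_i},
\qquad h_j = x_j' \mathbf C^{-1} x_j,
$$
using per-record leverages from the selected inverse, since
$E[\hat e_j^2] = v_j - h_j$. A proportional split of the model degrees of
freedom over classes ($d_i = (n_i/n)\,\mathrm{edf}$) was considered and
rejected: model leverage varies strongly along the lactation — the edge
DIM classes are fitted much more closely than mid-lactation ones because
DIM levels there are thinner and the regression bases are most flexible at
the boundary — and ignoring this creates a positive feedback between
weights and apparent class variances that makes the outer iteration
diverge. The leverage-exact update is unbiased at its fixed point and was
stable in all our simulations. For model scores, the heterogeneous
residual counts ten estimated parameters (`includeFixed = FALSE` counts
covariance parameters only, matching the convention that model-comparison
tables list covariance counts; a flag adds the fixed-effect rank).

### Model comparison and validation

$AIC = -2\log L + 2p$ and $BIC = -2\log L + p\log n$ with natural
logarithms and $n$ = records minus the rank of the fixed-effect design.
Predictive ability is assessed by refitting on data without the phenotypes
of cows calving in the last calendar year (a cow-level rule) and
correlating (Pearson, Spearman) the 305-day breeding values of those
validation cows between the two fits; an option correlates over all
recorded cows instead.

The 305-day heritability and repeatability use the variance-of-the-sum
definition: genetic variance $u'\mathbf G u$, permanent-environment
variance $u'\mathbf P u$, residual variance $\sum_t \sigma^2_e(t)$ with
daily residuals independent. Because residuals average out over 301 days,
this definition drives the 305-day repeatability toward 1 and yields a
305-day heritability close to $u'\mathbf G u / (u'\mathbf G u + u'\mathbf P u)$
rather than to mid-lactation daily values; alternative summaries (e.g.
averages of daily ratios) would give smaller values. We state the
definition explicitly precisely because published tables rarely do.

## The synthetic herd generator

Real test-day archives are proprietary, so the package carries a generator
whose output has *exactly* the covariance structure the model assumes, so
that every stage — editing, classing, relationship matrices, REML, scores,
validation — is testable end to end, including parameter recovery against
known truth.

* **Pedigree.** Discrete generations, random mating, no selection.
  Defaults: 100 artificial-insemination sires and 1,000 founder dams; two
  recorded cohorts of 1,000 cows each, the second cohort out of the first
  (so half the cows have recorded dams), for 2,000 recorded cows and about
  3,300 pedigree animals. This mirrors the structure of a regional
  dairy-herd-improvement population — moderately large paternal half-sib
  families plus recorded dam–daughter pairs — and both features carry most
  of the information separating genetic from permanent-environment
  variance. A single-cohort design with unique dams, and a deeper
  three-cohort design, were examined at design time and give visibly
  poorer or no better separation (the three-cohort layout confounds cohort
  with herd-year blocks over a five-year window).
* **Genetic coefficients** descend the sorted pedigree by the
  Mendelian-sampling recursion: founders $\sim N(0, \mathbf G)$, offspring
  = parent average + $N(0, d_i \mathbf G)$ with
  $d_i = 0.5 - 0.25(F_s + F_d)$, which reproduces
  $\mathbf A \otimes \mathbf G$ exactly (verified by Monte Carlo in the
  tests).
* **Records.** Cows calve in 10 herds over 2010–2014 (cohort 1 in the
  early years, cohort 2 in the late years), in months drawn from a
  configurable seasonal distribution; ages 21–36 months. Tests start at a
  uniform DIM in 5–35 and recur every $30 \pm 3$ days, each visit missed
  with probability 0.1, giving roughly 8 tests per cow and about 17,000
  records before editing. Yields are mean curve (Wilmink-type,
  $27.8 - 8e^{-0.05t} - 0.02t$, peaking near 26 kg) + herd–year–season
  effects (SD 2 kg) + age-class effects + $z'a$ + $z'pe$ + class-specific
  residual noise; yields outside [5, 80] kg are dropped (truncation, like
  real editing), which loses well under 1% of records.
* **True components.** Diagonal-dominant $\mathbf G$ and $\mathbf P$ with
  a negative intercept–slope genetic covariance
  ($\mathrm{diag}(\mathbf G) = 18, 4, 2.5, 1.5, 1.0, 0.7$ kg²;
  $\mathrm{diag}(\mathbf P) = 36, 8, 5, 3, 2, 1.5$ kg², truncated to the
  chosen order), giving daily $h^2 \approx 0.24$–0.28 and repeatability
  $\approx 0.7$, inside the ranges published for first-lactation Holstein
  test-day milk. The default residual follows the published ten-class
  pattern for an order-3 fit (elevated in early lactation, mean
  $\approx 12.2$ kg²), shipped in `inst/extdata` and exposed by
  `referenceResidualVariances()`.

What the generator does **not** emulate: selection and culling, seasonal
reproduction biology, multiple lactations, lactation-curve shapes outside
the Legendre family, and residual autocorrelation within cow beyond the
permanent-environment term. Passing recovery tests therefore demonstrate
that the estimation machinery is correct and well calibrated under the
model's own assumptions — not that the model is adequate for any
particular real population.

## Problem sizes, runtimes and statistical power of the checks

The test suite exercises the full default scale (2,000 cows, ~17,000
records, coefficient matrix of ~16,000 equations; one REML fit converges
in 10–20 AI iterations, tens of seconds on one core). Property suites use
smaller instances: dense-oracle equivalence on herds of 4–6 cows,
order-comparison and validation patterns on herds of 250 cows, chosen so
the whole suite completes in well under half an hour on a single core.

Two calibration facts, measured during design, matter for interpreting
the recovery checks:

* With 2,000 cows the sampling standard errors of the *small*
  higher-order variance components are a substantial fraction of their
  values, while the intercept variances are estimated much more
  precisely. Requiring every diagonal element of $\mathbf G$ and
  $\mathbf P$ to fall within 20% of truth simultaneously therefore
  succeeds only in a minority of replicates at this scale — not because
  the estimator is biased, but because for the smallest components that
  bound is on the order of one sampling standard deviation. The
  corresponding acceptance check reports its success fraction faithfully
  rather than enlarging the data or the tolerance.
* The predictive advantage of the true order (3) over a severe underfit
  (order 1), measured as full/reduced-data correlations of 305-day
  breeding values over one validation cohort, is small by construction:
  the 305-day value is dominated by the intercept coefficient
  ($u \approx (212.8, 0, 1.6, 0)$), which even the underfit model
  carries, and at small herd sizes the higher-order fit can itself land
  on a degenerate (boundary) REML solution. At a few hundred validation
  animals the difference is inside its own sampling noise in a sizable
  fraction of replicates; the acceptance check reports the observed win
  rate.

## Numerical choices

* Convergence: $10^{-6}$ relative parameter change, at most 200
  iterations; the heterogeneous outer loop stops at 1% relative change of
  the class variances.
* Positive definiteness by eigenvalue flooring (simple, logged in the
  iteration history through the step labels) rather than
  re-parameterization.
* Ties/degeneracies: empty residual classes and classes with no surviving
  records raise errors; confounded fixed-effect columns are constrained,
  not silently dropped from reports.
* The dense tabular relationship matrix is an oracle with a size guard;
  the production path is the sparse inverse with inbreeding
  (Meuwissen–Luo), `computeF = FALSE` reproducing the classic rules.
* All stochastic behaviour (simulation, subsampling in tests) is
  seed-controlled; REML itself is deterministic given data and starting
  values.

## Limitations

Single trait, first lactation, one lactation per cow; no genomic
relationships; no unknown-parent groups; equal Legendre orders for the
genetic and permanent-environment regressions are the tested path
(different orders are accepted by the data structures); standard errors of
variance components are not reported (the AI matrix at convergence could
provide them, but sampling-based uncertainty was out of scope).
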