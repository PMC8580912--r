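---
title: "Expected selection gain for two-trait index selection in hybrid breeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected selection gain for two-trait index selection in hybrid breeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indexgain)
```

## The problem

A hybrid breeding program wants to improve two traits at once — say grain
yield and a quality trait that is negatively correlated with it — under a
fixed annual budget. The program produces `n_ini` doubled-haploid (DH)
lines, discards 75% of them in an observation nursery (on highly heritable
traits uncorrelated with the breeding goal), and then selects in one or two
further stages until five lines remain. Two strategies are compared:

* **PSstandard** — two stages of phenotypic testcross evaluation at
  `L_j` locations with `T_j` testers (one replication per location);
* **GSrapid** — genomic selection on GEBVs of both traits, followed by a
  single phenotypic stage. Skipping one field stage shortens the cycle.

Everything here is a deterministic *model calculation*: given variance
components, economic weights, prediction accuracies, costs and a budget, the
package computes the **expected** selection gain and searches for the
allocation `[n_ini, N_j, L_j, T_j]` that maximizes the **annual** gain for
net merit (gain per cycle divided by cycle length). No phenotypic or marker
data are involved.

## The model

### Targets and criteria

The selection target of trait $k$ is its general combining ability (GCA)
$g_k$; net merit is $H = \sum_k a_k g_k$ with economic weights $a$. Each
post-nursery stage truncates candidates on a linear criterion
$I = \sum_j b_j x_j$ of that stage's observations $x$ (testcross means or
GEBVs). The gain of any target $y$ after multistage selection is
$\sigma_y \, E[\tilde y \mid \text{selected}]$, where the standardized
truncated mean is computed from the joint normal distribution of the stage
criteria and the target.

The testcross mean of a candidate evaluated at $L$ locations with $T$
testers (one replication) has entry-mean variance
$$P_{kk} = \sigma^2_{GCA} + \sigma^2_{GCA\times L}/L + \sigma^2_{SCA}/T +
  \sigma^2_{SCA\times L}/(LT) + \sigma^2_{e}/(LT),$$
so locations dilute GCA-by-location interaction, testers dilute specific
combining ability, and their product dilutes the residual. Between traits,
only the genetic covariance is kept by default: covariances of SCA,
interaction, and error effects are rarely estimated in practice and are
exposed as optional fields (their effect on results is small, which we
verified by sweeping them).

### Index weights

* **Smith–Hazel**: $b = P^{-1} C a$, with $P$ the criterion covariance
  matrix and $C_{kj} = \mathrm{cov}(x_k, g_j)$. This is the optimum index
  when the parameters are known without error.
* **Base**: $b = a$ — robust, ignores all covariances.
* **Restricted** (Kempthorne–Nordskog): maximizes
  $\mathrm{cov}(I, H)/\sigma_I$ subject to
  $\mathrm{cov}(I, g_2) = 0$, solved by a Lagrange multiplier. Trait 2 is
  then expected to stay exactly constant.
* **Independent culling levels (ICL)**: no index at all — each stage
  applies a separate threshold to each trait and a candidate must pass
  both.

### GEBV model

A genomic stage selects on GEBVs $u_k$ whose accuracy is
$\mathrm{corr}(u_k, g_k) = r_k$. Deterministic calculations need the full
second-moment structure of $(u_1, u_2, g_1, g_2)$, and more than one
convention exists for the GEBV–GEBV covariance. We use
$$\mathrm{Var}(u) = \mathrm{diag}(r)\, G \,\mathrm{diag}(r), \qquad
  \mathrm{cov}(u_k, g_j) = r_k^2\, G_{kj},$$
i.e. the GEBVs of the two traits **preserve the genetic correlation**
($\mathrm{corr}(u_1,u_2) = \rho_G$), as they do when both models are
trained on the same data. A convenient consequence: with equal accuracies
the net-merit accuracy of a GEBV index is exactly $r$, independent of
$\rho_G$. We also examined the projection alternative
$\mathrm{corr}(u_1,u_2) = r_1 r_2 \rho_G$; it makes the GS-stage net-merit
accuracy *increase* with the trait correlation
($r\sqrt{(1+\rho)/(1+r^2\rho)}$ for standardized symmetric parameters),
which inverts the published ordering of the GSrapid advantage between
negatively and positively correlated traits, so it was rejected.

### Truncation machinery

Per-stage selected fractions follow from the candidate counts
($\alpha_j = N_{j+1}/N_j$, final stage $5/N_S$). Truncation points are
solved sequentially so the joint survivor probability after stage $j$
equals $\prod_{i\le j}\alpha_i$; a fraction of 1 is the analytic sentinel
$q = -\infty$. The truncated mean of a target with correlations $\rho_j$
to the $d$ criteria is Tallis' first moment,
$$E = \frac{1}{\alpha}\sum_j \rho_j\, \varphi(q_j)\,
  \bar\Phi_{d-1}\!\big(\tilde q^{(j)}; R^{(j)}\big),$$
with conditional limits and partial correlations given $Z_j = q_j$. For
$d=1$ this is the classical $\rho\,\varphi(q)/\alpha$; for $d=2$ it is the
familiar two-ordinate formula. Criteria of different stages share only
GCA-level covariances, because every stage uses fresh locations and
testers.

Survivor probabilities use a deterministic integrator throughout (closed
forms for $d \le 2$; the Miwa algorithm for $d \le 4$), so results are
bit-reproducible. The bivariate CDF is our own vectorised Gauss–Legendre
evaluation of the single-integral representation (24 nodes, $|r|<0.925$;
deterministic TVPACK fallback above; analytic at $|r|\to 1$) because the
grid search needs it at hundreds of thousands of points per optimization.
A Monte-Carlo oracle (`mc_oracle()`) exists solely to validate the Tallis
implementation in the test suite.

### ICL thresholds

When the two per-trait criteria of a stage are correlated, nominal marginal
culling fractions $(\alpha_1, \alpha_2)$ with $\alpha_1\alpha_2 = \alpha_j$
do not automatically retain the fraction $\alpha_j$. We adjust both
thresholds jointly as $\alpha_k^{c}$ (one exponent per stage, preserving
the *relative* culling pressure $\log\alpha_1 / \log\alpha_2$) so the
realized joint survivor probability matches the stage fraction exactly.
`icl_search_fractions()` scans about 1000 split combinations
($\alpha_1 = \alpha_j^w$, $w$ on a uniform grid per stage) and keeps the
one maximizing net merit, mirroring how ICL is benchmarked against index
selection at the Smith–Hazel optimal allocation. This evaluation is the
exact expectation of the joint culling process (validated against Monte
Carlo); cruder textbook evaluations that treat the cullings as independent
give markedly lower ICL gains for correlated traits.

## Costs and optimization

The budget unit is one field-plot equivalent (default budget 10,000 per
cycle). Costs: DH production 1 per line (including its nursery
evaluation — charging the nursery separately makes the published optimum
allocations infeasible, so the default `cost_nursery_plot` is 0 and the
field is available for programs that do account it separately), genotyping
2 per line entering a genomic stage, hybrid seed 4 per candidate-by-tester
combination covering two phenotyping years (a second phenotypic stage pays
only for testers added beyond the first), and one plot per
candidate-location-tester.

`optimize_allocation()` searches candidate grids over stage-2 size,
locations and testers; for every grid point the number of initial DH lines
is set to the largest count the remaining budget affords (gain is monotone
in `n_ini`, so this is exact), and a step-1 refinement pass surrounds the
coarse incumbent. Default grids cover $L \le 20$, $T \le 10$ and stage
sizes up to the budget-feasible maximum; a full optimization takes seconds
(about 2.5 &times; 10^4 allocations for GSrapid, 2.7 &times; 10^5 for
PSstandard) because the two-criterion gain kernel is fully vectorised.
Ties are broken toward smaller `n_ini`, then fewer locations.

## Cycle lengths

Comparisons *between* strategies are annualized. The stage-to-year mapping
is configuration: the defaults are **7 years for PSstandard and 5 for
GSrapid** (crossing, two years of DH production, nursery, then hybrid-seed
production and one or two field seasons; genomic selection replaces a
field stage and its seed year). Within-strategy comparisons — between
indices, or between goals — are unaffected, since the cycle length
cancels. Both lengths can be overridden in `ps_standard()` / `gs_rapid()`.

## Worked example

```{r, eval = FALSE}
goal1 <- scenario_wheat(1)   # grain yield + protein content, rho = -0.40
opt <- optimize_allocation(gs_rapid(c(0.3, 0.3)), goal1$pair, goal1$weights, "sh")
opt
#> Optimum allocation — GSrapid, sh index
#>   n_ini = 2890, stage counts = 722/118, L = NA/12, T = NA/3
#>   cost = 9998 plot equivalents; 23025 grid points evaluated
#> Expected selection gain (sh index)
#>   per cycle : net 5.3071 | trait1 5.3436 | trait2 -0.3039
#>   per year  : net 1.0614 | trait1 1.0687 | trait2 -0.0608 (5-year cycle)
```

The Smith–Hazel index improves yield by about 1.07 dt/ha per year while
protein drifts down by 0.06 percentage points per year — the price of the
negative correlation under a small quality weight. A restricted index
holds protein exactly constant at the cost of net merit
(`index_kind = "restricted"`).

## Numerical choices, degenerate inputs, limitations

* Truncation-point root solves use `uniroot` to 1e-12 (the vectorised
  kernel a safeguarded Newton iteration to ~1e-13); the realized joint
  survivor probability is asserted to 1e-6.
* Criterion correlation matrices are validated (symmetry, PSD to -1e-8)
  and rejected with the offending eigenvalue otherwise; perfectly
  correlated criteria are handled analytically, not numerically.
* Zero genetic variance of a restricted trait, non-invertible criterion
  covariance, fractions outside (0, 1], and increasing candidate counts
  are all rejected with informative errors.
* The model is single-cycle: no erosion of genetic variance across cycles
  (Bulmer effect), no estimation error in the variance components, no GS
  model training or marker data. Expected — not realized — gains are
  reported; stochastic simulation is out of scope.
* Gains assume multivariate normality of criteria and targets, adequate
  for the infinitesimal quantitative-genetic setting the calculation
  addresses; strongly non-normal traits would need transformation.
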