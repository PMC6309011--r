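---
title: "Methods: group formation under resource variance and competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group formation under resource variance and competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupskew)
```

## The model

`groupskew` studies a population of foragers that may live solitarily or in
groups of size $N$, under two resource-sharing rules. *Egalitarian* groups
pool all harvests and split them equally, for both survival and
reproduction. *Eusocial* groups (maximal reproductive skew) also share
equally for survival, but channel every surplus unit to a single
reproductive dominant. At $N = 1$ the two rules coincide in the solitary
strategy.

### Stochastic foraging

Individual harvest over one reproductive period is modelled as a Gamma
random variable with mean $\bar{x}$ and scale $\theta$, the mean resource
item size, so that $\sigma^2 = \bar{x}\theta$ and
$\mathrm{CV} = \sqrt{\theta/\bar{x}}$. The scale has a concrete foraging
interpretation: when $\kappa = \bar{x}/\theta$ is an integer, the harvest
is the sum of $\kappa$ exponential item sizes of mean $\theta$ — fewer,
larger items mean a chancier season. The package treats $\kappa$ as a real
number throughout; no rounding is applied. Pooling $N$ harvests and
dividing by $N$ yields a per-capita share that is again Gamma, with shape
$N\bar{x}/\theta$ and scale $\theta/N$: the mean is unchanged and the
variance falls exactly as $1/N$ (`resource_dist()`, `pooled_share_cdf()`).

### Demography

Survival uses a step mortality: a member whose share falls below the
threshold $o_M$ starves with certainty; others die with the
resource-independent baseline probability $M_b$. Receiving exactly $o_M$
counts as survival. The expected per-capita mortality is therefore
$\mu = C + (1 - C)M_b$ with $C$ the probability mass of the pooled share
below $o_M$ — a closed form in the regularized incomplete gamma function
(`mean_mortality()`).

Reproduction converts the surplus $x_r = \max(0, x - o_M)$ into expected
offspring through the sigmoid fertility
$$F(x_r) = F_{\max}\left(1 - e^{-x_r/(c_0 F_{\max})}\right)^2,$$
zero at zero, saturating at $F_{\max}$, with initial steepness governed by
$1/c_0$ (so $c_0$ acts as an offspring cost). $F$ is convex below its
inflection point $c_0 F_{\max} \ln 2$ and concave above. This convex
region is the engine of the whole analysis: by Jensen's inequality,
variance in reproductive resources *raises* expected fertility when
resources are scarce, which is exactly what eusocial surplus-pooling
exploits, while variance in survival resources only raises starvation
risk, which egalitarian sharing dampens.

Per-capita natality is the expectation of $F$ over the pooled share law:
$\phi_{\mathrm{egal}} = E[F(x_r)]$ and
$\phi_{\mathrm{eusoc}} = E[F(N x_r)]/N$ — the dominant is evaluated at $N$
times the surplus and the result divided by $N$ (`natality()`). Lifetime
reproductive success is $\Psi = \phi/\mu$
(`lifetime_reproductive_success()`).

### Equilibrium, carrying capacity and optimal group size

Resource limitation couples the population to its food supply: a growing
population depresses the mean harvest $\bar{x}$ until natality balances
mortality, $\phi(N, \bar{x}_N, \theta) = \mu(N, \bar{x}_N, \theta)$. The
solution $\bar{x}_N$ is the strategy's minimal per-capita resource
requirement; carrying capacity follows as $K = X/\bar{x}_N$ for total
supply $X$, and the package reports capacities relative to the solitary
strategy so that $X$ drops out (`equilibrium_requirement()`,
`carrying_capacity()`). The optimal group size $N_{\mathrm{opt}}$
minimizes $\bar{x}_N$ — equivalently maximizes $K$ — over an exhaustive
integer scan (`optimal_group_size()`, `theta_sweep()`). A relative
capacity above one at $N_{\mathrm{opt}} > 1$ is supersaturation: the group
strategy packs more individuals onto the same resource base than
solitaries could, and in doing so depresses $\bar{x}$ below the level a
solitary needs — which is why the resource-minimizing strategy is also
uninvadable in the $\Psi$-based pairwise-invasibility analysis
(`invasion_fitness()`, `pairwise_invasibility_grid()`).

Because per-capita eusocial natality is bounded by $F_{\max}/N$, eusocial
equilibria can only exist while $F_{\max}/N > M_b$; the solver
short-circuits group sizes beyond $F_{\max}/M_b$ as infeasible and the
default search cap extends two sizes past that bound so the infeasibility
is confirmed rather than assumed.

### Stability of eusocial groups: minimum relatedness

Subordinates in eusocial groups reproduce only through the dominant.
Inclusive fitness is counted in gene-copy units: each offspring produced
anywhere is weighted by the focal individual's relatedness to *that
offspring*. A subordinate staying in a group of $N$ earns
$\Phi_{\mathrm{sub}} = r\,N\phi(N,\bar{x}_N)/\mu(N,\bar{x}_N)$, where $r$
is its relatedness to the dominant's offspring and $N\phi$ the dominant's
fertility. A defector forages solitarily at the resident resource level,
earning $r_{\mathrm{self}}\,\Psi_1$ from its own offspring
($r_{\mathrm{self}} = 1/2$ for an outbred diploid parent) plus
$r\,(N-1)\phi(N-1,\bar{x}_N)/\mu(N-1,\bar{x}_N)$ through the group it
left one helper short. Both expressions are affine in $r$, so the balance
point is the closed form
$$r_{\min} = \frac{r_{\mathrm{self}}\,\Psi_1}
{N\,\Psi_N - (N-1)\,\Psi_{N-1}},$$
with every $\Psi$ evaluated at the resident equilibrium
(`minimum_relatedness()`, `rmin_sweep()`). The tests verify this closed
form against an independent bisection of the inclusive-fitness balance.

The own-offspring weight is exposed as the argument `r_self` because two
normalizations circulate for Hamilton-type conditions: the gene-copy
accounting above (the package default), and a form in which kin effects
are measured relative to own reproduction, recovered by `r_self = 1`
(in that case $r$ is read as relatedness to the dominant itself). The two
differ by a factor of two in $r_{\min}$ but agree on every comparative
statement — which parameters raise or lower the threshold, and where
groups are unstabilizable. The default was chosen as the internally
consistent accounting for the quantity the analysis names: the
relatedness, to the dominant's offspring, below which leaving pays.

When the linear solve yields a balance point above one, or a nonpositive
denominator, no relatedness in $[0, 1]$ stabilizes the group; the result
carries `defined = FALSE` with the raw value retained for diagnostics.

## Parameters

| Parameter | Meaning | Default | Range explored |
|---|---|---|---|
| $F_{\max}$ | maximal net fecundity (offspring/period) | 3 | 3–5 |
| $c_0$ | cost of reproduction (resource units/offspring scale) | 4 | 4–8 |
| $M_b$ | baseline mortality probability per period | 0.1 | 0.1–0.2 |
| $o_M$ | survival resource threshold (resource units) | 1 | fixed |
| $\theta$ | mean item size, variance proxy (resource units) | swept | (0, 32] |

`preset_params()` bundles the four exemplary combinations used throughout
(standard, increased mortality $M_b = 0.2$, increased cost $c_0 = 8$,
increased fecundity $F_{\max} = 5$). The default variance grid is 48
log-spaced points on $[0.1, 16]$; at a mean intake of about 4 units this
spans CVs from about 0.16 to 2. The three qualitative regimes the sweeps
exhibit — solitary-dominated egalitarian optima at $\theta \lesssim 1$,
eusocial dominance at intermediate $\theta$, egalitarian recovery at high
$\theta$ — are asserted in the acceptance test suite rather than restated
here as numbers.

## Numerical choices

* **Quadrature.** Natality integrals run over
  $[\max(o_M, q_{10^{-15}}), q_{1-10^{-15}}]$, where $q_p$ are Gamma
  quantiles of the pooled share law, with `stats::integrate` at relative
  tolerance $10^{-10}$. The truncated tails carry $< 2\times10^{-15}$ of
  probability mass and $F$ is bounded by $F_{\max}$, so truncation error
  is negligible; quantile-based bounds stay robust for the very large
  shape parameters that arise at small $\theta$. Mortality needs no
  quadrature (closed-form incomplete gamma).
* **Root finding.** $\phi - \mu$ is strictly increasing in $\bar{x}$
  (natality rises, mortality falls with resources), so the equilibrium is
  unique when it exists. The solver scans a geometric grid of 64 points on
  $[o_M(1 + 10^{-6}),\; o_M + 10\,c_0 F_{\max}]$ for the first sign
  change, extends the bracket downward if needed, and bisects with
  `uniroot` to $10^{-10}$ relative tolerance. No sign change inside the
  window is reported as infeasible: near the eusocial feasibility bound
  the balance point (if any) recedes to astronomically large $\bar{x}$
  and can never be optimal, so the window cannot affect
  $N_{\mathrm{opt}}$.
* **Ties and degenerate inputs.** Ties in the group-size scan go to the
  smaller $N$ (`which.min`). Item sizes below `theta_min`
  (default $10^{-6}$) switch to a deterministic point-mass limit at
  $\bar{x}$, avoiding degenerate Gamma shapes; in that mode the
  equilibrium has the closed form
  $\bar{x}_1 = o_M + F^{-1}(M_b)$ against which the solver is tested.
* **Serialization.** Result tables are CSV with 12 significant digits and
  fixed column order; configs round-trip through JSON (full precision) or
  YAML (15 digits); identical configs produce byte-identical CSVs.

## The individual-based validator

`simulate_season()` enacts the model literally: each replicate group draws
$N$ Gamma harvests, pools and splits them, starves members below $o_M$
(starvation is group-wide because pooled shares are identical within a
group), applies independent Bernoulli baseline mortality to survivors, and
realizes fertility as the deterministic expected offspring for the
realized share — a stochastic offspring draw would add noise but not bias,
since only means enter the comparison. Two RNG streams derived from the
master seed (harvests; mortality) are drawn column-wise so that enlarging
the replicate count appends groups without reshuffling earlier ones.

`oracle_panel()` draws a random panel of parameter sets, strategies, means
and item sizes and z-scores the simulated mortality and natality against
quadrature; the test suite requires at most 2% of z-scores beyond three
standard errors on a 25-case panel of 20,000 groups each, and the full
validation suite solves equilibria over the standard presets at a handful
of variance values. These sizes keep the complete test run under a few
minutes on a single core while leaving Monte-Carlo standard errors around
$10^{-3}$.

What the simulator does *not* emulate — and hence what agreement does not
establish about real systems: correlated foraging success among group
members, within-period reallocation of a dead member's share, stochastic
fertility realization, age structure, and multi-season population
dynamics. It validates the quadrature under the model's own assumptions,
nothing more.

## Known limitations

* Only the two extreme sharing rules are modelled; intermediate
  reproductive skew, queuing for dominance, lottery-based dominant
  determination, and cheating on the redistribution rule are out of scope.
* The invasibility analysis is heuristic: $\Psi$-based pairwise invasion
  at the resident's equilibrium, not an explicit allele-frequency model.
  The minimum-relatedness condition inherits the usual caveats of linear
  inclusive-fitness arguments.
* Equilibrium is assumed throughout; transient or spatially heterogeneous
  settings (where solitary strategies can profit from abundant resources)
  are not represented.
* The resource distribution itself is fixed; feedbacks of consumption on
  the item-size distribution are not modelled.
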