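---
title: "From warming to niche contraction: the models behind bitenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From warming to niche contraction: the models behind bitenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitenet)
```

## The causal chain

`bitenet` models one specific route by which climate change restructures
trophic interactions: temperature drives body size, body size drives a
quasi-static biomechanical trait (maximum bite force), and that trait
gates which resources a consumer can physically process. Each link in
the chain is deliberately simple, because the point of the pipeline is
to compose the links and study the *network-level* consequences, not to
model any single link mechanistically.

**Allometry.** A trait $T$ relates to body mass $m$ as
$T = a\,m^{x}$. For bite force the geometric expectation is $x = 2/3$
(force tracks muscle cross-sectional area), and that is the package
default; $x$ is a free parameter everywhere because empirically fitted
exponents for specific taxa differ from the geometric ideal. The
prefactor $a$ carries the units (mN at 1 mg) and is likewise free.

**Temperature-size rule.** We encode size change as a multiplicative
per-degree factor $\alpha$: mass at a warming offset $\Delta T$ is
$m_0\,\alpha^{\Delta T}$. Geometric compounding (rather than a linear
per-degree decrement) is a modelling choice: it preserves positivity for
any $\Delta T$, reduces exactly to the single-degree factor at
$\Delta T = 1$, and makes the performance consequence a clean power law,
$(\alpha^{\Delta T})^{x}$. With $\alpha = 0.9$ one degree of warming
costs

```{r}
100 * (1 - propagate_performance_factor(0.9, c(1/3, 2/3, 1), 1))
```

percent of performance for length-, area- and volume-scaling traits —
the 3–10% band that motivates caring about this mechanism at all.

We apply the shrinkage factor to **mass**, not linear size. If a data
source states shrinkage per degree in linear dimensions, cube it before
passing it in ($\alpha_{mass} = \alpha_{length}^3$); the package does
not guess which convention the user's literature used.

**Q10 thermal performance.** Dynamic muscle performance roughly doubles
per 10 °C (Q10 ≈ 2) before plateauing at high temperature.
`thermal_performance()` implements
$v(T) = v_{ref}\,Q_{10}^{(\min(T, T_{plateau}) - T_{ref})/10}$ — a hard
cap at the plateau, continuous at the junction, because the data behind
"plateaus at high temperatures" do not constrain any smoother shape.
Note the deliberate asymmetry with the size pathway: Q10 raises
performance with temperature within a generation, while the size rule
lowers it across generations. The network pipeline uses only the size
pathway; the Q10 model is provided for trait-level calculations and
reporting (`q10_per_degree()` exposes both the exact geometric
per-degree factor $2^{0.1} \approx 1.072$ and the linear "10% per
degree" reading $(Q_{10}-1)/10$, since both circulate in the
literature).

## Feasibility networks

At temperature $T$, consumer $i$ is linked to resource $j$ iff its bite
force $F_i(T) = a_i (m_{0,i}\,\alpha^{T - T_{ref}})^{x_i}$ is at least
the resource's required cutting force $C_j$. Three conventions worth
stating:

- **Ties produce an edge** ($\geq$, not $>$). Exact equality is
  measure-zero for continuous traits, but the boundary must be fixed for
  reproducibility; inclusion matches the reading "sufficient force to
  cut".
- **Edge weights are force surpluses** ($F_i - C_j$, mN), not
  interaction frequencies. Frequencies are the ecologically richer
  currency but require feeding-rate data the feasibility model does not
  produce; surpluses are what the mechanics actually determine.
- **Abundance never gates edges.** An optional resource abundance column
  is carried through for weighted summaries, but co-occurrence and
  selectivity are out of scope: these are *potential* niches, upper
  bounds on realised ones.

Because warming under $\alpha < 1$, $x > 0$ only ever lowers every bite
force and the thresholds $C_j$ are fixed, hotter layers are always edge
subsets of colder layers. This nestedness is the load-bearing structural
fact of the whole analysis: it forces per-consumer degrees and hence
generality to be non-increasing in temperature, makes interlayer
turnover collapse to $1 - |E_{hot}|/|E_{cold}|$, and pins the
temperature at which a given edge vanishes to the closed form
$\Delta T^\ast = \log(C_j/F_i(T_{ref})) / (x \log \alpha)$
(`edge_loss_delta_t()`). The test suite checks the implementation
against all three consequences independently, plus a brute-force
pairwise oracle for the edge sets themselves.

**Trait matching.** `infer_feasibility_threshold()` inverts the
construction: from an observed 0/1 interaction matrix it brackets each
consumer's force threshold between the toughest resource it uses and the
most tender one it avoids. On networks the package itself built this
bracket must contain the true bite force in 100% of cases — a parameter
recovery property the tests assert over a thousand random instances —
and on real interaction data it is the estimator the feasibility model
implies.

## Metrics

- **Degree / generality.** Generality defaults to the plain mean
  consumer degree, which is the directly interpretable "average number
  of accessible plants". A weighted variant (mean exponential Shannon
  diversity of a consumer's force surpluses) exists behind
  `weighted = TRUE`; it is reported as an option, never silently
  substituted, because the two indices answer different questions and
  the unweighted one is the default reading of niche breadth here.
- **Robustness.** Resources are removed one at a time; a consumer goes
  secondarily extinct when its degree reaches zero (no energetic
  threshold — a single accessible plant counts as survival, the
  harshest-possible optimism). The attack-tolerance curve records the
  surviving-consumer fraction after each removal, with $(0, 1)$
  prepended by convention, and $R$ is its trapezoidal area over removal
  fractions $[0, 1]$. The two hand-checkable anchors — $R = 1/2$ for the
  single-edge 1×1 network and $R = 3/4$ for one consumer holding both of
  two resources — are fixed by this discretisation and asserted in the
  tests, as is agreement of the random strategy with exhaustive
  enumeration over all removal orders on small networks. Removal
  strategies: `random` (averaged over replicates under a recorded seed),
  `most-connected-first`, and `toughest-resource-first`. Because edges
  run only between classes, removing a resource never changes another
  resource's degree, so `most-connected-first` reduces to a static sort
  by initial degree (ties keep table order) — a small structural theorem
  the code comments rather than re-derives at each step. Consumer-side
  primary extinctions are available via `side = "consumers"`.
- **Turnover.** Jaccard dissimilarity of edge sets between layers, with
  the empty-vs-empty case defined as 0 (no links, no rewiring).

## Hypothesis verdicts

With deterministic traits the metric series are deterministic, so the
three warming hypotheses are scored by sign, not by p-value; each
verdict carries its statistic so the user can judge effect size:

- **H1** (generality declines): Spearman $\rho$ of generality against
  temperature is negative. Rank correlation, because the series are
  step-shaped and only direction is claimed.
- **H2** (individual degrees decline): every consumer whose degree
  series changes at all has negative $\rho$, and at least one changes.
  Consumers pinned at a constant degree (typically 0 — already shut out
  at baseline) carry no directional information and are excluded from
  the numerator rather than counted against the hypothesis.
- **H3** (loss differs by baseline bite force): the range of
  per-consumer total degree losses (first layer minus last) is positive.
  "Differs between colonies" needed an operational statistic; the range
  is the bluntest one that is zero exactly when all consumers lose
  alike, which is what the $\alpha = 1$ negative control produces.

The no-shrinkage control ($\alpha = 1$) must leave all three
unsupported: all layers identical, all turnover zero. This is asserted
in the tests and recomputed by the acceptance script.

## The synthetic community

`synthetic_config()` emulates the minimal study system the analysis
needs: a handful of colonies of one species sharing a bite-force
allometry, and a plant community with a right-skewed spectrum of
required cutting forces spanning the colonies' force range. Defaults,
chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_consumers` | 3 | three colonies of a single species |
| `consumer_mass_median`, `consumer_mass_sigma` | 30 mg, 0.4 | leaf-cutter worker scale; moderate between-colony variation so baseline bite forces differ (needed for H3 to be testable) |
| `allometry_prefactor`, `allometry_exponent` | 10 mN·mg⁻²ᐟ³, 2/3 | area-like force scaling; prefactor sets baseline bites near 100 mN |
| `n_resources`, `cutting_force_median`, `cutting_force_sigma` | 50, 90 mN, 0.6 | cutting forces straddle the bite range, giving intermediate baseline connectance (≈ 0.35 at seed 1) so warming has edges to remove and the baseline is neither empty nor complete |
| `alpha` | 0.9 | the canonical 10%-per-degree worked-example value |
| grid | 20–30 °C by 0.5 | a decade of warming at sub-degree resolution |

Both trait distributions are log-normal: strictly positive, right-skewed,
and the standard default for biological size-and-force data. The
generator is deterministic under its seed (byte-identical tables), and
its large-sample behaviour (median recovery, log-normality) is tested at
$n = 1000$.

What it does **not** emulate: phylogenetic or spatial structure,
co-occurrence, abundance dynamics, measured ant or leaf mechanics, or
any empirical covariance between mass and allometric parameters. Passing
tests therefore demonstrate that the pipeline's mathematics and
invariants are correct, not that any real community will show these
effect sizes.

## Numerical choices and degenerate inputs

- Temperature grids given as `"start:stop:step"` include both endpoints
  within a tolerance of 1e−9, so decimal steps that are inexact in
  binary still produce the intended final point.
- The sweep requires a strictly ascending grid containing the rule's
  reference temperature, so a baseline layer always exists and turnover
  series are well-defined.
- Empty consumer or resource sets are usage errors at network
  construction; an empty *edge set* is valid everywhere downstream
  (generality 0, robustness curve starting at 0 survivors after the
  first removal, turnover defined against other layers).
- Consumers isolated at baseline keep the conventional $(0,1)$ curve
  start; they simply depress the curve from the first removal onward.
- All validation is collected where practical (the generator config
  reports every offending field at once; table readers report row
  indices, edge-list readers line numbers).

## Problem sizes

The shipped tests and the acceptance script are sized to run comfortably
on a single CPU: the edge oracle battery uses 100 random communities up
to 50 consumers × 200 resources; nestedness is checked over 100 random
sweeps of 6 layers; Monte-Carlo robustness uses 10,000 replicates
against exhaustive enumeration on ≤ 5-resource networks; threshold
recovery runs 1000 random instances. These sizes were chosen as the
smallest at which the stochastic checks are decisive (Monte-Carlo error
well inside tolerances), and they are parameters of the scripts, not of
the package.

## Limitations

Everything the feasibility model ignores is a direction in which real
systems will deviate: behavioural selectivity among accessible plants,
co-occurrence and phenology, plasticity and selection pushing back
against the size rule, changes in leaf mechanics with climate, species
turnover, and interaction frequencies. The package computes potential
niches under a single mechanical constraint; treat its outputs as the
idealised baseline against which richer data can be compared, not as
predictions of realised diets.
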