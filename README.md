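# bitenet

Warming shrinks ectotherm bodies; smaller bodies bite less hard; weaker
bites cut fewer plants. `bitenet` turns that causal chain into a
quantitative pipeline for ecologists studying how climate change rewires
trophic interactions through biomechanics. It is built around the
leaf-cutter-ant-style study system — colonies whose maximum bite force
must exceed a plant's required cutting force for the interaction to be
mechanically feasible — but the machinery applies to any
consumer–resource guild limited by a force threshold.

## The model

Three pieces of trait-level biomechanics compose into network structure:

- **Allometry.** A biomechanical trait *T* scales with body mass *m* as a
  power law, *T = a·mˣ*, with *x* ≈ 1/3, 2/3, 1 for length-, area- and
  volume-like traits. Bite force, driven by muscle cross-section, is
  area-like (*x* ≈ 2/3).
- **Temperature-size rule.** Body mass shrinks by a factor α per degree
  Celsius of warming: *m(ΔT) = m₀·α^ΔT*. Performance consequently shrinks
  by *(α^ΔT)ˣ*; with α = 0.9 a single degree costs 3–10% of performance
  across *x* ∈ {1/3, 2/3, 1}.
- **Q10 thermal performance.** Muscle performance roughly doubles per
  10 °C (Q10 ≈ 2) until it plateaus at high temperature — available as a
  separate model (`thermal_performance()`) with both the exact geometric
  per-degree factor (2^0.1 ≈ 1.072) and the common linear "10% per
  degree" reading (`q10_per_degree()`).

At each temperature *T*, consumer *i* and resource *j* are linked iff
bite force *Fᵢ(T)* ≥ cutting force *Cⱼ* (ties included; edge weight is
the force surplus in mN). Sweeping a temperature grid yields a multilayer
stack of bipartite networks on which the package computes degree,
generality (mean consumer degree), connectance, robustness to secondary
extinctions (area under the attack-tolerance curve), and interlayer link
turnover (Jaccard dissimilarity of edge sets), and tests three warming
hypotheses: H1 generality declines, H2 individual degrees decline, H3
degree loss differs between consumers with different baseline bite
forces.

## Worked example

```r
library(bitenet)

comm <- generate_community(synthetic_config(seed = 1))
comm$consumers
#> # A tibble: 3 × 5
#>   id       reference_mass_mg prefactor exponent baseline_bite_force_mn
#> 1 colony_1              23.4        10    0.667                   81.7
#> 2 colony_2              32.3        10    0.667                  101.
#> 3 colony_3              21.5        10    0.667                   77.3

sw <- temperature_sweep(comm$consumers, comm$resources,
                        t_grid = "20:30:0.5", rule = temp_size_rule(0.9, 20))
sw
#> <sweep_result> 21 layers over 20-30 degrees C; generality 17.33 -> 3.67

evaluate_hypotheses(sw)
#> # A tibble: 3 × 5
#>   hypothesis statistic                                            value supported
#> 1 H1         spearman_rho_generality_vs_temperature              -0.999 TRUE
#> 2 H2         fraction_of_nonconstant_consumers_with_negative_rho  1     TRUE
#> 3 H3         range_of_per_consumer_degree_losses                 10     TRUE

robustness(sw$networks[[1]], "random", n_replicates = 100, seed = 1)
#> <robustness_result> R = 0.9473 (random removal, 100 replicates, seed 1)

autoplot(sw)   # per-colony degree and guild generality vs temperature
```

Reading the numbers: at the 20 °C baseline the three colonies can cut
into 17.3 of the 50 plants on average; ten degrees of warming (mass
shrinking 10% per degree) contracts that to 3.7. The contraction is
monotone (Spearman ρ ≈ −1), hits every colony whose niche changes at
all, and its magnitude spans a 10-plant range across colonies — the
strongest-biting colony has more margin to lose before edges disappear.
Robustness R = 0.95 says the baseline network tolerates random plant
loss well: secondary colony extinctions arrive only once most plants are
gone.

The full pipeline (community → sweep → per-layer robustness → verdicts →
report files) is one call, or a shell command via the bundled wrapper:

```r
run_sweep(scenario_config(synthetic = synthetic_config(seed = 1)), "out/")
```

```sh
Rscript inst/cli/bitenet.R sweep --config inst/extdata/demo_scenario.yaml --out out/
```

Trait tables can also be loaded from CSV/TSV (`read_consumers()`,
`read_resources()`) instead of being generated, and every report
directory contains a `manifest.json` from which `run_from_manifest()`
reruns the analysis bit for bit.

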