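# invaderkit

Tools for evolutionarily stable strategy (ESS) analysis built on a single
primitive: the **invasion fitness** λ(y, x̂) of a rare mutant lineage — the
leading-eigenvalue magnitude of the linearized rare-mutant dynamics in a
resident population. A phenotype x̂ is uninvadable (an ESS) when
λ(y, x̂) < 1 for every alternative y.

The package is for theoreticians in evolutionary ecology and population
genetics who want to move between the classic settings of ESS theory with
one consistent toolkit:

* **Matrix games** — 2×2 games with mixed strategies: bilinear pay-off
  w(x, y), strict/weak ESS classification per the conditions
  w(x\*, x\*) > w(y, x\*) (strict) and w(x\*, y) > w(y, y) on ties (weak),
  the interior mixed ESS
  x\* = (w₁₀ − w₀₀)/(w₁₀ − w₀₀ + w₀₁ − w₁₁), pairwise invasibility plots,
  and singular-point classification (css / branching / garden of Eden /
  repellor) for smooth invasion-fitness functions.
* **One-locus dynamics** — haploid and diploid selection recursions and the
  correspondence between internally stable equilibria and ESS phenotypes.
* **Two loci** — the selection–recombination recursion on chromosome
  frequencies and external stability of an equilibrium against a new
  allele, including the identity λ = w(x_μ, x̂)/w(x̂, x̂) for bilinear
  pay-offs.
* **Mutation-rate modifiers** — a haploid major locus tracking a cyclic
  environment (period 2T) plus a neutral modifier locus setting the
  mutation rate; monodromy-matrix invasion analysis, ES mutation rates
  (≈ 1/T at tight linkage, declining to 0 with recombination), and the
  reduction principle in constant environments.
* **Group structure** — rare-mutant projection matrices for the infinite
  island model, lineage fitness, within-group relatedness, exact
  inclusive-fitness and group-selection partitions of λ, and the Fisherian
  1:1 sex ratio as a two-class application.

Functions take plain inputs, return tibbles or small S3 objects with
broom-style `tidy()`/`glance()` methods, and PIP grids plot with
`autoplot()`.

## Worked example

```r
library(invaderkit)

W <- payoff_matrix(w11 = 3, w10 = 0, w01 = 5, w00 = 1)
W
#> <payoff_matrix> (prisoners_dilemma)
#>     partner
#> self C D
#>    C 3 0
#>    D 5 1

find_ess(W)
#> # A tibble: 1 × 3
#>       x ess_class interior
#>   <dbl> <chr>     <lgl>
#> 1     0 strict    FALSE
```

The pay-offs satisfy the Prisoner's Dilemma ordering, and the unique ESS is
never cooperating (x = 0), a strict ESS: any cooperating mutant earns
strictly less against the resident than the resident earns against itself.

The same question in a fluctuating environment, for a modifier allele that
sets the mutation rate of a selected locus (epoch length T = 50 generations,
mismatch costs 0.01 and 0.015, modifier fully linked):

```r
es_rate(modifier_model(T = 50, s1 = 0.01, s2 = 0.015, r = 0))
#> <es_rate>
#>   mu_star = 0.0279053 (diagonal_sign_change)
#>   uninvadable over scanned grid: FALSE (max lambda 1.1027211)
```

The ES mutation rate is ≈ 0.028 ≈ 1.4/T — the mutation rate evolves to
roughly one flip per environmental epoch. The honest flag on the second
line records that at these weakly asymmetric costs the interior ES rate is
only locally uninvadable: a non-mutating lineage parked on the cheaper
allele can still invade (max λ per cycle ≈ 1.10). With symmetric costs the
interior rate is globally uninvadable.

Group structure changes what counts as fit. A cooperating mutant (y = 1) in
a defecting resident (x̂ = 0), in groups of 2 with migration 0.5 and weak
selection:

```r
spec <- group_model(n = 2, m = 0.5, delta = 0.01, y = 1, xhat = 0, W = W)
invasion_analysis(spec)
#> <invasion_result>
#>   lambda      = 0.99044792
#>   relatedness = 0.141005
```

λ < 1: cooperation still fails here — relatedness 0.14 (close to the
neutral island-model value 1/7) is not enough to overcome the PD cost at
this migration rate. `inclusive_fitness()` and `group_partition()` split
the same λ into direct cost, relatedness-weighted benefit, and
between-/within-group components, all reconstructing λ exactly.

And the classic sex-ratio result: a mutant producing 50% daughters invades
a female-biased resident (λ = 1.12 > 1), and a scan identifies 0.5 —
daughters:sons = 1:1 — as the unique uninvadable ratio:

```r
sex_ratio_invasion(0.5, 0.3)
#> [1] 1.120923
```

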