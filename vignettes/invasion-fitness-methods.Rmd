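---
title: "Invasion fitness as the common currency of ESS analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invasion fitness as the common currency of ESS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invaderkit)
```

## The problem and the common primitive

An evolutionarily stable strategy (ESS) is a phenotype that, once common,
cannot be invaded by any rare alternative. `invaderkit` implements ESS
analysis for several population-genetic and demographic settings through one
primitive: the **invasion fitness** $\lambda(y, \hat{x})$, the per-generation
geometric growth rate of a rare mutant lineage with phenotype $y$ in a
resident population with phenotype $\hat{x}$. In every module, $\lambda$ is
the leading-eigenvalue magnitude of the linearized rare-mutant dynamics, and
$\hat{x}$ is uninvadable when $\lambda(y, \hat{x}) < 1$ for every $y \ne
\hat{x}$. Each module's machinery differs only in the state space on which
the mutant lineage lives: a single frequency, mutant chromosomes on genetic
backgrounds, a periodically forced two-type system, or group compositions.

## Matrix games (`payoff`, `find_ess`, `classify_strategy`)

Two-strategy games are parameterized by the four pay-offs $w(i, j)$ of pure
strategists and extended bilinearly to mixed strategies:
$w(x, y) = xy\,w_{11} + x(1{-}y)\,w_{10} + (1{-}x)y\,w_{01} +
(1{-}x)(1{-}y)\,w_{00}$. The bilinear form is the natural consequence of
mixed strategies being probabilities over behaviours; it also means both ESS
conditions need only be checked at the pure alternatives $y \in \{0, 1\}$:

* the first-order margin $w(x^*,x^*) - w(y,x^*)$ is linear in $y$ and
  vanishes at $y = x^*$, so its sign on $[0,1]$ is decided at the endpoints;
* on the tying set the second-order margin $w(x^*,y) - w(y,y)$ factors as
  $-k (y - x^*)^2$, so its sign is constant and again visible at the
  endpoints.

A strategy is a *strict* ESS when the first margin is positive for all
alternatives, and a *weak* ESS when ties are resolved by the second margin.
An interior mixed ESS always ties against the resident (that equal-pay-off
condition is what defines it), so interior ESSs are necessarily weak; the
strict label is reserved for corners. Equality is declared at $|\Delta| \le
\mathrm{tol}$ with a default of $10^{-9}$, chosen to sit far above the
rounding error of four-term pay-off arithmetic and far below any margin a
generically drawn game produces.

`find_ess()` examines the two corners and the interior candidate
$x^* = (w_{10} - w_{00}) / (w_{10} - w_{00} + w_{01} - w_{11})$, skipping the
latter when its denominator is within tolerance of zero (a degenerate game
with no isolated interior equilibrium) and merging it with a corner when it
lies within tolerance of 0 or 1.

For smooth invasion-fitness functions of continuous traits,
`classify_singular()` locates zeros of the selection gradient
$g(x) = \partial\lambda/\partial y|_{y=x}$ by scanning and bisection, then
classifies each singular point on two axes: local uninvadability
($\partial^2\lambda/\partial y^2 < 0$) and convergence stability
($g'(x^*) < 0$), yielding the labels `css`, `branching` (convergence stable
but invadable — the population is drawn to a point where it splits),
`garden_of_eden` (uninvadable but unreachable), and `repellor`. Derivatives
are central finite differences with step $h = 10^{-4}$, cross-checked at
$h/2$ (a Richardson-style consistency requirement of $10^{-3}$ relative);
scan values with $|g| \le \mathrm{tol}$ are treated as flat, which both
filters finite-difference noise in neutral regions and implements the
"marginal, not classified" rule for degenerate problems.

## One-locus dynamics and the ESS correspondence

The haploid two-genotype recursion $p' = p\,w(1,p)/\bar{w}$ and the diploid
multi-allele recursion (marginal allele fitnesses under Hardy–Weinberg
proportions, with pairing partners drawn mean-field at the population mean
phenotype $x(\mathbf{p}) = \sum_{ij} p_i p_j x_{ij}$) provide the
population-genetic side of the classical correspondence: internally stable
equilibria generate mean phenotypes that are ESSs of the pay-off matrix, and
unstable ones do not. The test suite checks this on random two-allele models
whose genotype–phenotype map spans the whole phenotype interval (homozygotes
at 1 and 0), because the correspondence concerns attainable ESSs: a map that
cannot produce the ESS phenotype equilibrates at a constrained optimum that
the game rightly refuses to certify. Internal stability is measured as the
spectral radius of the finite-difference Jacobian restricted to the simplex
tangent space; radii within $10^{-4}$ of 1 are left unclassified rather than
forced to a side.

Two modelling choices are fixed here and inherited everywhere: interactions
occur at adult (post-mating) genotype frequencies, and partners are sampled
mean-field from the population rather than within families.

## Two loci: external stability and the eigenvalue identity

The two-locus module tracks chromosome frequencies $p_{ij}$ (censused after
selection and recombination) under the classical recursion in which
recombination at rate $R \in (0, 1/2]$ exchanges the B-locus alleles of the
two parental chromosomes. The recursion is stated in many equivalent forms
in the literature, so the implementation is guarded by structural tests
rather than by transcription: under a constant-fitness game the
linkage disequilibrium $D$ must decay by exactly $(1-R)$ per generation, and
the external-stability analysis must satisfy the eigenvalue identity below.

A new allele $A_\mu$ entering a resident equilibrium $\hat{\mathbf{p}}$
defines a $b \times b$ linearized map on mutant chromosomes $A_\mu B_j$: a
mutant chromosome pairs with a resident chromosome $A_k B_l$ (probability
$\hat{p}_{kl}$), is weighted by $w(x_{\mu jkl}, \hat{x})/\bar{w}$, and
transmits $A_\mu B_j$ with probability $1-R$ or $A_\mu B_l$ with probability
$R$. Because pay-off is linear in the carrier's phenotype, the leading
eigenvalue obeys
$\lambda = w(x_\mu, \hat{x}) / w(\hat{x}, \hat{x})$ with
$x_\mu = \sum_{jkl} u_j \hat{p}_{kl} x_{\mu jkl}$ the eigenvector-weighted
mutant mean phenotype. The suite verifies this identity to $10^{-9}$ on 200
random models — it is the module's theorem-level check, and any error in the
recursion, the census point, or the linearization breaks it. The
`verify_external_stability_ess()` report checks the two directions of the long-term
correspondence (externally stable $\Rightarrow$ ESS; attainable ESS +
internal stability $\Rightarrow$ externally stable) on concrete instances.

## Mutation-rate modifiers in a cyclic environment

The modifier module is a haploid two-locus system: a major locus whose
alleles are alternately favoured by an environment that switches every $T$
generations (mismatch costs $s_1$ and $s_2$), and a neutral modifier locus
that sets the symmetric mutation rate at the major locus. The life cycle is
selection → mutation → recombination with census after recombination, and
the mutation rate applied to a chromosome is the one encoded by its own
modifier allele. This ordering makes the neutral-modifier case exactly
neutral: the mutant map applied to the resident composition reproduces the
resident recursion with multiplier 1, so the full-period (monodromy)
eigenvalue is 1 to machine precision — a structural guard that holds for
every $r$ and every environment schedule.

Invasion is decided by the leading-eigenvalue magnitude of the ordered
product of the $2T$ per-generation $2\times 2$ mutant matrices along the
resident limit cycle (found by iterating whole periods from frequency 0.5 to
a between-period residual below $10^{-12}$). The product is accumulated with
per-step rescaling on a log accumulator so large $T$ cannot underflow. The
ES rate `es_rate()` scans resident rates on a 41-point grid over
$[0, 0.05]$ (the range used for the pairwise invasibility figures), locates
the sign change of the diagonal gradient $\lambda(\mu + \delta, \mu) - 1$
with $\delta = 10^{-4}$, refines it by bisection to $10^{-5}$, and then
verifies the candidate against the whole mutant grid, reporting the outcome
in `uninvadable`.

Numerical results the tests and acceptance script compute at the headline
parameters ($T = 50$, $s_1 = 0.01$, $s_2 = 0.015$): the ES rate at tight
linkage sits at $\mu^* \approx 1.4/T$, within a factor of two of $1/T$ and
tracking $1/T$ across $T \in \{20, 50, 100\}$; $\mu^*(r)$ is non-increasing
in the modifier–major recombination rate and reaches 0 from $r \approx 0.2$
on; and in a constant environment the reduction principle holds exactly
(every lower rate invades every higher resident rate, and the ES rate is the
boundary 0). One honest caveat, reported by `es_rate()` rather than hidden:
at these weakly *asymmetric* costs the interior ES candidate is only locally
uninvadable — a non-mutating lineage parked on the cheaper allele (geometric
load $s_1/2$ per generation) beats the resident's combined mutation and
switching load, so $\mu' \approx 0$ mutants invade with $\lambda_{\rm
cycle}$ up to $\approx 1.1$. With symmetric costs of comparable size, or
stronger selection, the interior ES rate is globally uninvadable; the
uninvadability invariant is therefore asserted in those regimes.

## Group structure, inclusive fitness, and group selection

The structured module tracks a rare mutant in an infinite island model:
groups of $n$ haploid individuals, fecundity selection with intensity
$\delta$ (fecundity $1 + \delta \times$ pay-off against groupmates),
juvenile migration with probability $m$, and competition for each of the $n$
adult slots between philopatric juveniles (weight $1-m$) and immigrant
juveniles (weight $m$; immigrants are never mutants because the mutant is
globally rare among infinitely many groups). A group with $k$ mutants leaves
its own group in state $k' \sim \mathrm{Binomial}(n, \phi_k)$ and founds a
Poisson number of singleton-mutant groups through emigrants. Two exact
identities anchor the construction: the offspring-accounting identity
$\sum_{k'} k' a_{k'k} = k\,\omega_k$ (group-level bookkeeping equals
individual fitness bookkeeping) and the lineage-fitness identity
$\lambda = \sum_k \omega_k q_k$ with $q_k = k u_k / \sum_k k u_k$ the
stabilized distribution of the group state containing a random mutant
allele. Both hold to $10^{-9}$ on random kernels by construction of the
projection matrix, and the within-group relatedness
$r = E_q[(k-1)/(n-1)]$ reproduces the classical island-model
identity-by-descent value $(1-m)^2 / (n - (n-1)(1-m)^2)$ at neutrality.

The inclusive-fitness partition is written
$\lambda_{\rm IF} = 1 - c + b\,r$ and the group-selection partition
$\lambda_{\rm GS} = 1 + \omega_G + \omega_{\Delta G}$ with
$\omega_G = (b - c)\left(\tfrac{1}{n} + \tfrac{n-1}{n} r\right)$ and
$\omega_{\Delta G} = -\bigl(b + (n-1)c\bigr)\tfrac{1-r}{n}$, where $b$ is
the aggregate benefit a focal receives when all groupmates express the
mutant. The genuinely open design question here is how $c$
and $b$ are defined. A pointwise derivative of the fitness kernel at the
resident point leaves a first-order-in-$\delta$ gap to $\lambda$, because
kin competition and the pay-off's mutant–mutant cross term make $\omega_k$
quadratic in $k$ — two pointwise coefficients cannot represent that. This
package therefore uses the exact neighbour-modulated (Price-regression)
coefficients: $\omega_k$ is regressed on the groupmate mutant fraction
$(k-1)/(n-1)$ with weights $q_k$, the slope is $b$, and $c = 1 -$
intercept. A weighted regression passes through the weighted means, so both
partitions reconstruct $\lambda$ *exactly* (to machine precision in the
tests), the coefficients absorb kin competition rather than ignoring it,
and the familiar sign structure survives: a costly helping trait has
$c > 0$, $b > c$, is selected for between groups ($\omega_G > 0$) and
against within groups ($\omega_{\Delta G} < 0$), and the within-group
component carries the factor $1 - r$ and vanishes in the clonal-group
limit. At $n = 2$ the within-group term reduces to the familiar pairwise
form $-(b + c)(1 - r)/2$. Two caveats: for a kernel whose pay-off ignores
partners, the exact benefit coefficient is only zero when there is no local
competition ($m = 1$); and with a single demographic class the benefit a
focal receives equals the benefit an actor confers, so the actor-modulated
and neighbour-modulated readings coincide — multi-class kernels, where they
differ, are outside the built-in kernels.

The classic sex-ratio problem is the two-class application: a rare
autosomal mutant producing a fraction $y$ of daughters in a resident
producing $\hat{x}$ has the $2\times 2$ class projection matrix with
female-line entries $y/(2\hat{x})$ and $(1-y)/(2(1-\hat{x}))$ and male-line
entries $1/2$. At $\hat{x} = 1/2$ the leading eigenvalue is exactly 1 for
every $y$ (the selection gradient vanishes at the Fisherian ratio), and the
scan over residents identifies $\hat{x} = 1/2$ — daughters:sons $= 1{:}1$ —
as the unique uninvadable value.

## What the synthetic models do and do not emulate

All tests run on models generated in code: random ordering-constrained
games, random symmetric genotype–phenotype maps, random linear island
kernels, and the parameterized modifier model. These reproduce the
*structure* of the theory — orderings, symmetries, linearity of pay-off,
rare-mutant linearization — under which the implemented identities are
exact. They do not emulate finite-population drift, fixation probabilities,
stochastic environments, non-random mating, isolation by distance, games
with three or more strategies, or multi-trait coevolution; passing tests
say nothing about those settings, which are outside the package's scope.
Stochastic checks use multitype branching simulations whose offspring laws
(Poisson, binomial) share only their means with the deterministic
projection, providing an independent realization of the growth rate rather
than a re-evaluation of the same arithmetic.

## Problem sizes and numerical choices

The suite and the acceptance script use deliberately small state spaces —
$2\times 2$ chromosome systems, groups of $n \le 4$, 41-point rate grids,
$2\times 10^4$ to $2\times 10^5$ branching replicates — sizes at which every
eigenproblem is dense and exact and the whole analysis reruns in minutes on
one core. Convergence tolerances are $10^{-12}$ on fixed points and limit
cycles (flagged, never silently truncated, when not reached), $10^{-9}$ for
neutrality assertions, and $10^{-5}$ for ES-rate bisection. Eigenpairs come
from dense decomposition with a power-iteration fallback for defective or
reducible matrices, with ties broken by magnitude. Frequencies are clipped
to the simplex only within $10^{-10}$, with a warning beyond that.
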