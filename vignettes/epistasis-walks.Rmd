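---
title: "Methods: epistasis along adaptive walks on simulated fitness landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epistasis along adaptive walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiwalk)
library(dplyr)
```

## The question

On a fitness landscape over biallelic genotypes, the fitness effect of a
mutation can depend on the genetic background. For a quadruple of genotypes
`{ab, Ab, aB, AB}` differing at two focal loci, that dependence comes in
three flavours: *sign* epistasis (a mutation beneficial on one background is
deleterious on the other), and — when effects keep their direction —
*synergistic* or *antagonistic* epistasis, depending on whether the double
mutant over- or under-shoots the null expectation. Simulation studies have
observed that the relative prevalence of these classes shifts along an
adaptive walk: sign epistasis becomes more common as the walk proceeds, and
the antagonistic:synergistic balance tips toward synergistic.

This package provides the machinery to reproduce and dissect that
observation and its simplest explanation — regression to the mean. The
off-path genotype `aB` has a fitness component that is (partly) independent
of the three genotypes the walk actually traversed. Early in a walk, the
traversed genotypes sit in the low-fitness tail, so the independent `aB`
tends to regress *upward* past them (few rank-1/rank-4 configurations,
antagonistic bias). Late in a walk they sit high, and `aB` regresses
*downward* below them — the walk is on a ridge, and rank-4 `aB`
configurations (sign epistasis) dominate. Nothing about the walk process
itself is needed: conditioning the base genotype's fitness alone must — and,
in our checks, does — reproduce the same trends.

## Landscape families

**NK landscapes.** Each of the `L` loci contributes a value that depends on
its own allele and the alleles at `K` other loci, drawn uniformly without
replacement per locus. For each of the `2^(K+1)` states, the contribution is
an independent draw from `Uniform(c_min, c_max)`, and the genotype's fitness
is the *geometric mean* of its `L` contributions. `K = 0` gives a purely
multiplicative, epistasis-free landscape; `K = L - 1` makes genotype
fitnesses mutually independent. The positive floor `c_min` matters because
selection coefficients are fitness *ratios*: it bounds them away from
infinity. Defaults are `c_min = 0.1`, `c_max = 1.0`, chosen so that typical
single-step selection coefficients are of order 0.1; both are exposed in
`run_config()`.

**Rough Mount Fuji (RMF) landscapes.** A deterministic additive component
`slope * d(g)` (where `d(g)` counts derived alleles) plus an independent
`Uniform(noise)` draw per genotype, affinely rescaled so the realized
minimum and maximum equal `w_range`. The slope:noise ratio plays the role K
plays for NK landscapes: `slope = 0` is the uncorrelated house-of-cards
limit, large `slope` a smooth single-peaked landscape. Defaults
(`slope = 0.25`, `noise = c(0, 1)`, `w_range = c(1, 2)`) put the per-step
deterministic increment at a quarter of the noise width — rugged but
correlated, the regime where the mean-regression story is interesting — and
keep all fitnesses strictly positive with moderate selection coefficients.
The rescaling guarantees `min = w_min` and `max = w_max` exactly; a
zero-width noise interval is allowed (a noise-free additive landscape,
useful as the no-sign-epistasis limit), but a landscape whose raw values
are all equal (`slope = 0` *and* zero-width noise) is rejected as
unrescalable.

Both constructors are bit-reproducible from a seed. The default study
geometry is `L = 15` loci, `K = 10`.

## Fitness distribution, quartiles, and starting genotypes

The log-fitness of an NK genotype is the mean of `L` i.i.d. log-uniform
terms, so a Gaussian (central-limit) approximation with
`mu = E[ln U]` and `sigma = SD[ln U]/sqrt(L)` is accurate already at
`L = 10`; `nk_log_fitness_moments()` uses the closed-form log-uniform
moments, and `quartile_bounds(mode = "theoretical")` exponentiates the
Gaussian quantiles. The test suite checks the approximation against
exhaustive enumeration (maximum relative error on the three quartile
boundaries is about 1% at `L = 10`, against a 2% design tolerance). For RMF
landscapes the full table is stored, so empirical quantiles are used
throughout; the empirical quantile convention is linear interpolation of
order statistics (R's `type = 7`), fixed once and documented here.

Adaptive walks start in the low-fitness tail: for NK, uniform genotypes are
rejection-sampled until log-fitness falls below `mu - 1.5 * sigma`; for RMF
the start is drawn uniformly from the bottom `pnorm(-1.5)` (about 6.68%) of
the empirical table — the Gaussian-equivalent tail mass of the same rule.
The rejection sampler takes a budget and fails loudly on pathological
(near-constant) landscapes rather than looping forever. Note that the
threshold uses *ensemble* moments: a small realized landscape (low `L`,
low `K`) occasionally contains no genotype below it, which is again a loud
error; `start_rule = "uniform"` is the appropriate setting for such
geometries.

## Adaptive walks

Under strong selection and weak mutation (SSWM) the population is
monomorphic and each step fixes one beneficial mutation; the probability
that the mutation with selection coefficient `s_i = w_i/w - 1` fixes next is
`s_i / sum(s)`. This first-order formula is used verbatim (it ignores terms
of order `s^2`). The `equal` scheme instead picks uniformly among the
strictly fitter neighbors — the view of an observer who knows only fitness
*ranks*. Exact fitness ties are never taken as steps: continuous fitness
makes them measure-zero, but the rule must be fixed for reproducibility.
Strict improvement on a finite genotype set guarantees termination (the
`2^L` cap on steps is a pure safety guard), and each walk's invariants —
strictly increasing fitness, Hamming-1 steps, distinct consecutive loci,
local-optimum endpoint — are asserted in the test suite on every simulated
walk batch.

Reproducibility is hierarchical: a master seed fans out deterministically
into per-landscape and per-walk substreams, so any single walk can be
replayed in isolation and `(config, master_seed)` fully determines every
output table.

## Classification

Walk-derived quadruples take `ab, Ab, AB` from three consecutive walk
positions (`w_ab < w_Ab < w_AB` by construction) and complete `aB` by
locus-wise XOR. The classifier ranks `w_aB` among the four fitnesses: rank
1 or 4 is sign epistasis; rank 2 or 3 is non-sign, split by the sign of

* multiplicative scale: `epsilon = ln w_ab + ln w_AB - ln w_Ab - ln w_aB`
* additive scale: `epsilon = w_ab + w_AB - w_Ab - w_aB`

Both scales are always computed and stored; labels default to the scale
matching the landscape's construction (multiplicative for NK, additive for
RMF), and the directional conclusions are checked on both. Two numerical
edge cases are handled explicitly rather than silently: exact fitness ties
produce a `degenerate` label (excluded from frequency denominators,
reported in their own column), and `|epsilon| <= 1e-9` counts as "none",
because a multiplicative landscape evaluated in floating point yields
`epsilon ~ 1e-16` rather than exactly zero while genuine epistasis on these
families is orders of magnitude larger. The rank rule is verified against
an independent definitional oracle ("a mutation's fitness effect changes
direction across backgrounds") on 10^4 random quadruples.

## Stratified quadruple sampling

`sample_quadruples()` draws a candidate triple — base genotype `ab`
(optionally rejection-sampled into a fitness quartile), an ordered pair of
distinct focal loci — and accepts it when the chain `w_ab < w_Ab < w_AB`
holds, redrawing the *whole* candidate on failure. The alternative of
fixing `ab` and retrying loci until success looks equivalent but is not: on
a fixed landscape the loci trials are deterministic, so the first success
is conditioned on its own earlier failures (an `aB` that already failed in
the `Ab` role is biased low), and bases with few valid orientations are
over-weighted. Joint redrawing makes accepted quadruples uniform over all
valid (base, loci, orientation) triples, which is the sampling scheme under
which the textbook rank argument applies: on an uncorrelated landscape the
off-path fitness is independent of the acceptance condition, so its rank is
uniform on {1, 2, 3, 4} and sign epistasis has frequency 1/2. That
prediction is one of the package's acceptance checks (chi-square at
`n = 10^4`, 99% binomial interval on the sign fraction). Within-stratum
conditioning beyond the quartile of `w_ab` is deliberately absent.

Note that on any *single* realized landscape the number of valid quadruples
per locus pair fluctuates, so focal-pair uniformity holds marginally over
landscapes, not conditionally on one table; the corresponding test pools
fresh landscapes.

## The three analyses

* `epistasis_by_step()` tabulates class frequencies per two-step window
  index. The number of contributing walks is non-increasing in the step
  index (walks stop at local optima) — after roughly four steps it drops
  quickly, which bounds the usable step range.
* `epistasis_by_quartile()` is the static mirror: stratified quadruples per
  base-fitness quartile across a fresh ensemble, each landscape
  contributing equally to every stratum.
* `mean_regression_intervals()` computes 2.5/50/97.5 fitness percentiles
  across walks for each quadruple role in the early window (positions 1-3)
  or late window (positions 4-6), plus a random-genotype control drawn per
  landscape.

The directional claims the package commits to — sign frequency rising along
walks and across quartiles, the antagonistic:synergistic ratio falling, the
early `ab` interval sitting below the control, the late `aB` median sitting
below `AB`, and the equal-weight scheme showing the same directions at a
slower per-step pace — are exactly the ones asserted (with two-proportion
and chi-square tests at the 99% level) in `tests/testthat/test-acceptance.R`
and recomputed by `scripts/acceptance.R`. Those statistical guards are
deliberately part of the artifact, not of the modelled biology.

## Problem sizes and runtime

The canonical run is 1000 landscapes × 1 SSWM walk at `L = 15`, `K = 10`
(about ten seconds on one core); the scheme comparison uses 700 landscapes
per scheme, the quartile analysis 2000 quadruples per stratum spread over
250 landscapes, and the trend test 1500 walks so that the late-step
antagonistic/synergistic counts retain power. Exhaustive-limit checks run
at `L = 10`, where the full `2^L` table and all `choose(L,2) * 2^(L-2)`
quadruples are enumerable in well under a second. One walk per landscape is
the default (`walks_per_landscape` is exposed) so that records are
independent across landscapes.

## What the generators do and do not emulate

The synthetic landscapes provide tunable neighbor-fitness correlation, a
well-defined low-fitness tail for starts, and strictly positive fitnesses —
the three ingredients the mean-regression argument needs. They do *not*
emulate empirical measurement error (no "possible sign epistasis" category),
multi-allelic loci, higher-order interaction structure beyond what NK
induces, recombination, or polymorphic populations (SSWM is assumed, not
modelled). Passing checks on these families therefore support the
*mechanism* — independent fitness components regressing to the mean — and
its direction on rugged-but-correlated landscapes; they do not calibrate
magnitudes for any particular empirical system, and landscape families with
heavy-tailed fitness distributions could weaken the asymmetry between the
low- and high-fitness ends.

## Known limitations

* Theoretical quartiles exist only for NK (the CLT argument needs i.i.d.
  per-locus contributions); RMF always uses empirical quantiles.
* The first-order fixation probability slightly over-weights large
  selection coefficients relative to the exact diffusion result.
* `enumerate_quadruples()` and `fitness_table()` tabulate `2^L` values and
  are intended for `L` up to ~20.
* Late-step frequency estimates rest on the minority of walks still alive
  there; the tables carry `n_walks` precisely so that this is visible.
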