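---
title: "Information landscapes, paths and the minimum free energy complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information landscapes, paths and the minimum free energy complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infolattice)
```

## The model

`infolattice` analyses the statistical dependence structure of `n` discrete
random variables by computing Shannon information functions on the whole
simplicial lattice of variable subsets.  For every non-empty subset `S` up
to a chosen degree `kmax` it evaluates

* the joint entropy `H(S) = -sum p log2 p` (bits, `0 log 0 := 0`), and
* the multivariate mutual information (co-information)
  `I(S) = sum over non-empty T in S of (-1)^(|T|-1) H(T)`.

`I` of a singleton is its entropy; `I` of a pair is the familiar mutual
information; from triples on, `I` can be negative, which signals synergy:
variables that look pairwise independent but are jointly constrained.  The
canonical example, built in as `gen_borromean()`, puts probability 1/4 on
the states `000, 011, 101, 110` of three bits — every pair independent,
`I3 = -1` bit.

The decomposition at the heart of the package is thermodynamic in form.
Summing the lattice by degree splits the joint entropy as `H = U - G`,
where `U = sum of marginal entropies` plays the role of an internal
(self) energy and `G`, the alternating sum of the higher-degree `I`
values, equals Watanabe's total correlation: a Kullback-Leibler divergence
from the product of marginals, hence non-negative — a total free energy of
the k-body statistical interactions.  The per-state counterpart is the
elementary energy `E(state) = -sum_j log2 p_j(x_j)`, the unique extensive
(additive) assignment; `U` is its expectation, and `gibbs_distribution()`
inverts the construction.

## Landscapes, paths, and the complex

An *information landscape* plots every `I(S)` (or `H(S)`) against its
degree `|S|`, with degeneracy counts since `choose(n, k)` subsets share a
degree.  An *information path* follows one ordering of the variables up
the lattice; its increments are minus the conditional mutual informations,
so the chain rule turns each path into a piecewise-linear curve.  Entropy
paths can never decrease (conditional entropy is non-negative — a
combinatorial second law, audited by `second_law_audit()`); information
paths can rise again, and the first rise marks the *first informational
critical dimension* of the path.  Because conditional informations of
pairs are non-negative, no genuine critical point can occur below degree
3 — `first_critical_dimension()` asserts this.

A *positive information path* is an ordering whose `I` profile strictly
decreases; a maximal one cannot be extended by any variable while keeping
the conditional information strictly positive.  The variable sets of the
maximal positive paths are the facets of the *minimum free energy
complex*: extension stops either at conditional independence (the added
variable contributes nothing given the path) or at negativity (a critical
point).  `maximal_positive_paths()` finds these facets by depth-first
search with set-level memoization — extendability of a prefix depends only
on the variable set reached, so each set is visited once and a pruned
branch never reopens — which returns exactly the sets the exhaustive `k!`
permutation enumeration finds (the test suite keeps that oracle for
`n <= 6`).  `mfe_complex()` closes the facets downward and reports the
face vector, both dimension conventions (variable count, and geometric
`size - 1`), the Euler characteristic, and the minimum free energy
characteristic `H+ = sum over faces of (-1)^(size-1) I(face)`, which
collapses to `H(all variables)` when the complex is the full simplex.

## Coboundary identities

The information functions are not an ad-hoc toolbox: they arise as
low-degree coboundaries of three Hochschild-type operators acting on
functionals of variable tuples, with conditioning as the module action.
`coboundary()` evaluates all three numerically on any distribution, and
`verify_identities()` checks the resulting pattern — the left 1-coboundary
of `H` vanishes (the chain rule), the topological 1-coboundary is `I2`,
the left 2-coboundary is `-I3`, the topological 3-coboundary is `I4`, the
even topological/symmetric and odd left coboundaries vanish, and at degree
4 the left coboundary returns `-I5`.  These identities hold algebraically
for *every* distribution, so their residuals measure only floating-point
error; the suite requires `<= 1e-9` on seeded Dirichlet-random laws.
Vanishing of the `I` cochains themselves is equivalent to statistical
independence at the corresponding degree, which is what makes the
cohomological reading a dependence quantifier.

## What the generators emulate

The synthetic module fixes the study conditions for all tests:

* `gen_independent(n)` — product laws: all `I` of degree `>= 2` vanish,
  `G = 0`.
* `gen_redundant(n)` — perfectly copied variables: every `H(S)` and
  `I(S)` equals the base entropy.
* `gen_borromean()` — the three-bit XOR law above; marginals uniform, so
  every state has elementary energy 3 bits and `U = 3`, `G = 1`, `H = 2`.
* `gen_random_dirichlet(n, cardinality, concentration, seed)` — strictly
  positive laws for fuzzing the algebraic identities; `concentration = 1`
  (flat Dirichlet) is the default study condition.
* `block_product()` — tensor products to plant modules: a Borromean block
  next to three independent noise bits is the module-recovery fixture, and
  the expected readout is that `{1,2,3}` appears as a facet while no facet
  mixes block and noise variables beyond pairs.
* `sample_matrix(joint, m, seed)` — i.i.d. draws closing the loop from
  ground truth through `bin_data()` / `empirical_joint()` back to the
  measures.  At `m = 1e5` the plug-in `I3` of the Borromean law is
  reproducibly within 0.02 bits of -1.

None of these emulate the awkward parts of real assay data — dropout,
batch effects, library-size variation, continuous marginals with heavy
ties — so green tests certify the estimator and the lattice machinery, not
robustness to real-world noise.  Estimation is deliberately the naive
plug-in: empirical frequencies, no pseudocounts, no bias correction.
Plug-in entropies are biased low by roughly `(states - 1) / (2 m ln 2)`
bits, which propagates into every derived quantity; users needing small-m
inference should treat values within that order of zero as zero (the
optional data-driven tolerance in `maximal_positive_paths()` exists for
exactly this).

## Numerical choices

* All outputs are in bits (`log2`); `0 log 0 := 0` throughout.
* Comparisons against zero use an absolute tolerance, default `1e-10`
  bits, configurable in every function that branches on a sign.
* Positivity along a path is *strict*: a tie (conditional information
  within tolerance of zero) stops the path and is recorded as
  `"conditional-independence"`, distinct from `"negativity"`.  A
  `strict = FALSE` mode lets ties extend, for exploratory use, because
  exact ties are common in idealized fixtures (fully redundant variables)
  though measure-zero in generic data.
* Landscape degeneracies are grouped at `1e-9` absolute; exact grouping
  would report degeneracy 1 everywhere on empirical values.
* The subset count is capped at `2^21` evaluations by default
  (`force = TRUE` overrides): the lattice grows as `2^n`, which is the
  practical wall for this kind of analysis.
* Probabilities are stored as dense arrays; at the default cap this is at
  most a few million doubles, and the dense layout keeps marginalization a
  single `apply()` over array margins.

## Design choices on genuinely open points

* **Facets are variable sets, not orderings.**  A set is positive when at
  least one ordering of it is a positive path; the complex is the downward
  closure of the maximal positive sets.  This matches the identification
  of facets with maximal chains and guarantees a simplicial complex by
  construction; an independent closure checker in the tests confirms it.
* **Ties stop paths.**  Strict decrease is required for continuation;
  stopping at conditional independence doubles as the natural
  independence criterion.  The non-strict variant exists but is not the
  default.
* **Two dimension conventions are both reported.**  The critical-dimension
  convention counts variables (a triple facet has dimension 3); the
  geometric convention (`size - 1`) is used for the Euler characteristic.
* **The d >= 4 side condition is reported, not enforced.**  Theory
  suggests a non-simplex minimum free energy complex needs dimension at
  least four, yet generic flat-Dirichlet laws on four binary variables can
  have `I4` above every `I3`, making all four triples maximal — a
  dimension-3 non-simplex complex reached purely through negativity stops.
  The package therefore asserts only what is provable (no negativity stop
  below three variables) and leaves the side condition as a reported
  diagnostic.
* **Mean-path critical dimension counts a terminal drop.**  For the mean
  (homogeneous) path the final degree counts as a local minimum when the
  path strictly decreases into it and the degree is at least 3; a
  monotonically flat tail reports none.

## Problem sizes

The shipped tests and the acceptance script run on small lattices by
choice: exact fixtures at `n = 3..6`, Dirichlet fuzzing at `n <= 5` over
100 seeds, one `m = 1e5` sampling run, and exhaustive-permutation oracles
up to `6! = 720` orderings.  These sizes make every value checkable
against closed forms or brute force while exercising each code path; the
same functions scale to the `2^21`-subset cap for real analyses.

## Known limitations

* Only the simplicial sublattice of variable subsets is computed, not the
  full partition lattice of all coarse-grainings.
* No homology groups or Betti numbers — only the face vector and the Euler
  characteristic.
* No bias-corrected or Bayesian entropy estimators.
* No partial information decomposition; `I` negativity is reported as is,
  without a synergy/redundancy split.
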