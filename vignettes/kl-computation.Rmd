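---
title: "Computing KL divergence between Bayesian networks with an operations cache"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing KL divergence between Bayesian networks with an operations cache}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klbn)
```

## The problem

When a Bayesian network `B` is learned from data generated by a reference
network `A`, the natural error measure is the Kullback–Leibler divergence
between the two joint distributions, `KL(A, B) = Σ_x pA(x) log(pA(x)/pB(x))`.
Structural metrics (arc differences) can mislead: a sparser structure with
well-estimated parameters may approximate the joint better than a denser one.
The obstacle is computational — the sum runs over every joint configuration,
which is exponential in the number of variables.

`klbn` exploits the factorization of `pB` over its families
`f_i = {Xi} ∪ pa(Xi)`. Writing `LL(A, B) = Σ_x pA(x) log pB(x)`,

* `KL(A, B) = LL(A, A) − LL(A, B)`, and
* `LL(A, B) = Σ_i Σ_{x_fi} (pA)↓f_i(x_fi) log φ_i^B(x_fi)`,

so the whole computation reduces to one marginal of `pA` per family of
either network, each of which is a standard variable-elimination query.

## Potentials and networks

The algebra layer works with *potentials*: nonnegative tables over the
configurations of a variable scope, supporting multiplication (on the union
scope), marginalization (summing variables out) and selection (slicing at an
evidence configuration). Scopes are kept in a canonical order — variables
sorted by their position in the network's declaration order — so that two
potentials over the same variables are comparable cell by cell and symbolic
plans have well-defined cache keys. Empty-scope potentials are first-class
scalars; they arise routinely when evidence restriction consumes a CPT's
whole scope. Values are stored in linear space, and all logarithms are taken
only when log-likelihood terms are accumulated; this keeps the factor
operations exact and simple at the table sizes where exact computation is
feasible at all.

A network object couples the DAG with one CPT potential per family.
Construction validates acyclicity and scope/family agreement strictly;
CPT normalization is validated to 1e-6 but only warned about by default
(`strict = TRUE` upgrades it to an error), because file formats round
parameters — the package never renormalizes silently. Both networks of a
divergence computation must share the variable set and every state space
exactly; mismatches are a hard error rather than an implicit harmonization.

## The three engines

**Brute force** multiplies all CPTs into the full joint (capped at 2^22
cells) and evaluates the definition directly. It exists as the independent
oracle: every elimination engine is tested against it on small random
networks.

**Propagation** follows the classical scheme: for each variable `Xi` of `B`
and each configuration `x_pa` of its parents *in B*, restrict `A`'s
potentials to the evidence `pa = x_pa`, delete every other variable, and
read off the unnormalized marginal `q(xi) = pA(xi, x_pa)`. Irrelevant CPTs
are pruned first. The number of elimination runs is
`Σ_i Π_{Xj ∈ pa_B(Xi)} n_j`, which grows quickly with parent-set
cardinalities — the motivation for the cached engine.

Pruning for these unnormalized queries is the requisite-CPT variant of
Bayes-ball: the top-marked nodes of Shachter's traversal for the conditional
query, united with the ancestral closure of the evidence variables (the
latter supplies the evidence mass `p(e)`, which the unnormalized `q`
carries). The union is never larger than the ancestral closure of target
plus evidence, and equivalence with unpruned computation is tested on random
networks.

**Cache** plans all family marginals of both networks — `A`'s families
first, then `B`'s, in variable order, duplicates collapsed — in one symbolic
pass over `A`, then executes numerically. Two repositories drive it:

* the *potential repository* holds every factor with a time stamp, the id of
  the last operation that needs it; query results are protected with
  stamp −1 and never deleted;
* the *operation repository* records each planned combination or
  marginalization as a register `(id, type, arg1, arg2, result)`, keyed by
  its arguments. A request that matches an existing register is a *cache
  hit*: no new register, no new computation, only time-stamp updates.

The planner clock increments after every conditional call, hits included,
and register ids equal the clock at creation — so ids may skip values, and
the printed plan of the three-variable example shows registers 1, 2, 4, 5
with the gap at the hit. During execution, registers run once each in id
order; after register `t`, every unprotected entry whose stamp has expired
(`time ≤ t`) is freed. The expiry test is `≤` rather than `=` because a
stamp set by a cache hit can be a clock value that no register carries; this
is safe since any register using an entry has an id no larger than the
entry's stamp. Entries whose last use was a hit after the final register are
swept at the end; inputs a plan never references are left in place (a plan
with zero registers deletes nothing).

The counters reported are `ops` (registers planned — also exactly the
numeric operations executed), `rep` (conditional calls answered from the
cache) and `del` (potentials freed). Every conditional call is one or the
other, so `calls = ops + rep`, and whenever `rep > 0` the cache strictly
reduces numeric work.

## Orderings and determinism

Elimination orders use the greedy min-weight heuristic on the interaction
graph of the current scopes: repeatedly eliminate the variable whose closed
neighborhood has the smallest cardinality product, connecting its neighbors.
Ties break to the lowest variable index, making plans deterministic. The
divergence itself is invariant to the order (only efficiency changes), which
the tests assert by comparing min-weight against random orders. Within one
variable deletion, potentials are combined pairwise in ascending repository
id; optimizing that combination order is deliberately out of scope.

## Numerical choices

* Logarithms are natural by default (`log_base = "2"` for bits); KL in bits
  equals KL in nats divided by `log 2`.
* Zero handling: terms with zero reference mass contribute 0 regardless of
  the CPT value (`0·log 0 := 0`). Reference mass on a zero CPT entry makes
  the cross log-likelihood −∞, so KL is +∞; the default `"extended"` policy
  returns that with a warning, `"strict"` raises an error. Learned networks
  with zero parameters are common, so a hard default error would be
  impractical; the choice is exposed per call.
* Self- and cross-terms share one plan: `LL(A, A)`'s family marginals are
  part of the same query list, which is precisely where the cache pays off
  when the two structures overlap.

## Synthetic data

The generator emulates the reference/learned-network setting: `random_bn`
samples a DAG along a random topological order with at most `max_parents`
parents per node and symmetric Dirichlet(α) CPT columns; `perturb_bn`
applies random arc additions/removals/reversals (feasibility-checked for
acyclicity and the parent cap) and re-samples the CPTs of changed families,
standing in for a structure learned from finite data. Defaults — 8 binary
variables, at most 3 parents, Dirichlet(1), 3 edge moves — keep the exact
joint enumerable, so every engine can be compared against the brute-force
oracle; the test suite does this over 100 seeded pairs, alongside the
deterministic worked-example plan trace. What the generator does not emulate:
real learned networks' parameter estimation noise (perturbed CPTs are
re-drawn, not re-fitted from samples), deterministic or context-specific
CPTs, and the large state spaces of real repository networks — so passing
tests certify algorithmic correctness at oracle scale, not performance on
large networks.

`bn_sample` provides plain forward (ancestral) sampling for completeness of
the experimental loop; nothing in the divergence computation depends on
sampled data.

## Problem sizes

The suite and the acceptance checks run at desk scale by design: oracle
comparisons use 8–10 binary variables (joints of ≤ 1024 cells), 100 seeded
pairs for engine agreement and cache accounting, 20 pairs × 10 random orders
for order invariance. The three-variable worked example pins the exact
repository trace (register ids 1, 2, 4, 5; one hit; three deletions).

## Limitations

Discrete networks only; no approximate or sampled potentials; no
cross-invocation cache persistence; the BIF reader covers the
discrete-variable grammar used by the common repositories (no `default`
rows, no continuous variables). Wall-clock comparisons between engines are
reported by `bench_run` but never asserted — they are hardware facts, not
properties of the algorithms.
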