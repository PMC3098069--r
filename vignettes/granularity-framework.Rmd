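---
title: "An integrated spatio-structural granularity framework for partonomies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated spatio-structural granularity framework for partonomies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granpart)
```

## The problem

Anatomy ontologies organize material entities into *levels of granularity*
along part-whole relations: molecule < organelle < cell < organ < organism.
Most published schemes implicitly assume a *constitutive* organization, in
which every entity of one level is part of an entity of the next higher
level and the parts of each level sum exhaustively to the whole. Real
multicellular bodies are *cumulative-constitutive*: extracellular matrix
(ECM) molecules are parts of tissues without being parts of any cell, and
erythrocytes are parts of a body without being parts of any organ. Under
that organization single-perspective level schemes become formally
inconsistent — the sum of all cells is not the organism, types like
'molecule' have instances on several levels at once, and fiat-bounded
entities ("portion of tissue", "organ system") end up interleaved with
bona-fide objects in one ordered list.

`granpart` implements a multi-perspective alternative. Material types carry
one of three kind tags — `object` (bona-fide bounded unit), `fiat_object_part`
(arbitrarily bounded part, including aggregates-with-matrix such as a "cell
aggregate with ECM"), `object_aggregate` (mereological sum of separate
objects) — and parthood is recorded between *instances* only. From that
single input the package derives:

1. **Granular partitions** (`build_granularity_tree()`): rooted trees whose
   cuts are instance granularity levels; validation of proper parthood as a
   strict partial order (`validate_strict_partial_order()`).
2. **Sedimentation** (`sediment_types()`): each type is ranked at the
   lowest instance level any of its instances occupies;
   `detect_crossing_types()` lists the level-crossing types that make
   direct type-level trees impossible.
3. **Perspectives** (`build_framework()`): the compositional-object
   backbone plus two-level compositional, spatial and resolution
   perspectives and instance-only fiat chains, connected by overcrossing
   levels into one framework.
4. **Structural granularity values** (`propagate_framework_values()`):
   naturals 1, 2, ... on the backbone, exact rational intervals strictly
   between adjacent naturals for fiat and aggregate levels, nested
   sub-intervals for fiat chains, with part-to-whole monotonicity checked
   by `check_value_monotonicity()`.
5. **Scheme linting** (`check_kumar_principles()`,
   `check_scheme_consistency()`): audits of published level schemes against
   the seven classical granularity principles, the two general part/whole
   principles, and the mixed-perspective / misused-aggregate diagnostics.

## A worked example

```{r}
p <- fixture("fig2_organ")  # organ, 2 cells, 4 organelles, 12 molecules
tr <- build_granularity_tree("organ1", canonical_partitions(p, "organ1"), p)
sediment_types(enumerate_levels(tr), p)
detect_crossing_types(enumerate_levels(tr), p)
```

The extracellular molecules a–d sit directly below the organ, so 'molecule'
crosses three instance levels and sediments to level 1. The cellular cut is
not exhaustive — the check pinpoints the uncovered atoms:

```{r}
exhaustive_sum_check(c("q", "r"), "organ1", p)
```

Value assignment on the fiat-chain example (a cell inside three nested fiat
organ parts inside an organ):

```{r}
f <- build_framework(fixture("fig11_organ"))
v <- propagate_framework_values(f)
v$instances[, c("instance", "rep_num", "rep_den")]
```

Cell = 1, organ = 2, and the three fiat parts receive strictly increasing
representatives 19/16 < 11/8 < 7/4 inside the open interval (1, 2).

## Model and assumptions

**Strict order, derived reflexivity.** Subcell relations of granular
partitions are often axiomatized reflexively while parthood is strict. The
model commits to strict proper parthood (irreflexive, antisymmetric,
transitive) and treats the reflexive closure as derived; the order report
treats cycles and redundant "direct" edges as data, not exceptions, so
defective inputs can be audited rather than rejected.

**Atoms are graph-theoretic.** No spatial extents are modeled; an atom is
an instance with no recorded proper parts, and exhaustive summation
compares atom sets. A green summation check therefore establishes coverage
relative to the recorded decomposition, not relative to physical reality.

**Instance-level parthood only.** Type-level parthood is never asserted,
because under cumulative organization it is unreliable (some molecules are
direct parts of organs). The compositional-object backbone is derived as
the transitive reduction of the *object-restricted* closure, so
object-object adjacency survives interposed fiat parts: in the fiat-chain
example the cell is still an object-direct part of the organ.

**Longest-path layering.** The backbone level of an object subtype is one
plus the longest chain of object-subtype parthood beneath it. This keeps
'molecule' at the bottom even when some molecules are direct parts of
organs.

**Pass-through cuts.** A molecule that is already atomic in the coarsest
cut reappears in every finer cut. The tree stores each node once, at the
depth where it enters; `enumerate_levels()` re-inserts pass-through leaves
into deeper cuts (matching how cuts are read off a drawn tree), while
`tree_node_levels()` exposes the disjoint node assignment. Disjointness
invariants are stated against the latter.

## Numerical choices

**Exact rationals.** Interval endpoints and representatives are integer
numerator/denominator pairs, so equality of overcrossing values is decided
bit-exactly; no floating point enters any comparison.

**Interval placement.** A fiat or aggregate level anchored at backbone
level X receives the open interval (X, X+1) with the midpoint as
representative. Because the anchor is determined by content (the highest
backbone level among an aggregate's object parts; one below the minimal
host level for regional parts), the compositional and spatial copies of the
same fiat level automatically receive identical values, as the overcross
rule demands. Resolution levels share their host interval and use the
lower-third (countable) and upper-third (non-countable) points, realizing
"equal or less" as strictly less for determinism.

**Fiat chains refine by halving, not equal width.** Chain member i
(1 = finest) of n gets `(lo + w/2^(n-i+1), lo + w/2^(n-i))` inside the host
interval of width w. Equal-width subdivision would renumber every member
when a deeper part is added; the halving scheme only ever subdivides the
remaining gap at the fine end, so re-granulating a partition never changes
an already assigned value — a stability property the test suite asserts as
a regression. The cost is that a length-1 chain occupies the upper half of
its host rather than the whole host; ordering guarantees are unaffected.

**Sibling fiat parts.** Non-nested fiat parts of the same object receive
equal intervals (they are genuinely incomparable); ties between unrelated
instances are not monotonicity violations, since only part-whole pairs are
value-ordered.

## The synthetic generator

`generate_cumulative_partonomy()` emulates cumulative-constitutive
organization: `n_co_levels` object layers, `branching` direct parts per
whole, and per level a `free_fraction` of instances attached directly to
the maximum object (ECM molecules, circulating cells). Defaults —
3 levels, branching 2, free fraction 0.25 — describe a small
metazoan-like toy: cumulative by default, because that is the realistic
case for biological material entities. `with_ecm = TRUE` adds fiat
aggregates-with-matrix over the second-highest level plus a
countable/non-countable representation pair, so that spatial and
resolution perspectives have material to granulate. With all free
fractions zero the output is purely constitutive, and the classical
summation principle holds at every level; with any positive free fraction
it fails at some level — the paired property the acceptance suite checks.

What the generator does *not* emulate: realistic anatomical morphology,
size distributions, overlapping fiat partitions, or cumulative-aggregative
(rank-style) organization. A green test on generated data therefore
establishes the formal behavior of the algorithms, not anatomical
fidelity.

The backbone structure is a deterministic function of the parameters; the
seed only drives genuinely random choices (the grouping in
`generate_fiat_partition()`), so identical seeds replay byte-identical
documents.

## Known limitations and open corners

* The bundled organ fixture follows the printed cuts literally, which
  gives each organelle exactly one molecule; the backbone instance rule
  "every non-lowest object has at least two object parts" is therefore
  violated by the fixture's organelles, and the rule check reports exactly
  that. Toy figures and general rules do not always agree.
* The regional-part rule "a fiat part is part of an object at its
  name-giving type's level" cannot hold verbatim for aggregates-with-matrix
  (named after their members, hosted one level up); the check accepts a
  name-giving level equal to the minimal host level or one below it.
* Several sibling fiat partitions of one object are pooled into one
  two-level spatial perspective per fiat subtype; whether they should form
  one or several perspectives is not fixed by the underlying theory.
* Resolution-representation types usually carry no instances; overcross
  detection aliases them to their represented type, and instance-content
  levels to their member types, since raw content intersection would
  otherwise miss the intended connections.
* Taxonomic (is-a) granulation, OWL reasoning, geometry and temporal
  change of parthood are out of scope; `import_obo()` keeps `is_a` as
  taxonomy metadata and never converts it to parthood.
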