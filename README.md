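# granpart

Granular partitions and integrated granularity frameworks for part-whole
hierarchies of biomedical material entities.

## The problem

Anatomy and other domain ontologies order their types into *levels of
granularity* along part-whole relations (molecule < organelle < cell <
organ < organism). Those schemes silently assume a *constitutive*
organization in which every part of one level is inside a whole of the
next level and each level sums to the whole. Real organisms are
*cumulative-constitutive*: extracellular matrix molecules are parts of
tissues but of no cell, circulating cells are parts of the body but of no
organ. Under that organization, single-list level schemes break — levels
stop summing to the whole, type extensions straddle levels, and fiat
entities ("portion of tissue", "organ system") get interleaved with
bona-fide objects.

`granpart` is a toolkit for ontology engineers who need to audit or build
granularity schemes over such data. It models a **partonomy** — types
tagged with the three material-entity kinds (`object`,
`fiat_object_part`, `object_aggregate`), instances, and proper-parthood
edges between instances — and derives from it:

* **order validation**: proper parthood as a strict partial order
  (transitive, antisymmetric, irreflexive), with violations reported as
  data;
* **granularity trees and cuts**: rooted partition trees whose horizontal
  cuts are instance granularity levels;
* **sedimentation**: type granularity as the lowest instance level of a
  type's instances, plus detection of level-crossing types;
* **an integrated perspective framework**: a compositional-object backbone
  and two-level compositional / spatial / resolution perspectives plus
  instance-only fiat chains, knit together by overcrossing levels;
* **structural granularity values**: naturals 1, 2, ... on the backbone
  and exact rational open intervals (X, X+1) for fiat/aggregate levels,
  nested sub-intervals along fiat chains, strictly increasing from part to
  whole;
* **scheme linting**: audits of published level schemes against the seven
  classical granularity principles, the general part/whole principles, and
  mixed-perspective / misused-aggregate diagnostics;
* **I/O**: a canonical JSON document format (byte-identical round trips),
  TSV edge lists, OBO 1.2 import with a kind-map sidecar, DOT export, and
  a CLI (`exec/granpart`).

## Worked example

A 19-instance organ: two cells (q, r) and four extracellular molecules
(a–d) directly below the organ, organelles inside the cells, molecules
inside the organelles.

```r
library(granpart)
p  <- fixture("fig2_organ")
tr <- build_granularity_tree("organ1", canonical_partitions(p, "organ1"), p)
sediment_types(enumerate_levels(tr), p)
#>     type_id level
#> 1  molecule     1
#> 2 organelle     2
#> 3      cell     3
#> 4     organ     4
detect_crossing_types(enumerate_levels(tr), p)
#> $molecule
#> [1] 1 2 3
exhaustive_sum_check(c("q", "r"), "organ1", p)
#> $ok
#> [1] FALSE
#> $missing
#> [1] "a" "b" "c" "d"
```

'molecule' crosses three instance levels (its extension includes
extracellular, cellular and organelle molecules) and sediments to level 1;
the cells alone do not sum to the organ — the four extracellular molecules
are missing. Structural values on the nested fiat-organ-part chain:

```r
f <- build_framework(fixture("fig11_organ"))
v <- propagate_framework_values(f)
v$instances[, c("instance", "rep_num", "rep_den")]
#>   instance rep_num rep_den
#> 1       f1      19      16
#> 2       f2      11       8
#> 3       f3       7       4
#> 4    cell1       1       1
#> 5   organ1       2       1
check_value_monotonicity(fixture("fig11_organ"), v)
#> <lint report>: clean
```

Cell = 1 and organ = 2 are backbone naturals; the three fiat organ parts
receive exact rationals 19/16 < 11/8 < 7/4 strictly inside (1, 2), so every
part-whole pair is value-ordered. Linting a published scheme:

```r
check_scheme_consistency(fixture("fma_scheme"))
#> <lint report>: 1 finding(s)
#>   [error] mixed_perspective: scheme fma_salient declared compositional but
#>   contains fiat-part levels alongside object levels
#>   (Portion of tissue, Organ system, Cardinal body part)
```

## Command line

```sh
granpart validate --input doc.json
granpart simulate --seed 11 --with-ecm --output toy.json
granpart values   --input toy.json --output values.tsv
granpart lint kumar --input doc.json
granpart import-obo --input anatomy.obo --kind-map kinds.tsv --output doc.json
```

Exit codes: 0 clean, 1 findings, 2 input error — the linter is CI-friendly.

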