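test_that("transitive closure adds exactly the implied pairs", {
  e <- data.frame(child = c("a", "b"), relation = "proper_part_of",
                  parent = c("b", "c"), stringsAsFactors = FALSE)
  closed <- transitive_closure(e)
  expect_setequal(paste(closed$child, closed$parent), c("a b", "b c", "a c"))
  # input rows preserved
  expect_true(all(paste(e$child, e$parent) %in%
                    paste(closed$child, closed$parent)))
  expect_identical(nrow(transitive_closure(granpart:::empty_edges())), 0L)

  # 5-element chain: all 10 ordered pairs, checked against the DFS oracle
  p <- fixture("fig11_organ")
  closed <- transitive_closure(p)
  got <- sort(unique(paste(closed$child, closed$parent)))
  expect_identical(got, oracle_closure_pairs(p$edges, p$instances$id))
  expect_length(got, 10L)
})

test_that("transitive closure rejects unknown endpoints", {
  e <- data.frame(child = "a", relation = "proper_part_of", parent = "b",
                  stringsAsFactors = FALSE)
  expect_error(transitive_closure(e, instances = c("a")), "reference error")
})

test_that("transitive reduction recovers direct edges", {
  p <- fixture("fig11_organ")
  closed <- transitive_closure(p)
  red <- transitive_reduction(closed, p$instances$id)
  expect_identical(sort(paste(red$child, red$parent)),
                   sort(paste(p$edges$child, p$edges$parent)))
  expect_identical(nrow(red), 4L)

  # a diamond has no transitive shortcuts
  dia <- data.frame(child = c("a", "b", "a", "b"),
                    relation = "proper_part_of",
                    parent = c("c", "c", "d", "d"), stringsAsFactors = FALSE)
  red <- transitive_reduction(dia)
  expect_setequal(paste(red$child, red$parent),
                  paste(dia$child, dia$parent))

  expect_identical(nrow(transitive_reduction(granpart:::empty_edges())), 0L)
  cyc <- data.frame(child = c("a", "b"), relation = "proper_part_of",
                    parent = c("b", "a"), stringsAsFactors = FALSE)
  expect_error(transitive_reduction(cyc), "order error")
})

test_that("order validation reports each violated axiom with witnesses", {
  expect_identical(nrow(validate_strict_partial_order(fixture("fig2_organ"))),
                   0L)

  # direct self-loop (injected past the constructor, which refuses it)
  p <- fixture("fig5_co")
  p$edges <- rbind(p$edges, data.frame(child = "c1",
                                       relation = "proper_part_of",
                                       parent = "c1"))
  rep <- validate_strict_partial_order(p)
  expect_true("irreflexivity" %in% rep$rule)
  expect_true("c1" %in% rep$x[rep$rule == "irreflexivity"])

  # mutual parthood
  p <- fixture("fig5_co")
  p$edges <- rbind(p$edges,
                   data.frame(child = c("o1", "c2"),
                              relation = "proper_part_of",
                              parent = c("c2", "o1")))
  rep <- validate_strict_partial_order(p)
  expect_true("antisymmetry" %in% rep$rule)
  ab <- rep[rep$rule == "antisymmetry", ]
  expect_true(any(ab$x == "c2" & ab$y == "o1"))

  # closure gap only reported under the closedness claim
  p <- fixture("fig5_co")
  expect_false("transitivity_closure_gap" %in%
                 validate_strict_partial_order(p)$rule)
  rep <- validate_strict_partial_order(p, assume_closed = TRUE)
  gap <- rep[rep$rule == "transitivity_closure_gap", ]
  expect_true(any(gap$x == "o1" & gap$y == "organ1"))
})

test_that("redundant direct edges are downgraded with a warning", {
  types <- list(material_type("t", "object"))
  inst <- data.frame(id = c("a", "b", "c"), type_id = "t")
  edges <- data.frame(child = c("a", "b", "a"),
                      relation = "direct_proper_part_of",
                      parent = c("b", "c", "c"))
  expect_warning(p <- partonomy(types, inst, edges), "downgrading")
  expect_identical(p$edges$relation[p$edges$child == "a" &
                                      p$edges$parent == "c"],
                   "proper_part_of")
  expect_identical(nrow(validate_strict_partial_order(p)), 0L)
})

test_that("exhaustive sum check follows the atoms", {
  p <- fixture("fig2_organ")
  expect_true(exhaustive_sum_check(letters[1:12], "organ1", p)$ok)
  res <- exhaustive_sum_check(c("q", "r"), "organ1", p)
  expect_false(res$ok)
  expect_setequal(res$missing, c("a", "b", "c", "d"))
  # the cellular cut (cells + extracellular molecules) is exhaustive
  expect_true(exhaustive_sum_check(c("q", "r", "a", "b", "c", "d"),
                                   "organ1", p)$ok)
  expect_error(exhaustive_sum_check(c("q", "organ1"), "organ1", p),
               "precondition error")

  # constitutive case: direct parts always sum to the whole
  pc <- generate_cumulative_partonomy(generator_params(free_fraction = 0,
                                                       seed = 2))
  red <- transitive_reduction(pc$edges, pc$instances$id)
  whole <- setdiff(pc$instances$id, red$child)
  expect_true(exhaustive_sum_check(red$child[red$parent == whole],
                                   whole, pc)$ok)
})

test_that("closure and cycle detection agree with the brute-force oracle", {
  for (seed in 1:4) {
    p <- generate_cumulative_partonomy(
      generator_params(n_co_levels = 3, branching = 2,
                       free_fraction = c(0, 0.3), seed = seed))
    expect_lte(nrow(p$instances), 25L)
    expect_identical(nrow(validate_strict_partial_order(p)), 0L)
    closed <- transitive_closure(p)
    expect_identical(sort(unique(paste(closed$child, closed$parent))),
                     oracle_closure_pairs(p$edges, p$instances$id))
    expect_false(oracle_has_cycle(p$edges, p$instances$id))
    # reduction of the closure closes back to the same relation
    red <- transitive_reduction(closed, p$instances$id)
    reclosed <- transitive_closure(red, p$instances$id)
    expect_setequal(paste(reclosed$child, reclosed$parent),
                    unique(paste(closed$child, closed$parent)))
  }
})

test_that("sum check over all atoms is true and breaks when one is dropped", {
  p <- generate_cumulative_partonomy(generator_params(seed = 5))
  cl <- granpart:::closure_matrix(p)
  whole <- cl$ids[rowSums(cl$mat) == 0 & colSums(cl$mat) > 0]
  atoms <- granpart:::atoms_under(cl$mat, whole)
  expect_true(exhaustive_sum_check(atoms, whole, p)$ok)
  res <- exhaustive_sum_check(atoms[-1], whole, p)
  expect_false(res$ok)
  expect_identical(res$missing, atoms[1])
})

test_that("constructor enforces referential and annotation invariants", {
  expect_error(partonomy(list(material_type("t", "object")),
                         data.frame(id = "a", type_id = "missing")),
               "reference error")
  expect_error(partonomy(list(material_type("f", "fiat_object_part")),
                         data.frame(id = character(),
                                    type_id = character())),
               "annotation error")
  expect_error(
    partonomy(list(material_type("t", "object"),
                   material_type("f", "fiat_object_part",
                                 name_giving = "f")),
              data.frame(id = "a", type_id = "t")),
    "annotation error")
  expect_error(
    partonomy(list(material_type("t", "object")),
              data.frame(id = "a", type_id = "t"),
              data.frame(child = "a", relation = "proper_part_of",
                         parent = "a")),
    "order error")
})
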