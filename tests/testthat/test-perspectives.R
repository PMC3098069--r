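test_that("edges classify by endpoint kinds and relation", {
  p <- fixture("fig11_organ")
  e <- function(child, parent) {
    data.frame(child = child, relation = "direct_proper_part_of",
               parent = parent, stringsAsFactors = FALSE)
  }
  expect_identical(classify_edge(e("cell1", "f1"), p),
                   "compositional_object_of_fiat")
  expect_identical(classify_edge(e("f3", "organ1"), p),
                   "spatial_fiat_of_object")
  expect_identical(classify_edge(e("f1", "f2"), p), "spatial_fiat_of_fiat")
  p5 <- fixture("fig5_co")
  expect_identical(classify_edge(
    data.frame(child = "c1", relation = "direct_proper_part_of",
               parent = "organ1"), p5),
    "compositional_object")
  # countable edge needs a declared representation
  pe <- generate_cumulative_partonomy(generator_params(with_ecm = TRUE,
                                                       seed = 2))
  expect_error(classify_edge(
    data.frame(child = pe$instances$id[1],
               relation = "countable_proper_part_of",
               parent = pe$instances$id[2]), pe),
    "classification error")
})

test_that("the backbone perspective layers object subtypes bottom-up", {
  co <- build_co_perspective(fixture("fig5_co"))
  expect_length(co$levels, 3L)
  expect_identical(lapply(co$levels, `[[`, "content"),
                   list("organelle", "cell", "organ"))

  # interposed fiat parts do not break object adjacency
  co11 <- build_co_perspective(fixture("fig11_organ"))
  expect_identical(lapply(co11$levels, `[[`, "content"),
                   list("cell", "organ"))

  # single object subtype, no object-object edges
  p1 <- partonomy(list(material_type("t", "object")),
                  data.frame(id = c("a", "b"), type_id = "t"),
                  data.frame(child = "a", relation = "proper_part_of",
                             parent = "b"))
  expect_error(build_co_perspective(p1), "perspective error")

  # generator level-count recovery
  for (n in 2:4) {
    p <- generate_cumulative_partonomy(generator_params(n_co_levels = n,
                                                        seed = n))
    expect_length(build_co_perspective(p)$levels, n)
  }
})

test_that("additional compositional perspectives are two-level and anchored", {
  pe <- generate_cumulative_partonomy(generator_params(with_ecm = TRUE,
                                                       seed = 3))
  co <- build_co_perspective(pe)
  extra <- build_additional_compositional(pe, co)
  expect_length(extra, 1L)
  pp <- extra[[1]]
  expect_identical(pp$ptype, "compositional_object_of_fiat")
  expect_length(pp$levels, 2L)
  expect_identical(pp$levels[[1]]$content, "gen:obj_L2")
  expect_identical(pp$levels[[2]]$content, "gen:agg_matrix")
  expect_identical(pp$anchor_co_level, 2L)

  # no fiat or aggregate types -> empty list
  p5 <- fixture("fig5_co")
  expect_length(build_additional_compositional(p5, build_co_perspective(p5)),
                0L)

  # perspective count equals distinct (anchor, counterpart) combinations
  p11 <- fixture("fig11_organ")
  co11 <- build_co_perspective(p11)
  cls <- granpart:::classify_edges(p11)
  want <- unique(granpart:::instance_type(
    p11, cls$parent[cls$tag == "compositional_object_of_fiat"]))
  expect_length(build_additional_compositional(p11, co11), length(want))
})

test_that("spatial perspectives place fiat parts below their hosts", {
  p <- fixture("fig11_organ")
  co <- build_co_perspective(p)
  sp <- build_spatial_basic(p, co)
  expect_length(sp, 3L)
  for (pp in sp) {
    expect_identical(pp$ptype, "spatial_fiat_of_object")
    expect_length(pp$levels, 2L)
    expect_identical(pp$levels[[2]]$content, "organ")
    expect_identical(pp$anchor_co_level, 1L)
  }
  expect_setequal(vapply(sp, function(pp) pp$levels[[1]]$content,
                         character(1)),
                  c("fop1", "fop2", "fop3"))

  p5 <- fixture("fig5_co")
  expect_length(build_spatial_basic(p5, build_co_perspective(p5)), 0L)

  # however the object is cut, every fiat instance lands in the lower
  # level of exactly one spatial perspective
  for (seed in 1:3) {
    pf <- generate_fiat_partition(fixture("fig2_organ"), "organ1",
                                  2 + seed %% 2, seed = seed)
    cof <- build_co_perspective(pf)
    spf <- build_spatial_basic(pf, cof)
    fiat_inst <- pf$instances$id[
      granpart:::instance_kind(pf, pf$instances$id) == "fiat_object_part"]
    for (fi in fiat_inst) {
      hits <- vapply(spf, function(pp) {
        granpart:::instance_type(pf, fi) %in% pp$levels[[1]]$content
      }, logical(1))
      expect_identical(sum(hits), 1L)
    }
  }
})

test_that("resolution perspectives pair countable and mass representations", {
  pe <- generate_cumulative_partonomy(generator_params(with_ecm = TRUE,
                                                       seed = 3))
  res <- build_resolution(pe)
  expect_length(res, 1L)
  expect_identical(res[[1]]$levels[[1]]$content, "gen:rep_cluster")
  expect_identical(res[[1]]$levels[[2]]$content, "gen:rep_portion")
  expect_identical(res[[1]]$ptype, "resolution_of_aggregate_with_fiat")

  expect_length(build_resolution(fixture("fig5_co")), 0L)

  # a lone representation is skipped with a warning
  p <- pe
  p$types <- p$types[p$types$id != "gen:rep_portion", ]
  expect_warning(res1 <- build_resolution(p), "only one representation")
  expect_length(res1, 0L)
})

test_that("fiat chains are instance-only and ordered by parthood", {
  p <- fixture("fig11_organ")
  chains <- build_fiat_chain(p)
  expect_length(chains, 1L)
  expect_identical(vapply(chains[[1]]$levels, `[[`, character(1), "content"),
                   c("f1", "f2", "f3"))
  expect_true(chains[[1]]$instance_content)

  expect_length(build_fiat_chain(fixture("fig5_co")), 0L)

  # chain order equals the rank in the fiat-only order relation
  cl <- granpart:::closure_matrix(p)
  fiat <- c("f1", "f2", "f3")
  rank <- vapply(fiat, function(x) sum(cl$mat[x, fiat]), integer(1))
  expect_identical(vapply(chains[[1]]$levels, `[[`, character(1), "content"),
                   names(sort(rank, decreasing = TRUE)))

  # branching fiat structures are rejected and reported
  types <- list(material_type("organ", "object"),
                material_type("cell", "object"),
                material_type("fop", "fiat_object_part",
                              name_giving = "organ"))
  pb <- partonomy(types,
                  data.frame(id = c("org", "c0", "fa", "fb", "fc"),
                             type_id = c("organ", "cell", "fop", "fop",
                                         "fop")),
                  data.frame(child = c("c0", "fa", "fb", "fc"),
                             relation = "proper_part_of",
                             parent = c("org", "fc", "fc", "org")))
  ch <- build_fiat_chain(pb)
  expect_length(ch, 0L)
  expect_identical(attr(ch, "rejected"), list(c("fa", "fb", "fc")))
})

test_that("overcross detection equals all-pairs content intersection", {
  pe <- generate_cumulative_partonomy(generator_params(with_ecm = TRUE,
                                                       seed = 3))
  f <- build_framework(pe)
  # brute force over the same expanded contents
  expected <- 0L
  persp <- f$perspectives
  for (i in seq_along(persp)) for (j in seq_along(persp)) {
    if (j <= i) next
    for (li in persp[[i]]$levels) for (lj in persp[[j]]$levels) {
      ci <- granpart:::level_content_expanded(li, pe)
      cj <- granpart:::level_content_expanded(lj, pe)
      if (length(intersect(ci, cj))) expected <- expected + 1L
    }
  }
  expect_identical(nrow(f$overcross), expected)
  # symmetric-irreflexive representation: p1 always precedes p2
  expect_true(all(f$rp$p1 != f$rp$p2))

  # the three perspectives around the matrix aggregate overcross pairwise
  ids <- names(f$perspectives)
  comp <- grep("compositional_object_of_fiat", ids, value = TRUE)
  spat <- grep("spatial_fiat_of_object", ids, value = TRUE)
  reso <- grep("resolution", ids, value = TRUE)
  pair_in <- function(a, b) {
    any((f$rp$p1 == a & f$rp$p2 == b) | (f$rp$p1 == b & f$rp$p2 == a))
  }
  expect_true(pair_in("co", comp))
  expect_true(pair_in(comp, spat))
  expect_true(pair_in(spat, reso))

  # two perspectives over disjoint contents never overcross
  p5 <- fixture("fig5_co")
  f5 <- build_framework(p5)
  expect_identical(nrow(f5$overcross), 0L)
})

test_that("framework validation flags structural defects", {
  pe <- generate_cumulative_partonomy(generator_params(with_ecm = TRUE,
                                                       seed = 3))
  f <- build_framework(pe)
  expect_identical(nrow(validate_framework(f)), 0L)

  # a type inserted into two levels of one perspective
  f2 <- f
  f2$perspectives$co$levels[[2]]$content <-
    c(f2$perspectives$co$levels[[2]]$content,
      f2$perspectives$co$levels[[1]]$content[1])
  rep <- validate_framework(f2)
  expect_true("keet_unique_level" %in% rep$rule)

  # a single-level perspective
  f3 <- f
  f3$perspectives$co$levels <- f3$perspectives$co$levels[1]
  expect_true("keet_two_levels" %in% validate_framework(f3)$rule)

  # a perspective cut off from the backbone
  f4 <- f
  f4$rp <- f4$rp[f4$rp$p1 != "co" & f4$rp$p2 != "co", , drop = FALSE]
  expect_true("framework_connected" %in% validate_framework(f4)$rule)
})

test_that("instance rules report the documented violations", {
  p <- fixture("fig2_organ")
  f <- build_framework(fixture("fig5_co"))
  # fig2: the canonical molecule distribution gives each organelle exactly
  # one molecule, so the two-object-parts backbone rule flags exactly the
  # four organelles; everything else is clean
  f2 <- build_framework(p)
  rep <- check_instance_rules(p, f2)
  errs <- rep[rep$severity == "error", ]
  expect_identical(errs$rule, "co_rule_2")
  expect_setequal(strsplit(errs$witnesses, ", ")[[1]], c("m", "n", "o", "p"))

  # fig5 (two organelles per cell) is fully clean
  p5 <- fixture("fig5_co")
  rep5 <- check_instance_rules(p5, build_framework(p5))
  expect_identical(nrow(rep5[rep5$severity == "error", ]), 0L)

  # an object with exactly one object proper part
  types <- list(material_type("cell", "object"),
                material_type("organ", "object"))
  pv <- partonomy(types,
                  data.frame(id = c("org", "c1"),
                             type_id = c("organ", "cell")),
                  data.frame(child = "c1",
                             relation = "direct_proper_part_of",
                             parent = "org"))
  # a one-cell organ cannot even form a clean framework; check rule directly
  co <- build_co_perspective(pv)
  fv <- structure(list(perspectives = stats::setNames(list(co), co$id),
                       rp = NULL, re = data.frame(), partonomy = pv,
                       co = co$id),
                  class = "granularity_framework")
  repv <- check_instance_rules(pv, fv)
  expect_true("co_rule_2" %in% repv$rule[repv$severity == "error"])

  # a fiat part whose object parts are all at its name-giving level
  types <- list(material_type("cell", "object"),
                material_type("organ", "object"),
                material_type("fop", "fiat_object_part",
                              name_giving = "cell"))
  pf <- partonomy(types,
                  data.frame(id = c("org", "c1", "c2", "f1"),
                             type_id = c("organ", "cell", "cell", "fop")),
                  data.frame(child = c("c1", "c2", "f1"),
                             relation = "direct_proper_part_of",
                             parent = c("f1", "org", "org")))
  ff <- build_framework(pf)
  repf <- check_instance_rules(pf, ff)
  expect_true("comp_rule_3" %in% repf$rule[repf$severity == "error"])
})
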