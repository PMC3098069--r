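test_that("backbone levels receive consecutive naturals from one", {
  bb <- assign_backbone_values(build_co_perspective(fixture("fig5_co")))
  expect_identical(bb$natural, c(1, 2, 3))
  co2 <- build_co_perspective(fixture("fig11_organ"))
  expect_identical(assign_backbone_values(co2)$natural, c(1, 2))
  for (n in 2:4) {
    p <- generate_cumulative_partonomy(generator_params(n_co_levels = n,
                                                        seed = n))
    expect_identical(assign_backbone_values(build_co_perspective(p))$natural,
                     as.numeric(seq_len(n)))
  }
})

test_that("propagation pins fiat levels between the adjacent naturals", {
  pe <- generate_cumulative_partonomy(generator_params(with_ecm = TRUE,
                                                       seed = 3))
  f <- build_framework(pe)
  v <- propagate_framework_values(f)
  lv <- v$levels

  # the matrix-aggregate level sits strictly between its member level (2)
  # and the organ level (3), identically in both perspectives
  agg <- lv[lv$variant == "interval" &
              grepl("(compositional_object_of_fiat|spatial_fiat_of_object)",
                    lv$perspective), ]
  expect_identical(nrow(agg), 2L)
  for (i in 1:2) {
    expect_identical(c(agg$lo_num[i], agg$lo_den[i]), c(2, 1))
    expect_identical(c(agg$hi_num[i], agg$hi_den[i]), c(3, 1))
  }
  expect_identical(agg$rep_num[1] / agg$rep_den[1],
                   agg$rep_num[2] / agg$rep_den[2])

  # the additional-compositional lower level inherits the backbone natural
  low <- lv[grepl("compositional_object_of_fiat", lv$perspective) &
              lv$index == 1, ]
  expect_identical(low$variant, "natural")
  expect_identical(low$natural, 2)

  # resolution representatives: countable at the lower third
  res <- lv[grepl("resolution", lv$perspective), ]
  res <- res[order(res$index), ]
  expect_true(granpart:::rat_lt(rat(res$rep_num[1], res$rep_den[1]),
                                rat(res$rep_num[2], res$rep_den[2])))
  expect_identical(res$rep_num[1] / res$rep_den[1], 2 + 1 / 3)

  # every interval lies strictly inside (anchor, anchor + 1)
  iv <- lv[lv$variant == "interval", ]
  for (i in seq_len(nrow(iv))) {
    lo <- rat(iv$lo_num[i], iv$lo_den[i])
    hi <- rat(iv$hi_num[i], iv$hi_den[i])
    rp <- rat(iv$rep_num[i], iv$rep_den[i])
    expect_true(granpart:::rat_lt(lo, rp) && granpart:::rat_lt(rp, hi))
    expect_lte(hi[1] / hi[2] - lo[1] / lo[2], 1)
  }
})

test_that("fiat chain refinement orders and nests sub-intervals", {
  host <- sgv_interval(rat(1), rat(2))
  vals <- refine_fiat_chain_values(c("f1", "f2", "f3"), host)
  reps <- lapply(vals, `[[`, "rep")
  expect_true(granpart:::rat_lt(reps$f1, reps$f2))
  expect_true(granpart:::rat_lt(reps$f2, reps$f3))
  for (v in vals) {
    expect_true(granpart:::rat_le(host$lo, v$lo))
    expect_true(granpart:::rat_le(v$hi, host$hi))
  }
  # disjoint, ordered sub-intervals
  expect_true(granpart:::rat_le(vals$f1$hi, vals$f2$lo))
  expect_true(granpart:::rat_le(vals$f2$hi, vals$f3$lo))

  expect_length(refine_fiat_chain_values(character(0), host), 0L)
  one <- refine_fiat_chain_values("x", host)
  expect_true(granpart:::rat_lt(one$x$lo, one$x$rep))

  # representative ordering equals the chain rank for arbitrary lengths
  for (n in c(2, 5, 9)) {
    chain <- paste0("g", seq_len(n))
    vals <- refine_fiat_chain_values(chain, host)
    reps <- vapply(vals, function(v) v$rep[1] / v$rep[2], numeric(1))
    expect_identical(order(reps), seq_len(n))
  }
})

test_that("the fig11 assignment is monotone and breaks when swapped", {
  p <- fixture("fig11_organ")
  f <- build_framework(p)
  v <- propagate_framework_values(f)
  got <- instance_values(v)
  expect_identical(
    got,
    data.frame(instance = c("cell1", "f1", "f2", "f3", "organ1"),
               rep_num = c(1, 19, 11, 7, 2),
               rep_den = c(1, 16, 8, 4, 1), stringsAsFactors = FALSE))
  expect_identical(nrow(check_value_monotonicity(p, v)), 0L)

  # adversarial swap of f2 and f3
  vs <- v
  i2 <- which(vs$instances$instance == "f2")
  i3 <- which(vs$instances$instance == "f3")
  tmp <- vs$instances[i2, c("rep_num", "rep_den")]
  vs$instances[i2, c("rep_num", "rep_den")] <-
    vs$instances[i3, c("rep_num", "rep_den")]
  vs$instances[i3, c("rep_num", "rep_den")] <- tmp
  bad <- check_value_monotonicity(p, vs)
  expect_gt(nrow(bad), 0L)
  expect_true(all(grepl("f2|f3", bad$witnesses)))
})

test_that("monotonicity holds on every constructed framework", {
  for (seed in 1:3) {
    pe <- generate_cumulative_partonomy(
      generator_params(with_ecm = seed %% 2 == 0, seed = seed))
    f <- build_framework(pe)
    v <- propagate_framework_values(f)
    expect_identical(nrow(check_value_monotonicity(pe, v)), 0L)
    # brute-force pairwise comparison over the closure
    cl <- granpart:::closure_matrix(pe)
    reps <- stats::setNames(
      v$instances$rep_num / v$instances$rep_den, v$instances$instance)
    idx <- which(cl$mat, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      a <- cl$ids[idx[k, 1]]
      b <- cl$ids[idx[k, 2]]
      if (!is.na(reps[a]) && !is.na(reps[b])) {
        expect_lt(reps[[a]], reps[[b]])
      }
    }
  }
})

test_that("re-granulating a chain never changes pre-existing values", {
  p1 <- fixture("fig11_organ")
  v1 <- propagate_framework_values(build_framework(p1))
  p2 <- fig11_regranulated()
  v2 <- propagate_framework_values(build_framework(p2))
  old <- instance_values(v1)
  new <- instance_values(v2)
  merged <- merge(old, new, by = "instance")
  expect_identical(merged$rep_num.x, merged$rep_num.y)
  expect_identical(merged$rep_den.x, merged$rep_den.y)
  # the deeper member is finer than everything it refines
  f0 <- new[new$instance == "f0", ]
  expect_lt(f0$rep_num / f0$rep_den,
            min(old$rep_num[old$instance == "f1"] /
                  old$rep_den[old$instance == "f1"]))
  expect_gt(f0$rep_num / f0$rep_den, 1)
})

test_that("size perspectives bin instances by ascending thresholds", {
  p <- fixture("fig5_co")
  p$measures <- data.frame(instance = c("o1", "o2", "o3"),
                           quantity = "weight", value = c(2, 5, 9),
                           unit = "mg", stringsAsFactors = FALSE)
  sp <- build_size_perspective(p, "weight", c(4, 8))
  expect_identical(sp$ptype, "size_scale")
  expect_identical(sp$granularity_type, "scale")
  expect_identical(lapply(sp$levels, `[[`, "content"),
                   list("o1", "o2", "o3"))
  expect_identical(vapply(sp$levels, `[[`, integer(1), "scale_value"), 1:3)
  expect_setequal(attr(sp, "excluded"),
                  setdiff(p$instances$id, c("o1", "o2", "o3")))

  # all instances below the first threshold leaves empty levels
  expect_error(build_size_perspective(p, "weight", c(100, 200)),
               "perspective error")
  expect_error(build_size_perspective(p, "weight", c(8, 4)),
               "parameter error")
  expect_error(build_size_perspective(p, "missing", 4), "perspective error")

  # increasing a measure never decreases the level index
  lvl_of <- function(sp, id) {
    which(vapply(sp$levels, function(lv) id %in% lv$content, logical(1)))
  }
  prev <- 0L
  for (w in c(1, 3, 4.5, 6, 8, 11)) {
    p$measures <- data.frame(instance = c("o1", "o2", "o3", "o4"),
                             quantity = "weight", value = c(2, 5, 9, w),
                             unit = "mg", stringsAsFactors = FALSE)
    sp <- build_size_perspective(p, "weight", c(4, 8))
    lv <- lvl_of(sp, "o4")
    expect_gte(lv, prev)
    prev <- lv
  }
})
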