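## Structural granularity values: fixed naturals on the
## compositional-object backbone, exact rational intervals everywhere else.

value_level_row <- function(perspective, level_id, index, sgv) {
  if (sgv$variant == "natural") {
    data.frame(perspective = perspective, level_id = level_id, index = index,
               variant = "natural", natural = as.numeric(sgv$k),
               lo_num = NA_real_, lo_den = NA_real_,
               hi_num = NA_real_, hi_den = NA_real_,
               rep_num = sgv$rep[1], rep_den = sgv$rep[2],
               stringsAsFactors = FALSE)
  } else {
    data.frame(perspective = perspective, level_id = level_id, index = index,
               variant = "interval", natural = NA_real_,
               lo_num = sgv$lo[1], lo_den = sgv$lo[2],
               hi_num = sgv$hi[1], hi_den = sgv$hi[2],
               rep_num = sgv$rep[1], rep_den = sgv$rep[2],
               stringsAsFactors = FALSE)
  }
}

row_sgv <- function(row) {
  if (row$variant == "natural") {
    v <- sgv_natural(row$natural)
    v$rep <- rat(row$rep_num, row$rep_den)
    v
  } else {
    sgv_interval(rat(row$lo_num, row$lo_den), rat(row$hi_num, row$hi_den),
                 rat(row$rep_num, row$rep_den))
  }
}

#' Assign fixed natural values to the backbone levels
#'
#' The lowest level of the compositional-object perspective receives the
#' natural number one; each subsequent level receives the next natural, so
#' adjacent levels carry values X and X + 1.
#'
#' @param co the backbone perspective from [build_co_perspective()].
#' @return A data frame fragment of per-level values (see
#'   [propagate_framework_values()] for the full map).
#' @examples
#' assign_backbone_values(build_co_perspective(fixture("fig5_co")))
#' @export
assign_backbone_values <- function(co) {
  stopifnot(inherits(co, "granularity_perspective"),
            co$ptype == "compositional_object")
  out <- do.call(rbind, lapply(co$levels, function(lv) {
    value_level_row(co$id, lv$id, lv$index, sgv_natural(lv$index))
  }))
  rownames(out) <- NULL
  out
}

#' Refine a fiat chain's values inside a host interval
#'
#' Chain members (regional parts of regional parts) all live strictly
#' inside the host interval (X, X + 1) fixed by the object levels around
#' them; the finer-grained relation confines each member to its own
#' sub-interval. Sub-intervals are assigned by repeated halving anchored at
#' the coarse end: member i (1 = finest) of n gets
#' (lo + w/2^(n-i+1), lo + w/2^(n-i)) with the midpoint as representative,
#' where w is the host width. Representatives strictly increase along the
#' chain, and adding a deeper (finer) member later never changes any
#' already assigned value - the refinement only ever subdivides the
#' remaining gap at the fine end.
#'
#' @param chain character vector of instance ids, ordered finest to
#'   coarsest by proper parthood.
#' @param host an interval `sgv` (or `list(lo=, hi=)` of `rat()` pairs).
#' @return Named list of interval `sgv` values, one per chain member;
#'   empty chain yields an empty list.
#' @export
refine_fiat_chain_values <- function(chain, host) {
  if (!length(chain)) return(stats::setNames(list(), character(0)))
  lo <- host$lo
  hi <- host$hi
  stopifnot(rat_lt(lo, hi))
  w <- rat_sub(hi, lo)
  n <- length(chain)
  out <- lapply(seq_len(n), function(i) {
    li <- rat_add(lo, rat_mul(w, rat(1, 2^(n - i + 1))))
    hi_i <- if (i == n) hi else rat_add(lo, rat_mul(w, rat(1, 2^(n - i))))
    sgv_interval(li, hi_i)
  })
  stats::setNames(out, chain)
}

#' Propagate structural granularity values across a framework
#'
#' Starting from the backbone naturals, values spread through the
#' framework: levels of other perspectives whose content overcrosses a
#' backbone level inherit its natural; fiat and aggregate levels anchored
#' at CO level X receive the open interval (X, X + 1) with the midpoint as
#' representative, so overcrossing fiat levels of distinct perspectives
#' automatically receive identical values; the two levels of a resolution
#' perspective both receive the host interval of the represented type, the
#' countable level with the lower-third point and the non-countable level
#' with the upper-third point as representatives; fiat chain members
#' receive nested sub-intervals via [refine_fiat_chain_values()]. A level
#' whose content overcrosses two different backbone levels is a
#' consistency error.
#'
#' @param f a `granularity_framework`.
#' @param backbone backbone fragment from [assign_backbone_values()];
#'   computed from `f` when missing.
#' @return An object of class `value_map`: `levels` and `instances` data
#'   frames (exact rational columns `*_num`, `*_den`), `unvalued`
#'   (instances outside every valued perspective) and `notes`.
#' @examples
#' f <- build_framework(fixture("fig11_organ"))
#' v <- propagate_framework_values(f)
#' subset(v$instances, select = c(instance, variant, rep_num, rep_den))
#' @export
propagate_framework_values <- function(f, backbone = NULL) {
  stopifnot(inherits(f, "granularity_framework"))
  p <- f$partonomy
  co <- f$perspectives[[f$co]]
  if (is.null(backbone)) backbone <- assign_backbone_values(co)
  co_types <- co_level_of_types(co)
  notes <- list()

  level_rows <- list(backbone)
  add_level <- function(persp, lv, sgv) {
    level_rows[[length(level_rows) + 1L]] <<-
      value_level_row(persp, lv$id, lv$index, sgv)
  }
  backbone_natural <- function(content) {
    hits <- co_types[names(co_types) %in% content]
    u <- unique(unname(hits))
    if (length(u) > 1) {
      stop("consistency error: level content overcrosses backbone levels ",
           paste(u, collapse = " and "))
    }
    if (length(u)) u else NA_integer_
  }

  ordinary <- c("compositional_object_of_fiat", "compositional_aggregate_of_fiat",
                "compositional_object_of_aggregate",
                "compositional_aggregate_of_object",
                "compositional_aggregate_of_aggregate",
                "spatial_fiat_of_object", "spatial_fiat_of_aggregate")
  for (pp in f$perspectives) {
    if (pp$id == co$id || !(pp$ptype %in% ordinary)) next
    for (lv in pp$levels) {
      nat <- backbone_natural(lv$content)
      if (!is.na(nat)) {
        add_level(pp$id, lv, sgv_natural(nat))
      } else {
        anchor <- pp$anchor_co_level
        if (is.na(anchor)) {
          notes[[length(notes) + 1L]] <- lint_row(
            "unvalued_level", "warning",
            paste0("level ", lv$id, " has no backbone anchor"), lv$id)
          next
        }
        ## multi-level aggregate chains step one unit per level
        off <- if (pp$ptype == "compositional_aggregate_of_aggregate")
          lv$index - 1L else 0L
        add_level(pp$id, lv,
                  sgv_interval(rat(anchor + off), rat(anchor + off + 1)))
      }
    }
  }

  levels_df <- do.call(rbind, level_rows)
  find_type_level_value <- function(type_id) {
    for (pp in f$perspectives) {
      if (pp$instance_content ||
          pp$ptype %in% c("resolution_of_aggregate",
                          "resolution_of_aggregate_with_fiat")) next
      for (lv in pp$levels) {
        if (type_id %in% lv$content) {
          row <- levels_df[levels_df$level_id == lv$id, , drop = FALSE]
          if (nrow(row)) return(row_sgv(row[1, ]))
        }
      }
    }
    NULL
  }

  ## resolution perspectives: both levels live in the represented type's host
  for (pp in f$perspectives) {
    if (!pp$ptype %in% c("resolution_of_aggregate",
                         "resolution_of_aggregate_with_fiat")) next
    host <- find_type_level_value(pp$counterpart)
    if (is.null(host) || host$variant != "interval") {
      notes[[length(notes) + 1L]] <- lint_row(
        "unvalued_level", "warning",
        paste0("resolution perspective ", pp$id,
               " has no valued host interval"), pp$id)
      next
    }
    third <- rat_div(rat_sub(host$hi, host$lo), rat(3))
    reps <- list(rat_add(host$lo, third),
                 rat_add(host$lo, rat_mul(third, rat(2))))
    for (k in 1:2) {
      add_level(pp$id, pp$levels[[k]],
                sgv_interval(host$lo, host$hi, reps[[k]]))
    }
  }
  levels_df <- do.call(rbind, level_rows)

  ## fiat chains: refine inside the host interval of the members' types
  inst_rows <- list()
  add_inst <- function(instance, source, sgv) {
    row <- value_level_row(source, instance, NA_integer_, sgv)
    names(row)[names(row) == "level_id"] <- "instance"
    inst_rows[[length(inst_rows) + 1L]] <<- row
  }
  chain_members <- character(0)
  for (pp in f$perspectives) {
    if (pp$ptype != "spatial_fiat_of_fiat" || !pp$instance_content) next
    chain <- vapply(pp$levels, function(lv) lv$content[1], character(1))
    hosts <- lapply(unique(instance_type(p, chain)), find_type_level_value)
    hosts <- hosts[!vapply(hosts, is.null, logical(1))]
    if (!length(hosts) || hosts[[1]]$variant != "interval") {
      notes[[length(notes) + 1L]] <- lint_row(
        "unvalued_level", "warning",
        paste0("fiat chain ", pp$id, " has no valued host interval"), pp$id)
      next
    }
    for (h in hosts[-1]) {
      if (!sgv_equal(h, hosts[[1]])) {
        stop("consistency error: fiat chain ", pp$id,
             " spans differently valued host intervals")
      }
    }
    refined <- refine_fiat_chain_values(chain, hosts[[1]])
    for (i in seq_along(chain)) {
      add_level(pp$id, pp$levels[[i]], refined[[i]])
      add_inst(chain[i], pp$id, refined[[i]])
    }
    chain_members <- c(chain_members, chain)
  }
  levels_df <- do.call(rbind, level_rows)
  rownames(levels_df) <- NULL

  ## instance values from the governing perspective
  unvalued <- character(0)
  for (i in seq_len(nrow(p$instances))) {
    inst <- p$instances$id[i]
    if (inst %in% chain_members) next
    tid <- p$instances$type_id[i]
    if (!is.na(co_types[tid])[1] && tid %in% names(co_types)) {
      add_inst(inst, co$id, sgv_natural(unname(co_types[tid])))
      next
    }
    v <- find_type_level_value(tid)
    if (!is.null(v)) add_inst(inst, "type-level", v) else
      unvalued <- c(unvalued, inst)
  }
  instances_df <- if (length(inst_rows)) do.call(rbind, inst_rows) else
    value_level_row("x", "x", 1, sgv_natural(1))[0, ]
  rownames(instances_df) <- NULL
  if (nrow(instances_df)) {
    names(instances_df)[names(instances_df) == "level_id"] <- "instance"
  }

  ## overcross agreement: non-chain, non-resolution levels sharing content
  ## must carry bit-identical values
  oc <- f$overcross
  exempt <- vapply(f$perspectives, function(pp) {
    pp$instance_content || pp$granularity_type != "nrG"
  }, logical(1))
  exempt_ids <- names(f$perspectives)[exempt]
  for (k in seq_len(nrow(oc %||% data.frame()))) {
    if (oc$p1[k] %in% exempt_ids || oc$p2[k] %in% exempt_ids) next
    r1 <- levels_df[levels_df$level_id == oc$l1[k], , drop = FALSE]
    r2 <- levels_df[levels_df$level_id == oc$l2[k], , drop = FALSE]
    if (!nrow(r1) || !nrow(r2)) next
    if (!sgv_equal(row_sgv(r1[1, ]), row_sgv(r2[1, ]))) {
      stop("consistency error: overcrossing levels ", oc$l1[k], " and ",
           oc$l2[k], " carry different structural granularity values")
    }
  }

  structure(list(levels = levels_df, instances = instances_df,
                 unvalued = unvalued,
                 notes = new_lint_report(notes)),
            class = "value_map")
}

#' @export
print.value_map <- function(x, ...) {
  cat("<value map>: ", nrow(x$levels), " level values, ",
      nrow(x$instances), " instance values",
      if (length(x$unvalued)) paste0(", ", length(x$unvalued), " unvalued"),
      "\n", sep = "")
  invisible(x)
}

#' Check that structural granularity values increase from part to whole
#'
#' A consistent assignment orders every proper parthood pair: the
#' representative value of a part is strictly below that of its whole.
#' Countable-parthood (resolution) pairs are exempt up to equality, since
#' the countable representation may carry a value equal to or less than the
#' non-countable one.
#'
#' @param p a `partonomy`.
#' @param v a `value_map` from [propagate_framework_values()].
#' @return A `lint_report`; one finding per value-ordering violation.
#' @export
check_value_monotonicity <- function(p, v) {
  stopifnot(inherits(p, "partonomy"), inherits(v, "value_map"))
  cl <- closure_matrix(p)
  inst <- v$instances
  valued <- inst$instance
  countable_pairs <- p$edges[p$edges$relation == "countable_proper_part_of",
                             c("child", "parent"), drop = FALSE]
  rows <- list()
  idx <- which(cl$mat, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    child <- cl$ids[idx[k, 1]]
    parent <- cl$ids[idx[k, 2]]
    if (!(child %in% valued) || !(parent %in% valued)) next
    rc <- inst[inst$instance == child, ][1, ]
    rp_ <- inst[inst$instance == parent, ][1, ]
    a <- rat(rc$rep_num, rc$rep_den)
    b <- rat(rp_$rep_num, rp_$rep_den)
    cmp <- rat_cmp(a, b)
    is_countable <- any(countable_pairs$child == child &
                          countable_pairs$parent == parent)
    if ((is_countable && cmp > 0) || (!is_countable && cmp >= 0)) {
      rows[[length(rows) + 1L]] <- lint_row(
        "value_monotonicity", "error",
        paste0("part ", child, " does not carry a lower value than ", parent),
        c(child, parent))
    }
  }
  new_lint_report(rows)
}

#' Build a scale-dependent size perspective
#'
#' Material entities can be granulated purely by a measured quantity
#' (weight, volume, maximal width, ...): ascending thresholds demarcate the
#' levels and instances are binned into half-open intervals, the lowest
#' level collecting the smallest instances. Such perspectives apply to
#' instances only and carry scale granularity values (the bin index), not
#' structural ones.
#'
#' @param p a `partonomy` with `measures`.
#' @param quantity measured quantity name to granulate by.
#' @param thresholds strictly ascending numeric thresholds (at least one,
#'   yielding at least two levels).
#' @return A `granularity_perspective` (ptype `"size_scale"`) whose levels
#'   carry `scale_value` slots; instances lacking the measure are excluded
#'   and listed in the `excluded` attribute. Empty levels are a perspective
#'   error.
#' @export
build_size_perspective <- function(p, quantity, thresholds) {
  stopifnot(inherits(p, "partonomy"), length(thresholds) >= 1)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("parameter error: thresholds must be strictly ascending")
  }
  m <- p$measures[p$measures$quantity == quantity, , drop = FALSE]
  if (!nrow(m)) {
    stop("perspective error: no measures for quantity '", quantity, "'")
  }
  excluded <- setdiff(p$instances$id, m$instance)
  bin <- findInterval(m$value, thresholds) + 1L
  n_lev <- length(thresholds) + 1L
  empties <- setdiff(seq_len(n_lev), unique(bin))
  if (length(empties)) {
    stop("perspective error: empty size levels: ",
         paste(empties, collapse = ", "))
  }
  levels <- lapply(seq_len(n_lev), function(k) {
    list(content = sort(m$instance[bin == k]), content_kind = "instance",
         scale_value = k)
  })
  pp <- new_perspective(paste0("size_scale:", quantity), "size_scale",
                        levels, instance_content = TRUE)
  attr(pp, "excluded") <- excluded
  attr(pp, "quantity") <- quantity
  pp
}
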