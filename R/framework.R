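#' Assemble the integrated granularity framework of a partonomy
#'
#' Builds the compositional-object backbone, the additional compositional
#' perspectives, the basic spatial perspectives, the resolution
#' perspectives and the instance-only fiat chain perspectives, then detects
#' overcrossings (pairs of levels of distinct perspectives with shared
#' content). Overcrossing is the mechanism that integrates the perspectives
#' into one framework with the backbone at its center.
#'
#' @param p a `partonomy`.
#' @param size_perspectives optional list of perspectives from
#'   [build_size_perspective()] to include.
#' @return An object of class `granularity_framework`: fields
#'   `perspectives` (named list), `rl` (adjacent-level pairs per
#'   perspective), `rp` (overcrossing perspective pairs), `overcross`
#'   (level-pair detail), `re` (level-in-perspective containment) and
#'   `partonomy`.
#' @examples
#' f <- build_framework(fixture("fig11_organ"))
#' names(f$perspectives)
#' @export
build_framework <- function(p, size_perspectives = list()) {
  stopifnot(inherits(p, "partonomy"))
  co <- build_co_perspective(p)
  persp <- c(list(co),
             build_additional_compositional(p, co),
             build_spatial_basic(p, co),
             build_resolution(p),
             build_fiat_chain(p),
             size_perspectives)
  names(persp) <- vapply(persp, `[[`, character(1), "id")
  rl <- do.call(rbind, lapply(persp, function(pp) {
    n <- length(pp$levels)
    if (n < 2) return(NULL)
    data.frame(perspective = pp$id,
               lower = vapply(pp$levels[-n], `[[`, character(1), "id"),
               upper = vapply(pp$levels[-1], `[[`, character(1), "id"),
               stringsAsFactors = FALSE)
  }))
  rownames(rl) <- NULL
  re <- do.call(rbind, lapply(persp, function(pp) {
    data.frame(level = vapply(pp$levels, `[[`, character(1), "id"),
               perspective = pp$id, stringsAsFactors = FALSE)
  }))
  rownames(re) <- NULL
  f <- structure(list(perspectives = persp, rl = rl, rp = NULL,
                      overcross = NULL, re = re, partonomy = p,
                      co = co$id),
                 class = "granularity_framework")
  oc <- detect_overcross(f)
  f$overcross <- oc
  f$rp <- unique(oc[c("p1", "p2")])
  rownames(f$rp) <- NULL
  f
}

#' @export
print.granularity_framework <- function(x, ...) {
  cat("<granularity framework>: ", length(x$perspectives),
      " perspectives, ", nrow(x$re), " levels, ",
      nrow(x$rp %||% data.frame()), " overcrossing pairs\n", sep = "")
  for (pp in x$perspectives) {
    cat("  - ", pp$id, " (", length(pp$levels), " levels)\n", sep = "")
  }
  invisible(x)
}

## Expanded content for overcross comparison: representation types alias
## their represented target; instance content aliases its types. Without the
## aliases the claimed overcrossings (resolution <-> spatial/compositional,
## fiat chains <-> spatial) would be invisible to raw intersection.
level_content_expanded <- function(lv, p) {
  content <- lv$content
  if (identical(lv$content_kind, "instance")) {
    content <- unique(c(content, instance_type(p, content)))
  }
  tgt <- p$types$rep_target[match(content, p$types$id)]
  unique(c(content, tgt[!is.na(tgt)]))
}

#' Detect overcrossing levels between perspectives
#'
#' Two levels of distinct perspectives overcross when they share content;
#' overcrossing levels make their perspectives overcross (the RP relation,
#' irreflexive and symmetric). The full set of overcrossings is what knits
#' the perspectives into a connected framework.
#'
#' @param f a `granularity_framework`.
#' @return Data frame with columns `p1`, `p2` (perspective ids, `p1 < p2`),
#'   `l1`, `l2` (level ids), `shared` (comma-collapsed shared content).
#' @export
detect_overcross <- function(f) {
  stopifnot(inherits(f, "granularity_framework"))
  p <- f$partonomy
  persp <- f$perspectives
  rows <- list()
  ids <- names(persp)
  for (i in seq_along(persp)) {
    for (j in seq_along(persp)) {
      if (j <= i) next
      for (li in persp[[i]]$levels) {
        ci <- level_content_expanded(li, p)
        for (lj in persp[[j]]$levels) {
          shared <- intersect(ci, level_content_expanded(lj, p))
          if (length(shared)) {
            rows[[length(rows) + 1L]] <- data.frame(
              p1 = ids[i], p2 = ids[j], l1 = li$id, l2 = lj$id,
              shared = paste(sort(shared), collapse = ","),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(p1 = character(), p2 = character(),
                      l1 = character(), l2 = character(),
                      shared = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

lint_row <- function(rule, severity, message, witnesses = "") {
  data.frame(rule = rule, severity = severity, message = message,
             witnesses = paste(witnesses, collapse = ", "),
             stringsAsFactors = FALSE)
}

new_lint_report <- function(rows) {
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rule = character(), severity = character(),
               message = character(), witnesses = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("lint_report", class(out))
  out
}

#' @export
print.lint_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("<lint report>: clean\n")
    return(invisible(x))
  }
  cat("<lint report>: ", nrow(x), " finding(s)\n", sep = "")
  w <- x$witnesses %||% rep("", nrow(x))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %s: %s", x$severity[i] %||% "", x$rule[i],
                x$message[i] %||% ""))
    if (!is.na(w[i]) && nzchar(w[i])) cat(" (", w[i], ")", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Validate the structural consistency of a granularity framework
#'
#' Checks the framework-level requirements: every perspective has at least
#' two granularity levels; each level is contained in exactly one
#' perspective; within one perspective no entity occupies two levels; the
#' overcross relation RP is irreflexive and symmetric; the containment
#' relation RE is acyclic; and no perspective is cut off from the
#' compositional-object backbone (every perspective must be reachable via
#' chains of overcrossings).
#'
#' @param f a `granularity_framework`.
#' @return A `lint_report` (zero rows when consistent).
#' @export
validate_framework <- function(f) {
  stopifnot(inherits(f, "granularity_framework"))
  rows <- list()
  for (pp in f$perspectives) {
    if (length(pp$levels) < 2) {
      rows[[length(rows) + 1L]] <- lint_row(
        "keet_two_levels", "error",
        paste0("perspective ", pp$id, " has fewer than two levels"), pp$id)
    }
    raw <- unlist(lapply(pp$levels, `[[`, "content"))
    dup <- unique(raw[duplicated(raw)])
    if (length(dup)) {
      rows[[length(rows) + 1L]] <- lint_row(
        "keet_unique_level", "error",
        paste0("entities occupy two levels of perspective ", pp$id), dup)
    }
  }
  dup_lv <- f$re$level[duplicated(f$re$level)]
  if (length(dup_lv)) {
    rows[[length(rows) + 1L]] <- lint_row(
      "level_single_perspective", "error",
      "levels contained in more than one perspective", unique(dup_lv))
  }
  if (!is.null(f$rp) && nrow(f$rp)) {
    refl <- f$rp$p1 == f$rp$p2
    if (any(refl)) {
      rows[[length(rows) + 1L]] <- lint_row(
        "rp_irreflexive", "error", "RP relates a perspective to itself",
        unique(f$rp$p1[refl]))
    }
  }
  ## RE: level -> perspective -> domain; a cycle would need a perspective id
  ## reused as a level id
  clash <- intersect(f$re$level, f$re$perspective)
  if (length(clash)) {
    rows[[length(rows) + 1L]] <- lint_row(
      "re_acyclic", "error", "containment relation RE has a cycle", clash)
  }
  ## connectivity via overcrossing from the backbone
  reach <- f$co
  repeat {
    nxt <- unique(c(reach,
                    f$rp$p2[f$rp$p1 %in% reach],
                    f$rp$p1[f$rp$p2 %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  cut_off <- setdiff(names(f$perspectives), reach)
  if (length(cut_off)) {
    rows[[length(rows) + 1L]] <- lint_row(
      "framework_connected", "error",
      "perspectives unreachable from the compositional-object backbone",
      cut_off)
  }
  new_lint_report(rows)
}

#' Check the numbered instance-level granulation rules
#'
#' Audits the instances of a partonomy against the numbered rules that a
#' cumulative-constitutively organized granulation must satisfy, grouped by
#' the perspective family they belong to. Backbone (CO) rules: (1) an
#' object need not be part of an object of the adjacent higher level
#' (informational, never violated); (2) every object above the lowest CO
#' level has at least two object proper parts; (3) all objects of a
#' granulation are proper parts of one maximum object. Additional
#' compositional rules: (1) every aggregate instance has an object proper
#' part at its name-giving type's CO level; (2) informational; (3) every
#' fiat instance has an object proper part at a CO level *below* its
#' name-giving type's level. Spatial rules: (1) informational; (2) every
#' fiat instance has an object ancestor, and its name-giving level is
#' consistent with its minimal host level (equal to it, or one below it for
#' aggregates-with-matrix named after their member objects); (3) every
#' object with any fiat proper part has at least two; (4) every fiat
#' instance is a proper part of the maximum object.
#'
#' @param p a `partonomy`.
#' @param f its `granularity_framework` (supplies the CO layering).
#' @return A `lint_report`; informational rules appear with severity
#'   `"info"`, violations with severity `"error"`.
#' @export
check_instance_rules <- function(p, f) {
  stopifnot(inherits(p, "partonomy"), inherits(f, "granularity_framework"))
  co <- f$perspectives[[f$co]]
  cl <- closure_matrix(p)
  kinds <- stats::setNames(instance_kind(p, p$instances$id), p$instances$id)
  ilvl <- co_level_of_instances(p, co)
  objs <- names(kinds)[kinds == "object"]
  fiats <- names(kinds)[kinds == "fiat_object_part"]
  aggs <- names(kinds)[kinds == "object_aggregate"]
  rows <- list()
  note <- function(rule, severity, message, witnesses = "") {
    rows[[length(rows) + 1L]] <<- lint_row(rule, severity, message, witnesses)
  }

  note("co_rule_1", "info",
       "objects may skip the adjacent higher CO level (cumulative organization)")
  in_co <- objs[!is.na(ilvl[objs])]
  above_lowest <- in_co[ilvl[in_co] > 1]
  bad <- above_lowest[vapply(above_lowest, function(x) {
    parts <- cl$ids[cl$mat[, x]]
    sum(kinds[parts] == "object") < 2
  }, logical(1))]
  if (length(bad)) {
    note("co_rule_2", "error",
         "objects above the lowest CO level with fewer than two object proper parts",
         bad)
  }
  maxima <- in_co[vapply(in_co, function(x) {
    anc <- cl$ids[cl$mat[x, ]]
    !any(kinds[anc] == "object")
  }, logical(1))]
  if (length(maxima) != 1) {
    note("co_rule_3", "error",
         "granulation does not have a unique maximum object", maxima)
  } else {
    others <- setdiff(in_co, maxima)
    notpart <- others[!cl$mat[others, maxima]]
    if (length(notpart)) {
      note("co_rule_3", "error",
           "objects that are not proper parts of the maximum object", notpart)
    }
  }
  max_obj <- if (length(maxima) == 1) maxima else NA_character_

  ng_level <- function(ids) {
    tid <- instance_type(p, ids)
    ng <- p$types$name_giving[match(tid, p$types$id)]
    lvl <- co_level_of_types(co)
    unname(lvl[ng])
  }
  if (length(aggs)) {
    ngl <- ng_level(aggs)
    bad <- aggs[vapply(seq_along(aggs), function(i) {
      if (is.na(ngl[i])) return(TRUE)
      parts <- cl$ids[cl$mat[, aggs[i]]]
      parts <- parts[kinds[parts] == "object"]
      !any(!is.na(ilvl[parts]) & ilvl[parts] == ngl[i])
    }, logical(1))]
    if (length(bad)) {
      note("comp_rule_1", "error",
           "aggregates without an object proper part at their name-giving CO level",
           bad)
    }
  }
  note("comp_rule_2", "info",
       "objects at a counterpart's CO level need not be parts of any counterpart")
  if (length(fiats)) {
    ngl <- ng_level(fiats)
    bad <- fiats[vapply(seq_along(fiats), function(i) {
      if (is.na(ngl[i])) return(TRUE)
      parts <- cl$ids[cl$mat[, fiats[i]]]
      parts <- parts[kinds[parts] == "object"]
      !any(!is.na(ilvl[parts]) & ilvl[parts] < ngl[i])
    }, logical(1))]
    if (length(bad)) {
      note("comp_rule_3", "error",
           "fiat parts without an object proper part below their name-giving CO level",
           bad)
    }
  }
  note("spatial_rule_1", "info",
       "fiat parts may skip the adjacent higher CO level host")
  if (length(fiats)) {
    ngl <- ng_level(fiats)
    bad <- fiats[vapply(seq_along(fiats), function(i) {
      hosts <- cl$ids[cl$mat[fiats[i], ]]
      hosts <- hosts[kinds[hosts] == "object"]
      hl <- ilvl[hosts]
      if (!length(hosts) || all(is.na(hl))) return(TRUE)
      h <- min(hl, na.rm = TRUE)
      is.na(ngl[i]) || !(ngl[i] %in% c(h, h - 1L))
    }, logical(1))]
    if (length(bad)) {
      note("spatial_rule_2", "error",
           "fiat parts without an object host consistent with their name-giving level",
           bad)
    }
    with_fiat <- c(objs, aggs)[vapply(c(objs, aggs), function(x) {
      parts <- cl$ids[cl$mat[, x]]
      any(kinds[parts] == "fiat_object_part")
    }, logical(1))]
    bad <- with_fiat[vapply(with_fiat, function(x) {
      parts <- cl$ids[cl$mat[, x]]
      sum(kinds[parts] == "fiat_object_part") < 2
    }, logical(1))]
    if (length(bad)) {
      note("spatial_rule_3", "error",
           "hosts with exactly one fiat proper part (at least two required)",
           bad)
    }
    if (!is.na(max_obj)) {
      bad <- fiats[!cl$mat[fiats, max_obj]]
      if (length(bad)) {
        note("spatial_rule_4", "error",
             "fiat parts that are not proper parts of the maximum object", bad)
      }
    }
  }
  new_lint_report(rows)
}
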