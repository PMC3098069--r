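#' Represent an external granularity scheme
#'
#' An external scheme is a published ordered list of granularity levels
#' (GRAN = G1 < G2 < ... < Gn, fine to coarse) with member types per level,
#' as found in anatomy ontologies. Kind annotations record what each
#' level's members actually instantiate (object, fiat object part, object
#' aggregate), which is what the consistency lints audit.
#'
#' @param name scheme name.
#' @param levels list of `list(label, kind, members)` ordered fine to
#'   coarse; `members` is a character vector of type ids (defaults to the
#'   label itself).
#' @param declared the perspective family the scheme claims to be
#'   (`"compositional"`, `"spatial"`, `"mixed"` or `"unspecified"`).
#' @return An object of class `external_scheme`.
#' @examples
#' fixture("kumar_human")
#' @export
external_scheme <- function(name, levels,
                            declared = c("unspecified", "compositional",
                                         "spatial", "mixed")) {
  declared <- match.arg(declared)
  stopifnot(is.list(levels), length(levels) >= 1)
  levels <- lapply(levels, function(lv) {
    stopifnot(!is.null(lv$label))
    lv$kind <- match.arg(lv$kind, ENTITY_KINDS)
    lv$members <- lv$members %||% lv$label
    lv
  })
  labels <- vapply(levels, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("scheme error: duplicated level labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(name = name, declared = declared, levels = levels),
            class = "external_scheme")
}

#' @export
print.external_scheme <- function(x, ...) {
  labels <- vapply(x$levels, `[[`, character(1), "label")
  cat("<external scheme> ", x$name, " (", x$declared, ", ",
      length(labels), " levels)\n  ", paste(labels, collapse = " < "),
      "\n", sep = "")
  invisible(x)
}

#' Look up the granularity level of a type in a scheme (the gr function)
#'
#' The granularity function gr maps each member type onto exactly one level
#' of the ordered level set. A type unknown to the scheme is a lookup
#' error; a type listed in two levels violates the single-return contract
#' of gr and is a scheme error.
#'
#' @param scheme an `external_scheme`.
#' @param t type id.
#' @return The level label (character scalar).
#' @examples
#' gr_lookup(fixture("kumar_human"), "Cell")
#' @export
gr_lookup <- function(scheme, t) {
  stopifnot(inherits(scheme, "external_scheme"))
  hits <- which(vapply(scheme$levels, function(lv) t %in% lv$members,
                       logical(1)))
  if (length(hits) == 0) {
    stop("lookup error: type ", t, " is not a member of any level of ",
         scheme$name)
  }
  if (length(hits) > 1) {
    stop("scheme error: type ", t, " resides in more than one level of ",
         scheme$name, " (gr must return a single level)")
  }
  scheme$levels[[hits]]$label
}

scheme_level_instances <- function(scheme, p) {
  lapply(scheme$levels, function(lv) {
    p$instances$id[p$instances$type_id %in% lv$members]
  })
}

#' Audit a scheme against the seven granularity principles
#'
#' Checks an external scheme, instantiated over a partonomy, against the
#' seven classical granularity principles plus the two more general
#' part/whole principles. The report is total: every principle appears
#' exactly once per run. P1: each level is determined by at least one
#' grain type. P2: every grain instance is a proper part of some grain of
#' the next higher level. P3: the grains of every level sum exhaustively
#' to the whole (the principle that cumulative-constitutive organization
#' systematically breaks: e.g. summing all cells misses the extracellular
#' matrix). P4: grains need not be homogeneous in size - a non-requirement,
#' reported informationally. P5: grains must be smaller than the wholes
#' they are part of; requires an explicit measure quantity, otherwise not
#' evaluable. P6 (causal laws per level) and P7 (entities changing level
#' over time) are outside structural scope and reported as not evaluable.
#' G1: every instance below the top level is part of some instance at a
#' higher level. G2: every instance above the bottom level has a part at
#' some lower level.
#'
#' @param scheme an `external_scheme` whose member types are instantiated
#'   in `p`.
#' @param p a `partonomy`.
#' @param size_quantity optional measure quantity name used to evaluate P5.
#' @return A `lint_report` with exactly nine rows (`kumar_p1` ...
#'   `kumar_p7`, `general_g1`, `general_g2`) carrying a `status` column
#'   (`pass`, `fail`, `not_evaluable`).
#' @export
check_kumar_principles <- function(scheme, p, size_quantity = NULL) {
  stopifnot(inherits(scheme, "external_scheme"), inherits(p, "partonomy"))
  cl <- closure_matrix(p)
  inst <- scheme_level_instances(scheme, p)
  n <- length(scheme$levels)
  labels <- vapply(scheme$levels, `[[`, character(1), "label")
  rows <- list()
  finding <- function(rule, status, message, witnesses = "") {
    row <- lint_row(rule,
                    switch(status, fail = "error", pass = "info",
                           not_evaluable = "not_evaluable"),
                    message, witnesses)
    row$status <- status
    rows[[length(rows) + 1L]] <<- row
  }

  empty <- labels[vapply(scheme$levels, function(lv) length(lv$members) == 0,
                         logical(1))]
  finding("kumar_p1", if (length(empty)) "fail" else "pass",
          "each level is determined by at least one grain type", empty)

  p2_bad <- character(0)
  for (k in seq_len(n - 1)) {
    up <- inst[[k + 1]]
    for (x in inst[[k]]) {
      if (!length(up) || !any(cl$mat[x, up])) p2_bad <- c(p2_bad, x)
    }
  }
  finding("kumar_p2", if (length(p2_bad)) "fail" else "pass",
          "grains are parts of grains of the next higher level", p2_bad)

  top <- unlist(inst[n])
  whole <- if (length(top) == 1) top else {
    roots <- cl$ids[rowSums(cl$mat) == 0 & colSums(cl$mat) > 0]
    if (length(roots) == 1) roots else NA_character_
  }
  p3_bad <- character(0)
  if (is.na(whole)) {
    finding("kumar_p3", "not_evaluable",
            "no unique whole found to sum against")
  } else {
    for (k in seq_len(n - 1)) {
      members <- setdiff(inst[[k]], whole)
      if (!length(members)) next
      res <- tryCatch(exhaustive_sum_check(members, whole, p),
                      error = function(e) list(ok = FALSE, missing = "?"))
      if (!res$ok) p3_bad <- c(p3_bad, labels[k])
    }
    finding("kumar_p3", if (length(p3_bad)) "fail" else "pass",
            "summing all grains of each level yields the whole", p3_bad)
  }

  finding("kumar_p4", "pass",
          "grains need not be of the same size (non-requirement)")

  if (is.null(size_quantity)) {
    finding("kumar_p5", "not_evaluable",
            "size comparison requires an explicit measure quantity")
  } else {
    m <- p$measures[p$measures$quantity == size_quantity, , drop = FALSE]
    sz <- stats::setNames(m$value, m$instance)
    p5_bad <- character(0)
    for (k in seq_len(n - 1)) {
      up <- inst[[k + 1]]
      for (x in inst[[k]]) {
        wholes <- up[cl$mat[x, up]]
        for (w in wholes) {
          if (!is.na(sz[x]) && !is.na(sz[w]) && sz[x] >= sz[w]) {
            p5_bad <- c(p5_bad, paste0(x, ">=", w))
          }
        }
      }
    }
    finding("kumar_p5", if (length(p5_bad)) "fail" else "pass",
            "grains are smaller than the wholes they are parts of", p5_bad)
  }

  finding("kumar_p6", "not_evaluable",
          "causal-law content is outside structural scope")
  finding("kumar_p7", "not_evaluable",
          "temporal level change is outside structural scope")

  g1_bad <- character(0)
  for (k in seq_len(n - 1)) {
    above <- unique(unlist(inst[seq(k + 1, n)]))
    for (x in inst[[k]]) {
      if (!any(cl$mat[x, setdiff(above, x)])) g1_bad <- c(g1_bad, x)
    }
  }
  finding("general_g1", if (length(g1_bad)) "fail" else "pass",
          "every non-top instance is part of some higher-level instance",
          g1_bad)

  g2_bad <- character(0)
  for (k in seq_len(n)[-1]) {
    below <- unique(unlist(inst[seq_len(k - 1)]))
    for (x in inst[[k]]) {
      if (!any(cl$mat[setdiff(below, x), x])) g2_bad <- c(g2_bad, x)
    }
  }
  finding("general_g2", if (length(g2_bad)) "fail" else "pass",
          "every non-bottom instance has a part at some lower level",
          g2_bad)

  new_lint_report(rows)
}

#' Lint a scheme for mixed perspectives and misused aggregates
#'
#' Two structural defects recur in published granularity schemes. First, a
#' scheme declared compositional may interleave levels whose members are
#' actually fiat object parts with genuine object levels - a mixture of
#' compositional and spatial partitions inside one perspective, which is
#' formally inconsistent (`mixed_perspective`). Second, a type tagged as an
#' object aggregate whose instances contain fiat parts or foreign objects
#' (e.g. a "cell aggregate" whose instances include the extracellular
#' matrix between the cells) is really a fiat object part and should be
#' renamed "<aggregate> with <foreign part>" and re-kinded
#' (`aggregate_misuse`).
#'
#' @param scheme an `external_scheme` with kind annotations.
#' @param p optional `partonomy` for instance-based aggregate checks.
#' @return A `lint_report`.
#' @export
check_scheme_consistency <- function(scheme, p = NULL) {
  stopifnot(inherits(scheme, "external_scheme"))
  rows <- list()
  kinds <- vapply(scheme$levels, `[[`, character(1), "kind")
  labels <- vapply(scheme$levels, `[[`, character(1), "label")
  if (scheme$declared == "compositional" &&
      any(kinds == "fiat_object_part") &&
      any(kinds %in% c("object", "object_aggregate"))) {
    rows[[length(rows) + 1L]] <- lint_row(
      "mixed_perspective", "error",
      paste0("scheme ", scheme$name, " declared compositional but contains ",
             "fiat-part levels alongside object levels"),
      labels[kinds == "fiat_object_part"])
  }
  if (scheme$declared == "spatial" && any(kinds != "fiat_object_part")) {
    rows[[length(rows) + 1L]] <- lint_row(
      "mixed_perspective", "error",
      paste0("scheme ", scheme$name, " declared spatial but contains ",
             "non-fiat levels"),
      labels[kinds != "fiat_object_part"])
  }
  if (!is.null(p)) {
    stopifnot(inherits(p, "partonomy"))
    cl <- closure_matrix(p)
    kind_of <- stats::setNames(instance_kind(p, p$instances$id),
                               p$instances$id)
    aggs <- p$types[p$types$kind == "object_aggregate", , drop = FALSE]
    for (i in seq_len(nrow(aggs))) {
      tid <- aggs$id[i]
      ng <- aggs$name_giving[i]
      inst <- p$instances$id[p$instances$type_id == tid]
      foreign <- character(0)
      for (x in inst) {
        parts <- cl$ids[cl$mat[, x]]
        bad <- parts[kind_of[parts] == "fiat_object_part" |
                       (kind_of[parts] == "object" &
                          instance_type(p, parts) != ng)]
        foreign <- c(foreign, bad)
      }
      if (length(foreign)) {
        ftypes <- unique(instance_type(p, foreign))
        flabels <- p$types$label[match(ftypes, p$types$id)]
        rows[[length(rows) + 1L]] <- lint_row(
          "aggregate_misuse", "error",
          paste0("type ", tid, " is tagged object_aggregate but its ",
                 "instances contain foreign parts; suggest re-kinding as ",
                 "fiat_object_part and renaming to '",
                 aggs$label[i], " with ", paste(flabels, collapse = "/"),
                 "'"),
          unique(foreign))
      }
    }
  }
  new_lint_report(rows)
}

#' Derive an external scheme from a partonomy's backbone
#'
#' Convenience helper turning the compositional-object levels of a
#' partonomy into an [external_scheme()] (fine to coarse, object kind, one
#' member set per level), useful for auditing generated partonomies with
#' [check_kumar_principles()].
#'
#' @param p a `partonomy`.
#' @param name scheme name.
#' @return An `external_scheme`.
#' @export
co_scheme <- function(p, name = "co_backbone") {
  co <- build_co_perspective(p)
  levels <- lapply(co$levels, function(lv) {
    list(label = paste0("level_", lv$index), kind = "object",
         members = lv$content)
  })
  external_scheme(name, levels, declared = "compositional")
}
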