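## Perspective construction: the compositional-object backbone, the
## two-level compositional/spatial/resolution perspectives hung off it, and
## instance-only fiat-of-fiat chain perspectives.

PERSPECTIVE_TYPES <- c(
  compositional_object            = "nrG",
  compositional_object_of_fiat    = "nrG",
  compositional_aggregate_of_fiat = "nrG",
  compositional_object_of_aggregate = "nrG",
  compositional_aggregate_of_object = "nrG",
  compositional_aggregate_of_aggregate = "nrG",
  spatial_fiat_of_object          = "nrG",
  spatial_fiat_of_aggregate       = "nrG",
  resolution_of_aggregate         = "sgrG",
  resolution_of_aggregate_with_fiat = "sgrG",
  spatial_fiat_of_fiat            = "nrG",
  size_scale                      = "scale")

new_perspective <- function(id, ptype, levels, anchor_co_level = NA_integer_,
                            counterpart = NA_character_,
                            instance_content = FALSE) {
  stopifnot(ptype %in% names(PERSPECTIVE_TYPES))
  stopifnot(all(vapply(levels, function(lv) length(lv$content) > 0,
                       logical(1))))
  levels <- lapply(seq_along(levels), function(i) {
    lv <- levels[[i]]
    lv$index <- i
    lv$id <- paste0(id, "/L", i)
    lv
  })
  structure(list(id = id, ptype = ptype,
                 granularity_type = unname(PERSPECTIVE_TYPES[ptype]),
                 anchor_co_level = anchor_co_level,
                 counterpart = counterpart,
                 instance_content = instance_content,
                 levels = levels),
            class = "granularity_perspective")
}

#' @export
print.granularity_perspective <- function(x, ...) {
  cat("<granularity perspective> ", x$id, " [", x$ptype, ", ",
      x$granularity_type, "]\n", sep = "")
  for (lv in rev(x$levels)) {
    cat("  level ", lv$index, ": ",
        paste(lv$content, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Classify a parthood edge into a perspective type
#'
#' The kind tags of an edge's endpoints, together with its relation,
#' determine which granulation criterion it satisfies and hence which type
#' of granularity perspective it contributes to: object-in-object edges are
#' compositional-object, object-in-fiat edges feed the additional
#' compositional perspectives, fiat-in-object edges the spatial ones,
#' fiat-in-fiat edges the instance-only fiat chains, and countable
#' parthood edges the scale-dependent resolution perspectives (whose tag is
#' chosen by the kind of the represented entity).
#'
#' @param e a one-row edge data frame (columns `child`, `relation`,
#'   `parent`).
#' @param p a `partonomy`.
#' @return A perspective type tag (character scalar).
#' @examples
#' p <- fixture("fig11_organ")
#' classify_edge(p$edges[1, ], p)
#' @export
classify_edge <- function(e, p) {
  stopifnot(nrow(e) == 1)
  classify_edges(p, e)$tag
}

classify_edges <- function(p, edges = p$edges) {
  if (nrow(edges) == 0) {
    return(cbind(edges, data.frame(tag = character())))
  }
  ck <- instance_kind(p, edges$child)
  pk <- instance_kind(p, edges$parent)
  tag <- character(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    if (edges$relation[i] == "countable_proper_part_of") {
      rep_t <- p$types$rep_target[match(instance_type(p, edges$child[i]),
                                        p$types$id)]
      if (is.na(rep_t)) {
        stop("classification error: countable parthood edge whose child ",
             "type declares no represented entity: ", edges$child[i])
      }
      rk <- p$types$kind[match(rep_t, p$types$id)]
      tag[i] <- if (rk == "object_aggregate") "resolution_of_aggregate"
                else "resolution_of_aggregate_with_fiat"
    } else {
      tag[i] <- switch(
        paste(ck[i], pk[i], sep = ">"),
        "object>object"                       = "compositional_object",
        "object>fiat_object_part"             = "compositional_object_of_fiat",
        "object_aggregate>fiat_object_part"   = "compositional_aggregate_of_fiat",
        "object>object_aggregate"             = "compositional_object_of_aggregate",
        "object_aggregate>object"             = "compositional_aggregate_of_object",
        "object_aggregate>object_aggregate"   = "compositional_aggregate_of_aggregate",
        "fiat_object_part>object"             = "spatial_fiat_of_object",
        "fiat_object_part>object_aggregate"   = "spatial_fiat_of_aggregate",
        "fiat_object_part>fiat_object_part"   = "spatial_fiat_of_fiat",
        stop("classification error: edge ", edges$child[i], " < ",
             edges$parent[i], " (", ck[i], " in ", pk[i],
             ") matches no granulation criterion"))
    }
  }
  cbind(edges, data.frame(tag = tag, stringsAsFactors = FALSE))
}

## Object-restricted "direct" parthood: the transitive reduction of the
## object-only closure, so object-object adjacency survives interposed fiat
## parts (a cell inside fiat organ parts inside an organ is still an
## object-direct part of the organ).
object_direct_edges <- function(p, cl = closure_matrix(p)) {
  if (any(diag(cl$mat))) stop("order error: partonomy is cyclic")
  objs <- p$instances$id[instance_kind(p, p$instances$id) == "object"]
  sub <- cl$mat[objs, objs, drop = FALSE]
  reduction_from_matrix(sub, objs)
}

#' Build the compositional-object backbone perspective
#'
#' The compositional object (CO) perspective granulates the object subtypes
#' of a partonomy by direct proper parthood between objects. Its levels are
#' ordered bottom-up by longest-path layering: the level of an object
#' subtype is 1 plus the longest chain of object-subtype direct parthood
#' beneath it. Longest-path layering keeps e.g. 'molecule' at the bottom
#' even when some molecules are direct parts of organs, as happens under
#' cumulative organization.
#'
#' @param p a `partonomy` with at least two object subtypes connected by
#'   (derived) direct proper parthood; otherwise a perspective error.
#' @return A `granularity_perspective` with type content, plus an attribute
#'   `type_levels` (named integer: CO level per object subtype).
#' @examples
#' build_co_perspective(fixture("fig5_co"))
#' @export
build_co_perspective <- function(p) {
  stopifnot(inherits(p, "partonomy"))
  od <- object_direct_edges(p)
  tchild <- instance_type(p, od$child)
  tparent <- instance_type(p, od$parent)
  keep <- tchild != tparent
  tedges <- unique(data.frame(child = tchild[keep], parent = tparent[keep],
                              stringsAsFactors = FALSE))
  if (nrow(tedges) == 0) {
    stop("perspective error: fewer than two object subtypes connected by ",
         "direct proper parthood")
  }
  tys <- unique(c(tedges$child, tedges$parent))
  tcl <- closure_matrix(data.frame(child = tedges$child,
                                   relation = "proper_part_of",
                                   parent = tedges$parent), ids = tys)
  if (any(diag(tcl$mat))) {
    stop("perspective error: derived object-subtype parthood is cyclic")
  }
  ## longest chain of object subtypes strictly below each subtype
  lvl <- stats::setNames(rep(NA_integer_, length(tys)), tys)
  assign_level <- function(tp) {
    if (!is.na(lvl[[tp]])) return(lvl[[tp]])
    below <- tedges$child[tedges$parent == tp]
    v <- if (length(below)) {
      1L + max(vapply(below, assign_level, integer(1)))
    } else 1L
    lvl[[tp]] <<- v
    v
  }
  for (tp in tys) assign_level(tp)
  n <- max(lvl)
  levels <- lapply(seq_len(n), function(k) {
    list(content = sort(names(lvl)[lvl == k]), content_kind = "type")
  })
  if (any(vapply(levels, function(lv) length(lv$content) == 0, logical(1)))) {
    ## cannot happen with longest-path layering, but guard anyway
    stop("perspective error: empty CO level")
  }
  co <- new_perspective("co", "compositional_object", levels)
  attr(co, "type_levels") <- lvl
  co
}

co_level_of_types <- function(co) attr(co, "type_levels")

## CO level of each instance (NA for non-objects / objects outside CO)
co_level_of_instances <- function(p, co) {
  lvl <- co_level_of_types(co)
  out <- lvl[match(p$instances$type_id, names(lvl))]
  stats::setNames(as.integer(out), p$instances$id)
}

#' Build the additional compositional perspectives
#'
#' For each fiat-object-part or object-aggregate subtype that has objects
#' (or aggregates) as proper parts, a two-level perspective is built: the
#' lower level holds the object subtypes at the counterpart's anchoring CO
#' level, the upper level the counterpart subtype. There are as many such
#' perspectives as there are distinct (perspective type, anchoring CO
#' level, counterpart subtype) combinations; the anchor is the CO level of
#' the counterpart's name-giving object type. The
#' aggregate-of-aggregate variant may exceed two levels and is layered like
#' the backbone.
#'
#' @param p a `partonomy`.
#' @param co the backbone perspective from [build_co_perspective()].
#' @return List of `granularity_perspective` objects (possibly empty).
#' @export
build_additional_compositional <- function(p, co) {
  cls <- classify_edges(p)
  out <- list()
  comp_tags <- c("compositional_object_of_fiat",
                 "compositional_aggregate_of_fiat",
                 "compositional_object_of_aggregate",
                 "compositional_aggregate_of_object")
  lvl <- co_level_of_types(co)
  for (tag in comp_tags) {
    sel <- cls[cls$tag == tag, , drop = FALSE]
    if (!nrow(sel)) next
    ## counterpart = the fiat/aggregate endpoint; parts sit in the lower level
    if (tag %in% c("compositional_object_of_fiat",
                   "compositional_aggregate_of_fiat",
                   "compositional_object_of_aggregate")) {
      counterpart_of <- instance_type(p, sel$parent)
      part_type <- instance_type(p, sel$child)
      counterpart_upper <- TRUE
    } else {  # aggregate parts of an object
      counterpart_of <- instance_type(p, sel$child)
      part_type <- instance_type(p, sel$parent)
      counterpart_upper <- FALSE
    }
    for (ct in unique(counterpart_of)) {
      if (p$types$kind[match(ct, p$types$id)] != "object" &&
          is.na(p$types$name_giving[match(ct, p$types$id)])) {
        stop("annotation error: counterpart ", ct,
             " lacks a name-giving object type")
      }
      parts <- sort(unique(part_type[counterpart_of == ct]))
      part_lvl <- lvl[parts]
      if (all(is.na(part_lvl))) next  # parts outside the backbone
      if (counterpart_upper) {
        ## the counterpart's interval must lie above its object content:
        ## anchor at the highest CO level among the parts
        anchor <- max(part_lvl, na.rm = TRUE)
        parts <- sort(parts[!is.na(part_lvl) & part_lvl == anchor])
        levels <- list(list(content = parts, content_kind = "type"),
                       list(content = ct, content_kind = "type"))
      } else {
        ## aggregate parts of objects: the aggregate sits directly below
        ## its host objects
        anchor <- min(part_lvl, na.rm = TRUE) - 1L
        parts <- sort(parts[!is.na(part_lvl) & part_lvl == anchor + 1L])
        levels <- list(list(content = ct, content_kind = "type"),
                       list(content = parts, content_kind = "type"))
      }
      out[[length(out) + 1L]] <- new_perspective(
        paste0(tag, "@L", anchor, ":", ct), tag, levels,
        anchor_co_level = anchor, counterpart = ct)
    }
  }
  ## aggregate-of-aggregate chains: layered like the backbone
  sel <- cls[cls$tag == "compositional_aggregate_of_aggregate", ,
             drop = FALSE]
  if (nrow(sel)) {
    tedges <- unique(data.frame(child = instance_type(p, sel$child),
                                parent = instance_type(p, sel$parent),
                                stringsAsFactors = FALSE))
    tedges <- tedges[tedges$child != tedges$parent, , drop = FALSE]
    if (nrow(tedges)) {
      tys <- unique(c(tedges$child, tedges$parent))
      lv2 <- stats::setNames(rep(NA_integer_, length(tys)), tys)
      assign2 <- function(tp) {
        if (!is.na(lv2[[tp]])) return(lv2[[tp]])
        below <- tedges$child[tedges$parent == tp]
        v <- if (length(below)) 1L + max(vapply(below, assign2, integer(1)))
             else 1L
        lv2[[tp]] <<- v
        v
      }
      for (tp in tys) assign2(tp)
      levels <- lapply(seq_len(max(lv2)), function(k) {
        list(content = sort(names(lv2)[lv2 == k]), content_kind = "type")
      })
      ng <- p$types$name_giving[match(names(lv2)[lv2 == 1][1], p$types$id)]
      anchor <- if (!is.na(ng)) unname(lvl[ng]) else NA_integer_
      out[[length(out) + 1L]] <- new_perspective(
        "compositional_aggregate_of_aggregate",
        "compositional_aggregate_of_aggregate", levels,
        anchor_co_level = anchor,
        counterpart = names(lv2)[lv2 == 1][1])
    }
  }
  out
}

#' Build the basic spatial perspectives
#'
#' For each fiat-object-part subtype whose instances are proper parts of
#' objects (however the object was cut, every regional part is a proper
#' part of its object), a two-level perspective is built with the fiat
#' subtype in the lower level and the minimal host object subtypes in the
#' upper level. The anchor records the CO level directly below the hosts,
#' i.e. the fiat level's structural value will fall in
#' (anchor, anchor + 1). Parthood is taken from the transitive closure, so
#' fiat parts nested inside other fiat parts still register against their
#' object host.
#'
#' @inheritParams build_additional_compositional
#' @return List of `granularity_perspective` objects (possibly empty).
#' @export
build_spatial_basic <- function(p, co) {
  cl <- closure_matrix(p)
  if (any(diag(cl$mat))) stop("order error: partonomy is cyclic")
  kinds <- stats::setNames(instance_kind(p, p$instances$id), p$instances$id)
  fiats <- names(kinds)[kinds == "fiat_object_part"]
  ilvl <- co_level_of_instances(p, co)
  out <- list()
  if (!length(fiats)) return(out)
  ftype <- instance_type(p, fiats)
  for (ct in unique(ftype)) {
    inst <- fiats[ftype == ct]
    ## hosts: object or aggregate ancestors, minimal CO level
    hosts <- unique(unlist(lapply(inst, function(f) {
      anc <- cl$ids[cl$mat[f, ]]
      anc[kinds[anc] %in% c("object", "object_aggregate")]
    })))
    hl <- ilvl[hosts]
    if (!length(hosts) || all(is.na(hl))) next
    hmin <- min(hl, na.rm = TRUE)
    host_types <- sort(unique(instance_type(p, hosts[!is.na(hl) & hl == hmin])))
    host_kind <- p$types$kind[match(host_types[1], p$types$id)]
    tag <- if (host_kind == "object_aggregate") "spatial_fiat_of_aggregate"
           else "spatial_fiat_of_object"
    levels <- list(list(content = ct, content_kind = "type"),
                   list(content = host_types, content_kind = "type"))
    out[[length(out) + 1L]] <- new_perspective(
      paste0(tag, "@L", hmin - 1L, ":", ct), tag, levels,
      anchor_co_level = hmin - 1L, counterpart = ct)
  }
  out
}

#' Build the scale-dependent resolution perspectives
#'
#' An aggregate (or aggregate-with-fiat-part) can be represented in two
#' resolution-dependent ways: a countable object-cluster representation and
#' a non-countable portion-of-substance representation (e.g. 'cell cluster
#' with portion of ECM' vs 'portion of tissue', both standing for the same
#' 'cell aggregate with ECM'). Each represented type with both
#' representations declared yields a two-level perspective with the
#' countable representation in the lower level.
#'
#' @param p a `partonomy` whose types declare `represents` links.
#' @return List of `granularity_perspective` objects; represented types
#'   with only one representation are skipped with a warning.
#' @export
build_resolution <- function(p) {
  reps <- p$types[!is.na(p$types$rep_target), , drop = FALSE]
  out <- list()
  for (tgt in unique(reps$rep_target)) {
    sel <- reps[reps$rep_target == tgt, , drop = FALSE]
    lo <- sort(sel$id[sel$rep_countable])
    hi <- sort(sel$id[!sel$rep_countable])
    if (!length(lo) || !length(hi)) {
      warning("represented type ", tgt,
              " has only one representation; skipped")
      next
    }
    tk <- p$types$kind[match(tgt, p$types$id)]
    tag <- if (tk == "object_aggregate") "resolution_of_aggregate"
           else "resolution_of_aggregate_with_fiat"
    levels <- list(list(content = lo, content_kind = "type"),
                   list(content = hi, content_kind = "type"))
    out[[length(out) + 1L]] <- new_perspective(
      paste0(tag, ":", tgt), tag, levels, counterpart = tgt)
  }
  out
}

#' Build instance-only fiat-of-fiat chain perspectives
#'
#' Fiat object parts can themselves be partitioned into regional parts,
#' giving second- and higher-order regional parts. Because for any object
#' infinitely many incompatible fiat partitions are possible, such
#' perspectives are restricted to instances, never types. Each maximal
#' chain of fiat instances nested by proper parthood becomes one
#' perspective whose levels are the chain members, finest first. Branching
#' fiat subgraphs that are not simple chains are rejected from perspective
#' construction and reported via the `rejected` attribute.
#'
#' @param p a `partonomy`.
#' @return List of instance-content `granularity_perspective` objects with
#'   attribute `rejected` (list of non-chain fiat component memberships).
#' @export
build_fiat_chain <- function(p) {
  cl <- closure_matrix(p)
  if (any(diag(cl$mat))) stop("order error: partonomy is cyclic")
  kinds <- stats::setNames(instance_kind(p, p$instances$id), p$instances$id)
  fiats <- names(kinds)[kinds == "fiat_object_part"]
  out <- list()
  rejected <- list()
  if (length(fiats) < 2) {
    attr(out, "rejected") <- rejected
    return(out)
  }
  sub <- cl$mat[fiats, fiats, drop = FALSE]
  if (!any(sub)) {
    attr(out, "rejected") <- rejected
    return(out)
  }
  red <- reduction_from_matrix(sub, fiats)
  ## weakly connected components of the fiat-fiat subgraph
  touched <- unique(c(red$child, red$parent))
  comp <- stats::setNames(seq_along(touched), touched)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(red))) {
      a <- red$child[i]; b <- red$parent[i]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ci <- 0L
  for (cc in unique(comp)) {
    members <- names(comp)[comp == cc]
    indeg <- vapply(members, function(m) sum(red$parent == m), integer(1))
    outdeg <- vapply(members, function(m) sum(red$child == m), integer(1))
    if (any(indeg > 1) || any(outdeg > 1)) {
      rejected[[length(rejected) + 1L]] <- sort(members)
      next
    }
    start <- members[indeg == 0]
    chain <- start
    while (TRUE) {
      nxt <- red$parent[red$child == chain[length(chain)]]
      if (!length(nxt)) break
      chain <- c(chain, nxt)
    }
    ci <- ci + 1L
    levels <- lapply(chain, function(m) {
      list(content = m, content_kind = "instance")
    })
    out[[length(out) + 1L]] <- new_perspective(
      paste0("spatial_fiat_of_fiat#", ci), "spatial_fiat_of_fiat",
      levels, instance_content = TRUE)
  }
  attr(out, "rejected") <- rejected
  out
}
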