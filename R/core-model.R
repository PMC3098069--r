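#' @keywords internal
"_PACKAGE"

## Material-entity kinds: the three subtypes of BFO 'material entity' that
## classify every bounded material part (bona-fide unit, arbitrarily bounded
## part, mereological sum of separate units).
ENTITY_KINDS <- c("object", "fiat_object_part", "object_aggregate")

PARTHOOD_RELATIONS <- c("direct_proper_part_of", "proper_part_of",
                        "countable_proper_part_of")

#' Define a material type
#'
#' A material type is a named universal whose instances are material
#' entities of exactly one kind: `"object"` (bona-fide bounded unit, e.g. a
#' cell), `"fiat_object_part"` (arbitrarily bounded part, e.g. the upper
#' lobe of a lung or a cell aggregate with its extracellular matrix), or
#' `"object_aggregate"` (a mereological sum of separate objects).
#'
#' Fiat and aggregate types must name the object type they are defined in
#' reference to (`name_giving`), e.g. a "cell aggregate with ECM" is named
#' after 'cell'. This is how such a type is anchored to a level of the
#' compositional-object backbone, since the naming itself is lexical.
#'
#' Types that are scale-dependent *representations* of an aggregate (e.g.
#' the countable 'cell cluster with portion of ECM' vs the non-countable
#' 'portion of tissue', both standing for the same 'cell aggregate with
#' ECM') declare the represented type and whether the representation is
#' countable via `represents`.
#'
#' @param id unique type identifier.
#' @param kind one of `"object"`, `"fiat_object_part"`, `"object_aggregate"`.
#' @param label human-readable label; defaults to `id`.
#' @param name_giving id of the object type this fiat/aggregate type is
#'   named after. Required when `kind` is not `"object"`.
#' @param represents optional `list(target = <type id>, countable = <flag>)`
#'   marking this type as a resolution-dependent representation of `target`.
#' @return A list of class `material_type`.
#' @examples
#' material_type("cell", "object")
#' material_type("cell_aggregate_with_ecm", "fiat_object_part",
#'               label = "cell aggregate with ECM", name_giving = "cell")
#' @export
material_type <- function(id, kind, label = id, name_giving = NULL,
                          represents = NULL) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  kind <- match.arg(kind, ENTITY_KINDS)
  if (!is.null(represents)) {
    stopifnot(is.list(represents), !is.null(represents$target),
              is.logical(represents$countable))
  }
  structure(list(id = id, label = label, kind = kind,
                 name_giving = name_giving, represents = represents),
            class = "material_type")
}

type_table <- function(types) {
  if (is.data.frame(types)) {
    tab <- types
    for (col in c("label", "name_giving", "rep_target")) {
      if (is.null(tab[[col]])) tab[[col]] <- NA_character_
    }
    if (is.null(tab$rep_countable)) tab$rep_countable <- NA
    if (is.null(tab$label) || anyNA(tab$label)) {
      tab$label[is.na(tab$label)] <- tab$id[is.na(tab$label)]
    }
    return(tab[c("id", "label", "kind", "name_giving",
                 "rep_target", "rep_countable")])
  }
  stopifnot(is.list(types))
  rows <- lapply(types, function(tp) {
    stopifnot(inherits(tp, "material_type"))
    data.frame(id = tp$id, label = tp$label, kind = tp$kind,
               name_giving = tp$name_giving %||% NA_character_,
               rep_target = if (is.null(tp$represents)) NA_character_ else
                 tp$represents$target,
               rep_countable = if (is.null(tp$represents)) NA else
                 tp$represents$countable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_edges <- function() {
  data.frame(child = character(), relation = character(),
             parent = character(), stringsAsFactors = FALSE)
}

empty_measures <- function() {
  data.frame(instance = character(), quantity = character(),
             value = numeric(), unit = character(), stringsAsFactors = FALSE)
}

#' Construct and validate a partonomy
#'
#' A partonomy is a typed part-whole graph over material-entity instances:
#' a set of material types (with their kind tags), a set of instances, a
#' set of proper-parthood edges between instances, and optional scalar
#' measures (e.g. weights) per instance. The constructor checks referential
#' integrity, the type-level annotation rules (fiat/aggregate types name an
#' object type; representation targets are aggregates or fiat parts), and
#' downgrades user-supplied `direct_proper_part_of` edges that are not in
#' the transitive reduction of the parthood closure to plain
#' `proper_part_of` with a warning. Order-theoretic defects (cycles) are
#' *not* errors here: they are data for
#' [validate_strict_partial_order()].
#'
#' Parthood is stored at the instance level only; type-level parthood is
#' always derived, never asserted, because under cumulative-constitutive
#' organization (where e.g. some molecules are direct parts of an organ
#' rather than of any cell) asserted type-level parthood is unreliable.
#'
#' @param types a list of [material_type()] objects or an equivalent
#'   data frame.
#' @param instances data frame with columns `id`, `type_id`, or a named
#'   character vector `c(instance_id = type_id)`.
#' @param edges data frame with columns `child`, `relation`, `parent`;
#'   `relation` one of `"direct_proper_part_of"`, `"proper_part_of"`,
#'   `"countable_proper_part_of"`.
#' @param measures optional data frame with columns `instance`, `quantity`,
#'   `value`, `unit`.
#' @param schemes optional list of [external_scheme()] objects carried
#'   alongside the partonomy.
#' @return An object of class `partonomy`.
#' @seealso [validate_strict_partial_order()], [fixture()]
#' @examples
#' p <- fixture("fig2_organ")
#' p
#' @export
partonomy <- function(types, instances, edges = empty_edges(),
                      measures = NULL, schemes = NULL) {
  types <- type_table(types)
  if (!is.data.frame(instances)) {
    instances <- data.frame(id = names(instances),
                            type_id = unname(instances),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "type_id") %in% names(instances)))
  instances <- instances[c("id", "type_id")]
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- empty_edges()
  } else {
    stopifnot(all(c("child", "relation", "parent") %in% names(edges)))
    edges <- data.frame(child = as.character(edges$child),
                        relation = as.character(edges$relation),
                        parent = as.character(edges$parent),
                        stringsAsFactors = FALSE)
  }
  if (is.null(measures)) measures <- empty_measures()

  if (anyDuplicated(types$id)) {
    stop("reference error: duplicated type ids: ",
         paste(unique(types$id[duplicated(types$id)]), collapse = ", "))
  }
  if (anyDuplicated(instances$id)) {
    stop("reference error: duplicated instance ids: ",
         paste(unique(instances$id[duplicated(instances$id)]), collapse = ", "))
  }
  if (!all(types$kind %in% ENTITY_KINDS)) {
    stop("reference error: unknown entity kind: ",
         paste(setdiff(types$kind, ENTITY_KINDS), collapse = ", "))
  }
  bad <- setdiff(instances$type_id, types$id)
  if (length(bad)) {
    stop("reference error: instances reference unknown types: ",
         paste(bad, collapse = ", "))
  }
  non_obj <- types$kind != "object"
  if (any(non_obj & is.na(types$name_giving))) {
    stop("annotation error: fiat/aggregate types must declare a ",
         "name-giving object type: ",
         paste(types$id[non_obj & is.na(types$name_giving)], collapse = ", "))
  }
  ng <- types$name_giving[!is.na(types$name_giving)]
  bad <- setdiff(ng, types$id[types$kind == "object"])
  if (length(bad)) {
    stop("annotation error: name-giving type is not a known object type: ",
         paste(bad, collapse = ", "))
  }
  rt <- types$rep_target[!is.na(types$rep_target)]
  bad <- setdiff(rt, types$id[types$kind %in%
                                c("object_aggregate", "fiat_object_part")])
  if (length(bad)) {
    stop("annotation error: represented type must be an object aggregate ",
         "or fiat object part: ", paste(bad, collapse = ", "))
  }
  if (nrow(edges)) {
    if (!all(edges$relation %in% PARTHOOD_RELATIONS)) {
      stop("reference error: unknown parthood relation: ",
           paste(setdiff(edges$relation, PARTHOOD_RELATIONS), collapse = ", "))
    }
    bad <- setdiff(c(edges$child, edges$parent), instances$id)
    if (length(bad)) {
      stop("reference error: edge endpoints are not known instances: ",
           paste(bad, collapse = ", "))
    }
    if (any(edges$child == edges$parent)) {
      stop("order error: self-parthood edge on ",
           paste(edges$child[edges$child == edges$parent], collapse = ", "))
    }
  }
  if (nrow(measures)) {
    stopifnot(all(c("instance", "quantity", "value") %in% names(measures)))
    if (is.null(measures$unit)) measures$unit <- NA_character_
    bad <- setdiff(measures$instance, instances$id)
    if (length(bad)) {
      stop("reference error: measures reference unknown instances: ",
           paste(bad, collapse = ", "))
    }
    measures <- measures[c("instance", "quantity", "value", "unit")]
  }

  p <- structure(list(types = types, instances = instances, edges = edges,
                      measures = measures, schemes = schemes %||% list()),
                 class = "partonomy")

  ## Downgrade redundant "direct" edges (only meaningful on acyclic input).
  cl <- try(closure_matrix(p), silent = TRUE)
  if (!inherits(cl, "try-error") && !any(diag(cl$mat))) {
    red <- reduction_from_matrix(cl$mat, cl$ids)
    is_direct <- p$edges$relation == "direct_proper_part_of"
    keep <- paste(p$edges$child, p$edges$parent) %in%
      paste(red$child, red$parent)
    demote <- is_direct & !keep
    if (any(demote)) {
      warning("downgrading ", sum(demote),
              " redundant direct_proper_part_of edge(s) to proper_part_of: ",
              paste(paste(p$edges$child[demote], "<",
                          p$edges$parent[demote]), collapse = "; "))
      p$edges$relation[demote] <- "proper_part_of"
    }
  }
  p
}

#' @export
print.partonomy <- function(x, ...) {
  cat("<partonomy>: ", nrow(x$types), " types, ", nrow(x$instances),
      " instances, ", nrow(x$edges), " parthood edges",
      if (nrow(x$measures)) paste0(", ", nrow(x$measures), " measures"),
      if (length(x$schemes)) paste0(", ", length(x$schemes), " schemes"),
      "\n", sep = "")
  kinds <- table(x$types$kind)
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

instance_kind <- function(p, ids) {
  tid <- p$instances$type_id[match(ids, p$instances$id)]
  p$types$kind[match(tid, p$types$id)]
}

instance_type <- function(p, ids) {
  p$instances$type_id[match(ids, p$instances$id)]
}

## ---- graph primitives -------------------------------------------------

## Boolean reachability matrix (Warshall). ids fixes row/column order.
closure_matrix <- function(x, ids = NULL) {
  edges <- if (inherits(x, "partonomy")) x$edges else x
  if (is.null(ids)) {
    ids <- if (inherits(x, "partonomy")) x$instances$id else
      unique(c(edges$child, edges$parent))
  }
  n <- length(ids)
  mat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    bad <- setdiff(c(edges$child, edges$parent), ids)
    if (length(bad)) {
      stop("reference error: unknown edge endpoints: ",
           paste(bad, collapse = ", "))
    }
    mat[cbind(match(edges$child, ids), match(edges$parent, ids))] <- TRUE
  }
  for (k in seq_len(n)) {
    mat <- mat | outer(mat[, k], mat[k, ], `&`)
  }
  list(mat = mat, ids = ids)
}

matrix_to_edges <- function(mat, relation = "proper_part_of") {
  idx <- which(mat, arr.ind = TRUE)
  ids <- rownames(mat)
  data.frame(child = ids[idx[, 1]], relation = relation,
             parent = ids[idx[, 2]], stringsAsFactors = FALSE)
}

reduction_from_matrix <- function(mat, ids) {
  if (any(diag(mat))) stop("order error: input is cyclic")
  ## an edge x->z is redundant iff some y with x->y and y->z exists
  red <- mat & !((mat %*% mat) > 0)
  matrix_to_edges(red)
}

#' Transitive closure of a parthood edge set
#'
#' Returns the smallest transitively closed superset of the given edges
#' (proper parthood is transitive: if x is part of y and y part of z, x is
#' part of z). Input rows are preserved; derived pairs are added with
#' relation `"proper_part_of"`.
#'
#' @param edges data frame with columns `child`, `relation`, `parent`, or a
#'   `partonomy` (whose edge set is used).
#' @param instances optional character vector of known instance ids; edge
#'   endpoints outside it raise a reference error.
#' @return Edge data frame containing the closure.
#' @examples
#' e <- data.frame(child = c("a", "b"), relation = "proper_part_of",
#'                 parent = c("b", "c"))
#' transitive_closure(e)
#' @export
transitive_closure <- function(edges, instances = NULL) {
  if (inherits(edges, "partonomy")) {
    instances <- instances %||% edges$instances$id
    edges <- edges$edges
  }
  if (nrow(edges) == 0) return(edges)
  cl <- closure_matrix(edges, ids = instances)
  closed <- matrix_to_edges(cl$mat)
  key <- paste(closed$child, closed$parent)
  in_key <- paste(edges$child, edges$parent)
  rbind(edges, closed[!(key %in% in_key), , drop = FALSE])
}

#' Transitive reduction of an acyclic parthood edge set
#'
#' Computes the unique minimal edge set whose transitive closure equals the
#' closure of the input: the "direct" proper-parthood edges. Cyclic input is
#' an order error.
#'
#' @inheritParams transitive_closure
#' @return Edge data frame of the reduction (relation `"proper_part_of"`).
#' @export
transitive_reduction <- function(edges, instances = NULL) {
  if (inherits(edges, "partonomy")) {
    instances <- instances %||% edges$instances$id
    edges <- edges$edges
  }
  if (nrow(edges) == 0) return(edges)
  cl <- closure_matrix(edges, ids = instances)
  if (any(diag(cl$mat))) stop("order error: cyclic input")
  reduction_from_matrix(cl$mat, cl$ids)
}

#' Validate a partonomy as a strict partial order
#'
#' Proper parthood must be a strict partial order: transitive, antisymmetric
#' and irreflexive. Violations are reported as data, not raised as errors.
#' Rules checked: `irreflexivity` (an instance reaches itself through the
#' parthood closure), `antisymmetry` (two instances reach each other; pairs
#' connected only by countable-parthood edges are exempt, since countable
#' edges may relate two representations of the same aggregate),
#' `direct_edge_redundancy` (a `direct_proper_part_of` edge that is not in
#' the transitive reduction), and, when `assume_closed = TRUE`,
#' `transitivity_closure_gap` (an implied pair missing from an edge set
#' that claims to be closed).
#'
#' @param p a `partonomy`.
#' @param assume_closed treat the stored edge set as claiming transitive
#'   closedness and report gaps.
#' @return A data frame of class `order_report` with columns `rule`, `x`,
#'   `y`; zero rows iff the partonomy is a valid strict partial order with
#'   reduced direct edges.
#' @examples
#' validate_strict_partial_order(fixture("fig2_organ"))
#' @export
validate_strict_partial_order <- function(p, assume_closed = FALSE) {
  stopifnot(inherits(p, "partonomy"))
  out <- data.frame(rule = character(), x = character(), y = character(),
                    stringsAsFactors = FALSE)
  if (nrow(p$edges)) {
    cl <- closure_matrix(p)
    refl <- which(diag(cl$mat))
    if (length(refl)) {
      out <- rbind(out, data.frame(rule = "irreflexivity",
                                   x = cl$ids[refl], y = cl$ids[refl]))
    }
    ## antisymmetry on the closure of non-countable edges
    nc <- p$edges[p$edges$relation != "countable_proper_part_of", ,
                  drop = FALSE]
    ncl <- closure_matrix(nc, ids = p$instances$id)$mat
    sym <- which(ncl & t(ncl), arr.ind = TRUE)
    sym <- sym[sym[, 1] < sym[, 2], , drop = FALSE]
    if (nrow(sym)) {
      out <- rbind(out, data.frame(rule = "antisymmetry",
                                   x = cl$ids[sym[, 1]],
                                   y = cl$ids[sym[, 2]]))
    }
    if (assume_closed) {
      asserted <- cl$mat & FALSE
      asserted[cbind(match(p$edges$child, cl$ids),
                     match(p$edges$parent, cl$ids))] <- TRUE
      implied <- (asserted %*% asserted) > 0
      gap <- which(implied & !asserted, arr.ind = TRUE)
      if (nrow(gap)) {
        out <- rbind(out, data.frame(rule = "transitivity_closure_gap",
                                     x = cl$ids[gap[, 1]],
                                     y = cl$ids[gap[, 2]]))
      }
    }
    if (!any(diag(cl$mat))) {
      red <- reduction_from_matrix(cl$mat, cl$ids)
      dir <- p$edges[p$edges$relation == "direct_proper_part_of", ,
                     drop = FALSE]
      bad <- !(paste(dir$child, dir$parent) %in%
                 paste(red$child, red$parent))
      if (any(bad)) {
        out <- rbind(out, data.frame(rule = "direct_edge_redundancy",
                                     x = dir$child[bad], y = dir$parent[bad]))
      }
    }
  }
  class(out) <- c("order_report", class(out))
  out
}

## Descendant atoms: instances with no proper parts reachable below x
## (x itself if it has no parts). Atoms are defined graph-theoretically;
## the model carries no spatial extents.
atoms_under <- function(mat, x) {
  below <- rownames(mat)[mat[, x]]
  has_parts <- colSums(mat) > 0
  if (!length(below)) return(x)
  below[!has_parts[below]]
}

#' Check whether members exhaustively sum to a whole
#'
#' In a mereological granularity tree the parts of a level should sum to
#' the whole. Under cumulative-constitutive organization this fails for
#' most levels (e.g. the cells of an organ do not sum to the organ, since
#' the extracellular molecules are not inside any cell). The check is
#' graph-theoretic: the atoms (instances with no proper parts) reachable
#' below the members must equal the atoms below the whole.
#'
#' @param members character vector of instance ids; each must be a proper
#'   part of `whole` (precondition error otherwise).
#' @param whole instance id of the whole.
#' @param p a `partonomy`.
#' @return `list(ok = <flag>, missing = <uncovered atom ids>)`.
#' @examples
#' p <- fixture("fig2_organ")
#' exhaustive_sum_check(letters[1:12], "organ1", p)         # molecular cut
#' exhaustive_sum_check(c("q", "r"), "organ1", p)$missing   # cells only
#' @export
exhaustive_sum_check <- function(members, whole, p) {
  stopifnot(inherits(p, "partonomy"))
  cl <- closure_matrix(p)
  if (!whole %in% cl$ids) stop("reference error: unknown whole: ", whole)
  bad <- setdiff(members, cl$ids)
  if (length(bad)) {
    stop("reference error: unknown members: ", paste(bad, collapse = ", "))
  }
  not_part <- members[!cl$mat[members, whole]]
  if (length(not_part)) {
    stop("precondition error: members are not proper parts of ", whole, ": ",
         paste(not_part, collapse = ", "))
  }
  target <- atoms_under(cl$mat, whole)
  covered <- unique(unlist(lapply(members, atoms_under, mat = cl$mat)))
  missing <- setdiff(target, covered)
  list(ok = length(missing) == 0, missing = missing)
}
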