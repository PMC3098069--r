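#' Build a granularity tree from ordered partitions of a whole
#'
#' A granular partition of a whole is a system of cells and subcells that
#' forms a rooted tree of finite depth: the subcell relation is a partial
#' order, there is a unique root of which all cells are parts, chains are
#' finite, and two overlapping cells must be nested (no partial overlap).
#' Each supplied partition becomes one depth of the tree; partitions are
#' ordered coarse to fine and each finer partition must refine the coarser
#' one: every finer member is either a coarser member itself (a
#' "pass-through" entity that survives unchanged into the finer cut, like
#' an extracellular molecule that is already atomic in the coarsest cut) or
#' a proper part of exactly one coarser member.
#'
#' @param whole instance id of the root.
#' @param partitions list of character vectors (instance ids), ordered
#'   coarse to fine. May be empty (root-only tree).
#' @param p a `partonomy` supplying the parthood relation.
#' @return An object of class `granularity_tree` with fields `root`,
#'   `parent` (named character), `depth_of` (named integer, root = 0) and
#'   `depth` (number of levels including the root).
#' @examples
#' p <- fixture("fig2_organ")
#' tr <- build_granularity_tree("organ1", canonical_partitions(p, "organ1"), p)
#' tr$depth
#' @export
build_granularity_tree <- function(whole, partitions, p) {
  stopifnot(inherits(p, "partonomy"))
  cl <- closure_matrix(p)
  if (!whole %in% cl$ids) stop("reference error: unknown whole: ", whole)
  parent <- character(0)
  depth_of <- stats::setNames(0L, whole)
  prev_cut <- whole
  for (k in seq_along(partitions)) {
    cut <- unique(partitions[[k]])
    bad <- setdiff(cut, cl$ids)
    if (length(bad)) {
      stop("reference error: unknown instances in partition ", k, ": ",
           paste(bad, collapse = ", "))
    }
    not_part <- cut[!cl$mat[cut, whole]]
    if (length(not_part)) {
      stop("reference error: partition ", k,
           " members are not proper parts of ", whole, ": ",
           paste(not_part, collapse = ", "))
    }
    ## no nesting within one cut: cut members must be pairwise disjoint
    sub <- cl$mat[cut, cut, drop = FALSE]
    if (any(sub)) {
      idx <- which(sub, arr.ind = TRUE)
      stop("partition error: partition ", k, " contains nested members: ",
           paste(paste(cut[idx[, 1]], "<", cut[idx[, 2]]), collapse = "; "))
    }
    for (m in cut) {
      if (m %in% prev_cut) next  # pass-through, same node
      hosts <- prev_cut[cl$mat[m, prev_cut]]
      if (length(hosts) == 0) {
        stop("partition error: ", m, " in partition ", k,
             " is not a part of any member of the coarser partition")
      }
      if (length(hosts) > 1) {
        stop("partition error: partial overlap - ", m,
             " is a part of several coarser cells: ",
             paste(hosts, collapse = ", "))
      }
      if (m %in% names(depth_of)) {
        stop("partition error: ", m,
             " reappears below a different coarser cell")
      }
      parent[m] <- hosts
      depth_of[m] <- k
    }
    prev_cut <- cut
  }
  structure(list(root = whole, parent = parent, depth_of = depth_of,
                 depth = length(partitions) + 1L),
            class = "granularity_tree")
}

#' @export
print.granularity_tree <- function(x, ...) {
  cat("<granularity tree> root=", x$root, ", ", length(x$depth_of),
      " nodes, depth ", x$depth, "\n", sep = "")
  invisible(x)
}

tree_children <- function(t) {
  split(names(t$parent), factor(unname(t$parent), levels = names(t$depth_of)))
}

#' Enumerate instance granularity levels (cuts) of a granularity tree
#'
#' Every horizontal cut through a granularity tree is an instance
#' granularity level: the root alone is the coarsest cut and each finer cut
#' replaces the expandable members of the previous one by their children,
#' while leaves already present pass through unchanged into all deeper
#' cuts. Levels are indexed bottom-up: index 1 is the finest cut, index
#' `depth` is the root.
#'
#' @param t a `granularity_tree`.
#' @return List of `list(index, content)`, ordered finest (index 1) first.
#' @examples
#' p <- fixture("fig2_organ")
#' tr <- build_granularity_tree("organ1", canonical_partitions(p, "organ1"), p)
#' enumerate_levels(tr)[[1]]$content  # the molecular cut
#' @export
enumerate_levels <- function(t) {
  stopifnot(inherits(t, "granularity_tree"))
  nodes <- names(t$depth_of)
  is_leaf <- !(nodes %in% unname(t$parent))
  max_d <- t$depth - 1L
  lapply(seq_len(t$depth), function(index) {
    d <- t$depth - index  # cut depth for this level index
    content <- nodes[t$depth_of == d |
                       (is_leaf & t$depth_of < d)]
    list(index = index, content = content)
  })
}

#' Disjoint node-level assignment of a granularity tree
#'
#' Unlike [enumerate_levels()], which re-inserts pass-through leaves into
#' deeper cuts (so a molecule that is atomic from the coarsest cut on
#' appears in several cuts), this accessor reports each node exactly once,
#' at the depth where it enters the tree. Levels are therefore pairwise
#' disjoint and their union is the node set.
#'
#' @inheritParams enumerate_levels
#' @return List of `list(index, content)` as in [enumerate_levels()].
#' @export
tree_node_levels <- function(t) {
  stopifnot(inherits(t, "granularity_tree"))
  nodes <- names(t$depth_of)
  lapply(seq_len(t$depth), function(index) {
    d <- t$depth - index
    list(index = index, content = nodes[t$depth_of == d])
  })
}

#' Classify a granularity tree as bona fide, fiat or mixed
#'
#' A tree all of whose non-root entities exist independently of human
#' partitioning activity (objects and object aggregates) is a bona fide
#' granularity tree; one whose non-root entities are all arbitrarily
#' bounded (fiat object parts) is a fiat granularity tree; anything else is
#' mixed.
#'
#' @param t a `granularity_tree`.
#' @param p the `partonomy` supplying kind tags.
#' @return One of `"bona_fide"`, `"fiat"`, `"mixed"`.
#' @export
classify_tree <- function(t, p) {
  stopifnot(inherits(t, "granularity_tree"), inherits(p, "partonomy"))
  non_root <- setdiff(names(t$depth_of), t$root)
  if (!length(non_root)) return("bona_fide")
  kinds <- instance_kind(p, non_root)
  if (anyNA(kinds)) {
    stop("reference error: untyped nodes: ",
         paste(non_root[is.na(kinds)], collapse = ", "))
  }
  bona <- kinds %in% c("object", "object_aggregate")
  if (all(bona)) return("bona_fide")
  if (all(!bona)) return("fiat")
  "mixed"
}

#' Canonical compositional partitions of a whole
#'
#' Derives the canonical coarse-to-fine partition sequence of a whole from
#' the stored parthood edges: the first partition is the set of direct
#' proper parts of the whole; each subsequent partition replaces every
#' non-atomic member by its direct parts while atoms pass through; the
#' sequence stops when only atoms remain. Applied to an organ whose cells
#' contain organelles which contain molecules, with extracellular molecules
#' directly below the organ, this reproduces the cellular, organelle and
#' molecular cuts.
#'
#' @param p a `partonomy` (must be acyclic).
#' @param whole instance id to partition.
#' @return List of character vectors, coarse to fine (possibly empty when
#'   `whole` is an atom).
#' @export
canonical_partitions <- function(p, whole) {
  stopifnot(inherits(p, "partonomy"))
  cl <- closure_matrix(p)
  if (any(diag(cl$mat))) stop("order error: partonomy is cyclic")
  red <- reduction_from_matrix(cl$mat, cl$ids)
  kids <- split(red$child, factor(red$parent, levels = cl$ids))
  has_parts <- lengths(kids) > 0
  out <- list()
  cut <- sort(kids[[whole]])
  while (length(cut)) {
    out[[length(out) + 1L]] <- cut
    if (!any(has_parts[cut])) break
    cut <- sort(unique(unlist(lapply(cut, function(m) {
      if (has_parts[m]) kids[[m]] else m
    }))))
  }
  out
}
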