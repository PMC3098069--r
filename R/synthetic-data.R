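#' Parameters for the cumulative partonomy generator
#'
#' The generator emulates cumulative-constitutive organization: a backbone
#' of object levels (molecule-like at the bottom, an organism-like maximum
#' object at the top) in which a stated fraction of each level's instances
#' is "free" - attached directly to the maximum object rather than to a
#' whole of the adjacent level, like extracellular molecules or circulating
#' blood cells. With all free fractions zero the output is a purely
#' constitutive hierarchy.
#'
#' Defaults are the generator's stated world: three object levels,
#' branching two, free fraction 0.25 per level (cumulative organization is
#' the realistic default for metazoan-like anatomy), no matrix aggregates.
#'
#' @param n_co_levels number of object levels (>= 2).
#' @param branching children per whole, per level (scalar or vector of
#'   length `n_co_levels - 1`, each >= 2 so that every non-lowest object
#'   has at least two object parts).
#' @param free_fraction fraction of each level's instances attached
#'   directly to the maximum object (scalar or per-level vector, each in
#'   \eqn{[0, 1)}).
#' @param with_ecm add a matrix-embedded fiat aggregate layer (fiat
#'   aggregates of the second-highest level's objects, absorbing the free
#'   instances as matrix) plus a countable/non-countable representation
#'   pair for resolution perspectives.
#' @param n_fiat_parts number of fiat aggregates when `with_ecm` (>= 2).
#' @param seed integer RNG seed; the same seed yields a byte-identical
#'   partonomy.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_co_levels = 3, branching = 2,
                             free_fraction = 0.25, with_ecm = FALSE,
                             n_fiat_parts = 2, seed = 1) {
  if (n_co_levels < 2) {
    stop("parameter error: n_co_levels must be at least 2")
  }
  k <- n_co_levels - 1
  branching <- rep_len(branching, k)
  free_fraction <- rep_len(free_fraction, k)
  if (any(branching < 2)) {
    stop("parameter error: branching must be >= 2 at every level")
  }
  if (any(free_fraction < 0 | free_fraction >= 1)) {
    stop("parameter error: free_fraction must be in [0, 1)")
  }
  if (with_ecm && n_fiat_parts < 2) {
    stop("parameter error: n_fiat_parts must be >= 2")
  }
  structure(list(n_co_levels = as.integer(n_co_levels),
                 branching = as.integer(branching),
                 free_fraction = free_fraction,
                 with_ecm = isTRUE(with_ecm),
                 n_fiat_parts = as.integer(n_fiat_parts),
                 seed = as.integer(seed)),
            class = "generator_params")
}

#' Generate a cumulative-constitutively organized partonomy
#'
#' Builds a partonomy with one object type per level, a unique maximum
#' object, `branching` direct parts per whole, and per-level free
#' instances attached directly to the maximum object (so the level's type
#' crosses instance granularity levels whenever its free fraction is
#' positive). With `with_ecm`, the maximum object's direct parts are
#' grouped into fiat aggregates ("<member> aggregate with matrix") that
#' also absorb the free lower-level instances, and a countable /
#' non-countable representation pair is declared for them.
#'
#' @param params a [generator_params()] object.
#' @return A valid `partonomy` (strict partial order, deterministic for a
#'   given seed).
#' @examples
#' p <- generate_cumulative_partonomy(generator_params(seed = 42))
#' validate_strict_partial_order(p)
#' @export
generate_cumulative_partonomy <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_co_levels
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(params$seed)

  types <- lapply(seq_len(n), function(k) {
    material_type(paste0("gen:obj_L", k), "object",
                  label = paste0("level-", k, " object"))
  })
  max_id <- paste0("gen:L", n, "_i1")
  instances <- data.frame(id = max_id, type_id = paste0("gen:obj_L", n),
                          stringsAsFactors = FALSE)
  edges <- empty_edges()
  level_instances <- list()
  level_instances[[n]] <- max_id
  for (k in seq(n - 1, 1)) {
    b <- params$branching[k]
    ff <- params$free_fraction[k]
    parents <- level_instances[[k + 1]]
    n_reg <- b * length(parents)
    n_free <- if (ff > 0) max(1L, round(ff * n_reg / (1 - ff))) else 0L
    ids <- paste0("gen:L", k, "_i", seq_len(n_reg + n_free))
    reg <- ids[seq_len(n_reg)]
    free <- setdiff(ids, reg)
    edges <- rbind(edges, data.frame(
      child = reg, relation = "direct_proper_part_of",
      parent = rep(parents, each = b), stringsAsFactors = FALSE))
    if (length(free)) {
      edges <- rbind(edges, data.frame(
        child = free, relation = "direct_proper_part_of",
        parent = max_id, stringsAsFactors = FALSE))
    }
    instances <- rbind(instances, data.frame(
      id = ids, type_id = paste0("gen:obj_L", k), stringsAsFactors = FALSE))
    level_instances[[k]] <- ids
  }

  if (params$with_ecm) {
    member_type <- paste0("gen:obj_L", n - 1)
    agg_type <- material_type(
      "gen:agg_matrix", "fiat_object_part",
      label = paste0("level-", n - 1, " aggregate with matrix"),
      name_giving = member_type)
    rep_cluster <- material_type(
      "gen:rep_cluster", "fiat_object_part",
      label = "object cluster with portion of matrix",
      name_giving = member_type,
      represents = list(target = "gen:agg_matrix", countable = TRUE))
    rep_portion <- material_type(
      "gen:rep_portion", "fiat_object_part",
      label = "portion of substance",
      name_giving = member_type,
      represents = list(target = "gen:agg_matrix", countable = FALSE))
    types <- c(types, list(agg_type, rep_cluster, rep_portion))
    nf <- params$n_fiat_parts
    fiat_ids <- paste0("fiat:agg_", seq_len(nf))
    instances <- rbind(instances, data.frame(
      id = fiat_ids, type_id = "gen:agg_matrix", stringsAsFactors = FALSE))
    direct_to_max <- edges$parent == max_id
    movers <- edges$child[direct_to_max]
    if (length(movers) < nf) {
      stop("parameter error: not enough direct parts of the maximum object ",
           "to form ", nf, " fiat aggregates")
    }
    grp <- rep_len(seq_len(nf), length(movers))
    edges <- edges[!direct_to_max, , drop = FALSE]
    edges <- rbind(edges,
                   data.frame(child = movers,
                              relation = "direct_proper_part_of",
                              parent = fiat_ids[grp],
                              stringsAsFactors = FALSE),
                   data.frame(child = fiat_ids,
                              relation = "direct_proper_part_of",
                              parent = max_id, stringsAsFactors = FALSE))
  }

  partonomy(types, instances, edges)
}

#' Overlay a fiat partition on a whole
#'
#' Partitions a whole's direct parts into `k` pairwise disjoint fiat parts
#' (regional parts demarcated by arbitrary boundaries), each with at least
#' one member, whose contents union to the whole's direct content. The
#' members' direct edges to the whole are rerouted through the new fiat
#' instances.
#'
#' @param p a `partonomy`.
#' @param whole instance id to partition.
#' @param k number of fiat parts (>= 2, at most the number of direct
#'   parts).
#' @param seed RNG seed for the random grouping.
#' @return A new `partonomy` including the fiat partition.
#' @export
generate_fiat_partition <- function(p, whole, k, seed = 1) {
  stopifnot(inherits(p, "partonomy"))
  red <- transitive_reduction(p$edges, p$instances$id)
  members <- sort(red$child[red$parent == whole])
  if (k < 2 || k > length(members)) {
    stop("parameter error: k must be between 2 and the number of direct ",
         "parts (", length(members), ")")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  grp <- c(seq_len(k), sample(k, length(members) - k, replace = TRUE))
  grp <- grp[sample(length(grp))]

  whole_type <- instance_type(p, whole)
  whole_kind <- p$types$kind[match(whole_type, p$types$id)]
  name_giving <- if (whole_kind == "object") whole_type else
    p$types$name_giving[match(whole_type, p$types$id)]
  fiat_type_id <- paste0("fiat:", whole, "_part")
  types <- p$types
  if (!fiat_type_id %in% types$id) {
    types <- rbind(types, type_table(list(material_type(
      fiat_type_id, "fiat_object_part",
      label = paste0("fiat part of ", whole),
      name_giving = name_giving))))
  }
  fiat_ids <- paste0("fiat:", whole, "_p", seq_len(k))
  instances <- rbind(p$instances,
                     data.frame(id = fiat_ids, type_id = fiat_type_id,
                                stringsAsFactors = FALSE))
  drop <- p$edges$parent == whole &
    p$edges$child %in% members &
    p$edges$relation == "direct_proper_part_of"
  edges <- rbind(p$edges[!drop, , drop = FALSE],
                 data.frame(child = members,
                            relation = "direct_proper_part_of",
                            parent = fiat_ids[grp], stringsAsFactors = FALSE),
                 data.frame(child = fiat_ids,
                            relation = "direct_proper_part_of",
                            parent = whole, stringsAsFactors = FALSE))
  partonomy(types, instances, edges, measures = p$measures,
            schemes = p$schemes)
}

#' Bundled fixtures
#'
#' Returns a fresh copy of one of the bundled worked examples:
#' \describe{
#'   \item{`fig2_organ`}{an organ with two cells (q, r), four extracellular
#'     molecules (a-d) directly below the organ, four organelles (m-p)
#'     inside the cells, four cellular molecules (e-h), and four organelle
#'     molecules (i-l): a 19-instance cumulative-constitutive partonomy
#'     whose canonical cuts are the cellular, organelle and molecular
#'     partitions. The molecule distribution beneath cells and organelles
#'     (m,n and e,f under q; o,p and g,h under r; i-l one per organelle)
#'     is the canonical choice documented here; any distribution
#'     reproducing the three cuts would be admissible.}
#'   \item{`fig5_co`}{a purely constitutive organelle < cell < organ
#'     backbone (one organ, two cells, four organelles).}
#'   \item{`fig11_organ`}{a chain cell < fiat organ part 1 < fiat organ
#'     part 2 < fiat organ part 3 < organ, the worked example for
#'     structural-granularity-value assignment.}
#'   \item{`kumar_human`}{the published twelve-level human-anatomy scheme
#'     (Biological macromolecule < ... < Organism) with kind annotations
#'     reflecting what each level's members actually instantiate.}
#'   \item{`fma_scheme`}{the salient levels of structural organization of
#'     the Foundational Model of Anatomy (Biological macromolecule < Cell
#'     < Portion of tissue < Organ < Organ system < Cardinal body part <
#'     Body), declared compositional, with the transitional (fiat) levels
#'     attached as the `"transitional"` attribute.}
#' }
#'
#' @param name one of `"fig2_organ"`, `"fig5_co"`, `"fig11_organ"`,
#'   `"kumar_human"`, `"fma_scheme"`.
#' @return A `partonomy` or an `external_scheme`.
#' @export
fixture <- function(name) {
  switch(
    name,
    fig2_organ = fixture_fig2_organ(),
    fig5_co = fixture_fig5_co(),
    fig11_organ = fixture_fig11_organ(),
    kumar_human = fixture_kumar_human(),
    fma_scheme = fixture_fma_scheme(),
    stop("lookup error: unknown fixture '", name, "'"))
}

fixture_fig2_organ <- function() {
  types <- list(
    material_type("molecule", "object"),
    material_type("organelle", "object"),
    material_type("cell", "object"),
    material_type("organ", "object"))
  instances <- data.frame(
    id = c("organ1", "q", "r", "m", "n", "o", "p", letters[1:12]),
    type_id = c("organ", "cell", "cell", rep("organelle", 4),
                rep("molecule", 12)),
    stringsAsFactors = FALSE)
  edge <- function(child, parent) {
    data.frame(child = child, relation = "direct_proper_part_of",
               parent = parent, stringsAsFactors = FALSE)
  }
  edges <- rbind(
    edge(c("q", "r", "a", "b", "c", "d"), "organ1"),
    edge(c("m", "n", "e", "f"), "q"),
    edge(c("o", "p", "g", "h"), "r"),
    edge("i", "m"), edge("j", "n"), edge("k", "o"), edge("l", "p"))
  partonomy(types, instances, edges)
}

fixture_fig5_co <- function() {
  types <- list(
    material_type("organelle", "object"),
    material_type("cell", "object"),
    material_type("organ", "object"))
  instances <- data.frame(
    id = c("organ1", "c1", "c2", "o1", "o2", "o3", "o4"),
    type_id = c("organ", "cell", "cell", rep("organelle", 4)),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    child = c("c1", "c2", "o1", "o2", "o3", "o4"),
    relation = "direct_proper_part_of",
    parent = c("organ1", "organ1", "c1", "c1", "c2", "c2"),
    stringsAsFactors = FALSE)
  partonomy(types, instances, edges)
}

fixture_fig11_organ <- function() {
  types <- list(
    material_type("cell", "object"),
    material_type("organ", "object"),
    material_type("fop1", "fiat_object_part", label = "fiat organ part 1",
                  name_giving = "organ"),
    material_type("fop2", "fiat_object_part", label = "fiat organ part 2",
                  name_giving = "organ"),
    material_type("fop3", "fiat_object_part", label = "fiat organ part 3",
                  name_giving = "organ"))
  instances <- data.frame(
    id = c("cell1", "f1", "f2", "f3", "organ1"),
    type_id = c("cell", "fop1", "fop2", "fop3", "organ"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    child = c("cell1", "f1", "f2", "f3"),
    relation = "direct_proper_part_of",
    parent = c("f1", "f2", "f3", "organ1"),
    stringsAsFactors = FALSE)
  partonomy(types, instances, edges)
}

KUMAR_LEVELS <- c("Biological macromolecule", "Subcellular organelle",
                  "Collection of subcellular organelles", "Cell",
                  "Collection of cells", "Tissue subdivision", "Tissue",
                  "Organ part", "Organ", "Cardinal body part",
                  "Organ system", "Organism")

fixture_kumar_human <- function() {
  ## kind annotations record what the level members actually instantiate in
  ## a cumulative-constitutively organized body: the would-be collections,
  ## tissues and body-part/organ-system levels are matrix-embedded or
  ## arbitrarily bounded and hence fiat object parts
  kinds <- c("object", "object", "fiat_object_part", "object",
             "fiat_object_part", "fiat_object_part", "fiat_object_part",
             "fiat_object_part", "object", "fiat_object_part",
             "fiat_object_part", "object")
  levels <- Map(function(label, kind) {
    list(label = label, kind = kind, members = label)
  }, KUMAR_LEVELS, kinds)
  external_scheme("kumar_human", unname(levels), declared = "compositional")
}

FMA_SALIENT <- c("Biological macromolecule", "Cell", "Portion of tissue",
                 "Organ", "Organ system", "Cardinal body part", "Body")
FMA_TRANSITIONAL <- c("Cardinal cell part", "Cardinal tissue part",
                      "Cardinal organ part", "Organ system subdivision",
                      "Subdivision of cardinal body part")

fixture_fma_scheme <- function() {
  kinds <- c("object", "object", "fiat_object_part", "object",
             "fiat_object_part", "fiat_object_part", "object")
  levels <- Map(function(label, kind) {
    list(label = label, kind = kind, members = label)
  }, FMA_SALIENT, kinds)
  sch <- external_scheme("fma_salient", unname(levels),
                         declared = "compositional")
  attr(sch, "transitional") <- FMA_TRANSITIONAL
  sch
}
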