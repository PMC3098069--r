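#' Sediment instance granularity to type granularity
#'
#' Under cumulative-constitutive organization the instances of one type can
#' occupy several instance granularity levels (some molecules sit directly
#' below the organ, others inside organelles), so an instance granularity
#' tree cannot be mapped directly onto a type granularity tree. The
#' pragmatic rule is sedimentation: a type occupies the *lowest* instance
#' granularity level any of its instances occupies.
#'
#' @param levels ordered list of instance levels from [enumerate_levels()]
#'   (index 1 = finest).
#' @param p a `partonomy`.
#' @return A data frame of class `type_level_map` with columns `type_id`,
#'   `level`. Types with no instance in any level are omitted with a
#'   warning (ontologies commonly declare uninstantiated types).
#' @examples
#' p <- fixture("fig2_organ")
#' tr <- build_granularity_tree("organ1", canonical_partitions(p, "organ1"), p)
#' sediment_types(enumerate_levels(tr), p)
#' @export
sediment_types <- function(levels, p) {
  spans <- type_level_spans(levels, p)
  out <- data.frame(type_id = names(spans),
                    level = vapply(spans, min, integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  uninst <- setdiff(p$types$id, out$type_id)
  uninst <- uninst[!uninst %in% p$instances$type_id]
  if (length(uninst)) {
    warning("types without instances omitted from the level map: ",
            paste(uninst, collapse = ", "))
  }
  class(out) <- c("type_level_map", class(out))
  out
}

type_level_spans <- function(levels, p) {
  stopifnot(inherits(p, "partonomy"), is.list(levels))
  all_ids <- unique(unlist(lapply(levels, `[[`, "content")))
  tid <- instance_type(p, all_ids)
  if (anyNA(tid)) {
    stop("reference error: level members are not known instances: ",
         paste(all_ids[is.na(tid)], collapse = ", "))
  }
  spans <- list()
  for (lv in levels) {
    tys <- unique(instance_type(p, lv$content))
    for (tp in tys) {
      spans[[tp]] <- sort(unique(c(spans[[tp]], as.integer(lv$index))))
    }
  }
  spans
}

#' Detect types whose extension crosses instance granularity levels
#'
#' In a cumulative-constitutive hierarchy the extension of some types
#' crosses level boundaries: e.g. 'molecule' occupies the finest cut
#' (organelle molecules), the next cut (cellular molecules) and the
#' coarsest non-root cut (extracellular molecules). These crossing types
#' are exactly the reason type-level parthood cannot be read off the
#' instance tree.
#'
#' @inheritParams sediment_types
#' @return Named list: one entry per crossing type, holding the sorted
#'   integer vector of occupied level indices. Empty for purely
#'   constitutive organizations.
#' @examples
#' p <- fixture("fig2_organ")
#' tr <- build_granularity_tree("organ1", canonical_partitions(p, "organ1"), p)
#' detect_crossing_types(enumerate_levels(tr), p)
#' @export
detect_crossing_types <- function(levels, p) {
  spans <- type_level_spans(levels, p)
  spans[lengths(spans) > 1]
}
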