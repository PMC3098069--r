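#' Import an OBO 1.2 flat file as a partonomy
#'
#' Reads the restricted OBO subset `id`, `name`, `is_a` and
#' `relationship: part_of`. OBO carries types only, so each term is
#' materialized as one prototypical instance (convention: instance id
#' `inst:<term id>`) and `part_of` becomes instance-level proper parthood
#' between the prototypes. A sidecar kind map (TSV with header columns
#' `id`, `kind`, `name_giving`) assigns the material-entity kind and the
#' name-giving object type per term; unmapped terms default to `object`
#' with a warning. `is_a` edges are taxonomy, never parthood: they are
#' retained in the `taxonomy` attribute.
#'
#' @param path OBO file path.
#' @param kind_map kind-map TSV path, or `NULL` (everything defaults to
#'   `object`).
#' @return A `partonomy` with attribute `taxonomy` (data frame of is_a
#'   pairs).
#' @export
import_obo <- function(path, kind_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  km <- NULL
  if (!is.null(kind_map)) {
    km <- utils::read.delim(kind_map, stringsAsFactors = FALSE)
    if (!all(c("id", "kind") %in% names(km))) {
      stop("parse error: kind map needs columns 'id' and 'kind'")
    }
    if (is.null(km$name_giving)) km$name_giving <- NA_character_
    km$name_giving[is.na(km$name_giving) | !nzchar(km$name_giving)] <-
      NA_character_
  }

  terms <- list()
  cur <- NULL
  cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) {
      stop("parse error: [Term] stanza starting at line ", cur_line,
           " has no id")
    }
    terms[[cur$id]] <<- cur
  }
  in_term <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "[Term]") {
      flush()
      cur <- list(part_of = character(0), is_a = character(0))
      cur_line <- i
      in_term <- TRUE
      next
    }
    if (startsWith(ln, "[")) {  # some other stanza type
      flush()
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    strip <- function(v) trimws(sub("!.*$", "", v))
    if (startsWith(ln, "id:")) {
      cur$id <- strip(substring(ln, 4))
    } else if (startsWith(ln, "name:")) {
      cur$name <- trimws(substring(ln, 6))
    } else if (startsWith(ln, "is_a:")) {
      cur$is_a <- c(cur$is_a, strip(substring(ln, 6)))
    } else if (startsWith(ln, "relationship:")) {
      rest <- strsplit(strip(substring(ln, 14)), "\\s+")[[1]]
      if (length(rest) != 2) {
        stop("parse error: malformed relationship at line ", i)
      }
      if (rest[1] == "part_of") cur$part_of <- c(cur$part_of, rest[2])
    }
  }
  flush()
  if (!length(terms)) stop("parse error: no [Term] stanzas found")

  ids <- names(terms)
  kind_of <- stats::setNames(rep("object", length(ids)), ids)
  ng_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(km)) {
    hit <- km$id %in% ids
    kind_of[km$id[hit]] <- km$kind[hit]
    ng_of[km$id[hit]] <- km$name_giving[hit]
  }
  unmapped <- ids[!(ids %in% (km$id %||% character(0)))]
  if (!is.null(km) && length(unmapped)) {
    warning("terms missing from the kind map default to kind 'object': ",
            paste(unmapped, collapse = ", "))
  }
  types <- lapply(ids, function(tid) {
    material_type(tid, kind_of[[tid]],
                  label = terms[[tid]]$name %||% tid,
                  name_giving = if (is.na(ng_of[[tid]])) NULL else
                    ng_of[[tid]])
  })
  instances <- data.frame(id = paste0("inst:", ids), type_id = ids,
                          stringsAsFactors = FALSE)
  edges <- do.call(rbind, c(list(empty_edges()), lapply(ids, function(tid) {
    tgt <- terms[[tid]]$part_of
    tgt <- tgt[tgt %in% ids]
    if (!length(tgt)) return(NULL)
    data.frame(child = paste0("inst:", tid), relation = "proper_part_of",
               parent = paste0("inst:", tgt), stringsAsFactors = FALSE)
  })))
  taxonomy <- do.call(rbind, c(
    list(data.frame(child = character(), parent = character(),
                    stringsAsFactors = FALSE)),
    lapply(ids, function(tid) {
      isa <- terms[[tid]]$is_a
      if (!length(isa)) return(NULL)
      data.frame(child = tid, parent = isa, stringsAsFactors = FALSE)
    })))
  p <- partonomy(types, instances, edges)
  attr(p, "taxonomy") <- taxonomy
  p
}
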