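DOCUMENT_FORMAT_VERSION <- "1.0"

document_list <- function(p, results = NULL) {
  types <- p$types[order(p$types$id), , drop = FALSE]
  type_items <- lapply(seq_len(nrow(types)), function(i) {
    item <- list(id = types$id[i], label = types$label[i],
                 kind = types$kind[i])
    if (!is.na(types$name_giving[i])) {
      item$name_giving <- types$name_giving[i]
    }
    if (!is.na(types$rep_target[i])) {
      item$represents <- list(target = types$rep_target[i],
                              countable = types$rep_countable[i])
    }
    item
  })
  inst <- p$instances[order(p$instances$id), , drop = FALSE]
  inst_items <- lapply(seq_len(nrow(inst)), function(i) {
    list(id = inst$id[i], type = inst$type_id[i])
  })
  ed <- p$edges[order(p$edges$child, p$edges$parent, p$edges$relation), ,
                drop = FALSE]
  edge_items <- lapply(seq_len(nrow(ed)), function(i) {
    list(child = ed$child[i], relation = ed$relation[i],
         parent = ed$parent[i])
  })
  doc <- list(format_version = DOCUMENT_FORMAT_VERSION,
              types = type_items, instances = inst_items,
              edges = edge_items)
  if (nrow(p$measures)) {
    ms <- p$measures[order(p$measures$instance, p$measures$quantity), ,
                     drop = FALSE]
    doc$measures <- lapply(seq_len(nrow(ms)), function(i) {
      item <- list(instance = ms$instance[i], quantity = ms$quantity[i],
                   value = ms$value[i])
      if (!is.na(ms$unit[i])) item$unit <- ms$unit[i]
      item
    })
  }
  if (length(p$schemes)) {
    schemes <- p$schemes[order(vapply(p$schemes, `[[`, character(1),
                                      "name"))]
    doc$schemes <- lapply(schemes, function(s) {
      list(name = s$name, declared = s$declared,
           levels = lapply(s$levels, function(lv) {
             list(label = lv$label, kind = lv$kind,
                  members = I(as.character(lv$members)))
           }))
    })
  }
  if (!is.null(results)) doc$results <- results
  doc
}

#' Serialize a partonomy to a JSON document
#'
#' Writes the canonical JSON document format (sorted types, instances and
#' edges), so that write / parse / write round-trips are byte-identical.
#' An optional `results` list (perspectives, values, reports, as produced
#' by the CLI) is appended verbatim; it is output-only and ignored on
#' re-parse.
#'
#' @param p a `partonomy`.
#' @param path output file path, or `NULL` to return the JSON text.
#' @param results optional results list to embed.
#' @return The path (invisibly), or the JSON text when `path` is `NULL`.
#' @seealso [parse_document()]
#' @export
write_partonomy <- function(p, path = NULL, results = NULL) {
  stopifnot(inherits(p, "partonomy"))
  txt <- jsonlite::toJSON(document_list(p, results), pretty = 2,
                          auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

need <- function(x, field, where) {
  if (is.null(x[[field]])) {
    stop("parse error at ", where, ": missing required field '", field, "'")
  }
  x[[field]]
}

#' Parse a partonomy JSON document
#'
#' Reads the document format written by [write_partonomy()] and
#' reconstructs the validated model; all core referential invariants are
#' checked on load (a dangling edge endpoint, for instance, is a parse
#' error naming the edge).
#'
#' @param source file path or JSON text.
#' @return A `partonomy` (schemes attached in `$schemes`).
#' @export
parse_document <- function(source) {
  txt <- if (length(source) == 1 && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else paste(source, collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) {
                    stop("parse error: invalid JSON: ", conditionMessage(e))
                  })
  if (is.null(doc$format_version)) {
    stop("parse error at $: missing format_version")
  }
  types <- lapply(seq_along(doc$types), function(i) {
    tp <- doc$types[[i]]
    where <- paste0("$.types[", i, "]")
    rep <- NULL
    if (!is.null(tp$represents)) {
      rep <- list(target = need(tp$represents, "target",
                                paste0(where, ".represents")),
                  countable = isTRUE(tp$represents$countable))
    }
    material_type(need(tp, "id", where), need(tp, "kind", where),
                  label = tp$label %||% tp$id,
                  name_giving = tp$name_giving, represents = rep)
  })
  instances <- do.call(rbind, lapply(seq_along(doc$instances), function(i) {
    it <- doc$instances[[i]]
    where <- paste0("$.instances[", i, "]")
    data.frame(id = need(it, "id", where),
               type_id = need(it, "type", where), stringsAsFactors = FALSE)
  }))
  edges <- if (length(doc$edges)) {
    do.call(rbind, lapply(seq_along(doc$edges), function(i) {
      e <- doc$edges[[i]]
      where <- paste0("$.edges[", i, "]")
      data.frame(child = need(e, "child", where),
                 relation = need(e, "relation", where),
                 parent = need(e, "parent", where), stringsAsFactors = FALSE)
    }))
  } else empty_edges()
  measures <- if (length(doc$measures)) {
    do.call(rbind, lapply(seq_along(doc$measures), function(i) {
      m <- doc$measures[[i]]
      where <- paste0("$.measures[", i, "]")
      data.frame(instance = need(m, "instance", where),
                 quantity = need(m, "quantity", where),
                 value = as.numeric(need(m, "value", where)),
                 unit = m$unit %||% NA_character_, stringsAsFactors = FALSE)
    }))
  } else NULL
  schemes <- lapply(seq_along(doc$schemes), function(i) {
    s <- doc$schemes[[i]]
    where <- paste0("$.schemes[", i, "]")
    external_scheme(need(s, "name", where),
                    lapply(s$levels, function(lv) {
                      list(label = lv$label, kind = lv$kind,
                           members = unlist(lv$members))
                    }),
                    declared = s$declared %||% "unspecified")
  })
  tryCatch(partonomy(types, instances, edges, measures = measures,
                     schemes = schemes),
           error = function(e) {
             stop("parse error: ", conditionMessage(e), call. = FALSE)
           })
}

#' Export a value map as a tab-separated table
#'
#' One row per valued entity: entity id, governing perspective, level
#' index, representative value (numeric), and exact interval bounds where
#' applicable.
#'
#' @param v a `value_map`.
#' @param path output path or `NULL` for the text.
#' @return The path invisibly, or the TSV text.
#' @export
write_value_table <- function(v, path = NULL) {
  stopifnot(inherits(v, "value_map"))
  fmt <- function(df, id_col) {
    if (!nrow(df)) return(character(0))
    vapply(seq_len(nrow(df)), function(i) {
      r <- df[i, ]
      rep_v <- r$rep_num / r$rep_den
      bounds <- if (!is.na(r$lo_num)) {
        paste0(rat_format(rat(r$lo_num, r$lo_den)), "\t",
               rat_format(rat(r$hi_num, r$hi_den)))
      } else "\t"
      paste0(r[[id_col]], "\t", r$perspective, "\t",
             if (is.na(r$index)) "" else r$index, "\t", rep_v, "\t", bounds)
    }, character(1))
  }
  lines <- c("entity\tperspective\tlevel\trepresentative\tlo\thi",
             fmt(v$levels, "level_id"), fmt(v$instances, "instance"))
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV edge list as a partonomy
#'
#' Reads `child <tab> relation <tab> parent` lines (no header, `#`
#' comments allowed). Instances are inferred from the endpoints and all
#' typed with a single default object type, which suffices for order
#' validation.
#'
#' @param path TSV file path.
#' @return A `partonomy`.
#' @export
read_edge_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad)) {
    stop("parse error: line ", bad[1], " does not have three fields")
  }
  edges <- data.frame(child = vapply(parts, `[[`, character(1), 1),
                      relation = vapply(parts, `[[`, character(1), 2),
                      parent = vapply(parts, `[[`, character(1), 3),
                      stringsAsFactors = FALSE)
  ids <- sort(unique(c(edges$child, edges$parent)))
  partonomy(list(material_type("tsv:entity", "object")),
            data.frame(id = ids, type_id = "tsv:entity",
                       stringsAsFactors = FALSE),
            edges)
}
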