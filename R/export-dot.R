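#' Export a granularity tree or framework to Graphviz DOT
#'
#' Produces deterministic DOT text: nodes are emitted in sorted order,
#' granularity levels are rendered as `rank=same` groups, and (for
#' frameworks) overcrossing perspective pairs appear as dashed edges.
#' Identical input always yields identical text.
#'
#' @param x a `granularity_tree` or `granularity_framework`.
#' @param ... unused.
#' @return DOT source as a single character string.
#' @export
export_dot <- function(x, ...) UseMethod("export_dot")

dot_quote <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")

#' @export
export_dot.granularity_tree <- function(x, ...) {
  lines <- c("digraph granularity_tree {", "  rankdir=BT;")
  for (lv in tree_node_levels(x)) {
    lines <- c(lines, paste0(
      "  { rank=same; ",
      paste(dot_quote(sort(lv$content)), collapse = "; "), "; }"))
  }
  kids <- sort(names(x$parent))
  for (k in kids) {
    lines <- c(lines,
               paste0("  ", dot_quote(k), " -> ", dot_quote(x$parent[[k]]),
                      ";"))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
export_dot.granularity_framework <- function(x, ...) {
  lines <- c("digraph granularity_framework {", "  rankdir=BT;",
             "  node [shape=box];")
  for (pid in sort(names(x$perspectives))) {
    pp <- x$perspectives[[pid]]
    lines <- c(lines,
               paste0("  subgraph ", dot_quote(paste0("cluster_", pid)),
                      " {"),
               paste0("    label=", dot_quote(pid), ";"))
    for (lv in pp$levels) {
      lines <- c(lines, paste0(
        "    ", dot_quote(lv$id), " [label=",
        dot_quote(paste0("L", lv$index, ": ",
                         paste(sort(lv$content), collapse = ", "))), "];"))
    }
    lines <- c(lines, "  }")
    n <- length(pp$levels)
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        lines <- c(lines, paste0(
          "  ", dot_quote(pp$levels[[i]]$id), " -> ",
          dot_quote(pp$levels[[i + 1]]$id), ";"))
      }
    }
  }
  oc <- x$overcross
  if (!is.null(oc) && nrow(oc)) {
    oc <- oc[order(oc$l1, oc$l2), , drop = FALSE]
    for (i in seq_len(nrow(oc))) {
      lines <- c(lines, paste0(
        "  ", dot_quote(oc$l1[i]), " -> ", dot_quote(oc$l2[i]),
        " [style=dashed, dir=none];"))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
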