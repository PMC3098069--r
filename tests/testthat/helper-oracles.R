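# Independent brute-force oracles. These deliberately avoid the package's
# matrix-based closure machinery: reachability is computed by recursive
# depth-first search over the raw edge list, cuts by frontier expansion
# over an explicit children list.

oracle_reachable <- function(edges, from, to) {
  seen <- character(0)
  walk <- function(x) {
    if (x %in% seen) return(FALSE)
    seen <<- c(seen, x)
    nxt <- edges$parent[edges$child == x]
    if (to %in% nxt) return(TRUE)
    for (y in nxt) if (walk(y)) return(TRUE)
    FALSE
  }
  walk(from)
}

# all ordered pairs (x, y) with a directed path x -> y
oracle_closure_pairs <- function(edges, ids) {
  out <- character(0)
  for (x in ids) for (y in ids) {
    if (x != y && oracle_reachable(edges, x, y)) {
      out <- c(out, paste(x, y))
    }
  }
  sort(out)
}

oracle_has_cycle <- function(edges, ids) {
  any(vapply(ids, function(x) oracle_reachable(edges, x, x), logical(1)))
}

# frontier-expansion cut enumeration over an explicit children mapping:
# cut 0 = {root}; each next cut replaces nodes with children by their
# children and keeps leaves; returns the list of cuts coarse to fine
oracle_cuts <- function(root, parent_map) {
  children <- split(names(parent_map), unname(parent_map))
  cuts <- list(root)
  frontier <- root
  repeat {
    nxt <- unlist(lapply(frontier, function(n) {
      kids <- children[[n]]
      if (is.null(kids)) n else kids
    }))
    nxt <- sort(unique(nxt))
    if (identical(nxt, sort(frontier))) break
    cuts[[length(cuts) + 1L]] <- nxt
    frontier <- nxt
  }
  cuts
}

# minimum level index per type, straight from the level listing
oracle_sediment <- function(levels, p) {
  mins <- list()
  for (lv in levels) {
    for (inst in lv$content) {
      tp <- p$instances$type_id[p$instances$id == inst]
      mins[[tp]] <- min(c(mins[[tp]], lv$index))
    }
  }
  mins[order(names(mins))]
}

expect_clean_report <- function(report) {
  expect_s3_class(report, "lint_report")
  expect_identical(nrow(report[report$severity == "error", ]), 0L)
}
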