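# Threshold conformer graphs and their minimal spanning forests.

#' Build a conformer graph from a distance matrix
#'
#' Nodes are conformers (with abundances); edges connect pairs whose
#' distance is below the threshold (10 Angstrom by default). The minimal
#' spanning forest -- a minimum-weight spanning tree per connected
#' component -- is computed alongside, with ties broken by lexicographic
#' node-pair order so the result is deterministic.
#'
#' @param records a `conformer_set` (for names and abundances), or a
#'   character vector of node names
#' @param dist_matrix symmetric distance matrix with zero diagonal
#' @param threshold edge threshold in the matrix's units (Angstrom)
#' @return an object of class `conformer_graph`: list with `nodes`
#'   (data.frame: name, abundance), `edges` (data.frame: from, to, weight,
#'   in_forest)
#' @export
build_graph <- function(records, dist_matrix, threshold = 10) {
  d <- as.matrix(dist_matrix)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (inherits(records, "conformer_set")) {
    nodes <- data.frame(name = records$short_name,
                        abundance = records$abundance)
  } else {
    nodes <- data.frame(name = as.character(records),
                        abundance = NA_real_)
  }
  if (nrow(nodes) != nrow(d)) stop("node count does not match matrix")
  hit <- which(upper.tri(d) & d < threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = nodes$name[hit[, 1L]], to = nodes$name[hit[, 2L]],
    weight = d[hit], in_forest = logical(nrow(hit))
  )
  g <- structure(list(nodes = nodes, edges = edges, threshold = threshold),
                 class = "conformer_graph")
  g$edges$in_forest <- min_spanning_forest(g)
  g
}

#' @export
print.conformer_graph <- function(x, ...) {
  cat("Conformer graph:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (threshold", x$threshold, "A),",
      sum(x$edges$in_forest), "in the spanning forest\n")
  invisible(x)
}

#' Minimal spanning forest of a conformer graph
#'
#' Kruskal's algorithm per connected component; among equal-weight edges
#' the lexicographically smallest (from, to) pair wins.
#'
#' @param g a `conformer_graph`
#' @return logical vector flagging the forest edges (same order as
#'   `g$edges`)
#' @export
min_spanning_forest <- function(g) {
  e <- g$edges
  n_e <- nrow(e)
  if (n_e == 0L) return(logical(0))
  ord <- order(e$weight, e$from, e$to)
  parent <- stats::setNames(g$nodes$name, g$nodes$name)
  find <- function(v) {
    while (parent[[v]] != v) {
      parent[[v]] <<- parent[[parent[[v]]]]
      v <- parent[[v]]
    }
    v
  }
  keep <- logical(n_e)
  for (r in ord) {
    ra <- find(e$from[r]); rb <- find(e$to[r])
    if (ra != rb) { parent[[ra]] <- rb; keep[r] <- TRUE }
  }
  keep
}

#' Export a conformer graph as an edge-list text file
#' @param g a `conformer_graph`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_graph_edgelist <- function(g, path) {
  writeLines(c("# from\tto\tweight\tin_forest",
               sprintf("%s\t%s\t%.6f\t%d", g$edges$from, g$edges$to,
                       g$edges$weight, as.integer(g$edges$in_forest))),
             path)
  invisible(path)
}

#' Convert a conformer graph to an igraph object
#' @param g a `conformer_graph`
#' @return an `igraph` graph with `weight` and `in_forest` edge attributes
#'   and `abundance` vertex attribute
#' @export
as_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = g$nodes)
  ig
}
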