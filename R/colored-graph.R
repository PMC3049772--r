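#' Build a colored graph
#'
#' A colored graph holds a node set with one categorical color per node, a
#' set of directed arcs (e.g. chemical synapses) and a set of undirected
#' links (e.g. gap junctions). It is the substrate of the motif census: arcs
#' stay directed, links enter the directed encoding as reciprocal arc pairs.
#'
#' @param nodes tibble/data frame with columns `node` (character) and
#'   `color` (character or factor). Every node appearing in an edge must be
#'   present here.
#' @param arcs tibble with columns `from`, `to`: directed edges. Duplicates
#'   are merged (the census is unweighted).
#' @param links tibble with columns `from`, `to`: undirected edges, stored
#'   canonically with `from < to`.
#' @param color_levels optional character vector fixing the color alphabet
#'   and its index order (index 0 = first level). Defaults to the order of
#'   first appearance in `nodes$color`.
#' @return An object of class `colored_graph`: a list with tibbles `nodes`
#'   (columns `node`, `color`), `arcs` and `links`, plus the color-level
#'   table in `attr(, "color_levels")`.
#' @examples
#' g <- colored_graph(
#'   nodes = tibble::tibble(node = c("a", "b", "c"),
#'                          color = c("sensor", "inter", "motor")),
#'   arcs  = tibble::tibble(from = c("a", "b"), to = c("b", "c")),
#'   links = tibble::tibble(from = "a", to = "c")
#' )
#' g
#' @export
colored_graph <- function(nodes, arcs = NULL, links = NULL,
                          color_levels = NULL) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("node", "color") %in% names(nodes)))
  nodes$node <- as.character(nodes$node)
  nodes$color <- as.character(nodes$color)
  if (anyDuplicated(nodes$node)) {
    stop("duplicate node identifiers in the node table", call. = FALSE)
  }
  if (anyNA(nodes$color)) {
    stop("every node must have a color", call. = FALSE)
  }
  if (is.null(color_levels)) {
    color_levels <- unique(nodes$color)
  }
  if (!all(nodes$color %in% color_levels)) {
    stop("node colors outside the declared color alphabet", call. = FALSE)
  }

  arcs <- normalize_edges(arcs, nodes$node, directed = TRUE)
  links <- normalize_edges(links, nodes$node, directed = FALSE)

  structure(
    list(nodes = nodes, arcs = arcs, links = links),
    color_levels = color_levels,
    class = "colored_graph"
  )
}

normalize_edges <- function(edges, node_ids, directed) {
  if (is.null(edges) || nrow(tibble::as_tibble(edges)) == 0) {
    return(tibble::tibble(from = character(), to = character()))
  }
  edges <- tibble::as_tibble(edges)[, c("from", "to")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  bad <- setdiff(c(edges$from, edges$to), node_ids)
  if (length(bad) > 0) {
    stop("edge endpoints missing from the node table: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(edges$from == edges$to)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (!directed) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  dup <- duplicated(edges)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) merged", call. = FALSE)
    edges <- edges[!dup, ]
  }
  dplyr::arrange(edges, .data$from, .data$to)
}

#' @export
print.colored_graph <- function(x, ...) {
  lv <- attr(x, "color_levels")
  tab <- table(factor(x$nodes$color, levels = lv))
  cat("<colored_graph> ", nrow(x$nodes), " nodes, ",
      nrow(x$arcs), " arcs, ", nrow(x$links), " links\n", sep = "")
  cat("  colors: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Color levels of a colored graph
#' @param g a `colored_graph`
#' @return Character vector of color names; position i is color index i - 1.
#' @export
color_levels <- function(g) {
  stopifnot(inherits(g, "colored_graph"))
  attr(g, "color_levels")
}

#' Integer color indices (0-based) in node order
#' @noRd
color_indices <- function(g) {
  match(g$nodes$color, color_levels(g)) - 1L
}

#' Directed encoding of a colored graph
#'
#' Expands the mixed graph into a plain digraph over node indices: every arc
#' passes through and every undirected link \{u, v\} contributes both (u, v)
#' and (v, u), the adjacency-matrix representation of a gap junction. A
#' coincident arc and link between the same pair collapse onto the same
#' reciprocal pair; the original `colored_graph` keeps both so the ambiguity
#' can be flagged in reports.
#'
#' @param g a `colored_graph`
#' @return A list of class `digraph_encoding`: `n` (node count), `nodes`
#'   (identifiers), `edges` (integer matrix, 1-based from/to indices, one row
#'   per arc after expansion, duplicates collapsed), `colors` (0-based color
#'   indices per node).
#' @export
directed_encoding <- function(g) {
  stopifnot(inherits(g, "colored_graph"))
  idx <- setNames(seq_len(nrow(g$nodes)), g$nodes$node)
  ea <- cbind(idx[g$arcs$from], idx[g$arcs$to])
  el <- cbind(idx[g$links$from], idx[g$links$to])
  edges <- rbind(ea, el, el[, c(2, 1), drop = FALSE])
  edges <- unique(edges)
  rownames(edges) <- NULL
  structure(
    list(n = nrow(g$nodes), nodes = g$nodes$node,
         edges = matrix(as.integer(edges), ncol = 2),
         colors = color_indices(g)),
    class = "digraph_encoding"
  )
}

#' Undirected projection of a colored graph
#'
#' Forgets edge direction: every arc and every link becomes an undirected
#' link, duplicates merged. Used by the undirected census mode.
#'
#' @param g a `colored_graph`
#' @return A `colored_graph` with an empty arc set.
#' @export
undirected_projection <- function(g) {
  stopifnot(inherits(g, "colored_graph"))
  all_edges <- dplyr::bind_rows(g$arcs, g$links)
  if (nrow(all_edges) > 0) {
    swap <- all_edges$from > all_edges$to
    tmp <- all_edges$from[swap]
    all_edges$from[swap] <- all_edges$to[swap]
    all_edges$to[swap] <- tmp
    all_edges <- dplyr::distinct(all_edges)
  }
  suppressWarnings(
    colored_graph(g$nodes, arcs = NULL, links = all_edges,
                  color_levels = color_levels(g))
  )
}
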