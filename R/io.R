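#' Read a colored network from TSV files
#'
#' The edge list is a 3-column TSV with header `source`, `target`, `kind`
#' where `kind` is `directed` (chemical synapse) or `undirected` (gap
#' junction). The color map is a 2-column TSV with header `node`, `color`.
#' Nodes listed in the color map but absent from the edge list are ignored
#' with a warning (they would otherwise distort the color pool of the
#' shuffle null); nodes appearing in edges but missing from the color map
#' are an error.
#'
#' @param edge_list_path path to the edge-list TSV
#' @param color_map_path path to the node-color TSV
#' @param color_levels optional fixed color alphabet (see [colored_graph()])
#' @return A [colored_graph()].
#' @export
read_colored_network <- function(edge_list_path, color_map_path,
                                 color_levels = NULL) {
  edges <- readr::read_tsv(edge_list_path, col_types = "ccc",
                           progress = FALSE)
  if (!all(c("source", "target", "kind") %in% names(edges))) {
    stop("edge list must have columns source, target, kind", call. = FALSE)
  }
  bad <- which(!edges$kind %in% c("directed", "undirected"))
  if (length(bad) > 0) {
    stop("edge list line ", bad[1] + 1L,
         ": kind must be 'directed' or 'undirected', got '",
         edges$kind[bad[1]], "'", call. = FALSE)
  }
  loops <- which(edges$source == edges$target)
  if (length(loops) > 0) {
    stop("edge list line ", loops[1] + 1L, ": self-loop on '",
         edges$source[loops[1]], "'", call. = FALSE)
  }

  cmap <- readr::read_tsv(color_map_path, col_types = "cc", progress = FALSE)
  if (!all(c("node", "color") %in% names(cmap))) {
    stop("color map must have columns node, color", call. = FALSE)
  }

  edge_nodes <- unique(c(edges$source, edges$target))
  uncolored <- setdiff(edge_nodes, cmap$node)
  if (length(uncolored) > 0) {
    stop("nodes without a color: ",
         paste(head(uncolored, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(color_levels)) color_levels <- unique(cmap$color)
  unknown <- setdiff(cmap$node, edge_nodes)
  if (length(unknown) > 0) {
    warning(length(unknown),
            " color-map node(s) absent from the edge list ignored",
            call. = FALSE)
    cmap <- cmap[cmap$node %in% edge_nodes, ]
  }
  colored_graph(
    nodes = tibble::tibble(node = cmap$node, color = cmap$color),
    arcs = tibble::tibble(from = edges$source[edges$kind == "directed"],
                          to = edges$target[edges$kind == "directed"]),
    links = tibble::tibble(from = edges$source[edges$kind == "undirected"],
                           to = edges$target[edges$kind == "undirected"]),
    color_levels = color_levels
  )
}

#' Write a colored network to TSV files
#'
#' Inverse of [read_colored_network()]; a read/write/read round trip yields
#' an identical graph.
#'
#' @param g a [colored_graph()]
#' @param edge_list_path,color_map_path output paths
#' @return `g`, invisibly.
#' @export
write_colored_network <- function(g, edge_list_path, color_map_path) {
  stopifnot(inherits(g, "colored_graph"))
  edges <- dplyr::bind_rows(
    tibble::tibble(source = g$arcs$from, target = g$arcs$to,
                   kind = "directed"),
    tibble::tibble(source = g$links$from, target = g$links$to,
                   kind = "undirected")
  )
  readr::write_tsv(edges, edge_list_path, progress = FALSE)
  readr::write_tsv(tibble::tibble(node = g$nodes$node,
                                  color = g$nodes$color),
                   color_map_path, progress = FALSE)
  invisible(g)
}

#' Read a colored network from GraphML
#'
#' Expects a node attribute `color` and an edge attribute `kind`
#' (`directed`/`undirected`). Both directed and undirected GraphML files are
#' accepted; the `kind` attribute, not the file-level directedness, decides
#' whether an edge is an arc or a link.
#'
#' @param path GraphML file path
#' @param color_levels optional fixed color alphabet
#' @return A [colored_graph()].
#' @export
read_colored_graphml <- function(path, color_levels = NULL) {
  ig <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble::tibble(
    node = igraph::vertex_attr(ig, "name"),
    color = igraph::vertex_attr(ig, "color")
  )
  if (is.null(nodes$node[1]) || anyNA(nodes$node)) {
    nodes$node <- as.character(seq_len(igraph::vcount(ig)))
  }
  if (is.null(igraph::edge_attr(ig, "kind"))) {
    stop("GraphML file lacks the edge attribute 'kind'", call. = FALSE)
  }
  el <- igraph::as_edgelist(ig, names = TRUE)
  kind <- igraph::edge_attr(ig, "kind")
  colored_graph(
    nodes = nodes,
    arcs = tibble::tibble(from = el[kind == "directed", 1],
                          to = el[kind == "directed", 2]),
    links = tibble::tibble(from = el[kind == "undirected", 1],
                           to = el[kind == "undirected", 2]),
    color_levels = color_levels
  )
}

#' Convert a colored graph to an igraph object
#'
#' Directed igraph graph over the expanded encoding is used when
#' `encoding = "directed"`; `encoding = "mixed"` keeps one edge per arc/link
#' with a `kind` attribute (suitable for GraphML export via
#' [igraph::write_graph()]).
#'
#' @param g a [colored_graph()]
#' @param encoding `"mixed"` or `"directed"`
#' @return An igraph object with vertex attribute `color`.
#' @export
as_igraph <- function(g, encoding = c("mixed", "directed")) {
  stopifnot(inherits(g, "colored_graph"))
  encoding <- match.arg(encoding)
  if (encoding == "directed") {
    enc <- directed_encoding(g)
    ig <- igraph::graph_from_edgelist(
      cbind(enc$nodes[enc$edges[, 1]], enc$nodes[enc$edges[, 2]]),
      directed = TRUE
    )
    ig <- igraph::add_vertices(
      ig, sum(!g$nodes$node %in% igraph::V(ig)$name),
      name = setdiff(g$nodes$node, igraph::V(ig)$name)
    )
  } else {
    edges <- dplyr::bind_rows(
      tibble::tibble(from = g$arcs$from, to = g$arcs$to, kind = "directed"),
      tibble::tibble(from = g$links$from, to = g$links$to,
                     kind = "undirected")
    )
    ig <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                        vertices = g$nodes$node)
  }
  idx <- match(igraph::V(ig)$name, g$nodes$node)
  igraph::V(ig)$color <- g$nodes$color[idx]
  ig
}
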