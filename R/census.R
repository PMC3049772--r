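#' Canonical key of a colored motif
#'
#' The canonical key identifies a colored isomorphism class: two colored
#' subgraphs get the same key exactly when some node permutation maps one
#' onto the other, topology and colors simultaneously. The key is the
#' lexicographic minimum over all k! permutations of the pair
#' (adjacency bit code, color sequence), serialized as
#' `"k|mode|adjacency-code|color-code"` with `mode` `d` or `u`, the
#' adjacency code the off-diagonal entries read row-major as a big-endian
#' integer, and the color code the k color indices as decimal digits.
#'
#' @param adjacency k x k 0/1 matrix, zero diagonal; symmetric when
#'   `mode = "undirected"`.
#' @param colors integer vector of k color indices (0-based).
#' @param mode `"directed"` or `"undirected"`.
#' @return The key string. Disconnected subgraphs are an error: the census
#'   never produces one and class enumeration filters them.
#' @examples
#' # the sensor -> inter -> motor relay chain
#' adj <- matrix(0, 3, 3); adj[1, 2] <- 1; adj[2, 3] <- 1
#' canonical_key(adj, c(0, 1, 2), "directed")
#' @export
canonical_key <- function(adjacency, colors, mode = c("directed",
                                                      "undirected")) {
  mode <- match.arg(mode)
  cpp_canonical_key(adjacency, as.integer(colors), mode == "directed")
}

census_mode <- function(mode) {
  match.arg(mode, c("directed", "undirected"))
}

#' Colored motif census
#'
#' Enumerates every induced connected subgraph on `k` nodes with the ESU
#' (FANMOD) algorithm and tallies them by canonical colored class. In
#' directed mode the graph is the directed encoding (gap-junction links
#' expanded to reciprocal arc pairs; weak connectivity); in undirected mode
#' it is the undirected projection.
#'
#' @param g a [colored_graph()]
#' @param k motif size, 2 to 4. Size 5 is refused: the possible colored
#'   class count runs into the millions, which defeats the significance
#'   analysis downstream.
#' @param mode `"directed"` or `"undirected"`
#' @return A tibble of class `motif_census` with columns `key` and `count`,
#'   one row per observed class, plus attributes `k`, `mode`, `total`
#'   (number of induced connected k-subgraphs) and `color_levels`.
#' @examples
#' g <- colored_graph(
#'   nodes = tibble::tibble(node = c("a", "b", "c"),
#'                          color = c("sensor", "inter", "motor")),
#'   arcs  = tibble::tibble(from = c("a", "b"), to = c("b", "c"))
#' )
#' motif_census(g, k = 3)
#' @export
motif_census <- function(g, k, mode = c("directed", "undirected")) {
  stopifnot(inherits(g, "colored_graph"))
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1 || !k %in% 2:4) {
    stop("motif size k must be 2, 3 or 4", call. = FALSE)
  }
  if (mode == "directed") {
    enc <- directed_encoding(g)
    counts <- cpp_motif_census(enc$n, enc$edges, as.integer(enc$colors),
                               as.integer(k), TRUE)
  } else {
    pg <- undirected_projection(g)
    idx <- setNames(seq_len(nrow(pg$nodes)), pg$nodes$node)
    edges <- matrix(as.integer(cbind(idx[pg$links$from], idx[pg$links$to])),
                    ncol = 2)
    counts <- cpp_motif_census(nrow(pg$nodes), edges,
                               as.integer(color_indices(pg)),
                               as.integer(k), FALSE)
  }
  out <- tibble::tibble(key = names(counts), count = as.numeric(counts))
  out <- dplyr::arrange(out, .data$key)
  structure(out,
            k = as.integer(k), mode = mode, total = sum(out$count),
            color_levels = color_levels(g),
            class = c("motif_census", class(out)))
}

#' Connected induced k-subsets of a colored graph
#'
#' Exposes the raw ESU enumeration: each connected (weakly connected in
#' directed mode) induced k-node subset, exactly once.
#'
#' @inheritParams motif_census
#' @return Character matrix with k columns, one row per subset, node
#'   identifiers sorted within each row.
#' @export
enumerate_connected_subsets <- function(g, k,
                                        mode = c("directed", "undirected")) {
  stopifnot(inherits(g, "colored_graph"))
  mode <- match.arg(mode)
  if (mode == "directed") {
    enc <- directed_encoding(g)
    m <- cpp_connected_subsets(enc$n, enc$edges, as.integer(k), TRUE)
    nodes <- enc$nodes
  } else {
    pg <- undirected_projection(g)
    idx <- setNames(seq_len(nrow(pg$nodes)), pg$nodes$node)
    edges <- matrix(as.integer(cbind(idx[pg$links$from], idx[pg$links$to])),
                    ncol = 2)
    m <- cpp_connected_subsets(nrow(pg$nodes), edges, as.integer(k), FALSE)
    nodes <- pg$nodes$node
  }
  matrix(nodes[m], ncol = ncol(m))
}

#' Enumerate all possible colored motif classes
#'
#' Brute force over every edge configuration on k nodes and every coloring
#' from a `n_colors`-letter alphabet, keeping connected (weakly connected
#' for directed) graphs and deduplicating by canonical key. These are the
#' "possible" class counts against which observed class counts are compared
#' (e.g. 13 uncolored directed topologies of size 3; 13,770 directed
#' 3-colored classes of size 4).
#'
#' @param k motif size, 2 to 4
#' @param n_colors size of the color alphabet
#' @param mode `"directed"` or `"undirected"`
#' @return A tibble with columns `key`, `k`, `mode`, `n_colors`, one row per
#'   possible class.
#' @examples
#' nrow(enumerate_motif_classes(3, 1, "directed"))  # 13
#' @export
enumerate_motif_classes <- function(k, n_colors,
                                    mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1 || !k %in% 2:4) {
    stop("class enumeration supports sizes 2 to 4 only; size 5 has ",
         "millions of possible colored classes", call. = FALSE)
  }
  keys <- cpp_enumerate_classes(as.integer(k), as.integer(n_colors),
                                mode == "directed")
  tibble::tibble(key = keys, k = as.integer(k), mode = mode,
                 n_colors = as.integer(n_colors))
}

#' Parse motif keys
#'
#' Decodes canonical key strings back into adjacency matrices and color
#' index vectors.
#'
#' @param keys character vector of canonical keys
#' @return A tibble with columns `key`, `k`, `mode`, and list-columns
#'   `adjacency` (k x k 0/1 matrix) and `colors` (integer vector,
#'   0-based).
#' @export
parse_motif_key <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  bad <- lengths(parts) != 4
  if (any(bad)) {
    stop("malformed motif key: ", keys[which(bad)[1]], call. = FALSE)
  }
  k <- as.integer(purrr::map_chr(parts, 1))
  mode <- ifelse(purrr::map_chr(parts, 2) == "d", "directed", "undirected")
  code <- as.numeric(purrr::map_chr(parts, 3))
  colstr <- purrr::map_chr(parts, 4)
  adjacency <- purrr::map2(code, k, decode_adjacency)
  colors <- purrr::map(strsplit(colstr, ""), as.integer)
  tibble::tibble(key = keys, k = k, mode = mode,
                 adjacency = adjacency, colors = colors)
}

decode_adjacency <- function(code, k) {
  n_bits <- k * (k - 1)
  bits <- integer(n_bits)
  for (t in n_bits:1) {
    bits[t] <- code %% 2
    code <- code %/% 2
  }
  adj <- matrix(0L, k, k)
  t <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        adj[i, j] <- bits[t]
        t <- t + 1
      }
    }
  }
  adj
}

#' Pretty-print a motif key
#'
#' Renders a motif class as its arc list with colored node names, e.g.
#' `"S1>I2, I2>M3"` for the sensor-to-inter-to-motor relay chain. Reciprocal
#' arc pairs (the directed encoding of a gap junction) print as `=`.
#'
#' @param keys character vector of canonical keys
#' @param color_names character vector naming color indices; single letters
#'   are used as-is, longer names are abbreviated to their initial
#'   (uppercased).
#' @return Character vector of human-readable motif descriptions.
#' @export
format_motif <- function(keys, color_names = c("S", "I", "M")) {
  abbr <- toupper(substr(color_names, 1, 1))
  info <- parse_motif_key(keys)
  purrr::pmap_chr(info, function(key, k, mode, adjacency, colors) {
    labels <- paste0(abbr[colors + 1L], seq_len(k))
    pieces <- character(0)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i == j || adjacency[i, j] == 0) next
        if (adjacency[j, i] == 1) {
          if (i < j) pieces <- c(pieces,
                                 paste0(labels[i], "=", labels[j]))
        } else if (mode == "directed") {
          pieces <- c(pieces, paste0(labels[i], ">", labels[j]))
        }
      }
    }
    if (mode == "undirected") {
      pieces <- gsub("=", "-", pieces, fixed = TRUE)
    }
    paste(pieces, collapse = ", ")
  })
}

#' Serialize a census to TSV
#'
#' @param census a [motif_census()] result
#' @param path output TSV path; a sidecar JSON (same path with `.json`
#'   appended) records k, mode, total and color levels.
#' @return `census`, invisibly.
#' @export
write_census <- function(census, path) {
  stopifnot(inherits(census, "motif_census"))
  out <- tibble::tibble(
    motif_key = census$key,
    k = attr(census, "k"),
    mode = attr(census, "mode"),
    count = census$count
  )
  readr::write_tsv(out, path, progress = FALSE)
  meta <- list(k = attr(census, "k"), mode = attr(census, "mode"),
               total = attr(census, "total"),
               color_levels = attr(census, "color_levels"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(census)
}
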