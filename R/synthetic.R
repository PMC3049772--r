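#' Configuration for the synthetic colored-network generator
#'
#' Describes a simple colored graph to generate: node count, per-color node
#' counts, numbers of directed arcs and undirected links, the degree model,
#' and optional planted motifs. The generator emulates the statistical
#' structure the color-shuffle null assumes — colors exchangeable given the
#' topology — so generated networks are the calibration substrate for the
#' significance pipeline.
#'
#' @param n_nodes number of nodes
#' @param color_counts named integer vector of nodes per color (names are
#'   the color alphabet, in index order); must sum to `n_nodes`.
#' @param n_arcs number of directed arcs (at most `n_nodes * (n_nodes - 1)`)
#' @param n_links number of undirected links (at most `choose(n_nodes, 2)`)
#' @param degree_model `"uniform"` (Erdos-Renyi-style placement) or
#'   `"powerlaw"` (heavy-tailed out-degree, for robustness checks only)
#' @param exponent power-law exponent for `degree_model = "powerlaw"`
#' @param seed integer seed
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_nodes, color_counts, n_arcs, n_links,
                             degree_model = c("uniform", "powerlaw"),
                             exponent = 2.5, seed = 1) {
  degree_model <- match.arg(degree_model)
  stopifnot(n_nodes >= 2, all(color_counts >= 0),
            sum(color_counts) == n_nodes)
  if (is.null(names(color_counts))) {
    names(color_counts) <- paste0("color", seq_along(color_counts) - 1L)
  }
  if (n_arcs > n_nodes * (n_nodes - 1)) {
    stop("more arcs requested than a simple digraph admits", call. = FALSE)
  }
  if (n_links > choose(n_nodes, 2)) {
    stop("more links requested than a simple graph admits", call. = FALSE)
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 color_counts = color_counts,
                 n_arcs = as.integer(n_arcs), n_links = as.integer(n_links),
                 degree_model = degree_model, exponent = exponent,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Worm-like generator preset
#'
#' A synthetic stand-in for the *C. elegans* somatic wiring statistics: 279
#' nodes of which 86 are sensor and 80 are interneurons, the remainder (113)
#' motor neurons; 2,194 directed arcs (chemical synapses) and 514 undirected
#' links (gap junctions); uniform edge placement, no planted motifs, fixed
#' seed 1729.
#'
#' @return A [generator_config()].
#' @export
worm_preset <- function() {
  generator_config(
    n_nodes = 279,
    color_counts = c(sensor = 86, inter = 80, motor = 113),
    n_arcs = 2194, n_links = 514,
    degree_model = "uniform", seed = 1729
  )
}

#' Generate a synthetic colored network
#'
#' Draws a simple graph with exactly the configured arc and link counts and
#' assigns colors by a uniform random permutation of the color multiset.
#' Deterministic given the config's seed.
#'
#' @param config a [generator_config()]
#' @return A [colored_graph()].
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_nodes
  nodes <- sprintf("n%03d", seq_len(n))
  colors <- sample(rep(names(config$color_counts), config$color_counts))

  if (config$degree_model == "uniform") {
    # ordered pairs indexed 1..n(n-1), diagonal skipped
    pick <- sample.int(n * (n - 1L), config$n_arcs)
    from <- (pick - 1L) %/% (n - 1L) + 1L
    off <- (pick - 1L) %% (n - 1L) + 1L
    to <- ifelse(off >= from, off + 1L, off)
  } else {
    w <- (seq_len(n))^(-config$exponent / 2)
    seen <- character(0)
    from <- to <- integer(0)
    while (length(from) < config$n_arcs) {
      need <- config$n_arcs - length(from)
      f <- sample.int(n, 2L * need + 10L, replace = TRUE, prob = w)
      t <- sample.int(n, 2L * need + 10L, replace = TRUE)
      ok <- f != t & !duplicated(paste(f, t)) &
        !paste(f, t) %in% seen
      f <- f[ok][seq_len(min(need, sum(ok)))]
      t <- t[ok][seq_len(min(need, sum(ok)))]
      seen <- c(seen, paste(f, t))
      from <- c(from, f)
      to <- c(to, t)
    }
  }

  lpick <- sample.int(choose(n, 2), config$n_links)
  # unordered pairs indexed column-wise over i < j
  cum <- cumsum((n - 1L):1L)
  li <- findInterval(lpick - 1L, c(0L, cum), rightmost.closed = FALSE)
  lj <- lpick - c(0L, cum)[li] + li
  colored_graph(
    nodes = tibble::tibble(node = nodes, color = colors),
    arcs = tibble::tibble(from = nodes[from], to = nodes[to]),
    links = tibble::tibble(from = nodes[li], to = nodes[lj]),
    color_levels = names(config$color_counts)
  )
}

#' Plant copies of a colored motif
#'
#' Adds `copies` vertex-disjoint instances of a colored motif into an
#' existing graph, using existing nodes of the matching colors (so node
#' count and color frequencies — and hence the shuffle null — are
#' unchanged) and adding only the motif's edges. Host node sets are chosen
#' with no pre-existing edges among them, so each instance is induced.
#' Reciprocal arc pairs in the motif are planted as undirected links.
#'
#' @param g a [colored_graph()]
#' @param key canonical key of the motif to plant (directed mode)
#' @param copies number of vertex-disjoint instances
#' @param max_tries sampling attempts per instance before giving up
#' @return `g` with the added edges; the chosen node sets are recorded in
#'   `attr(, "planted")` (a list of character vectors).
#' @export
plant_motif <- function(g, key, copies, max_tries = 200) {
  stopifnot(inherits(g, "colored_graph"), copies >= 0)
  if (copies == 0) return(g)
  info <- parse_motif_key(key)
  k <- info$k[1]
  adj <- info$adjacency[[1]]
  motif_cols <- info$colors[[1]]
  lv <- color_levels(g)
  if (any(motif_cols + 1L > length(lv))) {
    stop("motif colors outside the graph's color alphabet", call. = FALSE)
  }

  enc_adj <- adjacency_lookup(g)
  node_col <- setNames(g$nodes$color, g$nodes$node)
  pool <- split(g$nodes$node, node_col)
  used <- character(0)
  planted <- list()
  new_arcs <- list()
  new_links <- list()

  for (cp in seq_len(copies)) {
    found <- FALSE
    for (try in seq_len(max_tries)) {
      slot_nodes <- character(k)
      ok <- TRUE
      for (i in seq_len(k)) {
        cand <- setdiff(pool[[lv[motif_cols[i] + 1L]]],
                        c(used, slot_nodes[seq_len(i - 1)]))
        if (length(cand) == 0) {
          ok <- FALSE
          break
        }
        slot_nodes[i] <- sample(cand, 1)
      }
      if (!ok) break
      # host slots must be edge-free among themselves
      pairs <- t(utils::combn(slot_nodes, 2))
      if (any(enc_adj[paste(pairs[, 1], pairs[, 2])] |
              enc_adj[paste(pairs[, 2], pairs[, 1])], na.rm = TRUE)) next
      found <- TRUE
      break
    }
    if (!found) {
      stop("could not place planted copy ", cp,
           ": not enough edge-free nodes of the required colors",
           call. = FALSE)
    }
    used <- c(used, slot_nodes)
    planted[[cp]] <- slot_nodes
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i == j || adj[i, j] == 0) next
        if (adj[j, i] == 1) {
          if (i < j) {
            new_links[[length(new_links) + 1]] <-
              c(slot_nodes[i], slot_nodes[j])
          }
        } else {
          new_arcs[[length(new_arcs) + 1]] <-
            c(slot_nodes[i], slot_nodes[j])
        }
      }
    }
  }

  arcs <- dplyr::bind_rows(
    g$arcs,
    if (length(new_arcs)) tibble::tibble(
      from = vapply(new_arcs, `[`, "", 1),
      to = vapply(new_arcs, `[`, "", 2)) else NULL
  )
  links <- dplyr::bind_rows(
    g$links,
    if (length(new_links)) tibble::tibble(
      from = vapply(new_links, `[`, "", 1),
      to = vapply(new_links, `[`, "", 2)) else NULL
  )
  out <- colored_graph(g$nodes, arcs, links, color_levels = lv)
  attr(out, "planted") <- planted
  out
}

adjacency_lookup <- function(g) {
  keys <- c(paste(g$arcs$from, g$arcs$to),
            paste(g$links$from, g$links$to),
            paste(g$links$to, g$links$from))
  setNames(rep(TRUE, length(keys)), keys)
}

#' Write a simulated network to disk
#'
#' Generates a network from a config (with optional planting) and writes
#' the edge-list TSV, the color-map TSV and a JSON manifest recording the
#' configuration, the seed and any planted instance node sets.
#'
#' @param config a [generator_config()]
#' @param dir output directory (created if missing)
#' @param planted optional list with elements `key` and `copies`
#' @return The generated [colored_graph()], invisibly.
#' @export
simulate_network <- function(config, dir, planted = NULL) {
  g <- generate_network(config)
  if (!is.null(planted)) {
    g <- plant_motif(g, planted$key, planted$copies)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_colored_network(g, file.path(dir, "edges.tsv"),
                        file.path(dir, "colors.tsv"))
  manifest <- list(
    config = unclass(config),
    planted = if (is.null(planted)) NULL else
      list(key = planted$key, copies = planted$copies,
           instances = attr(g, "planted"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(g)
}
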