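test_that("TSV read/write round trip preserves the graph", {
  dir <- withr::local_tempdir()
  g <- colored_graph(
    nodes = tibble::tibble(node = c("a", "b", "c"),
                           color = c("green", "red", "blue")),
    arcs = tibble::tibble(from = c("a", "b"), to = c("b", "c")),
    links = tibble::tibble(from = "a", to = "c")
  )
  ep <- file.path(dir, "edges.tsv")
  cp <- file.path(dir, "colors.tsv")
  write_colored_network(g, ep, cp)
  g2 <- read_colored_network(ep, cp)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$arcs, g$arcs)
  expect_equal(g2$links, g$links)
  expect_equal(color_levels(g2), color_levels(g))
  # second round trip is exact too
  write_colored_network(g2, ep, cp)
  expect_identical(read_colored_network(ep, cp), g2)
})

test_that("malformed edge lists are rejected with line context", {
  dir <- withr::local_tempdir()
  cp <- file.path(dir, "colors.tsv")
  writeLines(c("node\tcolor", "a\tgreen", "b\tred"), cp)

  ep <- file.path(dir, "edges.tsv")
  writeLines(c("source\ttarget\tkind", "a\ta\tdirected"), ep)
  expect_error(read_colored_network(ep, cp), "self-loop")

  writeLines(c("source\ttarget\tkind", "a\tb\tsideways"), ep)
  expect_error(read_colored_network(ep, cp), "kind")

  writeLines(c("source\ttarget\tkind", "a\tb\tdirected",
               "a\tc\tdirected"), ep)
  expect_error(read_colored_network(ep, cp), "without a color")
})

test_that("duplicate edges merge with a warning; unused color rows warn", {
  dir <- withr::local_tempdir()
  ep <- file.path(dir, "edges.tsv")
  cp <- file.path(dir, "colors.tsv")
  writeLines(c("source\ttarget\tkind", "a\tb\tdirected",
               "a\tb\tdirected"), ep)
  writeLines(c("node\tcolor", "a\tgreen", "b\tred", "zz\tblue"), cp)
  expect_warning(expect_warning(g <- read_colored_network(ep, cp),
                                "ignored"),
                 "duplicate")
  expect_equal(nrow(g$arcs), 1)
  expect_equal(nrow(g$nodes), 2)
})

test_that("directed encoding expands links and collapses coincidences", {
  mk <- function(arcs, links) {
    colored_graph(
      nodes = tibble::tibble(node = c("a", "b"), color = c("x", "y")),
      arcs = arcs, links = links, color_levels = c("x", "y")
    )
  }
  # single link -> both directions (a_ij = a_ji = 1)
  enc <- directed_encoding(mk(NULL, tibble::tibble(from = "a", to = "b")))
  expect_equal(nrow(enc$edges), 2)
  expect_setequal(paste(enc$edges[, 1], enc$edges[, 2]), c("1 2", "2 1"))
  # single arc passes through
  enc <- directed_encoding(mk(tibble::tibble(from = "a", to = "b"), NULL))
  expect_equal(nrow(enc$edges), 1)
  # coincident arc + link collapse onto the reciprocal pair
  enc <- directed_encoding(mk(tibble::tibble(from = "a", to = "b"),
                              tibble::tibble(from = "a", to = "b")))
  expect_equal(nrow(enc$edges), 2)
})

test_that("encoding arc count matches the adjacency-matrix construction", {
  set.seed(71)
  for (rep in 1:20) {
    g <- random_test_graph(8, p_arc = 0.25, p_link = 0.15)
    enc <- directed_encoding(g)
    a <- oracle_adjacency(g, "directed")
    expect_equal(nrow(enc$edges), sum(a))
  }
})

test_that("undirected projection symmetrizes, merges and is idempotent", {
  g <- colored_graph(
    nodes = tibble::tibble(node = c("a", "b", "c"),
                           color = c("x", "x", "x")),
    arcs = tibble::tibble(from = c("a", "b", "b"), to = c("b", "a", "c")),
    links = tibble::tibble(from = "a", to = "b")
  )
  p <- undirected_projection(g)
  expect_equal(nrow(p$arcs), 0)
  expect_equal(p$links, tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  expect_equal(undirected_projection(p)$links, p$links)
  # empty graph passes through
  e <- colored_graph(tibble::tibble(node = "a", color = "x"))
  expect_equal(nrow(undirected_projection(e)$links), 0)
})

test_that("GraphML round trip via the kind attribute", {
  dir <- withr::local_tempdir()
  g <- colored_graph(
    nodes = tibble::tibble(node = c("a", "b", "c"),
                           color = c("green", "red", "blue")),
    arcs = tibble::tibble(from = "a", to = "b"),
    links = tibble::tibble(from = "b", to = "c")
  )
  path <- file.path(dir, "net.graphml")
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  g2 <- read_colored_graphml(path, color_levels = color_levels(g))
  expect_equal(g2$arcs, g$arcs)
  expect_equal(g2$links, g$links)
  expect_equal(dplyr::arrange(g2$nodes, node), dplyr::arrange(g$nodes, node))
})

test_that("constructor enforces the invariants", {
  nodes <- tibble::tibble(node = c("a", "b"), color = c("x", "y"))
  expect_error(colored_graph(nodes, arcs = tibble::tibble(from = "a",
                                                          to = "a")),
               "self-loop")
  expect_error(colored_graph(nodes, arcs = tibble::tibble(from = "a",
                                                          to = "q")),
               "missing from the node table")
  expect_error(colored_graph(tibble::tibble(node = c("a", "a"),
                                            color = c("x", "x"))),
               "duplicate")
  # links stored canonically regardless of input order
  g <- colored_graph(nodes, links = tibble::tibble(from = "b", to = "a"))
  expect_equal(g$links, tibble::tibble(from = "a", to = "b"))
})
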