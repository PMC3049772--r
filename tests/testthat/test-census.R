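test_that("canonical keys are invariant under node relabeling", {
  set.seed(42)
  for (rep in 1:40) {
    k <- sample(2:4, 1)
    mode <- sample(c("directed", "undirected"), 1)
    repeat {
      adj <- matrix(rbinom(k * k, 1, 0.5), k, k)
      diag(adj) <- 0
      if (mode == "undirected") adj <- (adj + t(adj) > 0) * 1
      if (oracle_connected(adj)) break
    }
    colors <- sample(0:2, k, replace = TRUE)
    key <- canonical_key(adj, colors, mode)
    for (t in 1:4) {
      p <- sample(k)
      expect_identical(canonical_key(adj[p, p], colors[p], mode), key)
    }
    expect_identical(oracle_key(adj, colors, mode), key)
  }
})

test_that("the relay-chain class is one key across all labelings", {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 3] <- 1
  cols <- c(0, 1, 2)  # sensor -> inter -> motor
  perms <- all_perms(3)
  keys <- apply(perms, 1, function(p) canonical_key(adj[p, p], cols[p],
                                                    "directed"))
  expect_length(unique(keys), 1)
})

test_that("uncolored 3-node directed topologies form 13 distinct classes", {
  # exhaustive-permutation oracle over all 2^6 off-diagonal relations
  seen <- character(0)
  for (mask in 0:63) {
    bits <- as.integer(intToBits(mask))[6:1]
    adj <- matrix(0, 3, 3)
    t <- 1
    for (i in 1:3) for (j in 1:3) if (i != j) {
      adj[i, j] <- bits[t]; t <- t + 1
    }
    if (!oracle_connected(adj)) next
    seen <- c(seen, canonical_key(adj, c(0, 0, 0), "directed"))
  }
  expect_length(unique(seen), 13)
  expect_identical(sort(unique(seen)),
                   sort(enumerate_motif_classes(3, 1, "directed")$key))
})

test_that("disconnected subgraphs are rejected by canonical_key", {
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[3, 4] <- 1
  expect_error(canonical_key(adj, rep(0, 4), "directed"), "not connected")
})

test_that("ESU enumerates each connected induced subset exactly once", {
  # known cases
  tri <- colored_graph(
    tibble::tibble(node = c("a", "b", "c"), color = "x"),
    links = tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c"))
  )
  expect_equal(nrow(enumerate_connected_subsets(tri, 3, "undirected")), 1)

  star <- colored_graph(
    tibble::tibble(node = c("h", "l1", "l2", "l3"), color = "x"),
    links = tibble::tibble(from = "h", to = c("l1", "l2", "l3"))
  )
  expect_equal(nrow(enumerate_connected_subsets(star, 3, "undirected")), 3)

  empty <- colored_graph(tibble::tibble(node = c("a", "b", "c"),
                                        color = "x"))
  expect_equal(nrow(enumerate_connected_subsets(empty, 2, "directed")), 0)

  # multiset equality with the brute-force subset oracle
  set.seed(7)
  for (rep in 1:10) {
    g <- random_test_graph(sample(6:10, 1))
    for (mode in c("directed", "undirected")) {
      a <- oracle_adjacency(g, mode)
      for (k in 2:4) {
        got <- enumerate_connected_subsets(g, k, mode)
        got <- apply(got, 1, paste, collapse = " ")
        want <- utils::combn(nrow(a), k, function(s) {
          if (oracle_connected(a[s, s]))
            paste(g$nodes$node[s], collapse = " ") else NA_character_
        })
        want <- want[!is.na(want)]
        expect_identical(sort(got), sort(want))
      }
    }
  }
})

test_that("census agrees with the exhaustive subset oracle", {
  set.seed(11)
  for (rep in 1:6) {
    g <- random_test_graph(sample(7:10, 1))
    for (mode in c("directed", "undirected")) {
      for (k in 2:4) {
        cen <- motif_census(g, k, mode)
        expect_equal(tibble::as_tibble(cen), oracle_census(g, k, mode),
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("summing a census over colorings reproduces the uncolored census", {
  set.seed(13)
  g <- random_test_graph(10, p_arc = 0.2, p_link = 0.1)
  mono <- g
  mono$nodes$color <- "green"
  attr(mono, "color_levels") <- "green"
  for (k in 2:4) {
    colored <- motif_census(g, k, "directed")
    uncolored <- motif_census(mono, k, "directed")
    # strip color codes, sum counts per topology
    topo <- sub("\\|[0-9]+$", "", colored$key)
    marg <- tapply(colored$count, topo, sum)
    expect_equal(sort(as.numeric(marg)), sort(uncolored$count))
    expect_equal(attr(colored, "total"), attr(uncolored, "total"))
  }
})

test_that("census totals are invariant under color shuffling", {
  set.seed(17)
  g <- random_test_graph(12, p_arc = 0.15, p_link = 0.05)
  t0 <- attr(motif_census(g, 3, "directed"), "total")
  for (rep in 1:3) {
    gs <- shuffle_colors(g)
    expect_equal(attr(motif_census(gs, 3, "directed"), "total"), t0)
  }
})

test_that("class enumeration matches the combinatorial reference counts", {
  # spot cells; the full grid is exercised by the acceptance suite
  expect_equal(nrow(enumerate_motif_classes(2, 2, "undirected")), 3)
  expect_equal(nrow(enumerate_motif_classes(2, 1, "undirected")), 1)
  expect_equal(nrow(enumerate_motif_classes(2, 1, "directed")), 2)
  expect_equal(nrow(enumerate_motif_classes(3, 3, "directed")), 273)
})

test_that("size-5 analysis is refused", {
  g <- toy_relay_graph()
  expect_error(motif_census(g, 5), "2, 3 or 4")
  expect_error(enumerate_motif_classes(5, 1, "directed"), "size 5")
})

test_that("keys parse back to their adjacency and colors", {
  set.seed(19)
  for (rep in 1:15) {
    k <- sample(2:4, 1)
    repeat {
      adj <- matrix(rbinom(k * k, 1, 0.5), k, k)
      diag(adj) <- 0
      if (oracle_connected(adj)) break
    }
    colors <- sample(0:2, k, replace = TRUE)
    key <- canonical_key(adj, colors, "directed")
    info <- parse_motif_key(key)
    # re-canonicalizing the parsed form must reproduce the key
    expect_identical(canonical_key(info$adjacency[[1]], info$colors[[1]],
                                   "directed"), key)
    expect_identical(sort(info$colors[[1]]), sort(colors))
  }
})

test_that("motif pretty-printing is stable", {
  expect_identical(format_motif(chain3_key(),
                                c("sensor", "inter", "motor")),
                   "S2>I3, I3>M1")
  pair <- canonical_key(matrix(c(0, 1, 1, 0), 2, 2), c(0, 0), "undirected")
  expect_identical(format_motif(pair, c("S", "I", "M")), "S1-S2")
})
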