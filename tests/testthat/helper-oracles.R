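# Independent brute-force oracles, deliberately sharing no code with the
# package internals: canonicalization by explicit permutation search in R,
# censuses by exhaustive subset testing.

all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# mirrors the key serialization so oracle and implementation are comparable
oracle_key <- function(adj, colors, mode) {
  k <- nrow(adj)
  perms <- all_perms(k)
  off <- which(t(matrix(seq_len(k * k), k, k)) > 0 &
                 row(adj) != col(adj))
  best <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    b <- adj[p, p]
    bits <- as.vector(t(b))[as.vector(t(row(adj) != col(adj)))]
    code <- sum(bits * 2^((length(bits) - 1):0))
    cand <- list(code = code, cols = colors[p])
    if (is.null(best) || cand$code < best$code ||
        (cand$code == best$code &&
         paste(cand$cols, collapse = "") < paste(best$cols, collapse = ""))) {
      best <- cand
    }
  }
  sprintf("%d|%s|%.0f|%s", k, if (mode == "directed") "d" else "u",
          best$code, paste(best$cols, collapse = ""))
}

# adjacency matrices straight from the edge tables (a_ij rules: arc ij -> 1,
# link ij -> both 1)
oracle_adjacency <- function(g, mode) {
  n <- nrow(g$nodes)
  idx <- stats::setNames(seq_len(n), g$nodes$node)
  a <- matrix(0L, n, n)
  for (r in seq_len(nrow(g$arcs))) {
    a[idx[g$arcs$from[r]], idx[g$arcs$to[r]]] <- 1L
  }
  for (r in seq_len(nrow(g$links))) {
    a[idx[g$links$from[r]], idx[g$links$to[r]]] <- 1L
    a[idx[g$links$to[r]], idx[g$links$from[r]]] <- 1L
  }
  if (mode == "undirected") a <- (a + t(a) > 0) * 1L
  a
}

oracle_connected <- function(suba) {
  k <- nrow(suba)
  sym <- (suba + t(suba)) > 0
  seen <- c(TRUE, rep(FALSE, k - 1))
  repeat {
    new <- seen | apply(sym[seen, , drop = FALSE], 2, any)
    if (all(new == seen)) break
    seen <- new
  }
  all(seen)
}

oracle_census <- function(g, k, mode) {
  a <- oracle_adjacency(g, mode)
  n <- nrow(a)
  cols <- match(g$nodes$color, attr(g, "color_levels")) - 1L
  counts <- list()
  if (n >= k) {
    subsets <- utils::combn(n, k)
    for (ci in seq_len(ncol(subsets))) {
      s <- subsets[, ci]
      suba <- a[s, s]
      if (!oracle_connected(suba)) next
      key <- oracle_key(suba, cols[s], mode)
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  if (length(counts) == 0) {
    return(tibble::tibble(key = character(), count = numeric()))
  }
  out <- tibble::tibble(key = names(counts), count = as.numeric(unlist(counts)))
  dplyr::arrange(out, key)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Eq. 2-5 by direct loops: replicate r's raw P counts the OTHER replicates
# with a count at least its own (H(0) = 1), divided by N
oracle_minp <- function(obs, counts) {
  n <- nrow(counts)
  m <- ncol(counts)
  p_raw <- sapply(seq_len(m), function(i) sum(counts[, i] >= obs[i]) / n)
  mstar <- sapply(seq_len(n), function(r) {
    min(sapply(seq_len(m), function(i) {
      sum(counts[setdiff(seq_len(n), r), i] >= counts[r, i]) / n
    }))
  })
  list(p_raw = p_raw, mstar = mstar,
       p_adj = sapply(p_raw, function(p) sum(mstar <= p) / n))
}

random_test_graph <- function(n, p_arc = 0.15, p_link = 0.05,
                              colors = c("green", "red", "blue")) {
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  arcs <- NULL
  for (d in 1:2) {
    keep <- stats::runif(nrow(pairs)) < p_arc
    src <- if (d == 1) pairs[keep, 1] else pairs[keep, 2]
    dst <- if (d == 1) pairs[keep, 2] else pairs[keep, 1]
    arcs <- rbind(arcs, cbind(src, dst))
  }
  keep <- stats::runif(nrow(pairs)) < p_link
  colored_graph(
    nodes = tibble::tibble(node = nodes,
                           color = sample(colors, n, replace = TRUE)),
    arcs = if (is.null(arcs) || nrow(arcs) == 0) NULL else
      tibble::tibble(from = nodes[arcs[, 1]], to = nodes[arcs[, 2]]),
    links = if (!any(keep)) NULL else
      tibble::tibble(from = nodes[pairs[keep, 1]],
                     to = nodes[pairs[keep, 2]]),
    color_levels = colors
  )
}

toy_relay_graph <- function() {
  colored_graph(
    nodes = tibble::tibble(node = c("a", "b", "c"),
                           color = c("sensor", "inter", "motor")),
    arcs = tibble::tibble(from = c("a", "b"), to = c("b", "c")),
    color_levels = c("sensor", "inter", "motor")
  )
}

chain3_key <- function() {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 3] <- 1
  canonical_key(adj, c(0, 1, 2), "directed")
}
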