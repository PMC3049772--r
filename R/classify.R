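#' Structural classification of directed size-4 motifs
#'
#' Assigns each 4-node directed motif class to one of the functional
#' families seen in feed-forward-dominated neuronal wiring:
#' `bifan` (two sources each feeding two high-in-degree sinks), `chain`
#' (linear relay), `ffl_entry_exit` (a 3-node feed-forward loop plus one
#' pendant node), `nested_feed_forward` (acyclic, a single sink, and at
#' least one node pair joined by two distinct directed paths),
#' `integration_bifurcation` (acyclic with no such "shortcut" pair:
#' signals only merge or branch), and `other` (notably anything containing
#' a directed cycle, such as rings). Predicates are tested in the order
#' bifan, chain, ffl_entry_exit, nested_feed_forward,
#' integration_bifurcation.
#'
#' Motifs whose key contains a reciprocal arc pair (the directed encoding
#' of an undirected link) are classified on that encoding and flagged via
#' `has_reciprocal`.
#'
#' @param keys character vector of directed size-4 motif keys
#' @return A tibble with columns `key`, `class`, `n_sources`, `n_sinks`,
#'   `source_colors`, `sink_colors` (comma-separated color indices) and
#'   `has_reciprocal`.
#' @examples
#' bifan <- canonical_key(
#'   matrix(c(0,0,1,1, 0,0,1,1, 0,0,0,0, 0,0,0,0), 4, 4, byrow = TRUE),
#'   c(1, 1, 2, 2), "directed")
#' classify_size4(bifan)$class
#' @export
classify_size4 <- function(keys) {
  info <- parse_motif_key(keys)
  if (any(info$k != 4 | info$mode != "directed")) {
    stop("classify_size4 expects directed size-4 motif keys", call. = FALSE)
  }
  classify_impl(info, size4_label)
}

#' Structural classification of directed size-3 motifs
#'
#' Labels: `chain` (x to y to z), `feed_forward` (direct plus relayed path
#' to the same target), `ring` (three nodes feeding a signal around a
#' cycle), `merge` (two inputs into one target), `split` (one source into
#' two targets), `other`.
#'
#' @param keys character vector of directed size-3 motif keys
#' @return Same shape as [classify_size4()].
#' @export
classify_size3 <- function(keys) {
  info <- parse_motif_key(keys)
  if (any(info$k != 3 | info$mode != "directed")) {
    stop("classify_size3 expects directed size-3 motif keys", call. = FALSE)
  }
  classify_impl(info, size3_label)
}

classify_impl <- function(info, labeller) {
  rows <- purrr::pmap(info, function(key, k, mode, adjacency, colors) {
    a <- adjacency
    indeg <- colSums(a)
    outdeg <- rowSums(a)
    sources <- which(indeg == 0 & outdeg > 0)
    sinks <- which(outdeg == 0 & indeg > 0)
    tibble::tibble(
      key = key,
      class = labeller(a, indeg, outdeg, sources, sinks),
      n_sources = length(sources),
      n_sinks = length(sinks),
      source_colors = paste(colors[sources], collapse = ","),
      sink_colors = paste(colors[sinks], collapse = ","),
      has_reciprocal = any(a == 1 & t(a) == 1)
    )
  })
  dplyr::bind_rows(rows)
}

is_acyclic <- function(a) {
  k <- nrow(a)
  p <- a
  for (l in 2:k) {
    p <- p %*% a
    if (any(diag(p) > 0)) return(FALSE)
  }
  TRUE
}

# number of distinct directed paths between every ordered pair (DAG only:
# walks are paths there)
path_counts <- function(a) {
  k <- nrow(a)
  total <- a
  p <- a
  for (l in 2:(k - 1)) {
    p <- p %*% a
    total <- total + p
  }
  total
}

ffl_adj <- matrix(c(0, 1, 1, 0, 0, 1, 0, 0, 0), 3, 3, byrow = TRUE)

is_ffl <- function(a3) {
  sum(a3) == 3 && is_acyclic(a3) &&
    setequal(rowSums(a3), c(2, 1, 0)) && setequal(colSums(a3), c(0, 1, 2))
}

size4_label <- function(a, indeg, outdeg, sources, sinks) {
  acyc <- is_acyclic(a)
  if (length(sinks) == 2 && all(indeg[sinks] >= 2) &&
      length(sources) == 2) {
    return("bifan")
  }
  if (acyc && all(indeg <= 1) && all(outdeg <= 1)) {
    return("chain")
  }
  # feed-forward loop plus a pendant node attached by exactly one arc
  for (drop in 1:4) {
    tri <- setdiff(1:4, drop)
    a3 <- a[tri, tri]
    pend <- sum(a[drop, tri]) + sum(a[tri, drop])
    if (pend == 1 && is_ffl(a3)) {
      return("ffl_entry_exit")
    }
  }
  if (acyc) {
    shortcut <- any(path_counts(a) >= 2)
    if (shortcut && length(sinks) == 1) return("nested_feed_forward")
    if (!shortcut) return("integration_bifurcation")
  }
  "other"
}

size3_label <- function(a, indeg, outdeg, sources, sinks) {
  m <- sum(a)
  if (m == 2 && all(indeg <= 1) && all(outdeg <= 1) && is_acyclic(a)) {
    return("chain")
  }
  if (m == 3 && is_ffl(a)) return("feed_forward")
  if (m == 3 && all(indeg == 1) && all(outdeg == 1)) return("ring")
  if (m == 2 && any(indeg == 2)) return("merge")
  if (m == 2 && any(outdeg == 2)) return("split")
  "other"
}

#' Human-readable motif label
#'
#' Combines the arc-list rendering of [format_motif()] with the structural
#' class where one is defined (directed sizes 3 and 4), e.g.
#' `"S1>I2, I2>M3 (chain)"`.
#'
#' @inheritParams format_motif
#' @return Character vector of labels, stable across runs.
#' @export
motif_label <- function(keys, color_names = c("S", "I", "M")) {
  base <- format_motif(keys, color_names)
  info <- parse_motif_key(keys)
  cls <- rep(NA_character_, length(keys))
  d3 <- info$k == 3 & info$mode == "directed"
  d4 <- info$k == 4 & info$mode == "directed"
  if (any(d3)) cls[d3] <- classify_size3(keys[d3])$class
  if (any(d4)) cls[d4] <- classify_size4(keys[d4])$class
  ifelse(is.na(cls), base, paste0(base, " (", cls, ")"))
}
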