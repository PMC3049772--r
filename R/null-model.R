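#' Shuffle node colors
#'
#' The color-permutation null model: node colors are randomized while the
#' topology and the color frequencies stay fixed. The default mechanism
#' repeatedly switches the colors of two randomly chosen nodes
#' (`method = "swap"`); `method = "permute"` applies one uniform random
#' permutation of the color vector, which is the stationary distribution of
#' the swap chain and is statistically equivalent.
#'
#' @param g a [colored_graph()]
#' @param n_swaps number of color switches for `method = "swap"`; defaults
#'   to 10 swaps per node, ample mixing for a transposition shuffle.
#' @param method `"swap"` or `"permute"`
#' @return A [colored_graph()] with identical nodes, arcs and links and a
#'   shuffled color assignment.
#' @export
shuffle_colors <- function(g, n_swaps = NULL, method = c("swap", "permute")) {
  stopifnot(inherits(g, "colored_graph"))
  method <- match.arg(method)
  n <- nrow(g$nodes)
  cols <- g$nodes$color
  if (method == "permute") {
    cols <- sample(cols)
  } else {
    if (is.null(n_swaps)) n_swaps <- 10L * n
    stopifnot(n_swaps >= 1)
    for (s in seq_len(n_swaps)) {
      ij <- sample.int(n, 2)
      cols[ij] <- cols[c(ij[2], ij[1])]
    }
  }
  g$nodes$color <- cols
  g
}

#' Build a color-randomization ensemble
#'
#' Generates `n_rand` independent color shuffles of `g`, runs the motif
#' census on each, and collects the counts into an N x M matrix whose
#' columns cover every motif class observed in the real graph or any
#' replicate (missing classes filled with 0). Replicate r's random stream
#' depends only on `(seed, r)`, so the matrix is reproducible and
#' independent of evaluation order.
#'
#' @inheritParams motif_census
#' @param n_rand number of randomizations (at least 2)
#' @param seed integer seed for the ensemble
#' @param n_swaps,method passed to [shuffle_colors()]
#' @return An object of class `motif_ensemble`: list with `keys` (ordered
#'   class keys), `counts` (`n_rand` x M matrix), `observed` (the
#'   [motif_census()] of `g`), `k`, `mode`, `seed`, `n_swaps`, `method`,
#'   `color_levels`.
#' @export
build_ensemble <- function(g, k, mode = c("directed", "undirected"),
                           n_rand = 1000, seed = 1, n_swaps = NULL,
                           method = c("swap", "permute")) {
  stopifnot(inherits(g, "colored_graph"), n_rand >= 2)
  mode <- match.arg(mode)
  method <- match.arg(method)
  observed <- motif_census(g, k, mode)

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_rand)
  reps <- vector("list", n_rand)
  for (r in seq_len(n_rand)) {
    set.seed(sub_seeds[r])
    gs <- shuffle_colors(g, n_swaps = n_swaps, method = method)
    cen <- motif_census(gs, k, mode)
    reps[[r]] <- setNames(cen$count, cen$key)
  }

  keys <- sort(unique(c(observed$key, unlist(lapply(reps, names)))))
  counts <- matrix(0, nrow = n_rand, ncol = length(keys),
                   dimnames = list(NULL, keys))
  for (r in seq_len(n_rand)) {
    counts[r, names(reps[[r]])] <- reps[[r]]
  }

  structure(
    list(keys = keys, counts = counts, observed = observed,
         k = attr(observed, "k"), mode = mode, seed = seed,
         n_swaps = if (is.null(n_swaps) && method == "swap")
           10L * nrow(g$nodes) else n_swaps,
         method = method, color_levels = color_levels(g)),
    class = "motif_ensemble"
  )
}

#' @export
print.motif_ensemble <- function(x, ...) {
  cat("<motif_ensemble> k=", x$k, " mode=", x$mode, ": ",
      nrow(x$counts), " randomizations x ", length(x$keys),
      " motif classes (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Persist / restore a randomization ensemble
#'
#' The counts matrix is written as a (optionally gzipped) TSV with one
#' column per motif key plus the observed census, and a JSON sidecar holds
#' the parameters, so significance can be recomputed without re-running the
#' enumeration.
#'
#' @param ensemble a [build_ensemble()] result
#' @param path TSV output path (use a `.gz` suffix for compression); the
#'   sidecar is `paste0(path, ".json")`.
#' @return `ensemble` (write) / the restored `motif_ensemble` (read).
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "motif_ensemble"))
  df <- tibble::as_tibble(ensemble$counts, .name_repair = "minimal")
  readr::write_tsv(df, path, progress = FALSE)
  meta <- list(
    k = ensemble$k, mode = ensemble$mode, seed = ensemble$seed,
    n_rand = nrow(ensemble$counts), n_swaps = ensemble$n_swaps,
    method = ensemble$method, color_levels = ensemble$color_levels,
    observed = as.list(setNames(ensemble$observed$count,
                                ensemble$observed$key)),
    observed_total = attr(ensemble$observed, "total")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(ensemble)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double()), progress = FALSE)
  counts <- as.matrix(df)
  obs_counts <- unlist(meta$observed)
  observed <- tibble::tibble(key = names(obs_counts),
                             count = as.numeric(obs_counts))
  observed <- dplyr::arrange(observed, .data$key)
  observed <- structure(observed,
                        k = meta$k, mode = meta$mode,
                        total = meta$observed_total,
                        color_levels = unlist(meta$color_levels),
                        class = c("motif_census", class(observed)))
  structure(
    list(keys = colnames(counts), counts = counts, observed = observed,
         k = meta$k, mode = meta$mode, seed = meta$seed,
         n_swaps = meta$n_swaps, method = meta$method,
         color_levels = unlist(meta$color_levels)),
    class = "motif_ensemble"
  )
}
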