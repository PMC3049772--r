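#' Run the full colored-motif significance analysis
#'
#' Orchestrates census, color-randomization ensemble, significance table,
#' structural classification and absence analysis for each requested motif
#' size and mode, writing all artifacts to a run directory. The run is
#' deterministic given the inputs and the seed: each size/mode combination
#' gets its own derived seed, and within an ensemble replicate r's random
#' stream depends only on (seed, r).
#'
#' @param g a [colored_graph()], or a length-2 character vector of paths
#'   `c(edge_list, color_map)` read via [read_colored_network()]
#' @param sizes motif sizes, subset of 2:4
#' @param modes census modes, subset of `c("directed", "undirected")`
#' @param n_rand number of color randomizations (at least 2)
#' @param seed master seed
#' @param alpha significance level for flagging
#' @param out_dir run directory (created if missing); `NULL` to skip all
#'   file output
#' @param n_swaps,method passed to [shuffle_colors()]
#' @param absence if `TRUE`, run [absence_analysis()] against the full
#'   class universe (practical for up to 3 colors)
#' @return A list of class `motif_run`: per size/mode element named
#'   `"k<k>_<mode>"` with components `census`, `ensemble`, `significance`,
#'   `report`, and (when requested) `absence` and `classes`; plus a
#'   `summary` tibble with one row per combination.
#' @export
run_motif_analysis <- function(g, sizes = c(2, 3), modes = "directed",
                               n_rand = 200, seed = 1, alpha = 0.05,
                               out_dir = NULL, n_swaps = NULL,
                               method = c("swap", "permute"),
                               absence = FALSE) {
  method <- match.arg(method)
  if (is.character(g)) {
    stopifnot(length(g) == 2)
    g <- read_colored_network(g[1], g[2])
  }
  stopifnot(inherits(g, "colored_graph"), n_rand >= 2, length(sizes) >= 1)
  modes <- match.arg(modes, c("directed", "undirected"), several.ok = TRUE)
  n_colors <- length(color_levels(g))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_path <- file.path(out_dir, "run.log")
    cat(sprintf("coloredmotifs %s | seed=%d n_rand=%d alpha=%g\n",
                as.character(utils::packageVersion("coloredmotifs")),
                seed, n_rand, alpha),
        file = log_path)
  }
  log_line <- function(...) {
    msg <- sprintf(...)
    message(msg)
    if (!is.null(out_dir)) cat(msg, "\n", file = log_path, append = TRUE,
                               sep = "")
  }

  combos <- expand.grid(k = sizes, mode = modes,
                        stringsAsFactors = FALSE)
  results <- list()
  summary_rows <- list()
  for (ci in seq_len(nrow(combos))) {
    k <- combos$k[ci]
    mode <- combos$mode[ci]
    tag <- sprintf("k%d_%s", k, mode)
    combo_seed <- (seed + 7919L * ci) %% 2147483647L
    log_line("[%s] census + %d randomizations (seed %d)", tag, n_rand,
             combo_seed)

    ens <- build_ensemble(g, k, mode, n_rand = n_rand, seed = combo_seed,
                          n_swaps = n_swaps, method = method)
    sig <- significance_table(ens, alpha = alpha)
    rep <- rank_report(sig)
    res <- list(census = ens$observed, ensemble = ens,
                significance = sig, report = rep)

    if (mode == "directed" && k %in% 3:4) {
      cls <- if (k == 3) classify_size3(sig$key) else classify_size4(sig$key)
      res$structure <- cls
    }
    if (absence) {
      classes <- enumerate_motif_classes(k, n_colors, mode)
      res$classes <- classes
      res$absence <- absence_analysis(ens$observed, ens, classes)
    }

    if (!is.null(out_dir)) {
      write_census(ens$observed, file.path(out_dir,
                                           sprintf("census_%s.tsv", tag)))
      write_ensemble(ens, file.path(out_dir,
                                    sprintf("ensemble_%s.tsv.gz", tag)))
      sig_out <- tibble::as_tibble(sig)
      sig_out$label <- format_motif(sig_out$key, color_levels(g))
      if (!is.null(res$structure)) {
        sig_out <- dplyr::left_join(sig_out,
                                    res$structure[, c("key", "class",
                                                      "has_reciprocal")],
                                    by = "key")
      }
      readr::write_tsv(sig_out,
                       file.path(out_dir, sprintf("significance_%s.tsv",
                                                  tag)),
                       progress = FALSE)
    }

    summary_rows[[tag]] <- tibble::tibble(
      k = k, mode = mode, n_motifs = nrow(sig),
      total_subgraphs = attr(ens$observed, "total"),
      n_significant = sum(sig$significant),
      top_z = max(sig$z[is.finite(sig$z)], -Inf),
      absent_observed = if (absence) res$absence$n_absent_observed
                        else NA_integer_
    )
    results[[tag]] <- res
    log_line("[%s] %d classes observed, %d significant at alpha=%g", tag,
             nrow(sig), sum(sig$significant), alpha)
  }

  summary <- dplyr::bind_rows(summary_rows)
  if (!is.null(out_dir)) {
    readr::write_tsv(summary, file.path(out_dir, "summary.tsv"),
                     progress = FALSE)
    manifest <- list(sizes = sizes, modes = modes, n_rand = n_rand,
                     seed = seed, alpha = alpha, method = method,
                     n_swaps = n_swaps,
                     n_nodes = nrow(g$nodes), n_arcs = nrow(g$arcs),
                     n_links = nrow(g$links),
                     color_levels = color_levels(g))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  results$summary <- summary
  class(results) <- "motif_run"
  results
}

#' @export
print.motif_run <- function(x, ...) {
  cat("<motif_run>\n")
  print(x$summary)
  invisible(x)
}
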