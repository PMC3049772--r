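#' Motif z-score
#'
#' `(n_obs - null_mean) / null_sd`, the standardized deviation of the
#' observed motif count from its color-randomization expectation. When the
#' null distribution is degenerate (`null_sd = 0`) the score is 0 if the
#' observed count equals the null mean and signed infinity otherwise.
#'
#' @param n_obs observed count(s)
#' @param null_mean,null_sd mean and standard deviation of the count over
#'   the randomization ensemble
#' @return Numeric vector of z-scores.
#' @export
zscore <- function(n_obs, null_mean, null_sd) {
  stopifnot(all(null_sd >= 0))
  out <- (n_obs - null_mean) / null_sd
  deg <- null_sd == 0
  out[deg] <- sign(n_obs[deg] - null_mean[deg]) * Inf
  out[deg & n_obs == null_mean] <- 0
  out
}

#' Log2 abundance ratio
#'
#' `log2(n_obs / null_mean)`: positive for over-represented motifs,
#' negative for suppressed ones. A motif absent from the observed graph but
#' present in the null gives `-Inf` (and vice versa `Inf`); `NA` when both
#' are zero.
#'
#' @inheritParams zscore
#' @return Numeric vector.
#' @export
log2_ratio <- function(n_obs, null_mean) {
  stopifnot(all(n_obs >= 0), all(null_mean >= 0))
  out <- log2(n_obs / null_mean)
  out[n_obs == 0 & null_mean == 0] <- NA_real_
  out
}

#' Raw permutation P-value
#'
#' The fraction of randomizations whose count is at least the observed
#' count (ties count: the Heaviside convention H(0) = 1). A raw P of 0
#' means the motif was more abundant in the observed graph than in every
#' randomization.
#'
#' @param n_obs observed count (scalar)
#' @param ensemble_column counts of the same motif across the N
#'   randomizations
#' @return A single P-value in \[0, 1\].
#' @export
raw_p <- function(n_obs, ensemble_column) {
  stopifnot(length(ensemble_column) >= 1)
  mean(ensemble_column >= n_obs)
}

#' Single-step min-P adjusted P-values
#'
#' Westfall-Young single-step min-P correction over one size class of
#' motifs. For each randomization r and motif i, the replicate raw P
#' compares r's count with the counts of the other randomizations:
#' \deqn{\tilde p_i^{(r)} = \frac{1}{N}\sum_{s \ne r} H(m_i^{(s)} - m_i^{(r)}),}
#' with H(0) = 1. The per-randomization minimum
#' \eqn{m^{*(r)} = \min_i \tilde p_i^{(r)}} captures the most significant
#' over-representation attainable by chance, and the adjusted P-value is
#' the fraction of randomizations whose minimum falls at or below motif i's
#' raw P: \eqn{P_{adj}(i) = \frac{1}{N}\sum_r H(p_i - m^{*(r)})}.
#' The smallest attainable adjusted P equals the fraction of randomizations
#' with \eqn{m^{*(r)} = 0}, so with finitely many randomizations the
#' adjusted P of the top motifs is floored; it shrinks as N grows.
#'
#' @param obs_counts observed counts for the M motifs of one size class
#' @param ensemble N x M matrix of randomized counts (same motif order)
#' @return Numeric vector of M adjusted P-values, with attributes `p_raw`
#'   (the M raw P-values) and `min_p` (the N per-randomization minima
#'   \eqn{m^{*(r)}}).
#' @seealso [adjust_from_minp()] for the final comparison step alone.
#' @export
minp_adjust <- function(obs_counts, ensemble) {
  ensemble <- as.matrix(ensemble)
  n <- nrow(ensemble)
  m <- ncol(ensemble)
  if (length(obs_counts) != m) {
    stop("obs_counts length must match ensemble columns", call. = FALSE)
  }
  p_raw <- vapply(seq_len(m), function(i) raw_p(obs_counts[i], ensemble[, i]),
                  numeric(1))
  # #(s != r: m_s >= m_r) = N - rank_min(m_r); divide by N
  p_tilde <- apply(ensemble, 2, function(col) {
    (n - rank(col, ties.method = "min")) / n
  })
  p_tilde <- matrix(p_tilde, nrow = n)
  min_p <- apply(p_tilde, 1, min)
  p_adj <- adjust_from_minp(p_raw, min_p)
  attr(p_adj, "p_raw") <- p_raw
  attr(p_adj, "min_p") <- min_p
  p_adj
}

#' Adjusted P from raw P and the min-P null distribution
#'
#' The final step of the single-step min-P correction: each raw P-value is
#' compared against the distribution of per-randomization minimum raw
#' P-values, \eqn{P_{adj}(i) = \frac{1}{N}\sum_r H(p_i - m^{*(r)})} with
#' H(0) = 1.
#'
#' @param p_raw raw P-value(s)
#' @param min_p vector of per-randomization minimum raw P-values
#' @return Adjusted P-value(s), same length as `p_raw`.
#' @export
adjust_from_minp <- function(p_raw, min_p) {
  vapply(p_raw, function(p) mean(min_p <= p), numeric(1))
}

#' One-sample t-test of an ensemble column against the observed count
#'
#' Two-tailed one-sample t-test of the null hypothesis that the
#' randomization distribution of the motif count has mean equal to the
#' observed count.
#'
#' @inheritParams raw_p
#' @return Two-tailed P-value; `NA` for a zero-variance column.
#' @export
per_motif_ttest <- function(n_obs, ensemble_column) {
  stopifnot(length(ensemble_column) >= 2)
  if (sd(ensemble_column) == 0) return(NA_real_)
  t.test(ensemble_column, mu = n_obs)$p.value
}

#' Per-motif significance table
#'
#' Assembles, for every motif class of one size/mode, the observed count,
#' the null mean and standard deviation (population SD over the ensemble,
#' which *is* the null distribution), the z-score, log2 ratio, raw
#' permutation P, single-step min-P adjusted P, and the two-tailed
#' one-sample t-test P.
#'
#' @param ensemble a [build_ensemble()] result (it carries the observed
#'   census)
#' @param alpha significance level used for the `significant` flag
#'   (adjusted P at or below `alpha`)
#' @return A tibble of class `motif_significance` with columns `key`,
#'   `n_obs`, `null_mean`, `null_sd`, `z`, `log2_ratio`, `p_raw`, `p_adj`,
#'   `t_p`, `rank_z` and `significant`, sorted by descending z. Attributes:
#'   `alpha`, `k`, `mode`, `n_rand`, `min_p` (the per-randomization minimum
#'   raw P-values), `color_levels`.
#' @export
significance_table <- function(ensemble, alpha = 0.05) {
  stopifnot(inherits(ensemble, "motif_ensemble"))
  keys <- ensemble$keys
  counts <- ensemble$counts
  n <- nrow(counts)
  obs <- setNames(rep(0, length(keys)), keys)
  obs[ensemble$observed$key] <- ensemble$observed$count

  null_mean <- colMeans(counts)
  null_sd <- sqrt(colMeans(counts^2) - null_mean^2)
  null_sd[null_sd < 0] <- 0  # numerical guard

  p_adj <- minp_adjust(obs, counts)
  p_raw <- attr(p_adj, "p_raw")
  min_p <- attr(p_adj, "min_p")
  t_p <- vapply(seq_along(keys), function(i) {
    if (null_sd[i] == 0) NA_real_ else per_motif_ttest(obs[i], counts[, i])
  }, numeric(1))

  out <- tibble::tibble(
    key = keys,
    n_obs = as.numeric(obs),
    null_mean = null_mean,
    null_sd = null_sd,
    z = zscore(as.numeric(obs), null_mean, null_sd),
    log2_ratio = log2_ratio(as.numeric(obs), null_mean),
    p_raw = p_raw,
    p_adj = as.numeric(p_adj),
    t_p = t_p
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$z), .data$key)
  out$rank_z <- seq_len(nrow(out))
  out$significant <- out$p_adj <= alpha

  structure(out,
            alpha = alpha, k = ensemble$k, mode = ensemble$mode,
            n_rand = n, min_p = min_p,
            color_levels = ensemble$color_levels,
            class = c("motif_significance", class(out)))
}

#' @method tidy motif_significance
#' @export
tidy.motif_significance <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "alpha") <- attr(out, "k") <- attr(out, "mode") <- NULL
  attr(out, "n_rand") <- attr(out, "min_p") <- NULL
  attr(out, "color_levels") <- NULL
  out
}

#' @method glance motif_significance
#' @export
glance.motif_significance <- function(x, ...) {
  min_p <- attr(x, "min_p")
  tibble::tibble(
    k = attr(x, "k"),
    mode = attr(x, "mode"),
    n_rand = attr(x, "n_rand"),
    n_motifs = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    min_attainable_p_adj = mean(min_p == 0),
    top_z = max(x$z[is.finite(x$z)], -Inf)
  )
}

#' Absence analysis
#'
#' Counts how many of the theoretically possible motif classes never occur:
#' in the observed graph, and in each randomization (whose absent-class
#' counts give the by-chance expectation).
#'
#' @param observed a [motif_census()] result
#' @param ensemble a [build_ensemble()] result of the same size/mode
#' @param classes the class universe from [enumerate_motif_classes()]
#' @return A list of class `absence_report`: `n_possible`, `n_absent_observed`,
#'   `absent_keys` (classes never seen in the observed graph),
#'   `replicate_absent` (per-randomization absent-class counts), and
#'   `summary` (one-row tibble with observed/mean/max absent counts).
#' @export
absence_analysis <- function(observed, ensemble, classes) {
  stopifnot(inherits(observed, "motif_census"),
            inherits(ensemble, "motif_ensemble"))
  if (nrow(ensemble$counts) == 0) {
    stop("empty ensemble", call. = FALSE)
  }
  universe <- classes$key
  if (attr(observed, "k") != classes$k[1] ||
      attr(observed, "mode") != classes$mode[1]) {
    stop("census and class universe disagree on size or mode",
         call. = FALSE)
  }
  observed_present <- observed$key[observed$count > 0]
  absent_keys <- setdiff(universe, observed_present)
  in_universe <- ensemble$keys %in% universe
  replicate_present <- rowSums(ensemble$counts[, in_universe, drop = FALSE] > 0)
  replicate_absent <- length(universe) - replicate_present
  structure(
    list(
      n_possible = length(universe),
      n_absent_observed = length(absent_keys),
      absent_keys = absent_keys,
      replicate_absent = replicate_absent,
      summary = tibble::tibble(
        n_possible = length(universe),
        absent_observed = length(absent_keys),
        absent_replicate_mean = mean(replicate_absent),
        absent_replicate_max = max(replicate_absent)
      )
    ),
    class = "absence_report"
  )
}

#' @export
print.absence_report <- function(x, ...) {
  cat("<absence_report> ", x$n_absent_observed, " of ", x$n_possible,
      " possible classes absent from the observed graph\n",
      "  absent by chance per randomization: mean ",
      format(mean(x$replicate_absent), digits = 3), ", max ",
      max(x$replicate_absent), "\n", sep = "")
  invisible(x)
}

#' Ranked motif report
#'
#' Orders motifs by descending z-score, flags those whose adjusted P-value
#' is at or below `alpha`, and summarizes the color composition of the
#' flagged set: the fraction of node slots occupied by each color across
#' all flagged motifs (e.g. the interneuron enrichment among significant
#' motifs).
#'
#' @param table a [significance_table()] result
#' @param alpha significance level (defaults to the table's own)
#' @return A list of class `motif_report`: `ranked` (the table, ranked, with
#'   a `flagged` column and human-readable `label`), `flagged` (the flagged
#'   subset), and `color_composition` (tibble of per-color slot fractions
#'   among flagged motifs; fractions sum to 1 when any motif is flagged).
#' @export
rank_report <- function(table, alpha = NULL) {
  stopifnot(inherits(table, "motif_significance"))
  if (is.null(alpha)) alpha <- attr(table, "alpha")
  lv <- attr(table, "color_levels")
  ranked <- dplyr::arrange(tibble::as_tibble(table), dplyr::desc(.data$z),
                           .data$key)
  ranked$flagged <- ranked$p_adj <= alpha
  ranked$label <- format_motif(ranked$key, color_names = lv)
  flagged <- ranked[ranked$flagged, ]

  if (nrow(flagged) > 0) {
    slots <- unlist(parse_motif_key(flagged$key)$colors)
    comp <- tibble::tibble(
      color = lv,
      slot_fraction = vapply(seq_along(lv) - 1L,
                             function(ci) mean(slots == ci), numeric(1))
    )
  } else {
    comp <- tibble::tibble(color = lv,
                           slot_fraction = rep(NA_real_, length(lv)))
  }
  structure(list(ranked = ranked, flagged = flagged,
                 color_composition = comp, alpha = alpha),
            class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat("<motif_report> ", nrow(x$flagged), " of ", nrow(x$ranked),
      " motifs flagged at alpha = ", x$alpha, "\n", sep = "")
  if (nrow(x$flagged) > 0) {
    top <- head(x$flagged, 5)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %2d. z=%6.2f  p_adj=%.4g  %s\n", i, top$z[i],
                  top$p_adj[i], top$label[i]))
    }
    comp <- x$color_composition
    cat("  flagged slot composition: ",
        paste(sprintf("%s=%.0f%%", comp$color, 100 * comp$slot_fraction),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
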