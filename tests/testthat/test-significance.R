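test_that("z-score handles the degenerate null", {
  expect_equal(zscore(10, 10, 2), 0)
  expect_equal(zscore(10, 4, 2), 3)
  expect_equal(zscore(5, 5, 0), 0)
  expect_equal(zscore(6, 5, 0), Inf)
  expect_equal(zscore(4, 5, 0), -Inf)
})

test_that("log2 ratio uses infinity sentinels for one-sided absence", {
  expect_equal(log2_ratio(8, 8), 0)
  expect_equal(log2_ratio(8, 4), 1)
  expect_equal(log2_ratio(0, 3), -Inf)
  expect_equal(log2_ratio(3, 0), Inf)
  expect_true(is.na(log2_ratio(0, 0)))
})

test_that("raw P counts ties as exceedances", {
  expect_equal(raw_p(10, c(1, 2, 3)), 0)
  expect_equal(raw_p(1, c(1, 2, 3)), 1)
  expect_equal(raw_p(5, c(3, 5, 7, 9)), 0.75)
})

test_that("min-P adjustment matches the brute-force oracle", {
  # hand-scale instance
  counts <- matrix(c(1, 3, 5, 7,
                     2, 2, 2, 8), nrow = 4)
  obs <- c(6, 9)
  want <- oracle_minp(obs, counts)
  got <- minp_adjust(obs, counts)
  expect_equal(as.numeric(got), want$p_adj)
  expect_equal(attr(got, "p_raw"), want$p_raw)
  expect_equal(sort(attr(got, "min_p")), sort(want$mstar))

  # randomized property sweep
  set.seed(53)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    m <- sample(1:4, 1)
    counts <- matrix(rpois(n * m, 4), n, m)
    obs <- rpois(m, 5)
    want <- oracle_minp(obs, counts)
    got <- minp_adjust(obs, counts)
    expect_equal(as.numeric(got), want$p_adj)
    # adjusted never below raw
    expect_true(all(got >= want$p_raw))
  }
})

test_that("the adjusted-P floor is the zero fraction of the min-P vector", {
  min_p <- c(rep(0, 3), rep(0.2, 7))
  expect_equal(adjust_from_minp(0, min_p), 0.3)
  expect_equal(adjust_from_minp(0.2, min_p), 1)
  expect_equal(adjust_from_minp(0.1, min_p), 0.3)
})

test_that("one-sample t-test is symmetric and monotone", {
  col <- c(4, 5, 6, 7, 8)
  expect_equal(per_motif_ttest(mean(col), col), 1)
  mirrored <- 2 * mean(col) - col
  for (x in c(3, 6.5, 9)) {
    expect_equal(per_motif_ttest(x, col), per_motif_ttest(x, mirrored))
  }
  ps <- sapply(mean(col) + 0:4, function(x) per_motif_ttest(x, col))
  expect_true(all(diff(ps) <= 0))
  expect_true(is.na(per_motif_ttest(3, c(2, 2, 2))))
})

test_that("significance tables satisfy the P-value invariants", {
  set.seed(59)
  g <- random_test_graph(14, p_arc = 0.2, p_link = 0.08)
  ens <- build_ensemble(g, 3, "directed", n_rand = 40, seed = 8)
  sig <- significance_table(ens)
  expect_true(all(sig$p_raw >= 0 & sig$p_raw <= 1))
  expect_true(all(sig$p_adj >= 0 & sig$p_adj <= 1))
  expect_true(all(sig$p_adj >= sig$p_raw))
  expect_true(all(is.finite(sig$z[sig$null_sd > 0])))
  # monotone: p_adj non-decreasing in p_raw within the size class
  ord <- order(sig$p_raw)
  expect_true(all(diff(sig$p_adj[ord]) >= 0))
  # ranked by z
  expect_true(all(diff(sig$z[is.finite(sig$z)]) <= 0) ||
                !is.unsorted(rev(sig$z)))
  g1 <- glance(sig)
  expect_equal(g1$n_motifs, nrow(sig))
  expect_equal(g1$min_attainable_p_adj, mean(attr(sig, "min_p") == 0))
  td <- tidy(sig)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "motif_significance"))
})

test_that("absence analysis counts missing classes against the universe", {
  # single arc, two colors: 7 possible directed pair classes, 1 observed
  g <- colored_graph(
    tibble::tibble(node = c("a", "b"), color = c("x", "y")),
    arcs = tibble::tibble(from = "a", to = "b"),
    color_levels = c("x", "y")
  )
  ens <- build_ensemble(g, 2, "directed", n_rand = 5, seed = 2)
  classes <- enumerate_motif_classes(2, 2, "directed")
  expect_equal(nrow(classes), 7)
  rep <- absence_analysis(ens$observed, ens, classes)
  expect_equal(rep$n_possible, 7)
  expect_equal(rep$n_absent_observed, 6)
  expect_true(all(rep$replicate_absent == 6))

  # a graph realizing every class of its universe reports zero absences
  g2 <- colored_graph(
    tibble::tibble(node = c("a", "b", "c"), color = "x"),
    arcs = tibble::tibble(from = c("a", "b", "b"), to = c("b", "a", "c"))
  )
  ens2 <- build_ensemble(g2, 2, "directed", n_rand = 3, seed = 1)
  cls2 <- enumerate_motif_classes(2, 1, "directed")
  rep2 <- absence_analysis(ens2$observed, ens2, cls2)
  expect_equal(rep2$n_absent_observed, 0)

  # empty ensemble violates the precondition
  fake <- ens
  fake$counts <- fake$counts[0, , drop = FALSE]
  expect_error(absence_analysis(ens$observed, fake, classes), "empty")
})

test_that("rank report orders by z and normalizes color composition", {
  set.seed(61)
  g <- random_test_graph(14, p_arc = 0.2, p_link = 0.05)
  ens <- build_ensemble(g, 2, "directed", n_rand = 30, seed = 4)
  sig <- significance_table(ens)
  rep <- rank_report(sig, alpha = 1)  # flag everything
  expect_equal(rep$ranked$key[1], sig$key[which.max(sig$z)])
  expect_equal(sum(rep$color_composition$slot_fraction), 1)
  expect_equal(nrow(rep$flagged), nrow(sig))
  # single-motif table: that motif is rank 1
  one <- rank_report(sig, alpha = 0)
  expect_equal(one$ranked$rank_z[1], 1)
})
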