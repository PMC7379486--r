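test_that("hand-worked running sums, scores and leading edges reproduce", {
  # set exactly at the top: full signal
  rl10 <- build_ranked_list(setNames(10:1, LETTERS[1:10]))
  top <- enrichment_score(rl10, LETTERS[1:3], weight_p = 0)
  expect_equal(top$es, 1.0)
  expect_equal(top$peak_index, 3L)
  expect_setequal(leading_edge(top, rl10)$genes, LETTERS[1:3])

  # N = 4, hits at ranks 1 and 3, unweighted
  rl4 <- build_ranked_list(c(A = 4, B = 3, C = 2, D = 1))
  e0 <- enrichment_score(rl4, c("A", "C"), weight_p = 0)
  expect_equal(e0$running_sum, c(0.5, 0, 0.5, 0), tolerance = 1e-12)
  expect_equal(e0$es, 0.5)
  expect_equal(e0$peak_index, 1L)  # earliest max
  expect_identical(leading_edge(e0, rl4)$genes, "A")

  # same hits, score-weighted: N_R = 6
  e1 <- enrichment_score(rl4, c("A", "C"), weight_p = 1)
  expect_equal(e1$running_sum, c(2 / 3, 1 / 6, 1 / 2, 0), tolerance = 1e-12)
  expect_equal(e1$es, 2 / 3)

  # mirror case: hits at ranks 2 and 4 -> negative ES, last-min peak
  en <- enrichment_score(rl4, c("B", "D"), weight_p = 0)
  expect_equal(en$running_sum, c(-0.5, 0, -0.5, 0), tolerance = 1e-12)
  expect_equal(en$es, -0.5)
  expect_equal(en$peak_index, 3L)
  expect_identical(leading_edge(en, rl4)$genes, "D")
})

test_that("unweighted ES equals the brute-force KS deviation exactly", {
  set.seed(100)
  for (i in 1:300) {
    N <- sample(4:50, 1)
    rl <- random_ranked(N)
    k <- sample(1:(N - 1), 1)
    hits <- sort(sample(N, k))
    res <- enrichment_score(rl, rl$genes[hits], weight_p = 0)
    expect_identical(res$hit_positions, hits)
    expect_equal(res$es, ks_oracle(hits, N), tolerance = 1e-12)
  }
})

test_that("weighted ES agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(101)
  for (i in 1:100) {
    N <- sample(10:60, 1)
    sc <- sort(rnorm(N), decreasing = TRUE)
    names(sc) <- sprintf("G%03d", 1:N)
    hits <- sort(sample(N, sample(1:(N - 1), 1)))
    mine <- enrichment_score(build_ranked_list(sc), names(sc)[hits],
                             weight_p = 1)$es
    expect_equal(mine, fgsea::calcGseaStat(sc, selectedStats = hits,
                                           gseaParam = 1),
                 tolerance = 1e-10)
  }
})

test_that("ES bounds, terminal zero, and scale invariance hold on random input", {
  set.seed(102)
  for (i in 1:100) {
    N <- sample(5:80, 1)
    rl <- random_ranked(N)
    hits <- sort(sample(N, sample(1:(N - 1), 1)))
    for (p in c(0, 1)) {
      res <- enrichment_score(rl, rl$genes[hits], weight_p = p)
      expect_true(res$es >= -1 && res$es <= 1)
      expect_lt(abs(res$running_sum[N]), 1e-12)
      expect_equal(res$es, res$running_sum[res$peak_index])
      expect_equal(abs(res$es), max(abs(res$running_sum)))
    }
    # p = 0 depends on positions only: monotone transforms change nothing
    sc2 <- setNames(exp(rl$scores / 2), rl$genes)
    rl2 <- build_ranked_list(sc2)
    expect_equal(enrichment_score(rl2, rl$genes[hits], weight_p = 0)$es,
                 enrichment_score(rl, rl$genes[hits], weight_p = 0)$es,
                 tolerance = 1e-12)
  }
})

test_that("reversing the list negates ES and preserves the leading edge", {
  set.seed(103)
  n_checked <- 0
  for (i in 1:100) {
    N <- sample(6:40, 1)
    rl <- random_ranked(N)
    hits <- sort(sample(N, sample(2:(N - 1), 1)))
    res <- enrichment_score(rl, rl$genes[hits], weight_p = 0)
    rs <- res$running_sum
    # a positive/negative extremum tie (up to rounding) voids antisymmetry
    if (abs(abs(max(rs)) - abs(min(rs))) < 1e-9) next
    rev_rl <- build_ranked_list(setNames(rev(rl$scores), rev(rl$genes)),
                                direction = "ascending")
    expect_identical(rev_rl$genes, rev(rl$genes))
    res_rev <- enrichment_score(rev_rl, rl$genes[hits], weight_p = 0)
    expect_equal(res_rev$es, -res$es, tolerance = 1e-12)
    expect_setequal(leading_edge(res_rev, rev_rl)$genes,
                    leading_edge(res, rl)$genes)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 50)
})

test_that("degenerate gene sets are rejected or repaired with a warning", {
  rl <- random_ranked(12)
  expect_error(suppressWarnings(enrichment_score(rl, c("NOT1", "NOT2"))),
               "not represented")
  expect_error(enrichment_score(rl, rl$genes), "whole ranked list")
  expect_warning(res <- enrichment_score(rl, c(rl$genes[1:3], "ABSENT")),
                 "absent")
  expect_equal(res$n_hits, 3L)
  # all-zero member scores at p = 1 fall back to p = 0
  sc <- setNames(c(3, 2, 0, 0, -2, -3), sprintf("G%d", 1:6))
  rlz <- build_ranked_list(sc)
  expect_warning(rz <- enrichment_score(rlz, c("G3", "G4"), weight_p = 1),
                 "falling back")
  expect_equal(rz$es,
               enrichment_score(rlz, c("G3", "G4"), weight_p = 0)$es)
})

test_that("the sampled permutation null matches exhaustive enumeration", {
  rl <- random_ranked(8)
  null <- permutation_null(rl, set_size = 3, weight_p = 0, n_perm = 2000,
                           seed = 5)
  exact <- ks_null_enumeration(8, 3)  # all 56 subsets, independent oracle
  se <- sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null) - mean(exact)), 3 * se)
  expect_true(any(null > 0) && any(null < 0))
  # every sampled value must be attainable: subset of the enumerated support
  expect_true(all(vapply(null, function(v) any(abs(exact - v) < 1e-12),
                         logical(1))))
  expect_identical(permutation_null(rl, 3, 0, 200, seed = 9),
                   permutation_null(rl, 3, 0, 200, seed = 9))
  expect_error(permutation_null(rl, 3, 0, n_perm = 50), ">= 99")
  expect_error(permutation_null(rl, 8, 0, n_perm = 100), "set_size")
})

test_that("near-complete sets on a constant-score list draw from the enumerated support", {
  # with set_size = N - 1 the null ES depends only on the excluded position;
  # the sample must land inside that exact (small) support
  rl <- build_ranked_list(setNames(rep(1, 6), sprintf("G%d", 1:6)))
  null <- permutation_null(rl, set_size = 5, weight_p = 0, n_perm = 99, seed = 2)
  support <- vapply(1:6, function(j) ks_oracle(setdiff(1:6, j), 6), numeric(1))
  expect_true(all(vapply(null, function(v) any(abs(support - v) < 1e-12),
                         logical(1))))
})

test_that("significance follows the signed add-one convention", {
  # 100 same-sign nulls, none as extreme: p = 1/101
  null <- c(seq(0.001, 0.29, length.out = 100),
            seq(-0.29, -0.001, length.out = 99))
  sig <- significance(0.9, null)
  expect_equal(sig$p_nominal, 1 / 101)
  expect_equal(sig$nes, 0.9 / mean(abs(null[null > 0])))
  expect_equal(sig$fdr, sig$p_nominal)  # single-set FDR collapses to p

  # observed at the median of same-sign nulls -> p near 0.5
  pos <- seq(0.01, 1, length.out = 101)
  sig2 <- significance(median(pos), c(pos, -pos))
  expect_equal(sig2$p_nominal, (1 + 51) / 102, tolerance = 1e-12)

  # NES keeps the sign of ES
  sig3 <- significance(-0.4, c(-0.5, -0.1, 0.2, 0.3))
  expect_lt(sig3$nes, 0)
  expect_warning(sig4 <- significance(0.5, c(-0.1, -0.2)), "no same-sign")
  expect_equal(sig4$p_nominal, 1)
  expect_error(significance(0.5, numeric()), "empty")
})

test_that("run_gsea composes the stages and flags the screening direction", {
  cfg <- sim_config(n_genes = 400, n_samples = 60, module_size = 25,
                    delta = 1.5, sigma = 1, seed = 33)
  up <- contrast_gsea(cfg, "up")
  expect_gt(up$es, 0)
  expect_lt(up$p_nominal, 0.05)
  expect_true(all(up$leading_edge$genes %in%
                  simulate_compendium(cfg)$truth$module_genes))
  down <- contrast_gsea(cfg, "down")
  expect_lt(down$es, 0)
  expect_lt(down$p_nominal, 0.05)
  expect_equal(summary(down)$es, down$es)
})
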