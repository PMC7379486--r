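# Orthonormal sample-space directions for exact-correlation constructions.
ortho_basis <- function(n, k, seed = 1) {
  set.seed(seed)
  qr.Q(qr(cbind(1, matrix(rnorm(n * k), n, k))))[, -1L, drop = FALSE]
}

test_that("mean Fisher-z score matches its closed forms exactly", {
  n <- 12
  q <- ortho_basis(n, 4)
  # marker trio mutually uncorrelated; gene X identical to marker 1
  x <- rbind(POSTN = q[, 1], DDR2 = q[, 2], PDGFRA = q[, 3],
             X = q[, 1],
             Y = 0.5 * q[, 1] + sqrt(0.75) * q[, 4])
  colnames(x) <- paste0("S", 1:n)
  tab <- coexpression_scores(cfgm_dataset(x), c("POSTN", "DDR2", "PDGFRA"))
  expect_setequal(tab$gene, c("X", "Y"))
  # r = (1, 0, 0): clipped self-like term dominates
  expect_equal(tab$zbar[tab$gene == "X"], atanh(0.999999) / 3, tolerance = 1e-9)
  # r = (0.5, 0, 0)
  expect_equal(tab$zbar[tab$gene == "Y"], atanh(0.5) / 3, tolerance = 1e-9)
})

test_that("a gene correlated 0.5 with every marker scores atanh(0.5)", {
  n <- 12
  q <- ortho_basis(n, 2)
  x <- rbind(M1 = q[, 1], M2 = q[, 1], M3 = q[, 1],
             G = 0.5 * q[, 1] + sqrt(0.75) * q[, 2])
  colnames(x) <- paste0("S", 1:n)
  tab <- coexpression_scores(cfgm_dataset(x), c("M1", "M2", "M3"))
  expect_equal(tab$zbar[tab$gene == "G"], atanh(0.5), tolerance = 1e-9)
})

test_that("zbar is invariant to a common sample permutation", {
  sim <- simulate_compendium(sim_config(n_genes = 60, n_samples = 25,
                                        module_size = 6, seed = 2))
  t1 <- coexpression_scores(sim$dataset, sim$truth$marker_genes)
  perm <- sample(ncol(sim$dataset$expr))
  shuffled <- cfgm_dataset(sim$dataset$expr[, perm])
  t2 <- coexpression_scores(shuffled, sim$truth$marker_genes)
  expect_equal(t1$zbar, t2$zbar[match(t1$gene, t2$gene)], tolerance = 1e-12)
})

test_that("marker or sample preconditions fail loudly", {
  sim <- simulate_compendium(sim_config(n_genes = 50, n_samples = 20,
                                        module_size = 5, seed = 1))
  expect_error(coexpression_scores(sim$dataset, c("POSTN", "NOPE")), "NOPE")
  tiny <- cfgm_dataset(sim$dataset$expr[, 1:5])
  expect_error(coexpression_scores(tiny, "POSTN"), ">= 10")
})

test_that("permutation p-values honor the add-one floor and the seed", {
  sim <- simulate_compendium(sim_config(n_genes = 80, n_samples = 40,
                                        module_size = 10, beta = 3,
                                        sigma = 0.3, seed = 6))
  tab <- coexpression_scores(sim$dataset, sim$truth$marker_genes)
  p1 <- empirical_pvalues(tab, sim$dataset, sim$truth$marker_genes,
                          n_null = 99, seed = 10)
  p2 <- empirical_pvalues(tab, sim$dataset, sim$truth$marker_genes,
                          n_null = 99, seed = 10)
  expect_identical(p1$p_value, p2$p_value)
  expect_true(all(p1$p_value >= 1 / 100))
  # strongly coexpressed module genes beat all 99 permutations: exact floor
  mod <- setdiff(sim$truth$module_genes, sim$truth$marker_genes)
  expect_true(all(p1$p_value[p1$gene %in% mod] == 1 / 100))
  expect_error(empirical_pvalues(tab, sim$dataset, sim$truth$marker_genes,
                                 n_null = 50), ">= 99")
})

test_that("background p-values are uniform in a beta = 0 compendium", {
  cfg <- sim_config(n_genes = 503, n_samples = 60, module_size = 3,
                    n_markers = 3, beta = 0, seed = 17)
  sim <- simulate_compendium(cfg)
  tab <- coexpression_scores(sim$dataset, sim$truth$marker_genes)
  tab <- empirical_pvalues(tab, sim$dataset, sim$truth$marker_genes,
                           n_null = 199, seed = 17)
  ks <- suppressWarnings(ks.test(tab$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  # selection rate at threshold t stays near/below t (calibration)
  expect_lt(mean(tab$p_value < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})

test_that("module selection is strict at the threshold and keeps markers", {
  tab <- structure(data.frame(gene = c("A", "B", "C"),
                              zbar = c(2, 1, 0),
                              p_value = c(0.005, 0.5, 1.0),
                              n_null = 999L),
                   class = c("cfgm_coexpr_table", "data.frame"))
  mk <- gene_set(c("POSTN", "DDR2", "PDGFRA"), "markers")
  m1 <- select_module(tab, mk, p_threshold = 0.01)
  expect_setequal(m1$genes, c("POSTN", "DDR2", "PDGFRA", "A"))
  # p = 1 exactly is never selected, even at threshold 1.0 (strict <)
  m_all <- select_module(tab, mk, p_threshold = 1.0)
  expect_setequal(m_all$genes, c("POSTN", "DDR2", "PDGFRA", "A", "B"))
  expect_error(select_module(tab, mk, p_threshold = 0), "\\(0, 1]")
})

test_that("relaxing the threshold never shrinks the module", {
  sim <- simulate_compendium(sim_config(n_genes = 200, n_samples = 50,
                                        module_size = 15, seed = 4))
  fit <- build_module(sim$dataset, sim$truth$marker_genes, n_null = 199, seed = 4)
  m_strict <- select_module(fit$table, sim$truth$marker_genes, 0.01)
  m_loose <- select_module(fit$table, sim$truth$marker_genes, 0.05)
  expect_true(all(m_strict$genes %in% m_loose$genes))
  for (t in c(0.001, 0.02, 0.1, 0.5)) {
    expect_true(all(select_module(fit$table, sim$truth$marker_genes, t)$genes %in%
                    select_module(fit$table, sim$truth$marker_genes,
                                  min(1, t * 2))$genes))
  }
})
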