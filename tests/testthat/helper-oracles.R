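# Independent oracles, deliberately written along different paths than the
# package internals.

# Classic two-sample KS deviation between in-set and out-of-set rank CDFs,
# computed naively position by position (O(N * N)); the signed value with the
# largest magnitude (positive preferred on an exact magnitude tie).
ks_oracle <- function(hit_pos, N) {
  NH <- length(hit_pos)
  dev <- vapply(seq_len(N), function(i) {
    h <- sum(hit_pos <= i)
    h / NH - (i - h) / (N - NH)
  }, numeric(1))
  hi <- max(dev, 0)
  lo <- min(dev, 0)
  if (abs(hi) >= abs(lo) - 1e-9) hi else lo  # positive wins a magnitude tie
}

# All-subset enumeration of the KS null for sets of size k in a list of N.
ks_null_enumeration <- function(N, k) {
  apply(utils::combn(N, k), 2L, ks_oracle, N = N)
}

# Hypergeometric upper tail by explicit enumeration of every size-b draw from
# the universe, with set A fixed as the first `a` elements.
hyper_oracle <- function(k, a, b, U) {
  if (k == 0) return(1)
  draws <- utils::combn(U, b)
  mean(apply(draws, 2L, function(d) sum(d <= a)) >= k)
}

# Random ranked list with distinct scores.
random_ranked <- function(N) {
  sc <- sort(rnorm(N), decreasing = TRUE)
  names(sc) <- sprintf("G%03d", seq_len(N))
  build_ranked_list(sc)
}

# One synthetic contrast scored end-to-end; returns the cfgm_gsea result.
contrast_gsea <- function(cfg, direction, n_perm = 199L, weight_p = 1) {
  sim <- simulate_compendium(cfg)
  ds <- simulate_contrast(cfg, sim$truth, direction = direction)
  ranked <- rank_genes(ds, method = "moderated_t", direction = "descending")
  run_gsea(ranked, gene_set(sim$truth$module_genes, "module"),
           weight_p = weight_p, n_perm = n_perm,
           seed = derive_null_seed(cfg$seed))
}

derive_null_seed <- function(seed) (seed %% 100000L) * 7L + 13L
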