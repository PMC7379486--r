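#' Mean Fisher-z coexpression of every gene with a marker set
#'
#' For each non-marker gene g, computes
#' \deqn{\bar z(g) = \frac{1}{|M|}\sum_{m \in M} \mathrm{atanh}(r(g, m))}
#' where r is the Pearson correlation across compendium samples, clipped to
#' +/- 0.999999 before the Fisher transform so scores stay finite. This is the
#' local coexpression score used to seed a gene functional module from marker
#' genes; significance is attached by [empirical_pvalues()].
#'
#' @param compendium A [cfgm_dataset()] with at least 10 samples (the
#'   correlation estimate is too unstable to threshold below that).
#' @param markers A gene set or character vector; every marker must be present
#'   in the compendium.
#' @return A data frame of class `cfgm_coexpr_table` with columns `gene` and
#'   `zbar`, one row per non-marker gene (markers are excluded), plus columns
#'   `p_value`/`n_null` once [empirical_pvalues()] has run.
#' @examples
#' sim <- simulate_compendium(sim_config(n_genes = 100, n_samples = 30,
#'                                       module_size = 10, seed = 1))
#' tab <- coexpression_scores(sim$dataset, sim$truth$marker_genes)
#' head(tab[order(-tab$zbar), ])
#' @export
coexpression_scores <- function(compendium, markers) {
  stopifnot(inherits(compendium, "cfgm_dataset"))
  markers <- as_gene_set(markers, name = "markers")
  x <- compendium$expr
  n <- ncol(x)
  if (n < 10L) {
    stop("compendium has ", n, " samples; >= 10 are required for coexpression scoring",
         call. = FALSE)
  }
  absent <- setdiff(markers$genes, rownames(x))
  if (length(absent) > 0L) {
    stop("marker gene(s) absent from compendium: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  others <- setdiff(rownames(x), markers$genes)
  r <- stats::cor(t(x[others, , drop = FALSE]), t(x[markers$genes, , drop = FALSE]))
  r[is.na(r)] <- 0  # constant gene: define correlation as 0
  zbar <- rowMeans(atanh(pmin(pmax(r, -0.999999), 0.999999)))
  structure(data.frame(gene = others, zbar = unname(zbar),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("cfgm_coexpr_table", "data.frame"),
            markers = markers$genes)
}

# Mean Fisher-z of one (standardized) gene vector against standardized markers.
# zg: n-vector or n x k matrix of (possibly permuted) standardized gene values;
# zm: n x |M| standardized marker matrix. Returns length-k zbar vector.
zbar_std <- function(zg, zm, n) {
  r <- crossprod(zm, zg) / (n - 1)     # |M| x k
  rowMeans(t(atanh(pmin(pmax(r, -0.999999), 0.999999))))
}

std_rows <- function(x) {
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  sdv[sdv == 0] <- Inf  # constant row -> standardized to 0 -> correlation 0
  (x - mu) / sdv
}

#' Per-gene permutation p-values for coexpression scores
#'
#' For each scored gene, draws `n_null` independent random permutations of that
#' gene's sample vector, recomputes the mean Fisher-z score against the (fixed)
#' markers, and reports the one-sided add-one p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)`. Only positive coexpression
#' counts as extreme, matching the goal of collecting the most strongly
#' coexpressed genes; p-values are never exactly 0 and are bounded below by
#' `1 / (n_null + 1)`.
#'
#' @param table Output of [coexpression_scores()].
#' @param compendium The same compendium the table was computed from.
#' @param markers The same marker set.
#' @param n_null Number of permutations, >= 99 (fewer cannot resolve p < 0.01).
#' @param seed Integer seed; the null is fully reproducible.
#' @return The table with `p_value` and `n_null` columns filled.
#' @export
empirical_pvalues <- function(table, compendium, markers, n_null = 999L, seed = 1L) {
  stopifnot(inherits(table, "cfgm_coexpr_table"),
            inherits(compendium, "cfgm_dataset"))
  markers <- as_gene_set(markers, name = "markers")
  if (n_null < 99L) {
    stop("n_null must be >= 99 to resolve p-values near 0.01 (got ", n_null, ")",
         call. = FALSE)
  }
  n_null <- as.integer(n_null)
  x <- compendium$expr
  n <- ncol(x)
  zm <- t(std_rows(x[markers$genes, , drop = FALSE]))  # n x |M|
  zg_all <- std_rows(x[table$gene, , drop = FALSE])    # genes x n
  obs <- table$zbar
  p <- numeric(nrow(table))
  with_seed(seed, {
    for (i in seq_len(nrow(table))) {
      zg <- zg_all[i, ]
      idx <- vapply(seq_len(n_null), function(j) sample.int(n), integer(n))
      null_z <- zbar_std(matrix(zg[idx], nrow = n, ncol = n_null), zm, n)
      p[i] <- (1 + sum(null_z >= obs[i])) / (1 + n_null)
    }
  })
  table$p_value <- p
  table$n_null <- n_null
  table
}

#' Select a marker-seeded gene functional module
#'
#' The module is the union of the marker genes (always included, whatever
#' their score) and every gene whose empirical coexpression p-value is
#' strictly below `p_threshold`. Selection is monotone in the threshold:
#' relaxing it can only grow the module.
#'
#' @param table A `cfgm_coexpr_table` with p-values filled.
#' @param markers The marker gene set.
#' @param p_threshold Strict upper bound on the coexpression p-value, in
#'   `(0, 1]`; default 0.01.
#' @param name Name for the resulting set.
#' @return A [gene_set()].
#' @export
select_module <- function(table, markers, p_threshold = 0.01, name = "module") {
  stopifnot(inherits(table, "cfgm_coexpr_table"))
  markers <- as_gene_set(markers, name = "markers")
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      is.na(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("`p_threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(table$p_value)) {
    stop("table has no p-values; run empirical_pvalues() first", call. = FALSE)
  }
  selected <- table$gene[table$p_value < p_threshold]
  gene_set(c(markers$genes, selected), name = name,
           description = sprintf("markers + coexpressed genes at p < %g", p_threshold))
}

#' Build a marker-seeded module in one step
#'
#' Composition of [coexpression_scores()], [empirical_pvalues()] and
#' [select_module()].
#'
#' @inheritParams empirical_pvalues
#' @inheritParams select_module
#' @return A list with elements `module` (a [gene_set()]) and `table` (the
#'   scored `cfgm_coexpr_table`).
#' @examples
#' sim <- simulate_compendium(sim_config(n_genes = 150, n_samples = 40,
#'                                       module_size = 12, seed = 3))
#' fit <- build_module(sim$dataset, sim$truth$marker_genes, n_null = 199, seed = 3)
#' fit$module
#' @export
build_module <- function(compendium, markers, p_threshold = 0.01,
                         n_null = 999L, seed = 1L, name = "module") {
  tab <- coexpression_scores(compendium, markers)
  tab <- empirical_pvalues(tab, compendium, markers, n_null = n_null, seed = seed)
  list(module = select_module(tab, markers, p_threshold = p_threshold, name = name),
       table = tab)
}
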