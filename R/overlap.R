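#' Hypergeometric upper-tail probability of a gene-list overlap
#'
#' Probability of observing at least `k` shared genes between a set of size
#' `size_a` and an independent draw of `size_b` genes from a universe of
#' `universe` genes:
#' \deqn{P(X \ge k) = \sum_{j=k}^{\min(a,b)}
#'       \binom{a}{j}\binom{U-a}{b-j} \Big/ \binom{U}{b}}
#' Evaluated through the hypergeometric distribution functions (log-space
#' internals), so it is stable for large universes. `k = 0` returns exactly 1.
#'
#' @param k Observed overlap count.
#' @param size_a,size_b Set sizes.
#' @param universe Universe size.
#' @return Upper-tail p-value in `(0, 1]`.
#' @examples
#' hypergeom_tail(5, 5, 5, 10)   # 1 / choose(10, 5)
#' hypergeom_tail(3, 4, 4, 8)    # 17/70
#' @export
hypergeom_tail <- function(k, size_a, size_b, universe) {
  for (nm in c("k", "size_a", "size_b", "universe")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v)) {
      stop("`", nm, "` must be a single integer", call. = FALSE)
    }
  }
  if (k < 0) stop("violated bound: k >= 0", call. = FALSE)
  if (size_a > universe) stop("violated bound: size_a <= universe", call. = FALSE)
  if (size_b > universe) stop("violated bound: size_b <= universe", call. = FALSE)
  if (k > min(size_a, size_b)) {
    stop("violated bound: k <= min(size_a, size_b)", call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, m = size_a, n = universe - size_a, k = size_b,
                lower.tail = FALSE)
}

#' Overlap test between two core gene sets
#'
#' Counts the shared genes between two sets (after case normalization) and
#' returns the hypergeometric upper-tail p-value against a stated universe —
#' the standard test for whether two leading-edge ("core") gene sets from
#' different conditions agree more than chance. The natural universe for
#' leading edges is the module they were extracted from.
#'
#' Members of either set outside the universe are dropped with a warning (and
#' counted in the result).
#'
#' @param core_a,core_b Gene sets or character vectors.
#' @param universe_genes Gene set or character vector defining the universe.
#' @return An object of class `cfgm_overlap`: list with `k`, `size_a`,
#'   `size_b`, `universe`, `p_value`, `shared_genes`, `n_dropped`.
#' @examples
#' u <- sprintf("G%02d", 1:20)
#' compare_core_genes(u[1:6], u[4:9], u)
#' @export
compare_core_genes <- function(core_a, core_b, universe_genes) {
  universe_genes <- as_gene_set(universe_genes, name = "universe")
  a <- as_gene_set(core_a, name = "core_a")
  b <- as_gene_set(core_b, name = "core_b")
  u <- universe_genes$genes
  if (length(u) == 0L) stop("empty universe", call. = FALSE)
  out_a <- setdiff(a$genes, u)
  out_b <- setdiff(b$genes, u)
  n_drop <- length(out_a) + length(out_b)
  if (n_drop > 0L) {
    warning(n_drop, " gene(s) outside the universe dropped from the overlap test",
            call. = FALSE)
  }
  ga <- intersect(a$genes, u)
  gb <- intersect(b$genes, u)
  shared <- intersect(ga, gb)
  p <- hypergeom_tail(length(shared), length(ga), length(gb), length(u))
  structure(list(k = length(shared), size_a = length(ga), size_b = length(gb),
                 universe = length(u), p_value = p, shared_genes = shared,
                 n_dropped = n_drop),
            class = "cfgm_overlap")
}

#' @export
print.cfgm_overlap <- function(x, ...) {
  cat("<cfgm_overlap> ", x$k, " shared of ", x$size_a, " vs ", x$size_b,
      " in universe ", x$universe, "\n", sep = "")
  cat(sprintf("  hypergeometric upper-tail p = %.4g\n", x$p_value))
  if (x$n_dropped > 0L) cat("  (", x$n_dropped, " genes outside universe dropped)\n", sep = "")
  invisible(x)
}
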