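#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks a ranked gene list accumulating a hit/miss running sum. At position i,
#' \deqn{P_{hit}(i) = \sum_{j \le i,\ g_j \in S} |r_j|^p / N_R, \qquad
#'       P_{miss}(i) = \sum_{j \le i,\ g_j \notin S} \frac{1}{N - N_H}}
#' with \eqn{N_R = \sum_{g_j \in S} |r_j|^p}; the enrichment score ES is the
#' value of `running_sum = P_hit - P_miss` with the largest absolute deviation
#' from zero. For `weight_p = 0` this is exactly the (signed) two-sample KS
#' deviation between the in-set and out-of-set rank distributions, so
#' `-1 <= ES <= 1` and the running sum ends at 0. Positive ES means
#' concentration of the set at the top of the list, negative at the bottom.
#'
#' The extremum position is the *first* index attaining the maximum when ES is
#' positive and the *last* index attaining the minimum when ES is negative;
#' these tie rules make leading edges symmetric under list reversal. A tie
#' between equal-magnitude positive and negative deviations is resolved in
#' favor of the positive one.
#'
#' Gene-set members missing from the ranked list are dropped with a warning
#' (expression platforms rarely cover every set member). If `weight_p = 1` and
#' every member score is zero (`N_R = 0`), the score falls back to `weight_p =
#' 0` for that set, with a warning.
#'
#' @param ranked A [build_ranked_list()] object.
#' @param set A gene set or character vector; the intersection with the list
#'   must be non-empty and must not be the whole list.
#' @param weight_p Score weighting exponent: 0 (classic KS) or 1 (score-
#'   weighted, the usual enrichment-analysis default).
#' @return A list of class `cfgm_es` with `es`, `running_sum` (length N),
#'   `peak_index`, `hit_positions` (sorted), `weight_p`, `set_name`, `n_hits`.
#' @examples
#' rl <- build_ranked_list(c(A = 4, B = 3, C = 2, D = 1))
#' enrichment_score(rl, c("A", "C"), weight_p = 0)$running_sum  # 0.5 0 0.5 0
#' enrichment_score(rl, c("A", "C"), weight_p = 1)$es           # 2/3
#' @export
enrichment_score <- function(ranked, set, weight_p = 1) {
  stopifnot(inherits(ranked, "cfgm_ranked_list"))
  set <- as_gene_set(set)
  if (!weight_p %in% c(0, 1)) stop("`weight_p` must be 0 or 1", call. = FALSE)
  N <- length(ranked$genes)
  in_set <- ranked$genes %in% set$genes
  n_hits <- sum(in_set)
  n_missing <- length(set$genes) - n_hits
  if (n_missing > 0L) {
    warning(n_missing, " gene(s) of set '", set$name,
            "' absent from the ranked list; dropped", call. = FALSE)
  }
  if (n_hits == 0L) {
    stop("gene set '", set$name, "' not represented in ranked list", call. = FALSE)
  }
  if (n_hits == N) {
    stop("gene set '", set$name, "' covers the whole ranked list; ",
         "the miss distribution is undefined", call. = FALSE)
  }
  w <- if (weight_p == 1) abs(ranked$scores) else rep(1, N)
  NR <- sum(w[in_set])
  if (NR == 0) {
    warning("all member scores are zero at weight_p = 1; falling back to weight_p = 0",
            call. = FALSE)
    weight_p <- 0
    w <- rep(1, N)
    NR <- n_hits
  }
  step <- ifelse(in_set, w / NR, -1 / (N - n_hits))
  rs <- cumsum(step)
  hi <- max(rs); lo <- min(rs)
  # extremum comparisons use a small tolerance so that summation noise cannot
  # flip an analytic tie; a positive/negative magnitude tie resolves positive
  tol <- 1e-9
  if (abs(hi) >= abs(lo) - tol) {
    peak <- which(rs >= hi - tol)[1L]         # first index attaining the max
  } else {
    peak <- max(which(rs <= lo + tol))        # last index attaining the min
  }
  es <- rs[peak]
  structure(list(es = es, running_sum = rs, peak_index = peak,
                 hit_positions = which(in_set), weight_p = weight_p,
                 set_name = set$name, n_hits = n_hits),
            class = "cfgm_es")
}

# ES only, from sorted hit positions -- O(n_hits) once weights are in hand.
# Exactly equivalent to enrichment_score()'s extremum: between hits the running
# sum decreases linearly, so maxima occur at hit positions and minima just
# before a hit or at the terminal zero.
es_fast <- function(hit_pos, w, N) {
  k <- length(hit_pos)
  wh <- w[hit_pos]
  NR <- sum(wh)
  if (NR == 0) {
    wh <- rep(1, k)
    NR <- k
  }
  miss_step <- 1 / (N - k)
  cum_hit <- cumsum(wh) / NR
  miss_at <- (hit_pos - seq_len(k)) * miss_step     # misses before each hit
  top <- cum_hit - miss_at                          # value at each hit position
  bot <- c(0, cum_hit[-k]) - miss_at                # value just before each hit
  hi <- max(top, 0); lo <- min(bot, 0)
  if (abs(hi) >= abs(lo) - 1e-9) hi else lo
}

#' Random-set permutation null for the enrichment score
#'
#' Draws `n_perm` random gene sets of the given size (positions sampled
#' uniformly without replacement from the ranked list — the gene-tag null used
#' for preranked analysis, where phenotype permutation is unavailable) and
#' returns their enrichment scores.
#'
#' @inheritParams enrichment_score
#' @param set_size Size of the random sets, `1 <= set_size < N`.
#' @param n_perm Number of draws, >= 99.
#' @param seed Integer seed.
#' @return Numeric vector of `n_perm` null ES values.
#' @export
permutation_null <- function(ranked, set_size, weight_p = 1, n_perm = 1000L,
                             seed = 1L) {
  stopifnot(inherits(ranked, "cfgm_ranked_list"))
  N <- length(ranked$genes)
  if (n_perm < 99L) stop("n_perm must be >= 99 (got ", n_perm, ")", call. = FALSE)
  if (set_size < 1L || set_size >= N) {
    stop("set_size must satisfy 1 <= set_size < ", N, call. = FALSE)
  }
  if (!weight_p %in% c(0, 1)) stop("`weight_p` must be 0 or 1", call. = FALSE)
  w <- if (weight_p == 1) abs(ranked$scores) else rep(1, N)
  with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) es_fast(sort.int(sample.int(N, set_size)), w, N),
           numeric(1))
  })
}

#' Significance of an enrichment score against its permutation null
#'
#' Uses the signed convention: only null scores with the same sign as the
#' observed ES enter the comparison set D. Then
#' `p_nominal = (1 + #\{d in D : |d| >= |es|\}) / (1 + #D)` (add-one, never
#' exactly 0), `nes = es / mean(|D|)`, and the single-set FDR is the fraction
#' of normalized same-sign nulls at least as extreme as `|nes|` with the same
#' add-one guard (for one gene set this coincides with the nominal p; it is
#' reported separately to mirror the usual ES/FDR result pair).
#'
#' @param es Observed enrichment score.
#' @param es_null Non-empty numeric vector of null ES values.
#' @return List with `p_nominal`, `nes`, `fdr`.
#' @export
significance <- function(es, es_null) {
  if (length(es_null) == 0L) stop("es_null is empty", call. = FALSE)
  if (es == 0) {
    warning("observed ES is 0; significance undefined, reporting p = 1", call. = FALSE)
    return(list(p_nominal = 1, nes = 0, fdr = 1))
  }
  same <- es_null[sign(es_null) == sign(es)]
  if (length(same) == 0L) {
    warning("no same-sign null mass; reporting p = 1", call. = FALSE)
    return(list(p_nominal = 1, nes = NA_real_, fdr = 1))
  }
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  norm <- mean(abs(same))
  nes <- es / norm
  fdr <- (1 + sum(abs(same / norm) >= abs(nes))) / (1 + length(same))
  list(p_nominal = p, nes = nes, fdr = fdr)
}

#' Leading-edge (core) subset of an enrichment result
#'
#' The gene-set members that account for the enrichment signal: for positive
#' ES, members at or before the running-sum peak (first index attaining the
#' maximum); for negative ES, members at or after the peak (last index
#' attaining the minimum). An ES of exactly 0 yields an empty leading edge
#' with a warning.
#'
#' @param result A `cfgm_es` (or `cfgm_gsea`) object computed on `ranked`.
#' @param ranked The ranked list the result was computed on.
#' @return A [gene_set()]; non-empty whenever `es != 0`.
#' @export
leading_edge <- function(result, ranked) {
  stopifnot(inherits(ranked, "cfgm_ranked_list"))
  if (inherits(result, "cfgm_gsea")) result <- result$score
  stopifnot(inherits(result, "cfgm_es"))
  if (result$es == 0) {
    warning("ES is 0; leading edge is empty", call. = FALSE)
    return(structure(list(name = paste0(result$set_name, "_leading_edge"),
                          description = "leading edge (empty: ES = 0)",
                          genes = character()),
                     class = "cfgm_gene_set"))
  }
  pos <- if (result$es > 0) {
    result$hit_positions[result$hit_positions <= result$peak_index]
  } else {
    result$hit_positions[result$hit_positions >= result$peak_index]
  }
  gene_set(ranked$genes[pos], name = paste0(result$set_name, "_leading_edge"),
           description = sprintf("core genes at peak %d (ES = %.4f)",
                                 result$peak_index, result$es))
}

#' Preranked gene-set enrichment analysis
#'
#' The single entry point composing [enrichment_score()],
#' [permutation_null()], [significance()] and [leading_edge()]: running-sum
#' ES, random-set null, nominal p / NES / FDR, and the leading-edge core
#' genes. A negative ES with small p flags a signature-reversal candidate
#' (the set is concentrated at the bottom of the ranked list); a positive one
#' flags disease-like overexpression.
#'
#' @inheritParams enrichment_score
#' @inheritParams permutation_null
#' @return An object of class `cfgm_gsea`: list with `score` (the `cfgm_es`),
#'   `es`, `nes`, `p_nominal`, `fdr`, `es_null`, `leading_edge` (a
#'   [gene_set()]), `n_perm`, `seed`, `set_name`, `n_hits`.
#' @examples
#' rl <- build_ranked_list(setNames(seq(2, -2, length.out = 50),
#'                                  sprintf("G%02d", 1:50)))
#' res <- run_gsea(rl, sprintf("G%02d", 1:8), weight_p = 0, n_perm = 199, seed = 1)
#' res
#' @export
run_gsea <- function(ranked, set, weight_p = 1, n_perm = 1000L, seed = 1L) {
  set <- as_gene_set(set)
  sc <- enrichment_score(ranked, set, weight_p = weight_p)
  null <- permutation_null(ranked, set_size = sc$n_hits, weight_p = sc$weight_p,
                           n_perm = n_perm, seed = seed)
  sig <- significance(sc$es, null)
  le <- leading_edge(sc, ranked)
  structure(list(score = sc, es = sc$es, nes = sig$nes,
                 p_nominal = sig$p_nominal, fdr = sig$fdr,
                 es_null = null, leading_edge = le,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 set_name = set$name, n_hits = sc$n_hits),
            class = "cfgm_gsea")
}

#' @export
print.cfgm_gsea <- function(x, ...) {
  cat("<cfgm_gsea> set '", x$set_name, "' (", x$n_hits, " genes in list)\n", sep = "")
  cat(sprintf("  ES = %.4f  NES = %.4f  p = %.4g  FDR = %.4g\n",
              x$es, x$nes, x$p_nominal, x$fdr))
  cat("  peak at rank ", x$score$peak_index, "/", length(x$score$running_sum),
      "; leading edge: ", length(x$leading_edge$genes), " genes\n", sep = "")
  verdict <- if (x$es < 0 && x$p_nominal < 0.05) "signature-reversal candidate"
             else if (x$es > 0 && x$p_nominal < 0.05) "disease-like enrichment"
             else "not significant"
  cat("  verdict: ", verdict, "\n", sep = "")
  invisible(x)
}

#' @export
summary.cfgm_gsea <- function(object, ...) {
  data.frame(set = object$set_name, n_hits = object$n_hits, es = object$es,
             nes = object$nes, p_nominal = object$p_nominal, fdr = object$fdr,
             peak_index = object$score$peak_index,
             n_leading_edge = length(object$leading_edge$genes),
             n_perm = object$n_perm, seed = object$seed,
             stringsAsFactors = FALSE)
}

#' Plot the running enrichment sum
#'
#' Draws the running hit-minus-miss sum along the ranked list with tick marks
#' at gene-set member positions and a vertical line at the extremum, the
#' standard enrichment-plot layout.
#'
#' @param x A `cfgm_gsea` object.
#' @param ... Passed to [plot()].
#' @export
plot.cfgm_gsea <- function(x, ...) {
  rs <- x$score$running_sum
  plot(seq_along(rs), rs, type = "l", xlab = "rank in ordered gene list",
       ylab = "running enrichment score",
       main = sprintf("%s: ES = %.3f, p = %.3g", x$set_name, x$es, x$p_nominal),
       ...)
  graphics::abline(h = 0, lty = 2)
  graphics::abline(v = x$score$peak_index, col = "blue")
  graphics::rug(x$score$hit_positions)
  invisible(x)
}
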