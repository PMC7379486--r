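#' Per-gene differential expression scores for a two-class dataset
#'
#' Scores every gene of a two-class dataset by either the log fold change
#' (difference of class means; data assumed already log-scale) or a moderated
#' t statistic with a fixed shrinkage prior:
#' \deqn{t_g = \frac{\bar x_{g,case} - \bar x_{g,control}}
#'               {\tilde s_g \sqrt{1/n_1 + 1/n_2}},\quad
#'       \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}}
#' where \eqn{s_g^2} is the pooled within-class variance on
#' \eqn{d_g = n_1 + n_2 - 2} degrees of freedom, \eqn{s_0^2} is the median of
#' the \eqn{s_g^2} over genes, and the prior weight is fixed at
#' \eqn{d_0 = 4}. The shrinkage keeps the denominator positive even for genes
#' with zero sample variance (such genes trigger a warning).
#'
#' The case class is the second level of `dataset$classes`.
#'
#' @param dataset A two-class [cfgm_dataset()].
#' @param method `"moderated_t"` (default) or `"log_fc"`.
#' @param d0 Prior degrees of freedom of the variance shrinkage (moderated t
#'   only).
#' @return Named numeric vector of scores, one per gene.
#' @examples
#' m <- matrix(c(1, 1, 3, 3, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), paste0("S", 1:4)))
#' d <- cfgm_dataset(m, c("ctl", "ctl", "case", "case"))
#' differential_scores(d, method = "log_fc")  # A: 2, B: 0
#' @export
differential_scores <- function(dataset, method = c("moderated_t", "log_fc"),
                                d0 = 4) {
  stopifnot(inherits(dataset, "cfgm_dataset"))
  method <- match.arg(method)
  cls <- dataset$classes
  if (is.null(cls)) stop("dataset has no class labels; a two-class dataset is required",
                         call. = FALSE)
  ctl <- dataset$expr[, cls == levels(cls)[1L], drop = FALSE]
  cas <- dataset$expr[, cls == levels(cls)[2L], drop = FALSE]
  n1 <- ncol(cas); n2 <- ncol(ctl)
  min_n <- if (method == "moderated_t") 2L else 1L
  if (n1 < min_n || n2 < min_n) {
    stop("method '", method, "' needs >= ", min_n, " samples per class (got ",
         n1, " case, ", n2, " control)", call. = FALSE)
  }
  diff_means <- rowMeans(cas) - rowMeans(ctl)
  if (method == "log_fc") return(diff_means)
  dg <- n1 + n2 - 2L
  ss_case <- rowSums((cas - rowMeans(cas))^2)
  ss_ctl <- rowSums((ctl - rowMeans(ctl))^2)
  s2 <- (ss_case + ss_ctl) / dg
  if (any(s2 == 0)) {
    warning(sum(s2 == 0), " gene(s) with zero within-class variance; ",
            "scored via the shrunken variance", call. = FALSE)
  }
  s0_2 <- stats::median(s2)
  s_tilde2 <- (d0 * s0_2 + dg * s2) / (d0 + dg)
  diff_means / sqrt(s_tilde2 * (1 / n1 + 1 / n2))
}

#' Build a ranked gene list from differential scores
#'
#' Collapses duplicate gene identifiers (keeping the score of maximum absolute
#' value, a deterministic probe-to-gene rule) and sorts genes by score in the
#' requested direction; ties in score are broken lexicographically by gene
#' identifier so the order is reproducible across platforms. The default
#' direction is descending (most up-regulated first); ascending is the exact
#' mirror and is exposed because either convention is found in practice (with
#' the signed enrichment statistic they differ only in the sign of the result).
#'
#' @param scores Named numeric vector (gene -> score), length >= 2 after
#'   collapsing.
#' @param direction `"descending"` (default) or `"ascending"`.
#' @return An object of class `cfgm_ranked_list`: list with `genes`, `scores`
#'   (aligned, sorted), and `direction`.
#' @examples
#' build_ranked_list(c(A = 2, B = -1, C = 0.5))            # A, C, B
#' build_ranked_list(c(A = 2, B = -1, C = 0.5), "ascending")  # B, C, A
#' @export
build_ranked_list <- function(scores, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  if (!is.numeric(scores) || is.null(names(scores))) {
    stop("`scores` must be a named numeric vector", call. = FALSE)
  }
  if (anyNA(scores)) stop("`scores` contains NA/NaN", call. = FALSE)
  genes <- norm_genes(names(scores))
  if (anyDuplicated(genes)) {
    # keep max-|score| representative per gene
    keep <- tapply(seq_along(scores), genes, function(i) i[which.max(abs(scores[i]))])
    idx <- unname(unlist(keep))
    scores <- scores[idx]
    genes <- genes[idx]
  }
  if (length(genes) < 2L) stop("need >= 2 distinct genes to rank", call. = FALSE)
  ord <- order(scores, genes,
               decreasing = c(direction == "descending", FALSE),
               method = "radix")
  structure(list(genes = genes[ord], scores = unname(scores[ord]),
                 direction = direction),
            class = "cfgm_ranked_list")
}

#' @export
print.cfgm_ranked_list <- function(x, ...) {
  n <- length(x$genes)
  cat("<cfgm_ranked_list> ", n, " genes, ", x$direction, "\n", sep = "")
  cat("  head: ", paste(sprintf("%s (%.3g)", utils::head(x$genes, 3L),
                                utils::head(x$scores, 3L)), collapse = ", "), "\n", sep = "")
  cat("  tail: ", paste(sprintf("%s (%.3g)", utils::tail(x$genes, 3L),
                                utils::tail(x$scores, 3L)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Rank a two-class dataset in one step
#'
#' Convenience composition of [differential_scores()] and
#' [build_ranked_list()].
#'
#' @inheritParams differential_scores
#' @inheritParams build_ranked_list
#' @return A `cfgm_ranked_list`.
#' @export
rank_genes <- function(dataset, method = c("moderated_t", "log_fc"),
                       direction = c("descending", "ascending")) {
  build_ranked_list(differential_scores(dataset, method = method),
                    direction = direction)
}
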