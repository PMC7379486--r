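#' @keywords internal
"_PACKAGE"

# Gene identifiers are uppercased everywhere on ingestion so that human/mouse
# symbol casing (Postn vs POSTN) cannot silently split one gene into two.
norm_genes <- function(x) toupper(trimws(as.character(x)))

# Run `expr` under set.seed(seed) without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seeds for multi-stage runs; stays well below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

#' Construct an expression dataset
#'
#' A genes-by-samples expression matrix with optional two-class phenotype
#' labels, the common currency of the package. Gene identifiers are uppercased;
#' duplicated gene or sample identifiers are an error.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns.
#' @param classes Optional factor (or vector coercible to one) of length
#'   `ncol(expr)` with exactly two levels. The *second* level is treated as the
#'   case/treated class throughout; the first as control.
#' @return An object of class `cfgm_dataset`: a list with elements `expr` and
#'   `classes`.
#' @examples
#' m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' d <- cfgm_dataset(m, c("ctl", "ctl", "ctl", "case", "case"))
#' d
#' @export
cfgm_dataset <- function(expr, classes = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`expr` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(expr))) stop("`expr` must have gene rownames", call. = FALSE)
  rownames(expr) <- norm_genes(rownames(expr))
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate gene identifiers in `expr` after case normalization", call. = FALSE)
  }
  if (is.null(colnames(expr))) colnames(expr) <- sprintf("S%04d", seq_len(ncol(expr)))
  if (!is.null(classes)) {
    if (length(classes) != ncol(expr)) {
      stop("`classes` length (", length(classes), ") != number of samples (",
           ncol(expr), ")", call. = FALSE)
    }
    if (!is.factor(classes)) classes <- factor(classes, levels = unique(classes))
    if (nlevels(classes) != 2L) {
      stop("`classes` must have exactly two levels, got ", nlevels(classes), call. = FALSE)
    }
  }
  structure(list(expr = expr, classes = classes), class = "cfgm_dataset")
}

#' @export
print.cfgm_dataset <- function(x, ...) {
  cat("<cfgm_dataset> ", nrow(x$expr), " genes x ", ncol(x$expr), " samples\n", sep = "")
  if (!is.null(x$classes)) {
    tab <- table(x$classes)
    cat("  classes: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        " (case = '", levels(x$classes)[2L], "')\n", sep = "")
  } else {
    cat("  classes: none (compendium-style)\n")
  }
  invisible(x)
}

#' Construct a gene set
#'
#' @param genes Character vector of gene identifiers; uppercased and
#'   deduplicated (first occurrence kept).
#' @param name Set name.
#' @param description Free-text description (GMT second field).
#' @return An object of class `cfgm_gene_set` with elements `name`,
#'   `description`, `genes`.
#' @examples
#' gene_set(c("Postn", "Ddr2", "Pdgfra"), name = "markers")
#' @export
gene_set <- function(genes, name = "set", description = "") {
  genes <- norm_genes(genes)
  genes <- genes[!duplicated(genes) & nzchar(genes)]
  if (length(genes) == 0L) stop("gene set '", name, "' is empty", call. = FALSE)
  structure(list(name = as.character(name)[1L],
                 description = as.character(description)[1L],
                 genes = genes),
            class = "cfgm_gene_set")
}

#' @export
print.cfgm_gene_set <- function(x, ...) {
  cat("<cfgm_gene_set> '", x$name, "' (", length(x$genes), " genes)\n", sep = "")
  shown <- utils::head(x$genes, 8L)
  cat("  ", paste(shown, collapse = ", "),
      if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Accept a cfgm_gene_set or a bare character vector wherever a set is expected.
as_gene_set <- function(x, name = "set") {
  if (inherits(x, "cfgm_gene_set")) return(x)
  if (is.character(x)) return(gene_set(x, name = name))
  stop("expected a gene set or character vector of gene identifiers", call. = FALSE)
}
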