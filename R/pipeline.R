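#' Configuration for the end-to-end screening pipeline
#'
#' Validates and freezes everything a pipeline run needs: the compendium and
#' two-class contrasts (in-memory datasets or GCT/TSV + CLS paths), the marker
#' genes, and the stage parameters. A run without an explicit integer seed is
#' refused — every stochastic stage must be reproducible.
#'
#' @param compendium A [cfgm_dataset()] or a path to a GCT/TSV file.
#' @param contrasts Named list of contrasts; each element is either a labeled
#'   [cfgm_dataset()] or a `list(expr = <gct/tsv path>, cls = <cls path>)`.
#' @param markers Gene set, character vector, or path to a one-symbol-per-line
#'   text file. Default POSTN, DDR2, PDGFRA.
#' @param p_threshold Coexpression p-value cutoff for module membership.
#' @param rank_method `"moderated_t"` or `"log_fc"`.
#' @param direction Ranking direction, `"descending"` (default) or
#'   `"ascending"`.
#' @param weight_p Enrichment weighting exponent, 0 or 1.
#' @param n_perm Enrichment null size.
#' @param n_null Coexpression null size.
#' @param alpha Significance level for the screening verdicts.
#' @param seed Integer seed (required).
#' @param out_dir Output directory for `summary.json` and `pipeline.log`
#'   (`NULL` = no files written).
#' @return A list of class `cfgm_pipeline_config`.
#' @export
pipeline_config <- function(compendium, contrasts, markers = c("POSTN", "DDR2", "PDGFRA"),
                            p_threshold = 0.01, rank_method = "moderated_t",
                            direction = "descending", weight_p = 1,
                            n_perm = 1000L, n_null = 999L, alpha = 0.05,
                            seed = NULL, out_dir = NULL) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed) || seed != round(seed)) {
    stop("pipeline refused: an explicit integer `seed` is required for a run",
         call. = FALSE)
  }
  if (length(contrasts) == 0L || is.null(names(contrasts)) ||
      any(!nzchar(names(contrasts)))) {
    stop("`contrasts` must be a non-empty *named* list", call. = FALSE)
  }
  rank_method <- match.arg(rank_method, c("moderated_t", "log_fc"))
  direction <- match.arg(direction, c("descending", "ascending"))
  if (!weight_p %in% c(0, 1)) stop("`weight_p` must be 0 or 1", call. = FALSE)
  structure(list(compendium = compendium, contrasts = contrasts,
                 markers = markers, p_threshold = p_threshold,
                 rank_method = rank_method, direction = direction,
                 weight_p = weight_p, n_perm = as.integer(n_perm),
                 n_null = as.integer(n_null), alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "cfgm_pipeline_config")
}

resolve_dataset <- function(x, what) {
  if (inherits(x, "cfgm_dataset")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.gct$", x, ignore.case = TRUE)) return(read_gct(x))
    return(read_expr_tsv(x))
  }
  if (is.list(x) && !is.null(x$expr)) {
    if (grepl("\\.gct$", x$expr, ignore.case = TRUE)) {
      return(read_gct(x$expr, cls_path = x$cls))
    }
    return(read_expr_tsv(x$expr, cls_path = x$cls))
  }
  stop("cannot resolve ", what, ": expected a dataset, a file path, or ",
       "list(expr=, cls=)", call. = FALSE)
}

resolve_markers <- function(x) {
  if (inherits(x, "cfgm_gene_set")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(read_markers(x))
  as_gene_set(x, name = "markers")
}

#' Run the module-based drug-screening pipeline
#'
#' Executes the full analysis: (1) build the marker-seeded coexpression module
#' from the compendium; (2) for every contrast, rank genes by differential
#' expression and score the module's enrichment in the ranked list with the
#' running-sum statistic; (3) extract each contrast's leading-edge core genes;
#' (4) test pairwise core-gene overlap (hypergeometric, universe = the
#' module). Each contrast receives a screening verdict: a significantly
#' negative ES marks a *reversal candidate* (the module is suppressed — the
#' drug-screening signal), a significantly positive ES marks *disease-like*
#' enrichment.
#'
#' Stage seeds are derived deterministically from the configured seed, so a
#' rerun with the same configuration is byte-identical. With `out_dir` set,
#' writes `summary.json` (machine-readable) and `pipeline.log`.
#'
#' @param config A [pipeline_config()].
#' @return The summary (list of class `cfgm_pipeline`), invisibly when files
#'   are written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cfgm_pipeline_config"))
  log_lines <- c("cfgm pipeline",
                 sprintf("seed: %d", config$seed),
                 sprintf("p_threshold: %g; rank: %s/%s; weight_p: %g; n_perm: %d; n_null: %d",
                         config$p_threshold, config$rank_method, config$direction,
                         config$weight_p, config$n_perm, config$n_null))
  compendium <- resolve_dataset(config$compendium, "compendium")
  markers <- resolve_markers(config$markers)
  fit <- build_module(compendium, markers, p_threshold = config$p_threshold,
                      n_null = config$n_null, seed = derive_seed(config$seed, 1L))
  module <- fit$module
  log_lines <- c(log_lines,
                 sprintf("module: %d genes (%d markers) at p < %g",
                         length(module$genes), length(markers$genes),
                         config$p_threshold))
  contrast_rows <- list()
  edges <- list()
  for (i in seq_along(config$contrasts)) {
    nm <- names(config$contrasts)[i]
    ds <- resolve_dataset(config$contrasts[[i]], nm)
    ranked <- rank_genes(ds, method = config$rank_method,
                         direction = config$direction)
    res <- suppressWarnings(
      run_gsea(ranked, module, weight_p = config$weight_p,
               n_perm = config$n_perm, seed = derive_seed(config$seed, 10L + i))
    )
    verdict <- if (res$es < 0 && res$p_nominal < config$alpha) "reversal_candidate"
               else if (res$es > 0 && res$p_nominal < config$alpha) "disease_like"
               else "not_significant"
    edges[[nm]] <- res$leading_edge
    contrast_rows[[nm]] <- list(es = res$es, nes = res$nes,
                                p_nominal = res$p_nominal, fdr = res$fdr,
                                n_hits = res$n_hits,
                                n_leading_edge = length(res$leading_edge$genes),
                                verdict = verdict)
    log_lines <- c(log_lines,
                   sprintf("contrast %s: ES = %.4f, p = %.4g -> %s",
                           nm, res$es, res$p_nominal, verdict))
  }
  overlaps <- list()
  nms <- names(edges)
  if (length(nms) >= 2L) {
    for (i in seq_len(length(nms) - 1L)) {
      for (j in (i + 1L):length(nms)) {
        if (length(edges[[i]]$genes) == 0L || length(edges[[j]]$genes) == 0L) next
        ov <- suppressWarnings(compare_core_genes(edges[[i]], edges[[j]], module))
        key <- paste(nms[i], nms[j], sep = "_vs_")
        overlaps[[key]] <- list(k = ov$k, size_a = ov$size_a, size_b = ov$size_b,
                                universe = ov$universe, p_value = ov$p_value)
        log_lines <- c(log_lines,
                       sprintf("overlap %s: k = %d, p = %.4g", key, ov$k, ov$p_value))
      }
    }
  }
  summary <- structure(list(seed = config$seed,
                            module = list(name = module$name,
                                          n_genes = length(module$genes),
                                          genes = module$genes),
                            contrasts = contrast_rows,
                            overlaps = overlaps),
                       class = "cfgm_pipeline")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(summary),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
    return(invisible(summary))
  }
  summary
}

#' @export
print.cfgm_pipeline <- function(x, ...) {
  cat("<cfgm_pipeline> module '", x$module$name, "' (", x$module$n_genes,
      " genes), seed ", x$seed, "\n", sep = "")
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat(sprintf("  %s: ES = %.3f, p = %.3g, leading edge %d -> %s\n",
                nm, ct$es, ct$p_nominal, ct$n_leading_edge, ct$verdict))
  }
  for (nm in names(x$overlaps)) {
    ov <- x$overlaps[[nm]]
    cat(sprintf("  overlap %s: k = %d / universe %d, p = %.3g\n",
                nm, ov$k, ov$universe, ov$p_value))
  }
  invisible(x)
}
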