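# Readers and writers for the Broad-convention text formats: GMT (gene sets),
# RNK (ranked lists), GCT v1.2 (expression matrices), CLS (two-class labels).
# All are strict: malformed input errors with the offending line.

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then one or more gene identifiers, all
#' tab-separated. Genes are uppercased and deduplicated; duplicate set names
#' or lines with fewer than three fields are errors.
#'
#' @param path File path.
#' @return A named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file '", path, "' is empty", call. = FALSE)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("GMT parse error at line ", i, ": expected >= 3 tab-separated fields, got ",
           length(f), call. = FALSE)
    }
    sets[[i]] <- gene_set(f[-(1:2)], name = f[1L], description = f[2L])
    nms[i] <- f[1L]
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name(s) in '", path, "': ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(sets, nms)
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set()] or list of them.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "cfgm_gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else "na", s$genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranked list from an RNK file
#'
#' Two tab-separated columns (gene, score), no header. Duplicate genes are
#' collapsed by maximum absolute score (with a message reporting the count);
#' non-numeric scores are an error naming the line.
#'
#' @param path File path.
#' @param direction Ranking direction to apply, `"descending"` (default) or
#'   `"ascending"`.
#' @return A `cfgm_ranked_list`.
#' @export
read_rnk <- function(path, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("RNK file '", path, "' has < 2 entries", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop("RNK parse error at line ", bad[1L], ": expected 2 tab-separated fields",
         call. = FALSE)
  }
  genes <- vapply(parts, `[[`, character(1), 1L)
  sc_raw <- vapply(parts, `[[`, character(1), 2L)
  scores <- suppressWarnings(as.numeric(sc_raw))
  bad <- which(is.na(scores))
  if (length(bad) > 0L) {
    stop("RNK parse error at line ", bad[1L], ": non-numeric score '",
         sc_raw[bad[1L]], "'", call. = FALSE)
  }
  n_dup <- sum(duplicated(norm_genes(genes)))
  if (n_dup > 0L) {
    message(n_dup, " duplicate gene(s) in '", path, "' collapsed by max |score|")
  }
  build_ranked_list(stats::setNames(scores, genes), direction = direction)
}

#' Write a ranked list to an RNK file
#' @param ranked A `cfgm_ranked_list`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(inherits(ranked, "cfgm_ranked_list"))
  writeLines(sprintf("%s\t%s", ranked$genes,
                     formatC(ranked$scores, format = "g", digits = 15)), path)
  invisible(path)
}

#' Read an expression matrix from a GCT v1.2 file
#'
#' Expects the `#1.2` version line, a dimensions line, then a header row
#' (`Name`, `Description`, sample names) and one row per gene. Dimension
#' mismatches and non-numeric values are errors.
#'
#' @param path File path.
#' @param cls_path Optional CLS file with two-class labels for the samples.
#' @return A [cfgm_dataset()].
#' @export
read_gct <- function(path, cls_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1L]) != "#1.2") {
    stop("GCT parse error in '", path, "': first line must be '#1.2'", call. = FALSE)
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "[\t ]+")[[1]]))
  if (length(dims) != 2L || anyNA(dims)) {
    stop("GCT parse error at line 2: expected '<n_genes>\\t<n_samples>'", call. = FALSE)
  }
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1]]
  if (length(header) != dims[2L] + 2L) {
    stop("GCT dims line declares ", dims[2L], " samples but header row has ",
         length(header) - 2L, call. = FALSE)
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != dims[1L]) {
    stop("GCT dims line declares ", dims[1L], " genes but body has ",
         length(body), " rows", call. = FALSE)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != dims[2L] + 2L)
  if (length(bad) > 0L) {
    stop("GCT parse error at data row ", bad[1L], ": expected ", dims[2L] + 2L,
         " fields", call. = FALSE)
  }
  genes <- vapply(parts, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-(1:2)]), numeric(dims[2L]))
  )
  if (anyNA(vals)) {
    stop("GCT parse error: non-numeric expression value(s) in '", path, "'",
         call. = FALSE)
  }
  x <- t(matrix(vals, nrow = dims[2L], ncol = dims[1L],
                dimnames = list(header[-(1:2)], genes)))
  classes <- if (!is.null(cls_path)) read_cls(cls_path, n_samples = ncol(x)) else NULL
  cfgm_dataset(x, classes = classes)
}

#' Write an expression dataset as GCT v1.2 (plus optional CLS)
#'
#' @param dataset A [cfgm_dataset()].
#' @param path GCT output path.
#' @param cls_path Optional CLS output path for the class labels (requires a
#'   labeled dataset).
#' @return `path`, invisibly.
#' @export
write_gct <- function(dataset, path, cls_path = NULL) {
  stopifnot(inherits(dataset, "cfgm_dataset"))
  x <- dataset$expr
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t"),
               paste(c("Name", "Description", colnames(x)), collapse = "\t")), con)
  writeLines(paste(rownames(x), "na",
                   apply(x, 1L, function(r)
                     paste(formatC(r, format = "g", digits = 15), collapse = "\t")),
                   sep = "\t"), con)
  if (!is.null(cls_path)) {
    if (is.null(dataset$classes)) {
      stop("dataset has no class labels; cannot write CLS", call. = FALSE)
    }
    write_cls(dataset$classes, cls_path)
  }
  invisible(path)
}

#' Read two-class labels from a CLS file
#'
#' Space-delimited Broad dialect: header `<n> 2 1`, a `#`-prefixed class-name
#' line, then a line of `n` labels (0/1 or the class names). Exactly two
#' classes are enforced; label 0 / the first named class is the control level,
#' the second the case level.
#'
#' @param path File path.
#' @param n_samples Optional expected sample count to validate against.
#' @return A two-level factor of length `n`.
#' @export
read_cls <- function(path, n_samples = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("CLS file '", path, "' must have 3 lines", call. = FALSE)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "[\t ]+")[[1]]))
  if (length(hdr) != 3L || anyNA(hdr)) {
    stop("CLS parse error at line 1: expected '<n> <k> 1'", call. = FALSE)
  }
  if (hdr[2L] != 2L) {
    stop("CLS declares ", hdr[2L], " classes; exactly 2 are supported", call. = FALSE)
  }
  name_line <- trimws(sub("^\\s*#", "", lines[2L]))
  cls_names <- strsplit(name_line, "[\t ]+")[[1]]
  if (length(cls_names) != 2L) {
    stop("CLS parse error at line 2: expected 2 class names after '#'", call. = FALSE)
  }
  labels <- strsplit(trimws(lines[3L]), "[\t ]+")[[1]]
  if (length(labels) != hdr[1L]) {
    stop("CLS header declares ", hdr[1L], " samples but label line has ",
         length(labels), call. = FALSE)
  }
  if (!is.null(n_samples) && hdr[1L] != n_samples) {
    stop("CLS label count (", hdr[1L], ") != expression sample count (",
         n_samples, ")", call. = FALSE)
  }
  if (all(labels %in% c("0", "1"))) {
    labels <- cls_names[as.integer(labels) + 1L]
  } else if (!all(labels %in% cls_names)) {
    stop("CLS parse error at line 3: labels must be 0/1 or the declared class names",
         call. = FALSE)
  }
  factor(labels, levels = cls_names)
}

#' Write two-class labels as a CLS file
#' @param classes A two-level factor.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cls <- function(classes, path) {
  classes <- as.factor(classes)
  stopifnot(nlevels(classes) == 2L)
  writeLines(c(paste(length(classes), 2, 1),
               paste("#", paste(levels(classes), collapse = " ")),
               paste(as.integer(classes) - 1L, collapse = " ")), path)
  invisible(path)
}

#' Read an expression matrix from plain TSV
#'
#' Lenient alternative to GCT: a header row (first column = gene identifier
#' column, then sample names) and one numeric row per gene.
#'
#' @param path File path.
#' @param cls_path Optional CLS file.
#' @return A [cfgm_dataset()].
#' @export
read_expr_tsv <- function(path, cls_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("TSV '", path, "' needs a gene column plus >= 1 sample",
                          call. = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(x)) stop("non-numeric expression value(s) in '", path, "'",
                           call. = FALSE)
  rownames(x) <- df[[1L]]
  classes <- if (!is.null(cls_path)) read_cls(cls_path, n_samples = ncol(x)) else NULL
  cfgm_dataset(x, classes = classes)
}

#' Read marker symbols from a plain text file (one per line)
#' @param path File path.
#' @return A [gene_set()] named `markers`.
#' @export
read_markers <- function(path) {
  g <- readLines(path, warn = FALSE)
  g <- g[nzchar(trimws(g))]
  gene_set(g, name = "markers", description = "marker genes")
}
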