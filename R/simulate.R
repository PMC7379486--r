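#' Simulation configuration for planted-module expression data
#'
#' Bundles and validates all parameters of the synthetic-data generator: a
#' single-latent-factor Gaussian compendium in which a planted module of genes
#' (seeded by marker genes) shares a common factor, plus two-class contrasts in
#' which the module is shifted up (disease-like) or down (drug-reversal-like).
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: a 50-gene module planted in 2000 genes, factor loading `beta = 1`
#' with noise `sigma = 0.5` (so the expected module-gene pair correlation is
#' `beta^2 / (beta^2 + sigma^2) = 0.8`), contrast shift `delta = 1.5 * sigma`,
#' and 20 case vs 20 control samples.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of compendium samples.
#' @param module_size Planted module size, markers included.
#' @param n_markers Number of marker genes (first module slots).
#' @param beta Non-negative latent-factor loading of module genes.
#' @param sigma Positive iid noise standard deviation.
#' @param delta Signed per-gene mean shift of effected module genes in the
#'   case/treated class of a contrast.
#' @param n_case,n_control Contrast class sizes.
#' @param effect_fraction Fraction in `[0, 1]` of module genes that carry
#'   `delta` in contrasts.
#' @param seed Integer seed; all generator output is a pure function of the
#'   configuration including the seed.
#' @param marker_names Optional character vector of length `n_markers` naming
#'   the marker slots. Defaults to POSTN, DDR2, PDGFRA when `n_markers == 3`.
#' @return A validated list of class `cfgm_sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 300, n_samples = 40, module_size = 20, seed = 1)
#' @export
sim_config <- function(n_genes = 2000L, n_samples = 150L, module_size = 50L,
                       n_markers = 3L, beta = 1, sigma = 0.5,
                       delta = 0.75, n_case = 20L, n_control = 20L,
                       effect_fraction = 1, seed = 1L, marker_names = NULL) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
      stop("configuration error: `", nm, "` must be a positive integer", call. = FALSE)
    }
    as.integer(x)
  }
  n_genes <- chk_count(n_genes, "n_genes")
  n_samples <- chk_count(n_samples, "n_samples")
  module_size <- chk_count(module_size, "module_size")
  n_markers <- chk_count(n_markers, "n_markers")
  n_case <- chk_count(n_case, "n_case")
  n_control <- chk_count(n_control, "n_control")
  if (n_markers > module_size) {
    stop("configuration error: n_markers (", n_markers,
         ") must be <= module_size (", module_size, ")", call. = FALSE)
  }
  if (module_size > n_genes) {
    stop("configuration error: module_size (", module_size,
         ") must be <= n_genes (", n_genes, ")", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("configuration error: `beta` must be a non-negative real", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("configuration error: `sigma` must be > 0", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta)) {
    stop("configuration error: `delta` must be a real number", call. = FALSE)
  }
  if (!is.numeric(effect_fraction) || length(effect_fraction) != 1L ||
      is.na(effect_fraction) || effect_fraction < 0 || effect_fraction > 1) {
    stop("configuration error: `effect_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    stop("configuration error: `seed` must be a single integer", call. = FALSE)
  }
  if (!is.null(marker_names)) {
    marker_names <- norm_genes(marker_names)
    if (length(marker_names) != n_markers || anyDuplicated(marker_names)) {
      stop("configuration error: `marker_names` must be ", n_markers,
           " distinct symbols", call. = FALSE)
    }
  } else if (n_markers == 3L) {
    marker_names <- c("POSTN", "DDR2", "PDGFRA")
  } else {
    marker_names <- sprintf("MRK%04d", seq_len(n_markers))
  }
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 module_size = module_size, n_markers = n_markers,
                 beta = beta, sigma = sigma, delta = delta,
                 n_case = n_case, n_control = n_control,
                 effect_fraction = effect_fraction, seed = as.integer(seed),
                 marker_names = marker_names),
            class = "cfgm_sim_config")
}

sim_gene_names <- function(config) {
  n_mod_extra <- config$module_size - config$n_markers
  c(config$marker_names,
    if (n_mod_extra > 0L) sprintf("MOD%04d", seq_len(n_mod_extra)),
    sprintf("BG%05d", seq_len(config$n_genes - config$module_size)))
}

#' Simulate a coexpression compendium with a planted module
#'
#' Generates a genes-by-samples matrix in which module genes load on one
#' latent factor per sample: for module gene g and sample s,
#' `x[g, s] = beta * f_s + N(0, sigma)` with `f_s ~ N(0, 1)`; background genes
#' are pure `N(0, sigma)` noise. The first `n_markers` module slots carry the
#' marker symbols. The subset of module genes that will carry the mean shift in
#' contrasts (`effect_fraction` of the module) is drawn here with the seed and
#' recorded in the ground truth.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `dataset` (a [cfgm_dataset()] without class
#'   labels) and `truth` (list of class `cfgm_ground_truth` with character
#'   vectors `module_genes`, `marker_genes`, `effected_genes`).
#' @examples
#' sim <- simulate_compendium(sim_config(n_genes = 200, n_samples = 30,
#'                                       module_size = 10, seed = 7))
#' sim$dataset
#' sim$truth$marker_genes
#' @export
simulate_compendium <- function(config) {
  stopifnot(inherits(config, "cfgm_sim_config"))
  genes <- sim_gene_names(config)
  with_seed(config$seed, {
    f <- rnorm(config$n_samples)
    x <- matrix(rnorm(config$n_genes * config$n_samples, sd = config$sigma),
                nrow = config$n_genes, ncol = config$n_samples,
                dimnames = list(genes, sprintf("CPD%04d", seq_len(config$n_samples))))
    idx_mod <- seq_len(config$module_size)
    x[idx_mod, ] <- x[idx_mod, , drop = FALSE] +
      config$beta * matrix(f, nrow = config$module_size,
                           ncol = config$n_samples, byrow = TRUE)
    n_eff <- round(config$effect_fraction * config$module_size)
    effected <- if (n_eff > 0L) sort(sample(genes[idx_mod], n_eff)) else character()
    truth <- structure(list(module_genes = genes[idx_mod],
                            marker_genes = genes[seq_len(config$n_markers)],
                            effected_genes = effected),
                       class = "cfgm_ground_truth")
    list(dataset = cfgm_dataset(x), truth = truth)
  })
}

#' Simulate a two-class contrast with a shifted module
#'
#' Generates a case/control dataset (`n_case + n_control` samples) of iid
#' `N(0, sigma)` noise in which the effected module genes (recorded in
#' `truth$effected_genes`) have class-mean difference `+delta` (direction
#' `"up"`, disease-like overexpression) or `-delta` (direction `"down"`,
#' drug-like signature reversal) in the case class. All other genes have zero
#' mean difference.
#'
#' @param config A [sim_config()] object.
#' @param truth Ground truth from [simulate_compendium()] (or a compatible
#'   list); `truth$module_genes` must be non-empty and lie inside the
#'   configured gene universe.
#' @param direction `"up"` or `"down"`.
#' @return A [cfgm_dataset()] with a two-level `classes` factor
#'   (`control`, `case`); `case` is the treated/diseased class.
#' @examples
#' cfg <- sim_config(n_genes = 200, n_samples = 30, module_size = 10, seed = 7)
#' sim <- simulate_compendium(cfg)
#' dz <- simulate_contrast(cfg, sim$truth, "up")
#' table(dz$classes)
#' @export
simulate_contrast <- function(config, truth, direction = c("up", "down")) {
  stopifnot(inherits(config, "cfgm_sim_config"))
  direction <- match.arg(direction)
  if (is.null(truth$module_genes) || length(truth$module_genes) == 0L) {
    stop("truth$module_genes is empty", call. = FALSE)
  }
  genes <- sim_gene_names(config)
  missing <- setdiff(norm_genes(truth$module_genes), genes)
  if (length(missing) > 0L) {
    stop("truth genes not in the configured gene universe: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  n <- config$n_case + config$n_control
  shift <- if (direction == "up") config$delta else -config$delta
  with_seed(derive_seed(config$seed, if (direction == "up") 101L else 102L), {
    x <- matrix(rnorm(config$n_genes * n, sd = config$sigma),
                nrow = config$n_genes, ncol = n,
                dimnames = list(genes,
                                c(sprintf("CTRL%03d", seq_len(config$n_control)),
                                  sprintf("CASE%03d", seq_len(config$n_case)))))
    eff <- intersect(genes, norm_genes(truth$effected_genes))
    if (length(eff) > 0L) {
      case_cols <- config$n_control + seq_len(config$n_case)
      x[eff, case_cols] <- x[eff, case_cols, drop = FALSE] + shift
    }
    cfgm_dataset(x, classes = factor(rep(c("control", "case"),
                                         c(config$n_control, config$n_case)),
                                     levels = c("control", "case")))
  })
}
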