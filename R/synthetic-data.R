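# Seeded generator of labelled expression matrices with planted
# class-separating genes, emulating post-normalisation (log2-scale)
# two-class microarray data: small m, large n, Gaussian-like noise.

#' Configuration for the synthetic expression generator
#'
#' @param n_genes total gene count (default 2000).
#' @param n_samples_per_class integer pair `(n_normal, n_cancer)`
#'   (default `c(30, 30)`).
#' @param n_informative number of planted class-separating genes
#'   (default 20), `<= n_genes`.
#' @param effect_size class-1 mean shift of planted genes, in units of
#'   `noise_sd` (default 2).
#' @param noise_sd per-gene noise standard deviation on the log2 scale
#'   (default 1).
#' @param baseline_mean background mean expression, log2 scale
#'   (default 7, a typical normalised microarray intensity).
#' @param noise `"gaussian"` (default) or `"t"` for heavier-tailed
#'   Student-t noise (scaled to `noise_sd`), to stress-test robustness.
#' @param t_df degrees of freedom of the t noise (default 3).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_samples_per_class = c(30L, 30L),
                       n_informative = 20L, effect_size = 2,
                       noise_sd = 1, baseline_mean = 7,
                       noise = c("gaussian", "t"), t_df = 3, seed = 1L) {
  noise <- match.arg(noise)
  n_samples_per_class <- as.integer(n_samples_per_class)
  stopifnot(n_genes >= 1, length(n_samples_per_class) == 2L,
            all(n_samples_per_class >= 1L))
  if (n_informative > n_genes)
    stop("n_informative must be <= n_genes")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (noise == "t" && t_df <= 2) stop("t_df must be > 2 for finite variance")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_class = n_samples_per_class,
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, noise = noise,
                 t_df = t_df, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a labelled expression matrix with planted signal genes
#'
#' Background genes are `Normal(baseline_mean, noise_sd)` in both classes;
#' the first `n_informative` genes additionally receive a mean shift of
#' `effect_size * noise_sd` in class 1 (cancer). Gene ids are
#' `G000001...`; sample ids `N001... / C001...` with labels 0/1. The
#' matrix is flagged log2 scale and is bit-identical for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return List with `matrix` (labelled [expression_matrix()]) and
#'   `informative` (character vector of planted gene ids).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n0 <- cfg$n_samples_per_class[1L]
  n1 <- cfg$n_samples_per_class[2L]
  m <- n0 + n1
  draw <- function(n) {
    if (cfg$noise == "gaussian") stats::rnorm(n, 0, cfg$noise_sd)
    else stats::rt(n, df = cfg$t_df) *
      cfg$noise_sd / sqrt(cfg$t_df / (cfg$t_df - 2))
  }
  values <- with_seed(cfg$seed, {
    v <- matrix(draw(cfg$n_genes * m), cfg$n_genes, m) + cfg$baseline_mean
    if (cfg$n_informative > 0L && n1 > 0L)
      v[seq_len(cfg$n_informative), (n0 + 1L):m] <-
        v[seq_len(cfg$n_informative), (n0 + 1L):m, drop = FALSE] +
        cfg$effect_size * cfg$noise_sd
    v
  })
  ids <- sprintf("G%06d", seq_len(cfg$n_genes))
  samples <- c(sprintf("N%03d", seq_len(n0)), sprintf("C%03d", seq_len(n1)))
  labels <- c(rep(0L, n0), rep(1L, n1))
  mat <- expression_matrix(values, gene_ids = ids, sample_ids = samples,
                           labels = labels, scale = "log2")
  list(matrix = mat,
       informative = ids[seq_len(cfg$n_informative)])
}

#' Fraction of planted genes recovered by a selection
#'
#' @param selected character vector of selected gene ids.
#' @param planted character vector of planted (true) gene ids; non-empty.
#' @return `length(intersect(selected, planted)) / length(planted)`,
#'   in \[0, 1\].
#' @examples
#' recovery_score(c("G1", "G2", "G9"), c("G1", "G2", "G3", "G4", "G5"))
#' @export
recovery_score <- function(selected, planted) {
  if (length(planted) == 0L) stop("planted gene set must be non-empty")
  length(intersect(unique(selected), unique(planted))) / length(unique(planted))
}
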