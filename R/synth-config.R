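#' Configuration for a synthetic regulatory world
#'
#' Defines the study conditions under which every synthetic benchmark in the
#' package is generated: network size and density, the split between shared
#' and single-tissue regulation, the shape and noise level of expression
#' effects, and the error rates of the binding and motif evidence layers.
#'
#' Defaults describe the package's reference low-noise world: 20 TFs
#' regulating 400 genes across 3 tissues with 80 samples per tissue, 5%
#' edge density (about 20 targets per TF), 30% of edges active in exactly
#' one tissue and 30% of edges acting nonlinearly on their target.
#'
#' @param n_tfs number of transcription factors (the first `n_tfs` genes).
#' @param n_genes total number of genes, including the TFs.
#' @param n_tissues number of tissues.
#' @param samples_per_tissue RNA-seq samples simulated per tissue.
#' @param edge_density fraction of possible TF->gene pairs that are true
#'   edges.
#' @param tissue_specific_fraction fraction of true edges active in exactly
#'   one tissue; the remainder are active in all tissues.
#' @param nonlinear_fraction fraction of true edges whose effect on the
#'   target is nonlinear (hill-type saturation or hard threshold).
#' @param noise_sd standard deviation of Gaussian noise added to log2
#'   expression.
#' @param peak_fp_rate per-TF rate of spurious ChIP-seq peaks, expressed per
#'   gene (a TF receives about `peak_fp_rate * n_genes` false peaks).
#' @param peak_fn_rate probability that a true edge fails to produce a peak.
#' @param motif_noise_sd standard deviation of Gaussian noise on motif prior
#'   scores.
#' @param motif_spurious_frac fraction of non-edges given a nonzero motif
#'   prior score per tissue.
#' @param silent_gene_frac fraction of non-TF genes made near-silent so the
#'   low-expression filter has something to remove.
#' @param q_fail_frac fraction of true peaks assigned a q-value above 0.01
#'   so the q filter has something to remove.
#' @param eqtl_rate probability that a tissue-active true edge receives
#'   supporting eQTLs in that tissue.
#' @param coreg_fraction fraction of TFs arranged in co-regulating pairs
#'   with strongly overlapping target sets (gives the PPI layer signal).
#' @param seed integer master seed.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_tfs = 20L, n_genes = 400L, n_tissues = 3L,
                         samples_per_tissue = 80L, edge_density = 0.05,
                         tissue_specific_fraction = 0.3,
                         nonlinear_fraction = 0.3, noise_sd = 0.25,
                         peak_fp_rate = 0.005, peak_fn_rate = 0.05,
                         motif_noise_sd = 0.2, motif_spurious_frac = 0.05,
                         silent_gene_frac = 0.05, q_fail_frac = 0.1,
                         eqtl_rate = 0.5, coreg_fraction = 0.2, seed = 1L) {
  cfg <- list(
    n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
    n_tissues = as.integer(n_tissues),
    samples_per_tissue = as.integer(samples_per_tissue),
    edge_density = edge_density,
    tissue_specific_fraction = tissue_specific_fraction,
    nonlinear_fraction = nonlinear_fraction, noise_sd = noise_sd,
    peak_fp_rate = peak_fp_rate, peak_fn_rate = peak_fn_rate,
    motif_noise_sd = motif_noise_sd,
    motif_spurious_frac = motif_spurious_frac,
    silent_gene_frac = silent_gene_frac, q_fail_frac = q_fail_frac,
    eqtl_rate = eqtl_rate, coreg_fraction = coreg_fraction,
    seed = as.integer(seed)
  )
  counts <- c("n_tfs", "n_genes", "n_tissues", "samples_per_tissue")
  for (f in counts) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 1L)
      config_error(f, " must be a count >= 1")
  }
  if (cfg$n_tfs >= cfg$n_genes)
    config_error("n_tfs must be smaller than n_genes")
  if (!(cfg$edge_density > 0 && cfg$edge_density < 1))
    config_error("edge_density must be in (0, 1)")
  unit <- c("tissue_specific_fraction", "nonlinear_fraction",
            "motif_spurious_frac", "silent_gene_frac", "q_fail_frac",
            "eqtl_rate", "coreg_fraction")
  for (f in unit) {
    if (!(cfg[[f]] >= 0 && cfg[[f]] <= 1))
      config_error(f, " must be in [0, 1]")
  }
  for (f in c("peak_fp_rate", "peak_fn_rate")) {
    if (!(cfg[[f]] >= 0 && cfg[[f]] < 1))
      config_error(f, " must be in [0, 1)")
  }
  for (f in c("noise_sd", "motif_noise_sd")) {
    if (!(cfg[[f]] >= 0)) config_error(f, " must be nonnegative")
  }
  class(cfg) <- "synth_config"
  cfg
}

# canonical ids
gene_ids <- function(config) sprintf("G%04d", seq_len(config$n_genes))
tf_ids <- function(config) gene_ids(config)[seq_len(config$n_tfs)]
tissue_ids <- function(config) sprintf("T%d", seq_len(config$n_tissues))

# layer-specific sub-seeds, split once from the master seed
layer_seed <- function(config, layer) {
  layers <- c("truth", "expression", "binding", "priors", "eqtl", "extra")
  i <- match(layer, layers)
  stopifnot(!is.na(i))
  sub_seeds(config$seed, length(layers))[i]
}
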