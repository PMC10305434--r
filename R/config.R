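#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one place. The configuration is
#' embedded verbatim in model files and evaluation reports, so a run can be
#' reproduced from its outputs.
#'
#' @param k K-mer length of the candidate-pair prefilter.
#' @param min_shared Minimum shared distinct k-mers for a candidate pair.
#' @param identity_threshold Deduplication identity threshold.
#' @param norm_threshold Normalized-score threshold for similarity edges.
#' @param assign_threshold Normalized-score threshold when assigning a novel
#'   gene to a cluster (defaults to `norm_threshold`).
#' @param inflation,expansion,prune_below,mcl_tol,mcl_max_iter Markov
#'   clustering parameters (see [mcl()]).
#' @param min_prevalence Cluster prevalence removal threshold.
#' @param max_presence Variance-threshold presence cutoff.
#' @param min_impurity_split Tree stopping rule (see [train_tree()]).
#' @param decision_threshold Leaf positive-fraction cutoff for prediction.
#' @param balanced Balance class weights during tree training?
#' @param min_aa Minimum ORF length in residues.
#' @param fraction Train proportion of the corpus split.
#' @param top_n Number of most-phage-rich genera retained.
#' @param gap_open,gap_extend Affine gap penalties (BLOSUM62 scoring).
#' @param seed Integer seed for the corpus split (and any other randomness).
#' @return A `phagehost_config` list.
#' @export
phagehost_config <- function(k = 4L, min_shared = 2L,
                             identity_threshold = 0.95,
                             norm_threshold = 0.4,
                             assign_threshold = norm_threshold,
                             inflation = 2, expansion = 2L,
                             prune_below = 1e-5, mcl_tol = 1e-6,
                             mcl_max_iter = 200L,
                             min_prevalence = 0.01, max_presence = 0.99,
                             min_impurity_split = 0.03,
                             decision_threshold = 0.5, balanced = TRUE,
                             min_aa = 30L, fraction = 0.8, top_n = 50L,
                             gap_open = 11L, gap_extend = 1L, seed = 1L) {
  structure(
    list(k = as.integer(k), min_shared = as.integer(min_shared),
         identity_threshold = identity_threshold,
         norm_threshold = norm_threshold,
         assign_threshold = assign_threshold,
         inflation = inflation, expansion = as.integer(expansion),
         prune_below = prune_below, mcl_tol = mcl_tol,
         mcl_max_iter = as.integer(mcl_max_iter),
         min_prevalence = min_prevalence, max_presence = max_presence,
         min_impurity_split = min_impurity_split,
         decision_threshold = decision_threshold, balanced = balanced,
         min_aa = as.integer(min_aa), fraction = fraction,
         top_n = as.integer(top_n), gap_open = as.integer(gap_open),
         gap_extend = as.integer(gap_extend), seed = as.integer(seed)),
    class = "phagehost_config"
  )
}

config_from_list <- function(x) {
  defaults <- phagehost_config()
  known <- intersect(names(x), names(defaults))
  do.call(phagehost_config, x[known])
}
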