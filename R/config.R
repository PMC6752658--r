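#' Analysis configuration
#'
#' Bundles every threshold the pipeline uses, so the constants of the analysis
#' are data rather than code. Defaults encode the standard criteria for this
#' kind of family survey: a gene pair is tandem when the two genes lie within
#' 100 kb of each other with at most 10 non-homologous intervening genes; a
#' gene is expressed when its RPKM reaches 0.3 in at least two stages; a gene
#' is lowly expressed when RPKM stays below 1 in at least two thirds of the
#' stages; a duplicate pair is co-expressed when Pearson r exceeds 0.5.
#'
#' @param max_pair_distance_bp Maximum distance in bp between two family genes
#'   for them to count as a tandem pair. Interpreted according to
#'   `distance_mode`.
#' @param max_intervening Maximum number of non-family genes lying strictly
#'   between the two genes of a tandem pair.
#' @param distance_mode `"gap"` (default) measures the inner gap between gene
#'   spans (0 when they overlap); `"anchor"` measures start-to-start.
#' @param detection_threshold RPKM at or above which a gene is detected in a
#'   stage (values *lower than* this threshold count as not expressed).
#' @param min_expressed_stages Minimum number of detected stages for a gene to
#'   be called expressed.
#' @param low_expr_threshold RPKM below which a stage counts towards the
#'   low-expression call.
#' @param low_expr_fraction Fraction of stages (ceiling applied) that must be
#'   below `low_expr_threshold` for the low-expression flag.
#' @param corr_threshold Correlation above which (strictly) a pair is flagged
#'   as positively correlated.
#' @param min_shared_stages Minimum number of stages in which both genes are
#'   detected for the pair correlation to be defined.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param rng_seed Integer seed recorded into run manifests.
#'
#' @return A list of class `"analysis_config"`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$max_pair_distance_bp
analysis_config <- function(max_pair_distance_bp = 100000L,
                            max_intervening = 10L,
                            distance_mode = c("gap", "anchor"),
                            detection_threshold = 0.3,
                            min_expressed_stages = 2L,
                            low_expr_threshold = 1.0,
                            low_expr_fraction = 2 / 3,
                            corr_threshold = 0.5,
                            min_shared_stages = 3L,
                            cor_method = c("pearson", "spearman"),
                            rng_seed = 1L) {
  distance_mode <- match.arg(distance_mode)
  cor_method <- match.arg(cor_method)
  cfg <- list(
    max_pair_distance_bp = as.integer(max_pair_distance_bp),
    max_intervening = as.integer(max_intervening),
    distance_mode = distance_mode,
    detection_threshold = detection_threshold,
    min_expressed_stages = as.integer(min_expressed_stages),
    low_expr_threshold = low_expr_threshold,
    low_expr_fraction = low_expr_fraction,
    corr_threshold = corr_threshold,
    min_shared_stages = as.integer(min_shared_stages),
    cor_method = cor_method,
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$max_pair_distance_bp > 0, cfg$max_intervening >= 0,
    cfg$detection_threshold > 0, cfg$min_expressed_stages > 0,
    cfg$low_expr_threshold > 0,
    cfg$low_expr_fraction > 0, cfg$low_expr_fraction <= 1,
    cfg$corr_threshold > 0, cfg$min_shared_stages > 0
  )
  structure(cfg, class = "analysis_config")
}

as_analysis_config <- function(x) {
  if (inherits(x, "analysis_config")) return(x)
  if (is.null(x)) return(analysis_config())
  do.call(analysis_config, x)
}
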