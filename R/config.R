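#' Pipeline configuration
#'
#' Collects the tunable parameters of the metabolon pipeline. Defaults follow
#' the values used throughout: gap tolerances of 3 intermediate genes and 2
#' intermediate reactions, retention thresholds of 2 genes / 2 reactions / 2
#' Known associations per metabolon, and association-type weights
#' `alpha_known = 1 = 10 * alpha_potential`, with Inferred associations
#' weighted like Known ones.
#'
#' @param g_gene Number of intermediate genes (gaps) tolerated between two
#'   annotated genes of a metabolon. Non-negative integer.
#' @param g_rxn Number of intermediate reactions tolerated between two
#'   annotated reactions. Non-negative integer.
#' @param min_genes,min_rxns,min_known Minimal number of genes, reactions and
#'   Known gene-reaction associations (gap members count towards the first
#'   two) for a metabolon to be retained.
#' @param alpha_known,alpha_potential,alpha_inferred Category-specific weight
#'   numerators; an association's weight is `alpha / MPL`.
#' @param circular_replicons Should the first and last gene of a replicon
#'   with at least three genes be adjacent (wrap-around edge)?
#' @param rank_score Which score ranks candidate genes by default:
#'   `"r_to_f"` (reaction-to-family, cross-organism) or `"r_to_g"`
#'   (reaction-to-gene, single organism).
#'
#' @return A `pipeline_config` list.
#' @examples
#' pipeline_config()
#' pipeline_config(g_gene = 0, circular_replicons = FALSE)
#' @export
pipeline_config <- function(g_gene = 3L,
                            g_rxn = 2L,
                            min_genes = 2L,
                            min_rxns = 2L,
                            min_known = 2L,
                            alpha_known = 1,
                            alpha_potential = 0.1,
                            alpha_inferred = alpha_known,
                            circular_replicons = TRUE,
                            rank_score = c("r_to_f", "r_to_g")) {
  rank_score <- match.arg(rank_score)
  cfg <- list(
    g_gene = as.integer(g_gene),
    g_rxn = as.integer(g_rxn),
    min_genes = as.integer(min_genes),
    min_rxns = as.integer(min_rxns),
    min_known = as.integer(min_known),
    alpha_known = as.numeric(alpha_known),
    alpha_potential = as.numeric(alpha_potential),
    alpha_inferred = as.numeric(alpha_inferred),
    circular_replicons = isTRUE(circular_replicons),
    rank_score = rank_score
  )
  if (cfg$g_gene < 0L || cfg$g_rxn < 0L) {
    stop("gap parameters `g_gene` and `g_rxn` must be >= 0", call. = FALSE)
  }
  if (cfg$min_genes < 1L || cfg$min_rxns < 1L || cfg$min_known < 1L) {
    stop("retention thresholds must be >= 1", call. = FALSE)
  }
  if (cfg$alpha_known <= 0 || cfg$alpha_potential <= 0 || cfg$alpha_inferred <= 0) {
    stop("alpha weights must be > 0", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  gaps: g_gene = %d, g_rxn = %d\n", x$g_gene, x$g_rxn))
  cat(sprintf("  retention: >= %d genes, >= %d reactions, >= %d Known\n",
              x$min_genes, x$min_rxns, x$min_known))
  cat(sprintf("  alpha: known = %g, potential = %g, inferred = %g\n",
              x$alpha_known, x$alpha_potential, x$alpha_inferred))
  cat(sprintf("  circular replicons: %s; ranking score: %s\n",
              x$circular_replicons, x$rank_score))
  invisible(x)
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.null(config)) return(pipeline_config())
  do.call(pipeline_config, config)
}

alpha_for <- function(category, config) {
  unname(c(Known = config$alpha_known,
           Potential = config$alpha_potential,
           Inferred = config$alpha_inferred)[category])
}
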