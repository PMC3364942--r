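# Minimal Path Length (MPL), alpha/MPL association weights, and gene-level
# association scores.

# one igraph per metabolon: gene and reaction layers plus Known association
# edges; vertex names are prefixed to keep the two id spaces apart
metabolon_ig <- function(mset, id) {
  genes <- mset$genes$gene_id[mset$genes$metabolon_id == id]
  rxns <- mset$reactions$reaction_id[mset$reactions$metabolon_id == id]
  ge <- mset$gene_edges[mset$gene_edges$metabolon_id == id, ]
  re <- mset$reaction_edges[mset$reaction_edges$metabolon_id == id, ]
  known <- mset$associations[mset$associations$metabolon_id == id &
                               mset$associations$category == "Known", ]
  pref <- function(df, pa, a, pb, b) {
    if (!nrow(df)) return(tibble::tibble(from = character(), to = character()))
    tibble::tibble(from = paste0(pa, df[[a]]), to = paste0(pb, df[[b]]))
  }
  edges <- dplyr::bind_rows(
    pref(ge, "G|", "from", "G|", "to"),
    pref(re, "R|", "from", "R|", "to"),
    pref(known, "G|", "gene_id", "R|", "reaction_id")
  )
  ig_build(c(paste0("G|", genes), paste0("R|", rxns)), edges)
}

#' Minimal Path Length of every metabolon association
#'
#' The MPL of a (gene, reaction) association is the length of the shortest
#' path between the two inside the metabolon graph, where gene-gene and
#' reaction-reaction edges may always be traversed but only *Known*
#' gene-reaction edges cross between the layers. For a Known association the
#' path may not use its own edge, so the MPL measures local gene/reaction
#' colinearity rather than trivially returning 1. Paths may pass through gap
#' members. Consequences: a Known association has MPL >= 2 (2 only for
#' multifunctional genes or multi-subunit reactions), a Potential one
#' MPL >= 3. A pair with no such path has undefined MPL (`NA`).
#'
#' @param mset A `metabolon_set` (see [find_metabolons()]).
#' @return The `$associations` tibble with an integer `mpl` column.
#' @export
compute_mpl <- function(mset) {
  stopifnot(inherits(mset, "metabolon_set"))
  assoc <- mset$associations
  if (!nrow(assoc)) return(dplyr::mutate(assoc, mpl = integer()))
  out <- assoc |>
    dplyr::group_split(.data$metabolon_id) |>
    purrr::map(function(block) {
      ig <- metabolon_ig(mset, block$metabolon_id[[1L]])
      block$mpl <- purrr::pmap_int(
        list(block$gene_id, block$reaction_id, block$category),
        function(g, r, own) {
          gv <- paste0("G|", g)
          rv <- paste0("R|", r)
          h <- ig
          if (own == "Known") {
            eid <- igraph::get_edge_ids(h, c(gv, rv))
            if (eid > 0L) h <- igraph::delete_edges(h, eid)
          }
          d <- igraph::distances(h, v = gv, to = rv)[1L, 1L]
          if (is.finite(d)) as.integer(d) else NA_integer_
        })
      block
    })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$metabolon_id, .data$category, .data$gene_id,
                   .data$reaction_id)
}

#' Association weight
#'
#' The weight of a gene-reaction association is `alpha / MPL`, where `alpha`
#' depends on the category (defaults: Known 1, Potential 0.1, Inferred equal
#' to Known). Topologically close pairs are thus favored, and Known evidence
#' outweighs context-generated hypotheses tenfold.
#'
#' @param category Character vector of categories
#'   (`Known`/`Potential`/`Inferred`).
#' @param mpl Positive integer vector of MPL values (`NA` gives `NA`
#'   weight).
#' @param config A [pipeline_config()].
#' @return Numeric weights.
#' @examples
#' association_weight("Known", 2)      # 0.5
#' association_weight("Potential", 4)  # 0.025
#' @export
association_weight <- function(category, mpl, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  bad <- setdiff(unique(category), ASSOC_CATEGORIES)
  if (length(bad)) stop_input("invalid category: %s", paste(bad, collapse = ", "))
  if (any(!is.na(mpl) & mpl < 1)) stop_input("mpl must be >= 1")
  alpha_for(category, config) / as.numeric(mpl)
}

#' Attach MPL and weight to a metabolon set
#'
#' Computes [compute_mpl()] for every association and weights each as
#' `alpha / MPL`. Associations whose MPL is undefined (no admissible path)
#' receive no weight and are dropped with a warning, so that score
#' denominators stay well-defined.
#'
#' @param mset A `metabolon_set`.
#' @param config A [pipeline_config()].
#' @return The `metabolon_set` with `mpl` and `weight` columns on
#'   `$associations`.
#' @export
weight_associations <- function(mset, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  assoc <- compute_mpl(mset)
  undef <- dplyr::filter(assoc, is.na(.data$mpl))
  if (nrow(undef)) {
    warning(sprintf("dropping %d association(s) with undefined MPL: %s",
                    nrow(undef),
                    paste(sprintf("%s(%s,%s)", undef$metabolon_id,
                                  undef$gene_id, undef$reaction_id),
                          collapse = ", ")),
            call. = FALSE)
    assoc <- dplyr::filter(assoc, !is.na(.data$mpl))
  }
  assoc$weight <- association_weight(assoc$category, assoc$mpl, config)
  mset$associations <- assoc
  mset
}

#' Gene-level association scores
#'
#' For each weighted association, the gene-to-reaction score is the weight
#' of (G, R) over the total weight of all associations of gene G in its
#' organism, and the reaction-to-gene score is the weight of (G, R) over the
#' total weight of all associations of reaction R in that organism. Each is
#' a share in (0, 1]: per gene the gene-to-reaction scores sum to 1, per
#' (organism, reaction) the reaction-to-gene scores sum to 1. Only Known and
#' Potential associations enter gene-level scores (they are per-genome
#' descriptors, computed before any cross-organism inference).
#'
#' @param associations Weighted association tibble (needs `organism_id`,
#'   `gene_id`, `reaction_id`, `category`, `weight`).
#' @return The Known/Potential rows with `score_g_to_r` and `score_r_to_g`
#'   columns.
#' @export
score_genes <- function(associations) {
  require_columns(associations, c("organism_id", "gene_id", "reaction_id",
                                  "category", "weight"), "association table")
  associations |>
    dplyr::filter(.data$category %in% c("Known", "Potential")) |>
    dplyr::group_by(.data$organism_id, .data$gene_id) |>
    dplyr::mutate(score_g_to_r = .data$weight / sum(.data$weight)) |>
    dplyr::group_by(.data$organism_id, .data$reaction_id) |>
    dplyr::mutate(score_r_to_g = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$organism_id, .data$gene_id, .data$reaction_id)
}
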