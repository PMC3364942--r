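# Full pipeline: metabolon discovery -> MPL weighting -> gene-level scores
# -> cross-organism integration (non-metabolic filtering, Inferred
# promotion, family scores) -> candidate ranking.

#' Run the full candidate-gene pipeline
#'
#' Chains the four stages of the strategy over every organism of a dataset:
#'
#' 1. locate genomic metabolons in each genome ([find_metabolons()]);
#' 2. weight every Known/Potential association by `alpha / MPL`
#'    ([weight_associations()]) and compute per-genome gene-level scores
#'    ([score_genes()]);
#' 3. integrate across organisms: remove Potential associations of
#'    non-metabolic families ([drop_nonmetabolic()]), promote family-backed
#'    Potentials to Inferred ([promote_inferred()]), and compute
#'    family-level scores ([family_scores()]);
#' 4. rank candidate genes for every (organism, reaction) under both the
#'    reaction-to-family and the reaction-to-gene score
#'    ([rank_candidates()]).
#'
#' @param dataset A [metabolon_dataset()] (e.g. from [simulate_dataset()] or
#'   [read_dataset()]).
#' @param config A [pipeline_config()].
#' @return A `metabolon_run` object; see [tidy.metabolon_run()] for tidy
#'   accessors.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "metabolon_dataset"))
  config <- as_pipeline_config(config)
  dg <- build_data_graph(dataset, config)

  mset <- find_metabolons(dg, config)
  mset <- weight_associations(mset, config)
  gene_scores <- score_genes(mset$associations)

  assoc <- mset$associations
  if (!is.null(dataset$families)) {
    assoc <- drop_nonmetabolic(assoc, dataset$genes, dataset$families)
  }
  assoc <- promote_inferred(assoc, dataset$genes, config)
  # promoted genes/reactions are no longer gaps in their metabolon
  inf <- dplyr::filter(assoc, .data$category == "Inferred")
  if (nrow(inf)) {
    mset$genes$is_gap[paste(mset$genes$metabolon_id, mset$genes$gene_id) %in%
                        paste(inf$metabolon_id, inf$gene_id)] <- FALSE
    mset$reactions$is_gap[
      paste(mset$reactions$metabolon_id, mset$reactions$reaction_id) %in%
        paste(inf$metabolon_id, inf$reaction_id)] <- FALSE
  }
  fam <- family_scores(assoc, dataset$genes)

  rankings <- dplyr::bind_rows(
    rank_candidates(assoc, dataset$genes, fam, gene_scores, "r_to_f"),
    rank_candidates(assoc, dataset$genes, fam, gene_scores, "r_to_g")
  )
  status <- orphan_status_table(dataset$associations, dataset$reactions,
                                sort(unique(dataset$genes$organism_id)))

  structure(list(dataset = dataset, config = config, data_graph = dg,
                 metabolons = mset, associations = assoc,
                 gene_scores = gene_scores, family_scores = fam,
                 rankings = rankings, orphan_status = status),
            class = "metabolon_run")
}

#' @export
print.metabolon_run <- function(x, ...) {
  g <- glance(x)
  cat("<metabolon_run>\n")
  cat(sprintf("  %d organisms, %d metabolons\n", g$n_organisms, g$n_metabolons))
  cat(sprintf("  associations: %d Known, %d Potential, %d Inferred\n",
              g$n_known, g$n_potential, g$n_inferred))
  cat(sprintf("  %d (family, reaction) scores, %d ranked candidates\n",
              g$n_family_scores, g$n_candidates))
  invisible(x)
}

#' Tidy accessors for pipeline runs
#'
#' `tidy()` returns one of the run's result tables as a tibble; `glance()`
#' returns a one-row summary of counts.
#'
#' @param x A `metabolon_run`.
#' @param what Which table: `"associations"` (final, post-integration, with
#'   MPL/weight), `"metabolons"` (member genes and reactions with gap
#'   flags), `"gene_scores"`, `"family_scores"`, `"rankings"`, or
#'   `"orphan_status"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.metabolon_run <- function(x, what = c("associations", "metabolons",
                                           "gene_scores", "family_scores",
                                           "rankings", "orphan_status"), ...) {
  what <- match.arg(what)
  switch(what,
    associations = x$associations,
    metabolons = dplyr::bind_rows(
      dplyr::mutate(dplyr::rename(x$metabolons$genes, member_id = "gene_id"),
                    kind = "gene"),
      dplyr::mutate(dplyr::rename(x$metabolons$reactions, member_id = "reaction_id"),
                    kind = "reaction")
    ) |>
      dplyr::select("metabolon_id", "organism_id", "kind", "member_id", "is_gap") |>
      dplyr::arrange(.data$metabolon_id, .data$kind, .data$member_id),
    gene_scores = x$gene_scores,
    family_scores = x$family_scores,
    rankings = x$rankings,
    orphan_status = x$orphan_status
  )
}

#' @rdname tidy.metabolon_run
#' @export
glance.metabolon_run <- function(x, ...) {
  tab <- table(factor(x$associations$category, levels = ASSOC_CATEGORIES))
  tibble::tibble(
    n_organisms = dplyr::n_distinct(x$dataset$genes$organism_id),
    n_genes = nrow(x$dataset$genes),
    n_reactions = length(x$dataset$reactions),
    n_metabolons = dplyr::n_distinct(x$metabolons$associations$metabolon_id),
    n_known = as.integer(tab[["Known"]]),
    n_potential = as.integer(tab[["Potential"]]),
    n_inferred = as.integer(tab[["Inferred"]]),
    n_family_scores = nrow(x$family_scores),
    n_candidates = nrow(dplyr::filter(x$rankings, .data$score_name == "r_to_f"))
  )
}
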