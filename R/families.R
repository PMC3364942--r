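# Cross-organism integration: gene families, non-metabolic filtering,
# promotion of Potential associations to Inferred, family-level scores and
# candidate ranking.

#' Validate a family table
#'
#' @param families Data frame with `family_id` and optionally
#'   `non_metabolic` (defaults to `FALSE`).
#' @return Validated tibble with one row per family.
#' @export
validate_families <- function(families) {
  require_columns(families, "family_id", "family table")
  families <- tibble::as_tibble(families)
  if (!"non_metabolic" %in% names(families)) families$non_metabolic <- FALSE
  families <- dplyr::mutate(
    families,
    family_id = as.character(.data$family_id),
    non_metabolic = as.logical(.data$non_metabolic) %in% TRUE
  ) |>
    dplyr::distinct(.data$family_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$family_id)
  families
}

#' Single-linkage gene families from similarity edges
#'
#' A deliberately naive clustering convenience for when no curated families
#' are available: genes are grouped into the connected components of the
#' similarity graph thresholded at `threshold` (single linkage; singletons
#' allowed). Families built this way are meant only to tie equivalent genes
#' together across organisms for score integration, not to be accurate
#' ortholog groups.
#'
#' @param similarity_edges Data frame with `gene_a`, `gene_b`, `similarity`
#'   (symmetric scores; a pair listed twice with conflicting scores is
#'   rejected).
#' @param threshold Minimum similarity for an edge to count.
#' @param all_genes Optional vector of gene ids to include as singletons.
#' @return A tibble (`gene_id`, `family_id`); family ids are `fam0001`, ...
#'   ordered by smallest member gene id.
#' @export
naive_families_from_similarity <- function(similarity_edges, threshold,
                                           all_genes = NULL) {
  require_columns(similarity_edges, c("gene_a", "gene_b", "similarity"),
                  "similarity edge table")
  ed <- tibble::as_tibble(similarity_edges) |>
    dplyr::mutate(a = pmin(as.character(.data$gene_a), as.character(.data$gene_b)),
                  b = pmax(as.character(.data$gene_a), as.character(.data$gene_b)))
  conflict <- ed |>
    dplyr::distinct(.data$a, .data$b, .data$similarity) |>
    dplyr::count(.data$a, .data$b) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflict)) {
    stop_input("conflicting duplicate similarity scores for pair(s): %s",
               paste(sprintf("%s-%s", conflict$a, conflict$b), collapse = ", "))
  }
  keep <- dplyr::filter(ed, .data$similarity >= threshold)
  vertices <- unique(c(ed$a, ed$b, as.character(all_genes)))
  ig <- ig_build(vertices, tibble::tibble(from = keep$a, to = keep$b))
  mem <- igraph::components(ig)$membership
  tibble::tibble(gene_id = names(mem), comp = unname(mem)) |>
    dplyr::group_by(.data$comp) |>
    dplyr::mutate(key = min(.data$gene_id)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$key, .data$gene_id) |>
    dplyr::mutate(family_id = sprintf("fam%04d", match(.data$key, unique(.data$key)))) |>
    dplyr::select("gene_id", "family_id")
}

# organism/gene -> family lookup from a gene table
family_lookup <- function(genes) {
  genes |>
    dplyr::filter(!is.na(.data$family_id)) |>
    dplyr::select("organism_id", "gene_id", "family_id")
}

#' Remove Potential associations of non-metabolic families
#'
#' Families established as non-metabolic (transporters, regulators, ...)
#' cannot encode the enzymes we are looking for, so their Potential
#' associations are removed before integration. Known associations are never
#' touched by this rule.
#'
#' @param associations Association tibble (with `organism_id`, `gene_id`,
#'   `category`).
#' @param genes Gene table supplying the gene-to-family map.
#' @param families Family table with `non_metabolic` flags.
#' @return The filtered association tibble.
#' @export
drop_nonmetabolic <- function(associations, genes, families) {
  genes <- validate_genes(genes)
  families <- validate_families(families)
  nm <- families$family_id[families$non_metabolic]
  fl <- family_lookup(genes)
  flagged <- paste(fl$organism_id[fl$family_id %in% nm],
                   fl$gene_id[fl$family_id %in% nm])
  dplyr::filter(associations,
                .data$category != "Potential" |
                  !paste(.data$organism_id, .data$gene_id) %in% flagged)
}

#' Promote Potential associations to Inferred
#'
#' A Potential association (g, r) is promoted to Inferred when another gene
#' of g's family holds a Known association to the same reaction r in any
#' organism: the conserved metabolic context is considered sufficient to
#' transfer the annotation. Promoted associations are reweighted with
#' `alpha_inferred` (their MPL is inherited from the Potential association
#' they arose from). The promoted gene and reaction then cease to be gaps in
#' their metabolon, so every other Potential association involving either of
#' them in that metabolon is removed.
#'
#' Promotions are decided against the pre-promotion Known set only (no
#' chaining within a pass), which makes the operation deterministic and
#' idempotent.
#'
#' @param associations Weighted association tibble (`metabolon_id`,
#'   `organism_id`, `gene_id`, `reaction_id`, `category`, `mpl`, `weight`).
#' @param genes Gene table supplying the gene-to-family map.
#' @param config A [pipeline_config()] (for `alpha_inferred`).
#' @return The updated association tibble.
#' @export
promote_inferred <- function(associations, genes, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  genes <- validate_genes(genes)
  fl <- family_lookup(genes)
  assoc <- dplyr::left_join(associations, fl,
                            by = c("organism_id", "gene_id"))

  known <- dplyr::filter(assoc, .data$category == "Known", !is.na(.data$family_id))
  known_fam_rxn <- unique(paste(known$family_id, known$reaction_id))

  promote <- assoc$category == "Potential" & !is.na(assoc$family_id) &
    paste(assoc$family_id, assoc$reaction_id) %in% known_fam_rxn
  # ... provided the Known copy sits in a *different* gene (it always does:
  # a gap gene has no Known association anywhere, checked at generation)
  assoc$category[promote] <- "Inferred"
  if ("weight" %in% names(assoc)) {
    assoc$weight[promote] <- config$alpha_inferred / assoc$mpl[promote]
  }

  # promoted genes/reactions are no longer gaps in their metabolon: drop the
  # other Potential associations that involved them there
  if (any(promote) && "metabolon_id" %in% names(assoc)) {
    promoted <- assoc[promote, c("metabolon_id", "gene_id", "reaction_id")]
    hit_gene <- paste(assoc$metabolon_id, assoc$gene_id) %in%
      paste(promoted$metabolon_id, promoted$gene_id)
    hit_rxn <- paste(assoc$metabolon_id, assoc$reaction_id) %in%
      paste(promoted$metabolon_id, promoted$reaction_id)
    drop <- assoc$category == "Potential" & (hit_gene | hit_rxn)
    assoc <- assoc[!drop, ]
  }
  dplyr::select(assoc, -"family_id")
}

#' Family-level association scores
#'
#' Summarizes the support for each (family, reaction) pair across all
#' organisms, using Known, Potential and Inferred associations:
#'
#' * `coverage`: fraction of the family's member genes associated with the
#'   reaction, whatever the category;
#' * `score_f_to_r`: fraction of the family's total association weight that
#'   involves the reaction (sums to 1 over reactions, per family);
#' * `score_r_to_f`: fraction of the reaction's total association weight
#'   that involves the family (sums to at most 1 over families, per
#'   reaction; genes without a family contribute to the denominator only,
#'   so equality holds exactly when every associated gene is
#'   family-assigned).
#'
#' @param associations Weighted association tibble (post
#'   [drop_nonmetabolic()] and [promote_inferred()]).
#' @param genes Gene table supplying the gene-to-family map and family
#'   sizes.
#' @return A tibble (`family_id`, `reaction_id`, `family_size`, `coverage`,
#'   `score_f_to_r`, `score_r_to_f`); (family, reaction) pairs with no
#'   association are not emitted.
#' @export
family_scores <- function(associations, genes) {
  require_columns(associations, c("organism_id", "gene_id", "reaction_id",
                                  "category", "weight"), "association table")
  genes <- validate_genes(genes)
  fl <- family_lookup(genes)
  fam_size <- dplyr::count(fl, .data$family_id, name = "family_size")
  assoc <- dplyr::left_join(associations, fl, by = c("organism_id", "gene_id"))

  rxn_total <- assoc |>
    dplyr::group_by(.data$reaction_id) |>
    dplyr::summarise(rxn_weight = sum(.data$weight), .groups = "drop")

  fam_assoc <- dplyr::filter(assoc, !is.na(.data$family_id))
  if (!nrow(fam_assoc)) {
    return(tibble::tibble(family_id = character(), reaction_id = character(),
                          family_size = integer(), coverage = double(),
                          score_f_to_r = double(), score_r_to_f = double()))
  }
  fam_total <- fam_assoc |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(fam_weight = sum(.data$weight), .groups = "drop")

  fam_assoc |>
    dplyr::group_by(.data$family_id, .data$reaction_id) |>
    dplyr::summarise(
      pair_weight = sum(.data$weight),
      n_members = dplyr::n_distinct(paste(.data$organism_id, .data$gene_id)),
      .groups = "drop"
    ) |>
    dplyr::left_join(fam_size, by = "family_id") |>
    dplyr::left_join(fam_total, by = "family_id") |>
    dplyr::left_join(rxn_total, by = "reaction_id") |>
    dplyr::mutate(
      coverage = .data$n_members / .data$family_size,
      score_f_to_r = .data$pair_weight / .data$fam_weight,
      score_r_to_f = .data$pair_weight / .data$rxn_weight
    ) |>
    dplyr::select("family_id", "reaction_id", "family_size", "coverage",
                  "score_f_to_r", "score_r_to_f") |>
    dplyr::arrange(.data$family_id, .data$reaction_id)
}

#' Rank candidate genes for each (organism, reaction)
#'
#' Candidates are the genes holding a Potential or Inferred association to
#' the reaction in the organism. They are sorted descending by the chosen
#' score: the cross-organism reaction-to-family score (default, the score
#' the integration exists for) or the per-organism reaction-to-gene score.
#' When ranking by family score, genes without a family fall back to their
#' gene-level score and are ranked after all family-scored genes. Ties share
#' the minimum (competition) rank: 1, 1, 3.
#'
#' @param associations Post-promotion weighted association tibble.
#' @param genes Gene table (gene-to-family map).
#' @param fam_scores [family_scores()] output.
#' @param gene_scores [score_genes()] output.
#' @param score `"r_to_f"` or `"r_to_g"`.
#' @return A tibble (`organism_id`, `reaction_id`, `gene_id`, `category`,
#'   `score_name`, `score`, `rank`).
#' @export
rank_candidates <- function(associations, genes, fam_scores, gene_scores,
                            score = c("r_to_f", "r_to_g")) {
  score <- match.arg(score)
  genes <- validate_genes(genes)
  fl <- family_lookup(genes)
  cand <- associations |>
    dplyr::filter(.data$category %in% c("Potential", "Inferred")) |>
    dplyr::distinct(.data$organism_id, .data$reaction_id, .data$gene_id,
                    .data$category) |>
    dplyr::left_join(fl, by = c("organism_id", "gene_id")) |>
    dplyr::left_join(
      dplyr::select(gene_scores, "organism_id", "gene_id", "reaction_id",
                    gene_score = "score_r_to_g"),
      by = c("organism_id", "gene_id", "reaction_id")
    )
  if (score == "r_to_f") {
    cand <- cand |>
      dplyr::left_join(
        dplyr::select(fam_scores, "family_id", "reaction_id",
                      fam_score = "score_r_to_f"),
        by = c("family_id", "reaction_id")
      ) |>
      dplyr::mutate(has_family = !is.na(.data$family_id) & !is.na(.data$fam_score),
                    score_value = dplyr::if_else(.data$has_family,
                                                 .data$fam_score, .data$gene_score))
  } else {
    cand <- dplyr::mutate(cand, has_family = TRUE, score_value = .data$gene_score)
  }
  cand |>
    dplyr::group_by(.data$organism_id, .data$reaction_id) |>
    dplyr::arrange(dplyr::desc(.data$has_family), dplyr::desc(.data$score_value),
                   .data$gene_id, .by_group = TRUE) |>
    dplyr::mutate(rank = competition_rank(.data$has_family, .data$score_value)) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$organism_id, .data$reaction_id, .data$gene_id,
                     .data$category, score_name = !!score,
                     score = .data$score_value, rank = .data$rank)
}

# competition ranks (1,1,3) for rows already sorted by (tier desc, score
# desc); equal keys are contiguous after sorting, and fallback-tier rows
# never tie with family-tier rows
competition_rank <- function(tier, value) {
  n <- length(value)
  if (!n) return(integer())
  key <- paste(tier, signif(value, 12))
  new_group <- c(TRUE, key[-1L] != key[-n])
  as.integer(which(new_group)[cumsum(new_group)])
}
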