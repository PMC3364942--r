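# Synthetic corpus generator: prokaryote-like genomes with planted
# operon-like gene clusters coding connected reaction chains, conserved
# gene families across organisms, unannotated spacers and non-metabolic
# decoys. Every stage of the pipeline is testable on these corpora without
# any external data.

#' Simulation parameters
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 5 organisms of 200 genes on one circular replicon each, a global
#' network of 60 reactions arranged in 10 main-compound chains of 6, 6
#' planted clusters per genome conserved across organisms with probability
#' 0.9, a 0.2 per-junction chance of an unannotated spacer gene inside a
#' cluster, and 10% of background genes assigned to flagged non-metabolic
#' decoy families.
#'
#' @param n_organisms Number of genomes.
#' @param genes_per_organism Genes per genome (one replicon).
#' @param n_reactions Total reactions; must be a multiple of
#'   `chain_length`.
#' @param chain_length Reactions per pathway chain.
#' @param n_clusters Planted cluster templates (each uses a distinct
#'   chain).
#' @param cluster_span Range (min, max) of consecutive chain reactions a
#'   cluster codes for.
#' @param conservation Probability that a given organism carries a given
#'   cluster template.
#' @param spacer_rate Probability of one unannotated spacer gene at each
#'   junction between consecutive cluster genes.
#' @param decoy_fraction Fraction of non-cluster genes assigned to a
#'   non-metabolic decoy family.
#' @param family_noise Probability that a cluster gene's family label is
#'   corrupted to a random wrong family.
#' @param circular Are replicons circular?
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_organisms = 5L,
                       genes_per_organism = 200L,
                       n_reactions = 60L,
                       chain_length = 6L,
                       n_clusters = 6L,
                       cluster_span = c(4L, 6L),
                       conservation = 0.9,
                       spacer_rate = 0.2,
                       decoy_fraction = 0.1,
                       family_noise = 0.02,
                       circular = TRUE) {
  p <- list(n_organisms = as.integer(n_organisms),
            genes_per_organism = as.integer(genes_per_organism),
            n_reactions = as.integer(n_reactions),
            chain_length = as.integer(chain_length),
            n_clusters = as.integer(n_clusters),
            cluster_span = as.integer(cluster_span),
            conservation = as.numeric(conservation),
            spacer_rate = as.numeric(spacer_rate),
            decoy_fraction = as.numeric(decoy_fraction),
            family_noise = as.numeric(family_noise),
            circular = isTRUE(circular))
  stopifnot(p$n_organisms >= 1L, p$genes_per_organism >= 1L,
            p$n_reactions >= 1L, p$chain_length >= 2L, p$n_clusters >= 1L,
            length(p$cluster_span) == 2L,
            p$cluster_span[1L] >= 2L,
            p$cluster_span[1L] <= p$cluster_span[2L],
            p$cluster_span[2L] <= p$chain_length)
  probs <- c(p$conservation, p$spacer_rate, p$decoy_fraction, p$family_noise)
  if (any(probs < 0 | probs > 1)) stop_input("probabilities must be in [0, 1]")
  if (p$n_reactions %% p$chain_length != 0L) {
    stop_input("n_reactions must be a multiple of chain_length")
  }
  if (p$n_clusters > p$n_reactions %/% p$chain_length) {
    stop_input("n_clusters exceeds the number of pathway chains")
  }
  structure(p, class = "sim_params")
}

# minimum background genes kept between consecutive planted clusters, so
# that clusters never bleed into each other through the gap tolerance
CLUSTER_SEPARATION <- 4L

#' Simulate a corpus with planted metabolon structure
#'
#' Generates a complete, validated input bundle: a reaction graph of
#' main-compound chains; per-organism circular genomes in which each
#' planted cluster places the genes coding a contiguous window of one chain
#' consecutively (with occasional unannotated spacers); Known associations
#' for every cluster gene; and gene families that tie the coding genes of a
#' reaction together across organisms (one family per reaction), plus
#' flagged non-metabolic decoy families scattered over background genes.
#' Deterministic for a given seed.
#'
#' @param params A [sim_params()].
#' @param seed Integer random seed.
#' @return A [metabolon_dataset()] carrying two extra fields: `$truth`
#'   (planted gene-reaction assignments with their cluster template and
#'   within-cluster position) and `$params`.
#' @export
simulate_dataset <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(as.integer(seed))

  rids <- sprintf("r%03d", seq_len(p$n_reactions))
  n_chains <- p$n_reactions %/% p$chain_length
  chains <- split(rids, rep(seq_len(n_chains), each = p$chain_length))
  links <- purrr::imap(chains, function(ch, i) {
    tibble::tibble(reaction_a = ch[-length(ch)], reaction_b = ch[-1L])
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(main_compound_ids = sprintf("c%03d", dplyr::row_number()))

  # cluster templates: a distinct chain and a contiguous window of it each
  template_chains <- sort(sample(n_chains, p$n_clusters))
  templates <- purrr::map(seq_len(p$n_clusters), function(i) {
    ch <- chains[[template_chains[i]]]
    span <- sample(seq.int(p$cluster_span[1L], p$cluster_span[2L]), 1L)
    start <- sample(seq_len(p$chain_length - span + 1L), 1L)
    list(template_id = sprintf("T%02d", i), reactions = ch[start:(start + span - 1L)])
  })

  orgs <- sprintf("org%02d", seq_len(p$n_organisms))
  decoy_fams <- sprintf("NM%02d", 1:3)
  per_org <- purrr::map(orgs, function(org) {
    simulate_genome(org, templates, p, decoy_fams)
  })

  genes <- dplyr::bind_rows(purrr::map(per_org, "genes"))
  associations <- dplyr::bind_rows(purrr::map(per_org, "associations"))
  truth <- dplyr::bind_rows(purrr::map(per_org, "truth"))

  families <- tibble::tibble(
    family_id = sort(unique(stats::na.omit(genes$family_id))),
  ) |>
    dplyr::mutate(non_metabolic = .data$family_id %in% decoy_fams)

  ds <- metabolon_dataset(genes, links, associations, families = families,
                          reactions = rids)
  ds$truth <- dplyr::arrange(truth, .data$organism_id, .data$template_id,
                             .data$pos_in_template)
  ds$params <- p
  ds
}

simulate_genome <- function(org, templates, p, decoy_fams) {
  present <- which(stats::runif(length(templates)) < p$conservation)
  blocks <- purrr::map(templates[present], function(tpl) {
    rxns <- tpl$reactions
    rows <- tibble::tibble(
      reaction_id = rxns,
      template_id = tpl$template_id,
      pos_in_template = seq_along(rxns),
      spacer = FALSE
    )
    # at most one spacer per junction keeps flanking anchors within the
    # default gene-gap tolerance even after one interior gene is withheld
    out <- rows[1L, ]
    for (i in seq.int(2L, nrow(rows))) {
      if (stats::runif(1L) < p$spacer_rate) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          reaction_id = NA_character_, template_id = tpl$template_id,
          pos_in_template = NA_integer_, spacer = TRUE))
      }
      out <- dplyr::bind_rows(out, rows[i, ])
    }
    out
  })
  n_blocks <- length(blocks)
  n_cluster_genes <- sum(purrr::map_int(blocks, nrow))
  n_background <- p$genes_per_organism - n_cluster_genes
  if (n_blocks > 0L && n_background < CLUSTER_SEPARATION * n_blocks) {
    stop_input(paste0("infeasible packing for %s: %d cluster genes + %d ",
                      "separator genes exceed genome length %d"),
               org, n_cluster_genes, CLUSTER_SEPARATION * n_blocks,
               p$genes_per_organism)
  }

  # random background run lengths (each >= CLUSTER_SEPARATION) between the
  # shuffled blocks, around the (circular) genome
  slots <- if (n_blocks > 0L) {
    extra <- n_background - CLUSTER_SEPARATION * n_blocks
    add <- if (extra > 0L) {
      tabulate(sample.int(n_blocks, extra, replace = TRUE), nbins = n_blocks)
    } else rep(0L, n_blocks)
    CLUSTER_SEPARATION + add
  } else integer()
  blocks <- if (n_blocks > 1L) blocks[sample.int(n_blocks)] else blocks

  rows <- list()
  for (i in seq_len(n_blocks)) {
    rows <- c(rows, list(background_rows(slots[i])), list(blocks[[i]]))
  }
  if (n_blocks == 0L) rows <- list(background_rows(p$genes_per_organism))
  layout <- dplyr::bind_rows(rows)
  stopifnot(nrow(layout) == p$genes_per_organism)

  layout <- layout |>
    dplyr::mutate(
      position = dplyr::row_number() - 1L,
      gene_id = sprintf("%s_g%03d", org, .data$position),
      organism_id = org,
      replicon_id = "chr"
    )

  annotated <- !is.na(layout$reaction_id)
  family <- rep(NA_character_, nrow(layout))
  family[annotated] <- paste0("F_", layout$reaction_id[annotated])
  # label noise: a corrupted cluster gene keeps its Known association but is
  # filed under the wrong family
  noisy <- annotated & stats::runif(nrow(layout)) < p$family_noise
  if (any(noisy)) {
    pool <- paste0("F_", unique(layout$reaction_id[annotated]))
    family[noisy] <- vapply(layout$reaction_id[noisy], function(r) {
      wrong <- setdiff(pool, paste0("F_", r))
      if (length(wrong)) sample(wrong, 1L) else paste0("F_", r)
    }, character(1L))
  }
  background <- !annotated
  decoy <- background & stats::runif(nrow(layout)) < p$decoy_fraction
  family[decoy] <- sample(decoy_fams, sum(decoy), replace = TRUE)

  genes <- tibble::tibble(
    organism_id = layout$organism_id, replicon_id = layout$replicon_id,
    gene_id = layout$gene_id, position = layout$position,
    family_id = family, non_metabolic = FALSE
  )
  associations <- layout |>
    dplyr::filter(annotated) |>
    dplyr::transmute(.data$organism_id, .data$gene_id, .data$reaction_id,
                     category = "Known")
  truth <- layout |>
    dplyr::filter(annotated) |>
    dplyr::select("organism_id", "gene_id", "reaction_id", "template_id",
                  "pos_in_template")
  list(genes = genes, associations = associations, truth = truth)
}

background_rows <- function(n) {
  tibble::tibble(reaction_id = rep(NA_character_, n),
                 template_id = NA_character_,
                 pos_in_template = NA_integer_,
                 spacer = FALSE)
}

#' Withhold associations to create recoverable orphan targets
#'
#' Selects a set of reactions and removes every Known association involving
#' them (in all organisms), recording the removed set as ground truth for
#' end-to-end recovery tests. Selection is constrained so recovery remains
#' possible by construction: only reactions at *interior* positions of a
#' cluster template are eligible, at most every other interior position of
#' a template is taken (no two adjacent), and each template keeps at least
#' two annotated genes. When the requested fraction would violate these
#' constraints the selection is capped with a warning.
#'
#' @param dataset A [simulate_dataset()] result (needs `$truth`).
#' @param fraction Fraction of eligible reactions to withhold, in (0, 1).
#' @param seed Integer seed for the selection.
#' @return The dataset with the withheld rows removed from
#'   `$associations`, plus `$withheld` (the removed associations) and
#'   `$withheld_reactions`.
#' @export
withhold_orphans <- function(dataset, fraction = 0.25, seed = 1L) {
  stopifnot(inherits(dataset, "metabolon_dataset"))
  if (is.null(dataset$truth)) {
    stop_input("dataset has no $truth table; withholding needs a simulated corpus")
  }
  if (!(fraction > 0 && fraction < 1)) stop_input("fraction must be in (0, 1)")
  set.seed(as.integer(seed))

  spans <- dataset$truth |>
    dplyr::distinct(.data$template_id, .data$reaction_id, .data$pos_in_template) |>
    dplyr::group_by(.data$template_id) |>
    dplyr::mutate(span = max(.data$pos_in_template)) |>
    dplyr::ungroup()
  eligible <- spans |>
    dplyr::filter(.data$pos_in_template > 1L,
                  .data$pos_in_template < .data$span,
                  .data$span >= 4L)
  if (!nrow(eligible)) stop_input("no reaction is eligible for withholding")

  target <- max(1L, round(fraction * nrow(eligible)))
  shuffled <- eligible[sample.int(nrow(eligible)), ]
  taken <- shuffled[0, ]
  for (i in seq_len(nrow(shuffled))) {
    if (nrow(taken) >= target) break
    cand <- shuffled[i, ]
    same_tpl <- taken[taken$template_id == cand$template_id, ]
    if (any(abs(same_tpl$pos_in_template - cand$pos_in_template) < 2L)) next
    if (nrow(same_tpl) + 1L > cand$span - 2L) next
    taken <- dplyr::bind_rows(taken, cand)
  }
  if (nrow(taken) < target) {
    warning(sprintf("withholding capped at %d of %d requested reaction(s) to keep >= 2 anchors per cluster",
                    nrow(taken), target), call. = FALSE)
  }
  withheld_rxns <- sort(taken$reaction_id)
  withheld <- dplyr::filter(dataset$associations,
                            .data$reaction_id %in% withheld_rxns)
  dataset$associations <- dplyr::filter(dataset$associations,
                                        !.data$reaction_id %in% withheld_rxns)
  dataset$withheld <- withheld
  dataset$withheld_reactions <- withheld_rxns
  dataset
}
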