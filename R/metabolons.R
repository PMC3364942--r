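# Metabolon discovery: common-connected-component partitioning of the
# two-layer data graph (with g-partial transitive closures supplying gap
# tolerance), gap recovery, retention filtering, and generation of Potential
# gene-reaction associations.

#' Partition Known associations into common connected components
#'
#' Partitions the set of Known gene-reaction associations of each organism
#' into maximal blocks (CCCs) such that, within a block, the genes are
#' connected in the gap-closed gene graph and the reactions are connected in
#' the gap-closed reaction graph. Every gene of a block touches at least one
#' of its reactions and vice versa (they are association endpoints), and
#' each association belongs to exactly one block.
#'
#' The partition is computed by alternating refinement: starting from one
#' block per organism, blocks are repeatedly split by connected components
#' of their gene side, then of their reaction side, until a fixed point. The
#' fixed point is the unique coarsest valid partition, so the split order
#' does not matter (`first_side` exists to exercise that property).
#'
#' @param data_graph A [assemble_data_graph()] result.
#' @param config A [pipeline_config()].
#' @param first_side Which layer is refined first; the result is identical
#'   either way.
#' @return A tibble (`ccc_id`, `organism_id`, `gene_id`, `reaction_id`), one
#'   row per Known association.
#' @export
partition_cccs <- function(data_graph, config = pipeline_config(),
                           first_side = c("gene", "reaction")) {
  stopifnot(inherits(data_graph, "data_graph"))
  config <- as_pipeline_config(config)
  first_side <- match.arg(first_side)

  rg <- data_graph$reaction_graph
  ig_rxn <- ig_closed(ig_build(rg$reactions,
                               tibble::tibble(from = rg$edges$reaction_a,
                                              to = rg$edges$reaction_b)),
                      config$g_rxn)

  organisms <- sort(unique(data_graph$associations$organism_id))
  out <- purrr::map(organisms, function(org) {
    assoc <- dplyr::filter(data_graph$associations, .data$organism_id == org)
    if (!nrow(assoc)) return(NULL)
    ig_gene <- ig_closed(organism_gene_ig(data_graph, org), config$g_gene)
    block <- refine_blocks(assoc, ig_gene, ig_rxn, first_side)
    # deterministic block ids: order blocks by their smallest gene id
    key <- stats::ave(assoc$gene_id, block, FUN = min)
    ord <- order(key, block, method = "radix")
    assoc <- assoc[ord, ]
    block <- block[ord]
    assoc$ccc_id <- sprintf("%s#%03d", org, match(block, unique(block)))
    assoc
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    return(tibble::tibble(ccc_id = character(), organism_id = character(),
                          gene_id = character(), reaction_id = character()))
  }
  dplyr::select(out, "ccc_id", "organism_id", "gene_id", "reaction_id")
}

organism_gene_ig <- function(data_graph, org) {
  gg <- data_graph$gene_graph
  genes <- dplyr::filter(gg$genes, .data$organism_id == org)
  edges <- dplyr::filter(gg$edges, .data$organism_id == org)
  ig_build(genes$gene_id, edges)
}

refine_blocks <- function(assoc, ig_gene_closed, ig_rxn_closed, first_side) {
  block <- rep(1L, nrow(assoc))
  sides <- if (first_side == "gene") c("gene_id", "reaction_id") else
    c("reaction_id", "gene_id")
  repeat {
    before <- block
    for (col in sides) {
      ig <- if (col == "gene_id") ig_gene_closed else ig_rxn_closed
      block <- split_blocks_by_side(assoc[[col]], block, ig)
    }
    if (identical(block, before)) break
  }
  block
}

split_blocks_by_side <- function(ids, block, ig) {
  new <- character(length(block))
  for (b in unique(block)) {
    i <- which(block == b)
    mem <- induced_membership(ig, unique(ids[i]))
    new[i] <- paste0(b, ".", mem[ids[i]])
  }
  # canonical integer labels so the fixed-point test compares partitions
  match(new, unique(new))
}

#' Recover gap genes and gap reactions of one CCC
#'
#' Turns a CCC (a block of Known associations) into a metabolon by
#' recovering the vertices that the transitive closure jumped over: for
#' every pair of member genes at original gene-graph distance between 2 and
#' `g_gene + 1`, the interior vertices of *all* shortest original paths are
#' added as gap genes (and likewise for reactions with `g_rxn`). Gap members
#' carry no Known association inside the metabolon; after recovery both
#' layers are connected using original edges only, which are exported as the
#' metabolon's edge set.
#'
#' @param ccc Tibble of one CCC's associations (`organism_id`, `gene_id`,
#'   `reaction_id`), e.g. one `ccc_id` group from [partition_cccs()].
#' @param data_graph The [assemble_data_graph()] result the CCC came from.
#' @param config A [pipeline_config()].
#' @return A `metabolon` list: `organism_id`, member `genes` and `reactions`
#'   tibbles with `is_gap`, `associations`, and original `gene_edges` /
#'   `reaction_edges` induced on the members.
#' @export
recover_gaps <- function(ccc, data_graph, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  org <- unique(ccc$organism_id)
  stopifnot(length(org) == 1L)
  ig_gene <- organism_gene_ig(data_graph, org)
  rg <- data_graph$reaction_graph
  ig_rxn <- ig_build(rg$reactions,
                     tibble::tibble(from = rg$edges$reaction_a,
                                    to = rg$edges$reaction_b))

  anchor_g <- sort(unique(ccc$gene_id))
  anchor_r <- sort(unique(ccc$reaction_id))
  gap_g <- setdiff(gap_interiors(ig_gene, anchor_g, config$g_gene), anchor_g)
  gap_r <- setdiff(gap_interiors(ig_rxn, anchor_r, config$g_rxn), anchor_r)

  genes <- tibble::tibble(gene_id = c(anchor_g, gap_g),
                          is_gap = rep(c(FALSE, TRUE),
                                       c(length(anchor_g), length(gap_g)))) |>
    dplyr::arrange(.data$gene_id)
  reactions <- tibble::tibble(reaction_id = c(anchor_r, gap_r),
                              is_gap = rep(c(FALSE, TRUE),
                                           c(length(anchor_r), length(gap_r)))) |>
    dplyr::arrange(.data$reaction_id)

  structure(list(
    organism_id = org,
    genes = genes,
    reactions = reactions,
    associations = tibble::tibble(organism_id = org,
                                  gene_id = ccc$gene_id,
                                  reaction_id = ccc$reaction_id,
                                  category = "Known") |>
      dplyr::arrange(.data$gene_id, .data$reaction_id),
    gene_edges = induced_edges(ig_gene, genes$gene_id),
    reaction_edges = induced_edges(ig_rxn, reactions$reaction_id)
  ), class = "metabolon")
}

# interior vertices of all shortest paths between anchor pairs at distance
# 2..g+1 in the original graph
gap_interiors <- function(ig, anchors, g) {
  if (length(anchors) < 2L || g <= 0L) return(character())
  d <- igraph::distances(ig, v = anchors, to = anchors)
  out <- character()
  n <- length(anchors)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (d[i, j] >= 2 && d[i, j] <= g + 1) {
        asp <- igraph::all_shortest_paths(ig, from = anchors[i], to = anchors[j])
        paths <- if (!is.null(asp$vpaths)) asp$vpaths else asp$res
        for (p in paths) {
          nm <- names(p)
          if (length(nm) > 2L) out <- c(out, nm[-c(1L, length(nm))])
        }
      }
    }
  }
  sort(unique(out))
}

induced_edges <- function(ig, members) {
  sub <- igraph::induced_subgraph(ig, members)
  el <- igraph::as_edgelist(sub)
  if (!nrow(el)) return(tibble::tibble(from = character(), to = character()))
  tibble::tibble(from = pmin(el[, 1L], el[, 2L]),
                 to = pmax(el[, 1L], el[, 2L])) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$from, .data$to)
}

#' @export
print.metabolon <- function(x, ...) {
  cat(sprintf("<metabolon> %s: %d genes (%d gaps), %d reactions (%d gaps), %d Known\n",
              x$organism_id, nrow(x$genes), sum(x$genes$is_gap),
              nrow(x$reactions), sum(x$reactions$is_gap),
              nrow(x$associations)))
  invisible(x)
}

# ---- metabolon sets ------------------------------------------------------

new_metabolon_set <- function(genes, reactions, associations, gene_edges,
                              reaction_edges) {
  structure(list(genes = genes, reactions = reactions,
                 associations = associations, gene_edges = gene_edges,
                 reaction_edges = reaction_edges),
            class = "metabolon_set")
}

metabolon_set_from_list <- function(mlist) {
  # deterministic ids: sort by (organism, smallest member gene id)
  key <- purrr::map_chr(mlist, ~ paste(.x$organism_id, min(.x$genes$gene_id)))
  mlist <- mlist[order(key, method = "radix")]
  ids <- sprintf("M%04d", seq_along(mlist))
  pick <- function(field) {
    out <- purrr::map2(mlist, ids, function(m, id) {
      df <- m[[field]]
      if (!nrow(df)) return(NULL)
      tibble::tibble(metabolon_id = id, organism_id = m$organism_id, df)
    }) |> dplyr::bind_rows()
    if (!ncol(out)) NULL else out
  }
  empty <- function(...) tibble::tibble(metabolon_id = character(),
                                        organism_id = character(), ...)
  new_metabolon_set(
    genes = pick("genes") %||% empty(gene_id = character(), is_gap = logical()),
    reactions = pick("reactions") %||% empty(reaction_id = character(), is_gap = logical()),
    associations = {
      a <- purrr::map2(mlist, ids, function(m, id) {
        tibble::tibble(metabolon_id = id, m$associations)
      }) |> dplyr::bind_rows()
      if (is.null(a) || !nrow(a)) {
        tibble::tibble(metabolon_id = character(), organism_id = character(),
                       gene_id = character(), reaction_id = character(),
                       category = character())
      } else {
        dplyr::relocate(a, "metabolon_id", "organism_id")
      }
    },
    gene_edges = pick("gene_edges") %||% empty(from = character(), to = character()),
    reaction_edges = pick("reaction_edges") %||% empty(from = character(), to = character())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metabolon_set <- function(x, ...) {
  n <- dplyr::n_distinct(x$associations$metabolon_id)
  cat(sprintf("<metabolon_set> %d metabolons, %d organisms\n", n,
              dplyr::n_distinct(x$genes$organism_id)))
  cat(sprintf("  %d member genes (%d gaps), %d member reactions (%d gaps)\n",
              nrow(x$genes), sum(x$genes$is_gap),
              nrow(x$reactions), sum(x$reactions$is_gap)))
  tab <- table(x$associations$category)
  cat(sprintf("  associations: %s\n",
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Filter metabolons on retention thresholds
#'
#' A metabolon is retained when it has at least `min_genes` member genes and
#' `min_rxns` member reactions (gap members count) and at least `min_known`
#' Known associations.
#'
#' @param mset A `metabolon_set`.
#' @param config A [pipeline_config()].
#' @return The filtered `metabolon_set`.
#' @export
filter_metabolons <- function(mset, config = pipeline_config()) {
  stopifnot(inherits(mset, "metabolon_set"))
  config <- as_pipeline_config(config)
  counts <- dplyr::full_join(
    dplyr::count(mset$genes, .data$metabolon_id, name = "n_genes"),
    dplyr::count(mset$reactions, .data$metabolon_id, name = "n_rxns"),
    by = "metabolon_id"
  ) |>
    dplyr::full_join(
      dplyr::count(dplyr::filter(mset$associations, .data$category == "Known"),
                   .data$metabolon_id, name = "n_known"),
      by = "metabolon_id"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ tidyr::replace_na(.x, 0L)))
  keep <- counts$metabolon_id[counts$n_genes >= config$min_genes &
                                counts$n_rxns >= config$min_rxns &
                                counts$n_known >= config$min_known]
  subset_metabolon_set(mset, keep)
}

subset_metabolon_set <- function(mset, keep) {
  new_metabolon_set(
    genes = dplyr::filter(mset$genes, .data$metabolon_id %in% keep),
    reactions = dplyr::filter(mset$reactions, .data$metabolon_id %in% keep),
    associations = dplyr::filter(mset$associations, .data$metabolon_id %in% keep),
    gene_edges = dplyr::filter(mset$gene_edges, .data$metabolon_id %in% keep),
    reaction_edges = dplyr::filter(mset$reaction_edges, .data$metabolon_id %in% keep)
  )
}

#' Generate Potential gene-reaction associations
#'
#' Proposes one Potential association per eligible (gap gene, gap reaction)
#' pair inside each metabolon. A gap gene is not a candidate when it is
#' flagged non-metabolic (directly or through its family) or when it already
#' holds a Known association anywhere in its genome (it then belongs to
#' another functional unit); such genes stay in the metabolon as
#' connectivity gaps but receive no proposals. These associations are the
#' method's output hypotheses: they are generated from genomic and metabolic
#' context only, never from sequence similarity, so they exist even for
#' sequence-orphan reactions.
#'
#' @param mset A `metabolon_set`.
#' @param data_graph The originating [assemble_data_graph()] (supplies gene
#'   flags and the global Known set).
#' @param families Optional family table (`family_id`, `non_metabolic`).
#' @return The `metabolon_set` with Potential rows appended to
#'   `$associations`.
#' @export
generate_potential <- function(mset, data_graph, families = NULL) {
  stopifnot(inherits(mset, "metabolon_set"), inherits(data_graph, "data_graph"))
  genes <- data_graph$gene_graph$genes
  nm_families <- if (!is.null(families)) {
    families <- validate_families(families)
    families$family_id[families$non_metabolic]
  } else character()
  ineligible_flag <- genes$non_metabolic |
    (!is.na(genes$family_id) & genes$family_id %in% nm_families)
  flagged <- paste(genes$organism_id[ineligible_flag], genes$gene_id[ineligible_flag])
  known_anywhere <- paste(data_graph$associations$organism_id,
                          data_graph$associations$gene_id)

  gap_genes <- dplyr::filter(mset$genes, .data$is_gap) |>
    dplyr::filter(!paste(.data$organism_id, .data$gene_id) %in% flagged,
                  !paste(.data$organism_id, .data$gene_id) %in% known_anywhere)
  gap_rxns <- dplyr::filter(mset$reactions, .data$is_gap)

  potential <- dplyr::inner_join(
    dplyr::select(gap_genes, "metabolon_id", "organism_id", "gene_id"),
    dplyr::select(gap_rxns, "metabolon_id", "reaction_id"),
    by = "metabolon_id", relationship = "many-to-many"
  ) |>
    dplyr::mutate(category = "Potential") |>
    dplyr::arrange(.data$metabolon_id, .data$gene_id, .data$reaction_id)

  mset$associations <- dplyr::bind_rows(mset$associations, potential) |>
    dplyr::arrange(.data$metabolon_id, .data$category, .data$gene_id,
                   .data$reaction_id)
  mset
}

#' Find genomic metabolons
#'
#' End-to-end metabolon discovery for a data graph: partitions the Known
#' associations into common connected components under the configured gap
#' tolerances ([partition_cccs()]), recovers gap genes and reactions
#' ([recover_gaps()]), applies the retention thresholds
#' ([filter_metabolons()]) and generates Potential associations between gap
#' members ([generate_potential()]).
#'
#' @inheritParams generate_potential
#' @param data_graph A [assemble_data_graph()] result.
#' @param config A [pipeline_config()].
#' @return A `metabolon_set`.
#' @export
find_metabolons <- function(data_graph, config = pipeline_config(),
                            families = NULL) {
  config <- as_pipeline_config(config)
  cccs <- partition_cccs(data_graph, config)
  mlist <- cccs |>
    dplyr::group_split(.data$ccc_id) |>
    purrr::map(recover_gaps, data_graph = data_graph, config = config)
  mset <- metabolon_set_from_list(mlist)
  mset <- filter_metabolons(mset, config)
  generate_potential(mset, data_graph, families)
}
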