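# Core data model: gene tables, gene/reaction graphs, the two-layer data
# graph, and orphan status of reactions.

ASSOC_CATEGORIES <- c("Known", "Potential", "Inferred")

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_input("%s is missing required column(s): %s",
               what, paste(missing, collapse = ", "))
  }
}

#' Validate a gene table
#'
#' Checks the invariants every gene table must satisfy: one row per gene,
#' `gene_id` unique within an organism, and `position` ranks unique and
#' consecutive (0-based) within each replicon. Optional columns `family_id`
#' (NA when the gene has no family) and `non_metabolic` are filled with
#' defaults when absent.
#'
#' @param genes A data frame with columns `organism_id`, `replicon_id`,
#'   `gene_id`, `position`, and optionally `family_id`, `non_metabolic`.
#' @return The validated gene table as a tibble, sorted by organism,
#'   replicon and position.
#' @export
validate_genes <- function(genes) {
  require_columns(genes, c("organism_id", "replicon_id", "gene_id", "position"),
                  "gene table")
  genes <- tibble::as_tibble(genes)
  if (!"family_id" %in% names(genes)) genes$family_id <- NA_character_
  if (!"non_metabolic" %in% names(genes)) genes$non_metabolic <- FALSE
  genes <- dplyr::mutate(
    genes,
    organism_id = as.character(.data$organism_id),
    replicon_id = as.character(.data$replicon_id),
    gene_id = as.character(.data$gene_id),
    position = as.integer(.data$position),
    family_id = dplyr::if_else(is.na(.data$family_id) | .data$family_id == "",
                               NA_character_, as.character(.data$family_id)),
    non_metabolic = as.logical(.data$non_metabolic) %in% TRUE
  )

  dup <- genes |>
    dplyr::count(.data$organism_id, .data$gene_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop_input("duplicate gene_id within organism: %s",
               paste(sprintf("%s/%s", dup$organism_id, dup$gene_id), collapse = ", "))
  }

  bad <- genes |>
    dplyr::group_by(.data$organism_id, .data$replicon_id) |>
    dplyr::summarise(
      ok = anyDuplicated(.data$position) == 0L &&
        identical(sort(.data$position), seq.int(0L, dplyr::n() - 1L)),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    stop_input("positions on replicon(s) %s are not unique consecutive 0-based ranks",
               paste(sprintf("%s/%s", bad$organism_id, bad$replicon_id), collapse = ", "))
  }

  dplyr::arrange(genes, .data$organism_id, .data$replicon_id, .data$position)
}

#' Build the gene adjacency graph
#'
#' Connects immediately consecutive genes of each replicon, ignoring
#' transcription direction and intergenic distance (bidirectionally
#' transcribed operons exist, so strand is deliberately not used). On a
#' circular replicon with at least three genes the last and first gene are
#' also adjacent.
#'
#' @param genes A gene table (see [validate_genes()]).
#' @param circular Add the wrap-around edge on every replicon with >= 3
#'   genes?
#' @return A `gene_graph` object: list with the validated `genes` tibble and
#'   an `edges` tibble (`organism_id`, `replicon_id`, `from`, `to`).
#' @examples
#' g <- tibble::tibble(organism_id = "o1", replicon_id = "c1",
#'                     gene_id = paste0("g", 1:5), position = 0:4)
#' build_gene_graph(g, circular = FALSE)$edges
#' @export
build_gene_graph <- function(genes, circular = TRUE) {
  genes <- validate_genes(genes)
  edges <- genes |>
    dplyr::group_by(.data$organism_id, .data$replicon_id) |>
    dplyr::reframe(replicon_edges(.data$gene_id, circular)) |>
    dplyr::ungroup()
  structure(list(genes = genes, edges = tibble::as_tibble(edges),
                 circular = isTRUE(circular)),
            class = "gene_graph")
}

replicon_edges <- function(ids, circular) {
  n <- length(ids)
  if (n < 2L) return(tibble::tibble(from = character(), to = character()))
  from <- ids[-n]
  to <- ids[-1L]
  if (circular && n >= 3L) {
    from <- c(from, ids[n])
    to <- c(to, ids[1L])
  }
  tibble::tibble(from = from, to = to)
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph> %d genes, %d adjacency edges, %d organism(s)%s\n",
              nrow(x$genes), nrow(x$edges),
              dplyr::n_distinct(x$genes$organism_id),
              if (x$circular) ", circular replicons" else ""))
  invisible(x)
}

#' Build the global reaction graph
#'
#' Two reactions are adjacent when the product of one is a substrate of the
#' other and the shared metabolite is a "main compound" of both reactions in
#' at least one common pathway. Restricting to main compounds avoids the
#' hub-metabolite problem (water, ATP, ...) that makes naive metabolic
#' networks near-complete. The graph is global: pathway- and
#' organism-independent, and isolated reactions are kept as vertices.
#'
#' Supply either a pre-built edge list (`links`: `reaction_a`, `reaction_b`,
#' `main_compound_ids` comma-joined) or a reaction x compound table
#' (`reaction_compounds`: `reaction_id`, `compound_id`, `pathway_id`, `role`
#' in substrate/product, `is_main` 0/1) from which edges are derived.
#'
#' @param links Edge list data frame, or `NULL`.
#' @param reaction_compounds Reaction x compound table, or `NULL`.
#' @param reactions Optional character vector of all reaction ids (needed to
#'   keep isolated reactions and to reject links to unknown reactions).
#' @return A `reaction_graph` object: list with `reactions` (character) and
#'   `edges` tibble (`reaction_a` < `reaction_b`, `main_compound_ids`).
#' @export
build_reaction_graph <- function(links = NULL, reaction_compounds = NULL,
                                 reactions = NULL) {
  if (is.null(links) && is.null(reaction_compounds)) {
    stop_input("supply `links` or `reaction_compounds`")
  }
  if (!is.null(reaction_compounds)) {
    links <- links_from_compounds(reaction_compounds)
    if (is.null(reactions)) {
      reactions <- unique(as.character(reaction_compounds$reaction_id))
    }
  }
  require_columns(links, c("reaction_a", "reaction_b"), "reaction link table")
  links <- tibble::as_tibble(links)
  if (!"main_compound_ids" %in% names(links)) links$main_compound_ids <- ""
  links <- dplyr::mutate(
    links,
    reaction_a = as.character(.data$reaction_a),
    reaction_b = as.character(.data$reaction_b),
    main_compound_ids = as.character(.data$main_compound_ids)
  )
  if (any(links$reaction_a == links$reaction_b)) {
    bad <- unique(links$reaction_a[links$reaction_a == links$reaction_b])
    stop_input("self-links are not allowed (reaction %s)",
               paste(bad, collapse = ", "))
  }
  if (is.null(reactions)) {
    reactions <- unique(c(links$reaction_a, links$reaction_b))
  }
  reactions <- sort(unique(as.character(reactions)))
  unknown <- setdiff(unique(c(links$reaction_a, links$reaction_b)), reactions)
  if (length(unknown)) {
    stop_input("reaction link references unknown reaction(s): %s",
               paste(unknown, collapse = ", "))
  }
  # canonical undirected form: a < b, merged compound sets, no duplicates
  edges <- links |>
    dplyr::mutate(
      a = pmin(.data$reaction_a, .data$reaction_b),
      b = pmax(.data$reaction_a, .data$reaction_b)
    ) |>
    dplyr::group_by(reaction_a = .data$a, reaction_b = .data$b) |>
    dplyr::summarise(
      main_compound_ids = paste(
        sort(unique(unlist(strsplit(.data$main_compound_ids, ",", fixed = TRUE)))),
        collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$reaction_a, .data$reaction_b)
  structure(list(reactions = reactions, edges = edges),
            class = "reaction_graph")
}

links_from_compounds <- function(rc) {
  require_columns(rc, c("reaction_id", "compound_id", "pathway_id", "role", "is_main"),
                  "reaction-compound table")
  rc <- tibble::as_tibble(rc) |>
    dplyr::mutate(
      reaction_id = as.character(.data$reaction_id),
      compound_id = as.character(.data$compound_id),
      pathway_id = as.character(.data$pathway_id),
      role = as.character(.data$role),
      is_main = as.integer(.data$is_main)
    )
  bad_role <- setdiff(unique(rc$role), c("substrate", "product"))
  if (length(bad_role)) {
    stop_input("unknown role(s) in reaction-compound table: %s",
               paste(bad_role, collapse = ", "))
  }
  main <- dplyr::filter(rc, .data$is_main == 1L)
  # a compound links two reactions when, in one shared pathway, it is a main
  # compound of both and the product of one is a substrate of the other
  pairs <- dplyr::inner_join(
    main, main,
    by = c("compound_id", "pathway_id"),
    suffix = c("_x", "_y"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(
      .data$reaction_id_x < .data$reaction_id_y,
      .data$role_x != .data$role_y
    ) |>
    dplyr::distinct(reaction_a = .data$reaction_id_x,
                    reaction_b = .data$reaction_id_y,
                    main_compound_ids = .data$compound_id)
  pairs
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat(sprintf("<reaction_graph> %d reactions, %d main-compound edges\n",
              length(x$reactions), nrow(x$edges)))
  invisible(x)
}

#' Validate an association table
#'
#' @param associations Data frame with `organism_id`, `gene_id`,
#'   `reaction_id` and optionally `category` (defaults to `"Known"`).
#' @param known_only Require every category to be `Known` (true for input
#'   annotation tables)?
#' @return A validated tibble sorted by organism, gene, reaction.
#' @export
validate_associations <- function(associations, known_only = FALSE) {
  require_columns(associations, c("organism_id", "gene_id", "reaction_id"),
                  "association table")
  associations <- tibble::as_tibble(associations)
  if (!"category" %in% names(associations)) associations$category <- "Known"
  associations <- dplyr::mutate(
    associations,
    organism_id = as.character(.data$organism_id),
    gene_id = as.character(.data$gene_id),
    reaction_id = as.character(.data$reaction_id),
    category = as.character(.data$category)
  )
  bad_cat <- setdiff(unique(associations$category),
                     if (known_only) "Known" else ASSOC_CATEGORIES)
  if (length(bad_cat)) {
    stop_input("invalid association category: %s", paste(bad_cat, collapse = ", "))
  }
  dup <- associations |>
    dplyr::count(.data$organism_id, .data$gene_id, .data$reaction_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop_input("duplicate association(s): %s",
               paste(sprintf("%s/%s/%s", dup$organism_id, dup$gene_id,
                             dup$reaction_id), collapse = ", "))
  }
  dplyr::arrange(associations, .data$organism_id, .data$gene_id, .data$reaction_id)
}

#' Assemble the two-layer data graph
#'
#' Combines the per-organism gene adjacency graph, the global reaction graph
#' and the Known gene-reaction annotations into one structure with two vertex
#' kinds (genes, reactions) and three edge kinds (gene-gene,
#' reaction-reaction, gene-reaction). A gene may carry several Known
#' associations (bifunctional enzymes) and a reaction several genes
#' (multi-subunit enzymes).
#'
#' @param gene_graph A [build_gene_graph()] result.
#' @param reaction_graph A [build_reaction_graph()] result.
#' @param associations Known association table (`organism_id`, `gene_id`,
#'   `reaction_id`).
#' @return A `data_graph` object.
#' @export
assemble_data_graph <- function(gene_graph, reaction_graph, associations) {
  stopifnot(inherits(gene_graph, "gene_graph"),
            inherits(reaction_graph, "reaction_graph"))
  associations <- validate_associations(associations, known_only = TRUE)
  key <- paste(associations$organism_id, associations$gene_id)
  known_genes <- paste(gene_graph$genes$organism_id, gene_graph$genes$gene_id)
  dangling_g <- unique(key[!key %in% known_genes])
  if (length(dangling_g)) {
    stop_input("association references unknown gene(s): %s",
               paste(dangling_g, collapse = ", "))
  }
  dangling_r <- setdiff(unique(associations$reaction_id), reaction_graph$reactions)
  if (length(dangling_r)) {
    stop_input("association references unknown reaction(s): %s",
               paste(dangling_r, collapse = ", "))
  }
  structure(list(gene_graph = gene_graph,
                 reaction_graph = reaction_graph,
                 associations = associations),
            class = "data_graph")
}

#' @export
print.data_graph <- function(x, ...) {
  cat(sprintf(paste0("<data_graph> %d genes (%d organisms), %d reactions, ",
                     "%d Known associations\n"),
              nrow(x$gene_graph$genes),
              dplyr::n_distinct(x$gene_graph$genes$organism_id),
              length(x$reaction_graph$reactions),
              nrow(x$associations)))
  invisible(x)
}

#' Orphan status of a reaction in a target organism
#'
#' A reaction is a *global orphan* when it has no Known coding gene in any
#' loaded organism, a *local orphan* when it has none in the target organism
#' but at least one elsewhere, and *assigned* otherwise.
#'
#' @param associations Association table covering all loaded organisms
#'   (only `Known` rows are considered).
#' @param reaction_id Reaction to classify.
#' @param organism_id Target organism.
#' @param reactions Character vector of valid reaction ids (e.g.
#'   `reaction_graph$reactions`); used to reject unknown reactions.
#' @return One of `"assigned"`, `"local_orphan"`, `"global_orphan"`.
#' @export
classify_orphan_status <- function(associations, reaction_id, organism_id,
                                   reactions = NULL) {
  associations <- validate_associations(associations)
  if (!is.null(reactions) && !reaction_id %in% reactions) {
    stop_input("unknown reaction id: %s", reaction_id)
  }
  known <- dplyr::filter(associations, .data$category == "Known",
                         .data$reaction_id == !!reaction_id)
  if (nrow(known) == 0L) return("global_orphan")
  if (any(known$organism_id == organism_id)) return("assigned")
  "local_orphan"
}

#' Orphan status of every reaction in every organism
#'
#' Vectorized companion of [classify_orphan_status()].
#'
#' @param associations Association table (all organisms).
#' @param reactions Character vector of reaction ids to classify.
#' @param organisms Character vector of organism ids; defaults to the
#'   organisms present in `associations`.
#' @return A tibble (`organism_id`, `reaction_id`, `orphan_status`).
#' @export
orphan_status_table <- function(associations, reactions, organisms = NULL) {
  associations <- validate_associations(associations)
  if (is.null(organisms)) organisms <- sort(unique(associations$organism_id))
  known <- dplyr::filter(associations, .data$category == "Known")
  tidyr::expand_grid(organism_id = sort(organisms),
                     reaction_id = sort(unique(as.character(reactions)))) |>
    dplyr::mutate(orphan_status = dplyr::case_when(
      paste(.data$organism_id, .data$reaction_id) %in%
        paste(known$organism_id, known$reaction_id) ~ "assigned",
      .data$reaction_id %in% known$reaction_id ~ "local_orphan",
      TRUE ~ "global_orphan"
    ))
}
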