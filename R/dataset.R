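# Bundled input container: gene table + reaction graph inputs + Known
# associations (+ optional families), the unit the pipeline runs on.

#' Bundle pipeline inputs into a dataset
#'
#' @param genes Gene table (see [validate_genes()]).
#' @param reaction_links Reaction edge list (`reaction_a`, `reaction_b`,
#'   `main_compound_ids`).
#' @param associations Known association table.
#' @param families Optional family table (`family_id`, `non_metabolic`).
#' @param reactions Optional character vector of all reaction ids (defaults
#'   to those appearing in `reaction_links` and `associations`).
#' @return A `metabolon_dataset` list.
#' @export
metabolon_dataset <- function(genes, reaction_links, associations,
                              families = NULL, reactions = NULL) {
  genes <- validate_genes(genes)
  associations <- validate_associations(associations, known_only = TRUE)
  if (is.null(reactions)) {
    reactions <- unique(c(reaction_links$reaction_a, reaction_links$reaction_b,
                          associations$reaction_id))
  }
  reactions <- sort(unique(as.character(reactions)))
  if (!is.null(families)) families <- validate_families(families)
  ds <- structure(list(genes = genes,
                       reaction_links = tibble::as_tibble(reaction_links),
                       reactions = reactions,
                       associations = associations,
                       families = families),
                  class = "metabolon_dataset")
  # fail fast on dangling references
  build_data_graph(ds)
  ds
}

#' Build the data graph of a dataset
#'
#' Convenience wrapper chaining [build_gene_graph()],
#' [build_reaction_graph()] and [assemble_data_graph()] for a bundled
#' dataset, honoring the configuration's replicon-circularity flag.
#'
#' @param dataset A [metabolon_dataset()].
#' @param config A [pipeline_config()].
#' @return A `data_graph` object.
#' @export
build_data_graph <- function(dataset, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  gg <- build_gene_graph(dataset$genes, circular = config$circular_replicons)
  rg <- build_reaction_graph(links = dataset$reaction_links,
                             reactions = dataset$reactions)
  assemble_data_graph(gg, rg, dataset$associations)
}

#' @export
print.metabolon_dataset <- function(x, ...) {
  cat(sprintf("<metabolon_dataset> %d organisms, %d genes, %d reactions, %d Known associations\n",
              dplyr::n_distinct(x$genes$organism_id), nrow(x$genes),
              length(x$reactions), nrow(x$associations)))
  if (!is.null(x$families)) {
    cat(sprintf("  %d families (%d non-metabolic)\n", nrow(x$families),
                sum(x$families$non_metabolic)))
  }
  if (!is.null(x$withheld)) {
    cat(sprintf("  %d associations withheld over %d orphanized reactions\n",
                nrow(x$withheld), dplyr::n_distinct(x$withheld$reaction_id)))
  }
  invisible(x)
}
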