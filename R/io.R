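# Tab-separated readers/writers for the input dialects, result tables,
# GraphML export of metabolon graphs, and the run manifest. All files are
# UTF-8, tab-separated with a header row, "." decimal; scores are printed
# to 4 decimals so diffs are stable.

read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  # readr warns about parsers for absent columns; the missing-column check
  # below reports those properly
  df <- suppressWarnings(readr::read_tsv(path, col_types = col_types,
                                         progress = FALSE))
  missing <- setdiff(names(col_types$cols), names(df))
  if (length(missing)) {
    stop_input("%s is missing required column(s): %s", basename(path),
               paste(missing, collapse = ", "))
  }
  df
}

#' Read input tables
#'
#' `read_genes()`, `read_reaction_links()`, `read_reaction_compounds()`,
#' `read_associations()` and `read_families()` each read one tab-separated
#' input file (header row required) and validate it; `read_dataset()` reads
#' a directory containing `genes.tsv`, `reaction_links.tsv` (or
#' `reaction_compounds.tsv`), `associations.tsv` and optionally
#' `families.tsv`, cross-validates the references (reporting offending row
#' numbers) and returns a [metabolon_dataset()].
#'
#' @param path A file (or, for `read_dataset()`, directory) path.
#' @return A validated tibble, or a `metabolon_dataset` for
#'   `read_dataset()`.
#' @export
read_genes <- function(path) {
  df <- read_tsv_strict(path, readr::cols(
    organism_id = readr::col_character(), replicon_id = readr::col_character(),
    gene_id = readr::col_character(), position = readr::col_integer(),
    family_id = readr::col_character(), non_metabolic = readr::col_integer()))
  validate_genes(df)
}

#' @rdname read_genes
#' @export
read_reaction_links <- function(path) {
  read_tsv_strict(path, readr::cols(
    reaction_a = readr::col_character(), reaction_b = readr::col_character(),
    main_compound_ids = readr::col_character()))
}

#' @rdname read_genes
#' @export
read_reaction_compounds <- function(path) {
  read_tsv_strict(path, readr::cols(
    reaction_id = readr::col_character(), compound_id = readr::col_character(),
    pathway_id = readr::col_character(), role = readr::col_character(),
    is_main = readr::col_integer()))
}

#' @rdname read_genes
#' @export
read_associations <- function(path) {
  df <- read_tsv_strict(path, readr::cols(
    organism_id = readr::col_character(), gene_id = readr::col_character(),
    reaction_id = readr::col_character(), category = readr::col_character()))
  validate_associations(df, known_only = TRUE)
}

#' @rdname read_genes
#' @export
read_families <- function(path) {
  df <- read_tsv_strict(path, readr::cols(
    family_id = readr::col_character(), non_metabolic = readr::col_integer()))
  validate_families(df)
}

#' @rdname read_genes
#' @export
read_dataset <- function(path) {
  if (!dir.exists(path)) stop_input("directory not found: %s", path)
  genes <- read_genes(file.path(path, "genes.tsv"))
  links_path <- file.path(path, "reaction_links.tsv")
  rc_path <- file.path(path, "reaction_compounds.tsv")
  if (file.exists(links_path)) {
    links <- read_reaction_links(links_path)
  } else if (file.exists(rc_path)) {
    links <- links_from_compounds(read_reaction_compounds(rc_path))
  } else {
    stop_input("neither reaction_links.tsv nor reaction_compounds.tsv found in %s",
               path)
  }
  assoc_raw <- readr::read_tsv(file.path(path, "associations.tsv"),
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE)
  bad <- which(!paste(assoc_raw$organism_id, assoc_raw$gene_id) %in%
                 paste(genes$organism_id, genes$gene_id))
  if (length(bad)) {
    stop_input("associations.tsv row(s) %s reference unknown gene(s): %s",
               paste(bad, collapse = ", "),
               paste(unique(assoc_raw$gene_id[bad]), collapse = ", "))
  }
  associations <- read_associations(file.path(path, "associations.tsv"))
  fam_path <- file.path(path, "families.tsv")
  families <- if (file.exists(fam_path)) read_families(fam_path) else NULL
  metabolon_dataset(genes, links, associations, families = families)
}

fmt4 <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))

write_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], fmt4)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a dataset's input tables
#'
#' Writes `genes.tsv`, `reaction_links.tsv`, `associations.tsv` and (when
#' present) `families.tsv` into a directory, in the dialects
#' [read_dataset()] reads back.
#'
#' @param dataset A [metabolon_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "metabolon_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- dataset$genes |>
    dplyr::mutate(family_id = tidyr::replace_na(.data$family_id, ""),
                  non_metabolic = as.integer(.data$non_metabolic))
  readr::write_tsv(genes, file.path(dir, "genes.tsv"), progress = FALSE)
  readr::write_tsv(dataset$reaction_links, file.path(dir, "reaction_links.tsv"),
                   progress = FALSE)
  readr::write_tsv(dataset$associations, file.path(dir, "associations.tsv"),
                   progress = FALSE)
  if (!is.null(dataset$families)) {
    fam <- dplyr::mutate(dataset$families,
                         non_metabolic = as.integer(.data$non_metabolic))
    readr::write_tsv(fam, file.path(dir, "families.tsv"), progress = FALSE)
  }
  invisible(dir)
}

#' Write all result tables of a run
#'
#' Emits `associations_out.tsv` (final associations with MPL, weight and
#' gene-level scores), `family_scores.tsv`, `rankings.tsv` (with orphan
#' status), `metabolons.graphml` (see [write_metabolons_graphml()]),
#' `manifest.json`, and `benchmark.tsv` when a benchmark result is given.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param benchmark Optional [run_benchmark()] result.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(run, dir, benchmark = NULL) {
  stopifnot(inherits(run, "metabolon_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  assoc_out <- run$associations |>
    dplyr::left_join(
      dplyr::select(run$gene_scores, "organism_id", "gene_id", "reaction_id",
                    "score_g_to_r", "score_r_to_g"),
      by = c("organism_id", "gene_id", "reaction_id")
    ) |>
    dplyr::select("organism_id", "gene_id", "reaction_id", "category",
                  "metabolon_id", "mpl", "weight", "score_g_to_r",
                  "score_r_to_g")
  write_table(assoc_out, file.path(dir, "associations_out.tsv"))
  write_table(run$family_scores, file.path(dir, "family_scores.tsv"))

  rankings <- run$rankings |>
    dplyr::left_join(run$orphan_status, by = c("organism_id", "reaction_id")) |>
    dplyr::select("score_name", "organism_id", "reaction_id", "gene_id",
                  "rank", "score", "category", "orphan_status")
  write_table(rankings, file.path(dir, "rankings.tsv"))

  if (!is.null(benchmark)) {
    write_table(benchmark$table, file.path(dir, "benchmark.tsv"))
  }
  write_metabolons_graphml(run, file.path(dir, "metabolons.graphml"))
  write_manifest(run, dir, benchmark = benchmark)
  invisible(dir)
}

#' Export metabolon graphs as GraphML
#'
#' Writes the disjoint union of all metabolon graphs to one GraphML file.
#' Vertices carry `metabolon_id`, `organism_id`, `kind` (gene/reaction),
#' `label` (the gene/reaction id) and `is_gap`; edges carry `kind`
#' (gene/reaction/association) and, for association edges, `category`,
#' `mpl` and `weight`. Only original adjacency edges are exported (closure
#' edges never are), so the drawing reflects real gene/reaction adjacency.
#'
#' @param run A [run_pipeline()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metabolons_graphml <- function(run, path) {
  ig <- metabolon_union_graph(run)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

metabolon_union_graph <- function(run) {
  mset <- run$metabolons
  # NB: paste() recycles zero-length inputs to "", so keys are built only
  # from non-empty tables
  vkey <- function(m, kind, id) {
    if (!length(m)) return(character())
    paste(m, kind, id, sep = "|")
  }
  vertices <- dplyr::bind_rows(
    tibble::tibble(name = vkey(mset$genes$metabolon_id, "gene", mset$genes$gene_id),
                   metabolon_id = mset$genes$metabolon_id,
                   organism_id = mset$genes$organism_id,
                   kind = "gene", label = mset$genes$gene_id,
                   is_gap = mset$genes$is_gap),
    tibble::tibble(name = vkey(mset$reactions$metabolon_id, "reaction",
                               mset$reactions$reaction_id),
                   metabolon_id = mset$reactions$metabolon_id,
                   organism_id = mset$reactions$organism_id,
                   kind = "reaction", label = mset$reactions$reaction_id,
                   is_gap = mset$reactions$is_gap)
  )
  assoc <- run$associations
  edges <- dplyr::bind_rows(
    tibble::tibble(from = vkey(mset$gene_edges$metabolon_id, "gene",
                               mset$gene_edges$from),
                   to = vkey(mset$gene_edges$metabolon_id, "gene",
                             mset$gene_edges$to),
                   kind = "gene", category = "", mpl = NA_real_,
                   weight = NA_real_),
    tibble::tibble(from = vkey(mset$reaction_edges$metabolon_id, "reaction",
                               mset$reaction_edges$from),
                   to = vkey(mset$reaction_edges$metabolon_id, "reaction",
                             mset$reaction_edges$to),
                   kind = "reaction", category = "", mpl = NA_real_,
                   weight = NA_real_),
    tibble::tibble(from = vkey(assoc$metabolon_id, "gene", assoc$gene_id),
                   to = vkey(assoc$metabolon_id, "reaction", assoc$reaction_id),
                   kind = "association", category = assoc$category,
                   mpl = as.numeric(assoc$mpl), weight = assoc$weight)
  )
  igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                vertices = as.data.frame(vertices))
}

write_manifest <- function(run, dir, benchmark = NULL) {
  ds <- run$dataset
  digest_table <- function(df) {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp), add = TRUE)
    readr::write_tsv(df, tmp, progress = FALSE)
    unname(tools::md5sum(tmp))
  }
  g <- glance(run)
  manifest <- list(
    tool = "metabolons",
    version = as.character(utils::packageVersion("metabolons")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(run$config),
    input_digests = list(
      genes = digest_table(ds$genes),
      reaction_links = digest_table(ds$reaction_links),
      associations = digest_table(ds$associations),
      families = if (!is.null(ds$families)) digest_table(ds$families) else NULL
    ),
    counts = as.list(g),
    benchmark = if (!is.null(benchmark)) list(
      eligible_reactions = length(benchmark$eligible_reactions)
    ) else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
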