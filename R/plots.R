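# ggplot2 views of results: precision-recall curves, self-rank curves, and
# a layered drawing of one metabolon.

#' Precision-recall curve of a benchmark
#'
#' One curve per ranking score, points labelled by the rank cutoff k.
#'
#' @param object A [run_benchmark()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.benchmark_result <- function(object, ...) {
  df <- dplyr::mutate(object$table,
                      k_label = ifelse(is.infinite(.data$k), "Inf",
                                       format(.data$k)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   color = .data$score_name)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$k_label),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Recall", y = "Precision", color = "Ranking score",
                  title = "Orphanization benchmark") +
    ggplot2::theme_minimal()
}

#' Cumulative self-rank curve of a benchmark
#'
#' Fraction of all recovered true positives found within each rank.
#'
#' @param benchmark A [run_benchmark()] result.
#' @return A ggplot.
#' @export
plot_self_rank <- function(benchmark) {
  ggplot2::ggplot(benchmark$self_rank,
                  ggplot2::aes(x = .data$rank, y = .data$cum_fraction,
                               color = .data$score_name)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Rank cutoff", y = "Cumulative fraction of true positives",
                  color = "Ranking score") +
    ggplot2::theme_minimal()
}

#' Draw one metabolon
#'
#' Layered drawing: genes along the bottom (in genome order), reactions
#' along the top; adjacency edges within each layer, gene-reaction
#' associations between layers colored by category. Gap members are drawn
#' hollow.
#'
#' @param run A [run_pipeline()] result.
#' @param metabolon_id Which metabolon to draw.
#' @return A ggplot.
#' @export
plot_metabolon <- function(run, metabolon_id) {
  stopifnot(inherits(run, "metabolon_run"))
  mset <- run$metabolons
  genes <- dplyr::filter(mset$genes, .data$metabolon_id == !!metabolon_id)
  rxns <- dplyr::filter(mset$reactions, .data$metabolon_id == !!metabolon_id)
  if (!nrow(genes)) stop_input("no metabolon with id %s", metabolon_id)
  pos <- run$dataset$genes |>
    dplyr::filter(.data$organism_id == genes$organism_id[[1L]]) |>
    dplyr::select("gene_id", "position")
  genes <- genes |>
    dplyr::left_join(pos, by = "gene_id") |>
    dplyr::arrange(.data$position) |>
    dplyr::mutate(x = dplyr::row_number(), y = 0, label = .data$gene_id,
                  kind = "gene")
  rxns <- rxns |>
    dplyr::arrange(.data$reaction_id) |>
    dplyr::mutate(x = seq(1, max(2, nrow(genes)), length.out = dplyr::n()),
                  y = 1, label = .data$reaction_id, kind = "reaction")
  nodes <- dplyr::bind_rows(
    dplyr::select(genes, "x", "y", "label", "kind", "is_gap"),
    dplyr::select(rxns, "x", "y", "label", "kind", "is_gap")
  )
  coords <- stats::setNames(seq_len(nrow(nodes)), paste(nodes$kind, nodes$label))
  seg <- function(edges, kind) {
    if (!nrow(edges)) return(NULL)
    tibble::tibble(
      x = nodes$x[coords[paste(kind, edges$from)]],
      y = nodes$y[coords[paste(kind, edges$from)]],
      xend = nodes$x[coords[paste(kind, edges$to)]],
      yend = nodes$y[coords[paste(kind, edges$to)]],
      category = "adjacency"
    )
  }
  ge <- dplyr::filter(mset$gene_edges, .data$metabolon_id == !!metabolon_id)
  re <- dplyr::filter(mset$reaction_edges, .data$metabolon_id == !!metabolon_id)
  assoc <- dplyr::filter(run$associations, .data$metabolon_id == !!metabolon_id)
  ae <- if (nrow(assoc)) tibble::tibble(
    x = nodes$x[coords[paste("gene", assoc$gene_id)]],
    y = nodes$y[coords[paste("gene", assoc$gene_id)]],
    xend = nodes$x[coords[paste("reaction", assoc$reaction_id)]],
    yend = nodes$y[coords[paste("reaction", assoc$reaction_id)]],
    category = assoc$category
  ) else NULL
  edges <- dplyr::bind_rows(seg(ge, "gene"), seg(re, "reaction"), ae)

  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, color = .data$category,
                   linetype = .data$category)) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$kind,
                   fill = .data$is_gap), size = 4) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y + ifelse(.data$y > 0, 0.12, -0.12),
                   label = .data$label), size = 3) +
    ggplot2::scale_shape_manual(values = c(gene = 22, reaction = 21)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "white", `FALSE` = "grey40"),
                               labels = c(`TRUE` = "gap", `FALSE` = "member"),
                               name = NULL) +
    ggplot2::scale_color_manual(values = c(adjacency = "grey60",
                                           Known = "forestgreen",
                                           Potential = "violetred",
                                           Inferred = "royalblue")) +
    ggplot2::scale_linetype_manual(values = c(adjacency = "solid",
                                              Known = "solid",
                                              Potential = "dashed",
                                              Inferred = "solid")) +
    ggplot2::labs(title = paste("Metabolon", metabolon_id),
                  color = NULL, linetype = NULL) +
    ggplot2::theme_void()
}
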