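# Systematic orphanization benchmark: every reaction with Known metabolon
# evidence is in turn stripped of all its annotations in all organisms, the
# pipeline is rerun, and recovery of the genuine gene-reaction associations
# is measured by rank under each score.

#' Remove all Known associations of a reaction
#'
#' Renders a reaction a sequence-orphan: every Known association involving
#' it, in every organism, is deleted from the dataset. Downstream results
#' must be recomputed in full.
#'
#' @param dataset A [metabolon_dataset()].
#' @param reaction_id Reaction to orphanize.
#' @return The modified dataset.
#' @export
orphanize_reaction <- function(dataset, reaction_id) {
  stopifnot(inherits(dataset, "metabolon_dataset"))
  dataset$associations <- dplyr::filter(dataset$associations,
                                        .data$reaction_id != !!reaction_id)
  dataset
}

# reactions eligible for the benchmark: >= 1 Known association inside a
# metabolon of the reference run
eligible_reactions <- function(reference_run) {
  known <- dplyr::filter(reference_run$metabolons$associations,
                         .data$category == "Known")
  sort(unique(known$reaction_id))
}

#' Recovery counts for one orphanized reaction
#'
#' Compares the candidates proposed for an orphanized reaction against the
#' genuine (removed) associations. A genuine (organism, gene, reaction)
#' association counts as a true positive when it reappears among the
#' proposals with rank at most `k` under the chosen score, and as a false
#' negative otherwise; every proposal with rank at most `k` that does not
#' match a genuine association is a false positive. `k = Inf` declares every
#' recovered association a positive hit.
#'
#' @param reference_run The [run_pipeline()] result on the intact dataset.
#' @param orphanized_run The [run_pipeline()] result after
#'   [orphanize_reaction()].
#' @param reaction_id The orphanized reaction.
#' @param k Rank cutoff (positive integer or `Inf`).
#' @param score `"r_to_f"` or `"r_to_g"`.
#' @return A one-row tibble (`reaction_id`, `score_name`, `k`, `tp`, `fp`,
#'   `fn`).
#' @export
score_recovery <- function(reference_run, orphanized_run, reaction_id,
                           k = Inf, score = c("r_to_f", "r_to_g")) {
  score <- match.arg(score)
  genuine <- reference_run$dataset$associations |>
    dplyr::filter(.data$reaction_id == !!reaction_id)
  proposals <- recovered_proposals(orphanized_run, reaction_id, score)
  tally_recovery(genuine, proposals, reaction_id, k, score)
}

recovered_proposals <- function(orphanized_run, reaction_id, score) {
  orphanized_run$rankings |>
    dplyr::filter(.data$score_name == !!score,
                  .data$reaction_id == !!reaction_id)
}

tally_recovery <- function(genuine, proposals, reaction_id, k, score) {
  genuine_key <- paste(genuine$organism_id, genuine$gene_id)
  prop_key <- paste(proposals$organism_id, proposals$gene_id)
  within_k <- proposals$rank <= k
  tp <- sum(within_k & prop_key %in% genuine_key)
  fp <- sum(within_k & !prop_key %in% genuine_key)
  tibble::tibble(reaction_id = reaction_id, score_name = score, k = k,
                 tp = tp, fp = fp, fn = length(genuine_key) - tp)
}

#' Run the orphanization benchmark
#'
#' For every reaction having at least one Known association inside a
#' metabolon of the reference run, removes all its associations in all
#' organisms, recomputes metabolons and scores from scratch, and records the
#' rank at which each genuine association is recovered. Results are pooled
#' across all eligible reactions into a precision-recall table per (score,
#' k) and a cumulative "self-rank" view (fraction of all true positives
#' found within each rank).
#'
#' @param dataset A [metabolon_dataset()].
#' @param config A [pipeline_config()].
#' @param k_grid Rank cutoffs (use `Inf` for the unbounded cutoff).
#' @param scores Which ranking scores to benchmark.
#' @return A `benchmark_result` object with `$table` (`score_name`, `k`,
#'   `tp`, `fp`, `fn`, `recall`, `precision`), `$self_rank`, and
#'   `$eligible_reactions`. `$table` is also what [tidy.benchmark_result()]
#'   returns.
#' @export
run_benchmark <- function(dataset, config = pipeline_config(),
                          k_grid = c(1, 2, 3, Inf),
                          scores = c("r_to_f", "r_to_g")) {
  stopifnot(inherits(dataset, "metabolon_dataset"))
  config <- as_pipeline_config(config)
  scores <- match.arg(scores, several.ok = TRUE)
  reference_run <- run_pipeline(dataset, config)
  eligible <- eligible_reactions(reference_run)
  if (!length(eligible)) {
    warning("no reaction has Known metabolon evidence; empty benchmark",
            call. = FALSE)
    return(structure(list(
      table = tibble::tibble(score_name = character(), k = double(),
                             tp = integer(), fp = integer(), fn = integer(),
                             recall = double(), precision = double()),
      self_rank = tibble::tibble(score_name = character(), rank = integer(),
                                 cum_tp = integer(), cum_fraction = double()),
      eligible_reactions = character(), k_grid = k_grid
    ), class = "benchmark_result"))
  }

  per_reaction <- purrr::map(eligible, function(r) {
    run_r <- run_pipeline(orphanize_reaction(dataset, r), config)
    genuine <- dplyr::filter(dataset$associations, .data$reaction_id == r)
    rows <- purrr::map(scores, function(s) {
      proposals <- recovered_proposals(run_r, r, s)
      counts <- purrr::map(k_grid, ~ tally_recovery(genuine, proposals, r, .x, s)) |>
        dplyr::bind_rows()
      hit <- proposals[paste(proposals$organism_id, proposals$gene_id) %in%
                         paste(genuine$organism_id, genuine$gene_id), ]
      list(counts = counts,
           tp_ranks = tibble::tibble(score_name = s, rank = hit$rank))
    })
    list(counts = dplyr::bind_rows(purrr::map(rows, "counts")),
         tp_ranks = dplyr::bind_rows(purrr::map(rows, "tp_ranks")))
  })

  table <- dplyr::bind_rows(purrr::map(per_reaction, "counts")) |>
    dplyr::group_by(.data$score_name, .data$k) |>
    dplyr::summarise(tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
                     .groups = "drop") |>
    dplyr::mutate(recall = .data$tp / (.data$tp + .data$fn),
                  precision = ifelse(.data$tp + .data$fp > 0,
                                     .data$tp / (.data$tp + .data$fp), NA_real_)) |>
    dplyr::arrange(.data$score_name, .data$k)

  n_genuine <- dplyr::distinct(table, .data$score_name, total = .data$tp + .data$fn)
  self_rank <- dplyr::bind_rows(purrr::map(per_reaction, "tp_ranks")) |>
    dplyr::count(.data$score_name, .data$rank) |>
    dplyr::group_by(.data$score_name) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::mutate(cum_tp = cumsum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(cum_fraction = .data$cum_tp /
                    stats::ave(.data$cum_tp, .data$score_name, FUN = max)) |>
    dplyr::select("score_name", "rank", "cum_tp", "cum_fraction")

  structure(list(table = table, self_rank = self_rank,
                 eligible_reactions = eligible, k_grid = k_grid,
                 n_genuine = n_genuine),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d orphanized reactions\n",
              length(x$eligible_reactions)))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Tidy accessors for benchmark results
#'
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @return `tidy()`: the pooled precision-recall table; `glance()`: one row
#'   per score at the unbounded cutoff.
#' @export
tidy.benchmark_result <- function(x, ...) x$table

#' @rdname tidy.benchmark_result
#' @export
glance.benchmark_result <- function(x, ...) {
  dplyr::filter(x$table, is.infinite(.data$k)) |>
    dplyr::select("score_name", "tp", "fp", "fn", "recall", "precision")
}
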