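toy_weighted <- function() {
  ds <- toy_dataset()
  mset <- find_metabolons(build_data_graph(ds, toy_config()), toy_config())
  weight_associations(mset, toy_config())
}

test_that("MPL matches the independent BFS oracle on toy and simulated metabolons", {
  check_against_oracle <- function(mset) {
    assoc <- compute_mpl(mset)
    known <- dplyr::filter(assoc, category == "Known")
    for (m_id in unique(assoc$metabolon_id)) {
      rows <- dplyr::filter(assoc, metabolon_id == m_id)
      for (i in seq_len(nrow(rows))) {
        want <- o_mpl(
          gene_edges = mset$gene_edges[mset$gene_edges$metabolon_id == m_id, ],
          rxn_edges = mset$reaction_edges[mset$reaction_edges$metabolon_id == m_id, ],
          known = known[known$metabolon_id == m_id, ],
          genes = mset$genes$gene_id[mset$genes$metabolon_id == m_id],
          rxns = mset$reactions$reaction_id[mset$reactions$metabolon_id == m_id],
          gene = rows$gene_id[i], rxn = rows$reaction_id[i],
          category = rows$category[i])
        expect_equal(rows$mpl[i], want,
                     info = sprintf("%s (%s,%s)", m_id, rows$gene_id[i],
                                    rows$reaction_id[i]))
      }
    }
    assoc
  }
  check_against_oracle(find_metabolons(
    build_data_graph(toy_dataset(), toy_config()), toy_config()))
  ds <- withhold_orphans(simulate_dataset(small_params(), seed = 3L),
                         fraction = 0.3, seed = 3L)
  check_against_oracle(find_metabolons(
    build_data_graph(ds, pipeline_config()), pipeline_config()))
})

test_that("MPL floors: >= 2 for Known, >= 3 for Potential, 2 reachable only via shared context", {
  mset <- toy_weighted()
  known <- dplyr::filter(mset$associations, category == "Known")
  pot <- dplyr::filter(mset$associations, category == "Potential")
  expect_true(all(known$mpl >= 2L))
  expect_true(all(pot$mpl >= 3L))

  # a bifunctional gene annotated with two adjacent reactions attains MPL 2:
  # its second Known edge plus one reaction-reaction edge
  genes <- tibble::tibble(organism_id = "o1", replicon_id = "c1",
                          gene_id = c("gA", "gB"), position = 0:1)
  links <- tibble::tibble(reaction_a = "r1", reaction_b = "r2",
                          main_compound_ids = "c")
  assoc <- tibble::tibble(organism_id = "o1", gene_id = c("gA", "gA", "gB"),
                          reaction_id = c("r1", "r2", "r2"),
                          category = "Known")
  ds <- metabolon_dataset(genes, links, assoc)
  mset2 <- weight_associations(
    find_metabolons(build_data_graph(ds, toy_config()), toy_config()),
    toy_config())
  bif <- dplyr::filter(mset2$associations, gene_id == "gA", reaction_id == "r1")
  expect_equal(bif$mpl, 2L)
  expect_equal(bif$weight, 0.5)

  # corpus-wide floors on a simulated corpus with orphanized targets
  ds3 <- withhold_orphans(simulate_dataset(small_params(), seed = 9L),
                          fraction = 0.3, seed = 9L)
  mset3 <- weight_associations(
    find_metabolons(build_data_graph(ds3, pipeline_config()),
                    pipeline_config()), pipeline_config())
  expect_true(all(mset3$associations$mpl[
    mset3$associations$category == "Known"] >= 2L))
  expect_true(all(mset3$associations$mpl[
    mset3$associations$category == "Potential"] >= 3L))
})

test_that("a gap gene one step from an anchor whose reaction neighbors the gap reaction has MPL 3", {
  # gB(gap) - gC(anchor, Known r2) ; r2 - r4(gap): path gB-gC, gC-r2, r2-r4
  mset <- toy_weighted()
  ge <- dplyr::filter(mset$associations, gene_id == "gE", reaction_id == "r4")
  expect_equal(ge$mpl, 3L)
  expect_equal(ge$weight, 0.1 / 3)
})

test_that("association weights follow alpha / MPL by category", {
  expect_equal(association_weight("Known", 2), 0.5)
  expect_equal(association_weight("Potential", 4), 0.025)
  expect_equal(association_weight("Inferred", 3), association_weight("Known", 3))
  cfg <- pipeline_config(alpha_known = 2, alpha_potential = 0.5)
  expect_equal(association_weight("Potential", 5, cfg), 0.1)
  expect_error(association_weight("Bogus", 2), "invalid category")
  expect_error(association_weight("Known", 0), "mpl")
  # strictly decreasing in MPL at fixed category
  w <- association_weight(rep("Potential", 5), 3:7)
  expect_true(all(diff(w) < 0))
})

test_that("associations with undefined MPL are dropped with a warning", {
  # one gene Known to one isolated reaction: with its own edge excluded
  # there is no path, so the MPL is undefined
  genes <- tibble::tibble(organism_id = "o1", replicon_id = "c1",
                          gene_id = c("gA", "gB"), position = 0:1)
  links <- tibble::tibble(reaction_a = "r1", reaction_b = "r2",
                          main_compound_ids = "c")
  assoc <- tibble::tibble(organism_id = "o1", gene_id = "gA",
                          reaction_id = "r3", category = "Known")
  ds <- metabolon_dataset(genes, links, assoc, reactions = paste0("r", 1:3))
  cfg <- pipeline_config(min_genes = 1, min_rxns = 1, min_known = 1,
                         circular_replicons = FALSE)
  mset <- find_metabolons(build_data_graph(ds, cfg), cfg)
  expect_warning(out <- weight_associations(mset, cfg), "undefined MPL")
  expect_equal(nrow(out$associations), 0L)
})

test_that("gene-level scores are the documented weight ratios", {
  # a gene with two Potential associations of MPL 3 and 4:
  # scores (0.1/3, 0.1/4) / (0.1/3 + 0.1/4) = 4/7, 3/7
  assoc <- tibble::tibble(
    organism_id = "o1", gene_id = "g1", reaction_id = c("rA", "rB"),
    category = "Potential", weight = c(0.1 / 3, 0.1 / 4))
  sc <- score_genes(assoc)
  expect_equal(sc$score_g_to_r[sc$reaction_id == "rA"], 4 / 7)
  expect_equal(sc$score_g_to_r[sc$reaction_id == "rB"], 3 / 7)

  # Known (MPL 3) vs Potential (MPL 3) on one reaction: 10/11 vs 1/11
  assoc2 <- tibble::tibble(
    organism_id = "o1", gene_id = c("g1", "g2"), reaction_id = "rA",
    category = c("Known", "Potential"), weight = c(1 / 3, 0.1 / 3))
  sc2 <- score_genes(assoc2)
  expect_equal(sc2$score_r_to_g[sc2$gene_id == "g1"], 10 / 11)
  expect_equal(sc2$score_r_to_g[sc2$gene_id == "g2"], 1 / 11)

  # single-association gene and two symmetric candidates
  one <- score_genes(tibble::tibble(organism_id = "o", gene_id = "g",
                                    reaction_id = "r", category = "Potential",
                                    weight = 0.025))
  expect_equal(one$score_g_to_r, 1)
  expect_equal(one$score_r_to_g, 1)
  sym <- score_genes(tibble::tibble(organism_id = "o", gene_id = c("g1", "g2"),
                                    reaction_id = "r", category = "Potential",
                                    weight = 0.1 / 3))
  expect_equal(sym$score_r_to_g, c(0.5, 0.5))
})

test_that("gene-level scores normalize to 1 within 1e-12 on a simulated corpus", {
  ds <- withhold_orphans(simulate_dataset(small_params(), seed = 13L),
                         fraction = 0.3, seed = 13L)
  mset <- weight_associations(
    find_metabolons(build_data_graph(ds, pipeline_config()),
                    pipeline_config()), pipeline_config())
  sc <- score_genes(mset$associations)
  expect_true(all(sc$score_g_to_r > 0 & sc$score_g_to_r <= 1))
  expect_true(all(sc$score_r_to_g > 0 & sc$score_r_to_g <= 1))
  by_gene <- sc |>
    dplyr::group_by(organism_id, gene_id) |>
    dplyr::summarise(s = sum(score_g_to_r), .groups = "drop")
  expect_true(all(abs(by_gene$s - 1) < 1e-12))
  by_rxn <- sc |>
    dplyr::group_by(organism_id, reaction_id) |>
    dplyr::summarise(s = sum(score_r_to_g), .groups = "drop")
  expect_true(all(abs(by_rxn$s - 1) < 1e-12))
})
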