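test_that("naive single-linkage families follow the thresholded components", {
  edges <- tibble::tibble(gene_a = c("a", "b", "a"), gene_b = c("b", "c", "c"),
                          similarity = c(0.9, 0.8, 0.2))
  # chain a-b, b-c above threshold, a-c below: one family by single linkage
  fams <- naive_families_from_similarity(edges, threshold = 0.5)
  expect_equal(dplyr::n_distinct(fams$family_id), 1L)
  # all pairwise above threshold: still one family of 3
  fams2 <- naive_families_from_similarity(edges, threshold = 0.1)
  expect_equal(dplyr::n_distinct(fams2$family_id), 1L)
  expect_equal(nrow(fams2), 3L)
  # threshold above all scores: singletons
  fams3 <- naive_families_from_similarity(edges, threshold = 0.99)
  expect_equal(dplyr::n_distinct(fams3$family_id), 3L)
  # conflicting duplicate scores are rejected
  bad <- dplyr::bind_rows(edges, tibble::tibble(gene_a = "b", gene_b = "a",
                                                similarity = 0.1))
  expect_error(naive_families_from_similarity(bad, 0.5), "conflicting")
})

test_that("non-metabolic family filtering removes Potential rows only", {
  genes <- promotion_genes()
  genes$family_id[genes$gene_id == "g1G"] <- "NMX"
  fams <- tibble::tibble(family_id = c("D", "F", "G", "NMX"),
                         non_metabolic = c(FALSE, FALSE, FALSE, TRUE))
  assoc <- promotion_associations()
  out <- drop_nonmetabolic(assoc, genes, fams)
  expect_false(any(out$gene_id == "g1G" & out$category == "Potential"))
  # Known rows of a flagged family survive
  assoc2 <- dplyr::mutate(assoc,
                          category = replace(category, gene_id == "g1G" &
                                               reaction_id == "r4", "Known"))
  out2 <- drop_nonmetabolic(assoc2, genes, fams)
  expect_true(any(out2$gene_id == "g1G" & out2$category == "Known"))
  # without flagged families the operation is the identity
  no_flags <- dplyr::mutate(fams, non_metabolic = FALSE)
  expect_equal(drop_nonmetabolic(assoc, genes, no_flags), assoc)
})

test_that("promotion turns the family-backed Potential into Inferred and removes rivals", {
  assoc <- promotion_associations()
  genes <- promotion_genes()
  out <- promote_inferred(assoc, genes)
  # (g3F, r5) promoted: g2F of family F holds Known (g2F, r5)
  g3F_r5 <- dplyr::filter(out, gene_id == "g3F", reaction_id == "r5")
  expect_equal(g3F_r5$category, "Inferred")
  # Inferred is weighted like Known at the inherited MPL
  expect_equal(g3F_r5$weight, 1 / 3)
  # the other Potentials of g3F and of r5 in that metabolon are removed
  expect_false(any(out$gene_id == "g3F" & out$reaction_id == "r4"))
  expect_false(any(out$gene_id == "g3D" & out$reaction_id == "r5"))
  # (g3D, r4) in the same metabolon is untouched
  expect_true(any(out$gene_id == "g3D" & out$reaction_id == "r4" &
                    out$category == "Potential"))
  # unrelated organisms keep their Potentials
  expect_true(all(c("r4", "r8") %in% out$reaction_id[out$gene_id == "g1G"]))
})

test_that("promotion is idempotent and never increases Potential count", {
  assoc <- promotion_associations()
  genes <- promotion_genes()
  once <- promote_inferred(assoc, genes)
  twice <- promote_inferred(once, genes)
  expect_equal(once, twice)
  n_pot <- function(a) sum(a$category == "Potential")
  expect_lte(n_pot(once), n_pot(assoc))
  n_strong <- function(a) sum(a$category %in% c("Known", "Inferred"))
  expect_gte(n_strong(once), n_strong(assoc))
})

test_that("a Potential without a Known family copy stays Potential", {
  assoc <- promotion_associations() |>
    dplyr::filter(!(gene_id == "g2F"))  # remove the Known evidence
  out <- promote_inferred(assoc, promotion_genes())
  expect_false(any(out$category == "Inferred"))
})

test_that("family coverage counts associated members over family size", {
  genes <- tibble::tibble(
    organism_id = paste0("o", 1:4), replicon_id = "chr",
    gene_id = paste0("g", 1:4), position = 0L,
    family_id = "F1", non_metabolic = FALSE)
  assoc <- tibble::tibble(
    organism_id = c("o1", "o2"), gene_id = c("g1", "g2"),
    reaction_id = "rA", category = "Potential", weight = 0.1 / 3)
  fs <- family_scores(assoc, genes)
  expect_equal(fs$coverage, 0.5)   # 2 of 4 members
  expect_equal(fs$family_size, 4L)
  # all members associated -> coverage 1
  assoc_all <- tibble::tibble(
    organism_id = paste0("o", 1:4), gene_id = paste0("g", 1:4),
    reaction_id = "rA", category = "Potential", weight = 0.1 / 3)
  expect_equal(family_scores(assoc_all, genes)$coverage, 1)
  # unassociated (family, reaction) pairs are not emitted
  expect_equal(nrow(fs), 1L)
})

test_that("family-to-reaction and reaction-to-family scores are the documented ratios", {
  genes <- tibble::tibble(
    organism_id = c("o1", "o2", "o3", "o4"), replicon_id = "chr",
    gene_id = c("g1", "g2", "g3", "gX"), position = 0L,
    family_id = c("F1", "F1", "F1", NA), non_metabolic = FALSE)

  # family F1 with weights {R: 0.5, R2: 0.025} -> Score_F->R = 0.5/0.525
  assoc <- tibble::tibble(
    organism_id = c("o1", "o1"), gene_id = "g1",
    reaction_id = c("R", "R2"), category = c("Known", "Potential"),
    weight = c(0.5, 0.025))
  fs <- family_scores(assoc, genes)
  expect_equal(fs$score_f_to_r[fs$reaction_id == "R"], 0.5 / 0.525)
  expect_equal(sum(fs$score_f_to_r), 1)

  # family weights 0.1/3 + 0.1/3 + 0.1/4 to R, one family-less gene with
  # 0.1/3: Score_R->F = 0.0917/0.1250
  assoc2 <- tibble::tibble(
    organism_id = c("o1", "o2", "o3", "o4"),
    gene_id = c("g1", "g2", "g3", "gX"),
    reaction_id = "R", category = "Potential",
    weight = c(0.1 / 3, 0.1 / 3, 0.1 / 4, 0.1 / 3))
  fs2 <- family_scores(assoc2, genes)
  num <- 2 * 0.1 / 3 + 0.1 / 4
  den <- num + 0.1 / 3
  expect_equal(fs2$score_r_to_f, num / den)
  expect_equal(round(fs2$score_r_to_f, 4), 0.7333)
})

test_that("family score normalization holds corpus-wide", {
  ds <- withhold_orphans(simulate_dataset(small_params(), seed = 21L),
                         fraction = 0.3, seed = 21L)
  run <- run_pipeline(ds)
  fs <- run$family_scores
  by_fam <- fs |>
    dplyr::group_by(family_id) |>
    dplyr::summarise(s = sum(score_f_to_r), .groups = "drop")
  expect_true(all(abs(by_fam$s - 1) < 1e-12))
  by_rxn <- fs |>
    dplyr::group_by(reaction_id) |>
    dplyr::summarise(s = sum(score_r_to_f), .groups = "drop")
  expect_true(all(by_rxn$s <= 1 + 1e-12))
  # reactions whose associated genes all carry families reach exactly 1
  fl <- dplyr::filter(run$dataset$genes, !is.na(family_id))
  assoc <- run$associations |>
    dplyr::mutate(has_fam = paste(organism_id, gene_id) %in%
                    paste(fl$organism_id, fl$gene_id))
  full_fam <- assoc |>
    dplyr::group_by(reaction_id) |>
    dplyr::summarise(all_fam = all(has_fam), .groups = "drop") |>
    dplyr::filter(all_fam)
  covered <- dplyr::filter(by_rxn, reaction_id %in% full_fam$reaction_id)
  expect_gt(nrow(covered), 0L)
  expect_true(all(abs(covered$s - 1) < 1e-12))
})

test_that("candidates are ranked by descending score with competition ties", {
  genes <- tibble::tibble(
    organism_id = "o1", replicon_id = "chr",
    gene_id = c("gK", "gL", "gM", "gN"), position = 0:3,
    family_id = c("FK", "FL", "FM", NA), non_metabolic = FALSE)
  assoc <- tibble::tibble(
    metabolon_id = "M1", organism_id = "o1",
    gene_id = c("gK", "gL", "gM", "gN"), reaction_id = "rA",
    category = "Potential", mpl = 3L, weight = 0.1 / 3)
  fam_scores <- tibble::tibble(
    family_id = c("FK", "FL", "FM"), reaction_id = "rA",
    family_size = 1L, coverage = 1,
    score_f_to_r = 1, score_r_to_f = c(0.344, 0.334, 0.252))
  gene_scores <- score_genes(assoc)
  rk <- rank_candidates(assoc, genes, fam_scores, gene_scores, "r_to_f")
  expect_equal(rk$rank[match(c("gK", "gL", "gM"), rk$gene_id)], c(1L, 2L, 3L))
  # the family-less gene falls back to its gene-level score, ranked last
  expect_equal(rk$rank[rk$gene_id == "gN"], 4L)

  # equal family scores share the minimum rank
  fam_tie <- dplyr::mutate(fam_scores, score_r_to_f = c(0.4, 0.4, 0.2))
  rk2 <- rank_candidates(assoc, genes, fam_tie, gene_scores, "r_to_f")
  expect_equal(sort(rk2$rank[rk2$gene_id %in% c("gK", "gL")]), c(1L, 1L))
  expect_equal(rk2$rank[rk2$gene_id == "gM"], 3L)

  # single candidate gets rank 1
  solo <- rank_candidates(assoc[1, ], genes, fam_scores, gene_scores, "r_to_f")
  expect_equal(solo$rank, 1L)

  # two members of one family share a rank under the family score
  genes2 <- dplyr::mutate(genes, family_id = c("FK", "FK", "FM", NA))
  rk3 <- rank_candidates(assoc, genes2, fam_scores, gene_scores, "r_to_f")
  expect_equal(rk3$rank[rk3$gene_id == "gK"], rk3$rank[rk3$gene_id == "gL"])
})
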