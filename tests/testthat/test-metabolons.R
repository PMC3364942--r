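# helpers ------------------------------------------------------------------

instance_data_graph <- function(inst, config) {
  gg <- build_gene_graph(inst$genes, circular = inst$circular)
  rg <- build_reaction_graph(links = inst$rxn_edges, reactions = inst$rxns)
  assemble_data_graph(gg, rg, inst$assoc)
}

# canonical form: one string per CCC listing its associations, plus member
# sets with gap flags
canonical_partition <- function(blocks) {
  unname(sort(vapply(blocks, function(b) {
    paste(sort(paste(b$gene_id, b$reaction_id, sep = "~")), collapse = ";")
  }, "")))
}

oracle_partition <- function(inst, config) {
  gene_edges <- o_gene_edges(inst$genes, inst$circular)
  rxn_edges <- data.frame(from = inst$rxn_edges$reaction_a,
                          to = inst$rxn_edges$reaction_b)
  o_cccs(inst$genes$gene_id, gene_edges, inst$rxns, rxn_edges,
         inst$assoc, config$g_gene, config$g_rxn)
}

# tests ---------------------------------------------------------------------

test_that("the six-gene / five-reaction toy yields one metabolon with gaps gB, gE, r4", {
  ds <- toy_dataset()
  run_set <- find_metabolons(build_data_graph(ds, toy_config()), toy_config())
  expect_equal(dplyr::n_distinct(run_set$genes$metabolon_id), 1L)
  expect_setequal(run_set$genes$gene_id, paste0("g", LETTERS[1:6]))
  expect_setequal(run_set$genes$gene_id[run_set$genes$is_gap], c("gB", "gE"))
  expect_setequal(run_set$reactions$reaction_id, paste0("r", 1:5))
  expect_setequal(run_set$reactions$reaction_id[run_set$reactions$is_gap], "r4")
  pot <- dplyr::filter(run_set$associations, category == "Potential")
  expect_setequal(paste(pot$gene_id, pot$reaction_id), c("gB r4", "gE r4"))
})

test_that("splitting the gene cluster across replicons splits the CCC", {
  ds <- toy_dataset()
  genes <- ds$genes
  genes$replicon_id <- c("c1", "c1", "c1", "c2", "c2", "c2")
  genes$position <- c(0:2, 0:2)
  ds2 <- metabolon_dataset(genes, ds$reaction_links, ds$associations)
  cccs <- partition_cccs(build_data_graph(ds2, toy_config()), toy_config())
  expect_equal(dplyr::n_distinct(cccs$ccc_id), 2L)
})

test_that("partition + gap recovery matches the brute-force enumerator on random instances", {
  config <- pipeline_config()
  for (seed in 1:25) {
    inst <- random_instance(seed + 1000L)
    dg <- instance_data_graph(inst, config)
    cccs <- partition_cccs(dg, config)
    blocks <- split(cccs, cccs$ccc_id)
    expect_equal(canonical_partition(blocks),
                 canonical_partition(oracle_partition(inst, config)),
                 info = paste("seed", seed))
    # gap members agree with the all-shortest-paths oracle
    gene_edges <- o_gene_edges(inst$genes, inst$circular)
    rxn_edges <- data.frame(from = inst$rxn_edges$reaction_a,
                            to = inst$rxn_edges$reaction_b)
    for (b in blocks) {
      m <- recover_gaps(b, dg, config)
      expect_setequal(m$genes$gene_id[m$genes$is_gap],
                      o_gaps(inst$genes$gene_id, gene_edges,
                             b$gene_id, config$g_gene))
      expect_setequal(m$reactions$reaction_id[m$reactions$is_gap],
                      o_gaps(inst$rxns, rxn_edges, b$reaction_id, config$g_rxn))
    }
  }
})

test_that("the partition fixed point is independent of the split order", {
  config <- pipeline_config()
  for (seed in 1:8) {
    inst <- random_instance(seed + 2000L)
    dg <- instance_data_graph(inst, config)
    a <- partition_cccs(dg, config, first_side = "gene")
    b <- partition_cccs(dg, config, first_side = "reaction")
    expect_equal(a, b)
  }
})

test_that("every Known association lies in exactly one metabolon", {
  config <- pipeline_config()
  for (seed in 1:8) {
    inst <- random_instance(seed + 3000L)
    cccs <- partition_cccs(instance_data_graph(inst, config), config)
    expect_equal(nrow(cccs), nrow(inst$assoc))
    expect_equal(anyDuplicated(paste(cccs$gene_id, cccs$reaction_id)), 0L)
  }
})

test_that("increasing the gap tolerance never increases the number of CCCs", {
  for (seed in 1:8) {
    inst <- random_instance(seed + 4000L)
    counts <- vapply(0:4, function(g) {
      config <- pipeline_config(g_gene = g, g_rxn = g)
      dplyr::n_distinct(
        partition_cccs(instance_data_graph(inst, config), config)$ccc_id)
    }, integer(1L))
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("metabolons are invariant under permuted input ordering", {
  ds <- simulate_dataset(small_params(), seed = 11L)
  config <- pipeline_config()
  run1 <- find_metabolons(build_data_graph(ds, config), config)
  set.seed(1)
  ds2 <- ds
  ds2$genes <- ds$genes[sample.int(nrow(ds$genes)), ]
  ds2$associations <- ds$associations[sample.int(nrow(ds$associations)), ]
  run2 <- find_metabolons(build_data_graph(ds2, config), config)
  expect_equal(run1$associations, run2$associations)
  expect_equal(run1$genes, run2$genes)
})

test_that("gap recovery bridges short breaks but not breaks beyond g+1", {
  mk <- function(n_between) {
    n <- 2L + n_between
    genes <- tibble::tibble(organism_id = "o1", replicon_id = "c1",
                            gene_id = sprintf("g%02d", seq_len(n)),
                            position = seq_len(n) - 1L)
    links <- tibble::tibble(reaction_a = "r1", reaction_b = "r2",
                            main_compound_ids = "c")
    assoc <- tibble::tibble(organism_id = "o1",
                            gene_id = c("g01", sprintf("g%02d", n)),
                            reaction_id = c("r1", "r2"), category = "Known")
    metabolon_dataset(genes, links, assoc)
  }
  cfg <- toy_config()
  # one unannotated gene between the anchors: recovered as a gap
  near <- find_metabolons(build_data_graph(mk(1L), cfg), cfg)
  expect_setequal(near$genes$gene_id[near$genes$is_gap], "g02")
  # four unannotated genes: distance 5 > g_gene + 1 = 4, no closure edge,
  # the anchors fall into different (sub-threshold) CCCs
  far_cccs <- partition_cccs(build_data_graph(mk(4L), cfg), cfg)
  expect_equal(dplyr::n_distinct(far_cccs$ccc_id), 2L)
})

test_that("reaction gaps recover all interiors of shortest paths at distance <= g+1", {
  genes <- tibble::tibble(organism_id = "o1", replicon_id = "c1",
                          gene_id = c("gA", "gB"), position = 0:1)
  links <- tibble::tibble(reaction_a = paste0("r", 1:3),
                          reaction_b = paste0("r", 2:4),
                          main_compound_ids = "c")
  assoc <- tibble::tibble(organism_id = "o1", gene_id = c("gA", "gB"),
                          reaction_id = c("r1", "r4"), category = "Known")
  ds <- metabolon_dataset(genes, links, assoc)
  cfg <- toy_config()  # g_rxn = 2: r1..r4 are at distance 3 <= 3
  mset <- find_metabolons(build_data_graph(ds, cfg), cfg)
  expect_setequal(mset$reactions$reaction_id[mset$reactions$is_gap],
                  c("r2", "r3"))
})

test_that("retention thresholds are applied to genes, reactions and Known counts", {
  ds <- toy_dataset()
  cfg <- toy_config()
  dg <- build_data_graph(ds, cfg)
  cccs <- partition_cccs(dg, cfg)
  mlist <- lapply(split(cccs, cccs$ccc_id), recover_gaps,
                  data_graph = dg, config = cfg)
  mset <- metabolons:::metabolon_set_from_list(mlist)
  expect_equal(dplyr::n_distinct(
    filter_metabolons(mset, cfg)$associations$metabolon_id), 1L)

  # a single-association CCC (1 gene, 1 reaction) is discarded at 2/2/2 but
  # kept at 1/1/1
  lone <- tibble::tibble(organism_id = "o1", gene_id = "gA",
                         reaction_id = "r1", category = "Known")
  single <- metabolons:::metabolon_set_from_list(list(
    recover_gaps(lone, dg, pipeline_config(g_gene = 0, g_rxn = 0))))
  expect_equal(nrow(filter_metabolons(single, cfg)$associations), 0L)
  loose <- pipeline_config(min_genes = 1, min_rxns = 1, min_known = 1)
  expect_equal(nrow(filter_metabolons(single, loose)$associations), 1L)
})

test_that("gap genes flagged non-metabolic or Known elsewhere get no proposals", {
  # gA..gF with gB in a non-metabolic family, gE Known to a remote reaction
  ds <- toy_dataset()
  genes <- ds$genes
  genes$family_id <- c(NA, "NM", NA, NA, NA, NA)
  assoc <- dplyr::bind_rows(
    ds$associations,
    tibble::tibble(organism_id = "o1", gene_id = "gE", reaction_id = "r9",
                   category = "Known"))
  links <- dplyr::bind_rows(
    ds$reaction_links,
    tibble::tibble(reaction_a = "r8", reaction_b = "r9",
                   main_compound_ids = "z"))
  fams <- tibble::tibble(family_id = "NM", non_metabolic = TRUE)
  ds2 <- metabolon_dataset(genes, links, assoc, families = fams)
  cfg <- toy_config()
  dg <- build_data_graph(ds2, cfg)
  mset <- find_metabolons(dg, cfg, families = fams)
  main <- mset$associations[mset$associations$reaction_id == "r4", ]
  # gB excluded (non-metabolic family), gE excluded (Known elsewhere):
  # no Potential proposals remain for r4, yet both stay as gap members
  expect_equal(nrow(main), 0L)
  m_id <- mset$genes$metabolon_id[mset$genes$gene_id == "gB"]
  expect_true(all(c("gB", "gE") %in%
                    mset$genes$gene_id[mset$genes$metabolon_id == m_id[1]]))
  expect_true(all(mset$genes$is_gap[mset$genes$gene_id %in% c("gB", "gE")]))
})

test_that("gap members never carry Known associations inside their metabolon", {
  ds <- simulate_dataset(small_params(), seed = 5L)
  dsw <- withhold_orphans(ds, fraction = 0.3, seed = 5L)
  mset <- find_metabolons(build_data_graph(dsw, pipeline_config()),
                          pipeline_config())
  known <- dplyr::filter(mset$associations, category == "Known")
  gap_genes <- dplyr::filter(mset$genes, is_gap)
  gap_rxns <- dplyr::filter(mset$reactions, is_gap)
  expect_equal(nrow(dplyr::inner_join(
    known, gap_genes, by = c("metabolon_id", "gene_id"))), 0L)
  expect_equal(nrow(dplyr::inner_join(
    known, gap_rxns, by = c("metabolon_id", "reaction_id"))), 0L)
})
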