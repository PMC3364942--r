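# Shared fixtures, built in code.

# six consecutive genes gA..gF on one linear replicon; five chained
# reactions r1..r5; Known annotations on gA, gC, gD, gF -> r1, r2, r3, r5;
# under the default gap tolerances this yields one metabolon with gaps
# gB, gE (genes) and r4 (reaction)
toy_dataset <- function() {
  genes <- tibble::tibble(
    organism_id = "o1", replicon_id = "c1",
    gene_id = paste0("g", LETTERS[1:6]), position = 0:5
  )
  links <- tibble::tibble(
    reaction_a = paste0("r", 1:4), reaction_b = paste0("r", 2:5),
    main_compound_ids = paste0("cpd", 1:4)
  )
  assoc <- tibble::tibble(
    organism_id = "o1",
    gene_id = c("gA", "gC", "gD", "gF"),
    reaction_id = c("r1", "r2", "r3", "r5"),
    category = "Known"
  )
  metabolon_dataset(genes, links, assoc)
}

toy_config <- function(...) pipeline_config(circular_replicons = FALSE, ...)

# three organisms carrying homologous clusters over the chain r4-r5 plus a
# private r8 context in org1; family D is Known to neither reaction, family
# F is Known to r5 in org2 only: promotion material for the integration
# stage
promotion_associations <- function() {
  tibble::tibble(
    metabolon_id = c("M1", "M1", "M1", "M2", "M3", "M3", "M3", "M3"),
    organism_id = c("org1", "org1", "org1", "org2", "org3", "org3", "org3",
                    "org3"),
    gene_id = c("g1D", "g1G", "g1G", "g2F", "g3F", "g3F", "g3D", "g3D"),
    reaction_id = c("r4", "r4", "r8", "r5", "r5", "r4", "r5", "r4"),
    category = c("Potential", "Potential", "Potential", "Known",
                 "Potential", "Potential", "Potential", "Potential"),
    mpl = c(3L, 3L, 4L, 3L, 3L, 4L, 4L, 3L),
    weight = c(0.1 / 3, 0.1 / 3, 0.1 / 4, 1 / 3, 0.1 / 3, 0.1 / 4, 0.1 / 4,
               0.1 / 3)
  )
}

promotion_genes <- function() {
  tibble::tibble(
    organism_id = rep(c("org1", "org2", "org3"), each = 3L),
    replicon_id = "chr",
    gene_id = c("g1D", "g1G", "g1X", "g2F", "g2D", "g2X", "g3F", "g3D", "g3X"),
    position = rep(0:2, 3L),
    family_id = c("D", "G", NA, "F", "D", NA, "F", "D", NA),
    non_metabolic = FALSE
  )
}

small_params <- function(...) {
  sim_params(n_organisms = 3L, genes_per_organism = 80L, n_reactions = 24L,
             chain_length = 6L, n_clusters = 3L, ...)
}
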