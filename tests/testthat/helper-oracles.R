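# Independent brute-force oracles, written in base R against adjacency
# lists (no igraph), used to verify the graph machinery: BFS distances,
# all-shortest-path interiors, partial closure, maximal common connected
# components by subset enumeration, and MPL by BFS.

o_adjacency <- function(vertices, edges) {
  adj <- stats::setNames(vector("list", length(vertices)), vertices)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$from[i]
      b <- edges$to[i]
      adj[[a]] <- unique(c(adj[[a]], b))
      adj[[b]] <- unique(c(adj[[b]], a))
    }
  }
  adj
}

o_bfs_dist <- function(adj, source) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

o_all_dist <- function(adj) {
  t(vapply(names(adj), function(v) o_bfs_dist(adj, v),
           numeric(length(adj))))
}

# interiors of all shortest paths between u and v
o_interiors <- function(adj, u, v) {
  dist <- o_bfs_dist(adj, u)
  if (is.infinite(dist[v])) return(character())
  walk <- function(x) {
    if (x == u) return(list(u))
    preds <- adj[[x]][dist[adj[[x]]] == dist[x] - 1]
    unlist(lapply(preds, function(p) {
      lapply(walk(p), function(path) c(path, x))
    }), recursive = FALSE)
  }
  paths <- walk(v)
  interior <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
  sort(unique(interior))
}

# vertex pairs joined after a g-partial transitive closure (including the
# original edges): shortest-path distance between 1 and g+1
o_closed_pairs <- function(vertices, edges, g) {
  adj <- o_adjacency(vertices, edges)
  d <- o_all_dist(adj)
  out <- list()
  vs <- names(adj)
  for (i in seq_along(vs)) {
    for (j in seq_along(vs)) {
      if (i < j && d[i, j] >= 1 && d[i, j] <= g + 1) {
        out[[length(out) + 1L]] <- sort(c(vs[i], vs[j]))
      }
    }
  }
  out
}

o_closed_adjacency <- function(vertices, edges, g) {
  pairs <- o_closed_pairs(vertices, edges, g)
  ed <- if (length(pairs)) {
    data.frame(from = vapply(pairs, `[`, "", 1L),
               to = vapply(pairs, `[`, "", 2L))
  } else {
    data.frame(from = character(), to = character())
  }
  o_adjacency(vertices, ed)
}

o_connected <- function(adj, subset) {
  if (length(subset) <= 1L) return(TRUE)
  sub <- lapply(adj[subset], function(nb) intersect(nb, subset))
  all(is.finite(o_bfs_dist(sub, subset[[1L]])))
}

# maximal common connected components by exhaustive subset enumeration:
# a subset of associations is valid when its genes are connected in the
# closed gene graph induced on them, and likewise its reactions; valid sets
# sharing an association are closed under union, so each association has a
# unique maximal valid set and those sets partition the associations
o_cccs <- function(gene_vertices, gene_edges, rxn_vertices, rxn_edges,
                   assoc, g_gene, g_rxn) {
  stopifnot(nrow(assoc) <= 12L)
  gadj <- o_closed_adjacency(gene_vertices, gene_edges, g_gene)
  radj <- o_closed_adjacency(rxn_vertices, rxn_edges, g_rxn)
  n <- nrow(assoc)
  valid <- function(idx) {
    o_connected(gadj, unique(assoc$gene_id[idx])) &&
      o_connected(radj, unique(assoc$reaction_id[idx]))
  }
  valid_sets <- Filter(valid, lapply(seq_len(2^n - 1L), function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
  }))
  blocks <- unique(lapply(seq_len(n), function(i) {
    sort(unique(unlist(Filter(function(s) i %in% s, valid_sets))))
  }))
  lapply(blocks, function(idx) assoc[idx, , drop = FALSE])
}

# gap members of one CCC: interiors of all shortest original paths between
# anchor pairs at distance 2..g+1
o_gaps <- function(vertices, edges, anchors, g) {
  adj <- o_adjacency(vertices, edges)
  d <- o_all_dist(adj)
  out <- character()
  anchors <- sort(unique(anchors))
  if (length(anchors) >= 2L && g > 0L) {
    for (i in seq_len(length(anchors) - 1L)) {
      for (j in seq.int(i + 1L, length(anchors))) {
        dd <- d[anchors[i], anchors[j]]
        if (dd >= 2 && dd <= g + 1) {
          out <- c(out, o_interiors(adj, anchors[i], anchors[j]))
        }
      }
    }
  }
  sort(unique(setdiff(out, anchors)))
}

# MPL by BFS on one metabolon's traversable graph (gene-gene,
# reaction-reaction, and Known gene-reaction edges; own edge removed for a
# Known association)
o_mpl <- function(gene_edges, rxn_edges, known, genes, rxns,
                  gene, rxn, category) {
  v <- c(paste0("G:", genes), paste0("R:", rxns))
  ed <- rbind(
    if (nrow(gene_edges)) data.frame(from = paste0("G:", gene_edges$from),
                                     to = paste0("G:", gene_edges$to)),
    if (nrow(rxn_edges)) data.frame(from = paste0("R:", rxn_edges$from),
                                    to = paste0("R:", rxn_edges$to)),
    if (nrow(known)) data.frame(from = paste0("G:", known$gene_id),
                                to = paste0("R:", known$reaction_id))
  )
  if (is.null(ed)) ed <- data.frame(from = character(), to = character())
  if (category == "Known") {
    drop <- ed$from == paste0("G:", gene) & ed$to == paste0("R:", rxn)
    ed <- ed[!drop, , drop = FALSE]
  }
  adj <- o_adjacency(v, ed)
  d <- o_bfs_dist(adj, paste0("G:", gene))[paste0("R:", rxn)]
  if (is.finite(d)) as.integer(d) else NA_integer_
}

# brute-force gene adjacency from positions (chain, optional wrap)
o_gene_edges <- function(genes, circular) {
  out <- list()
  for (key in unique(paste(genes$organism_id, genes$replicon_id))) {
    sub <- genes[paste(genes$organism_id, genes$replicon_id) == key, ]
    sub <- sub[order(sub$position), ]
    n <- nrow(sub)
    if (n >= 2L) {
      out[[length(out) + 1L]] <- data.frame(from = sub$gene_id[-n],
                                            to = sub$gene_id[-1L])
    }
    if (circular && n >= 3L) {
      out[[length(out) + 1L]] <- data.frame(from = sub$gene_id[n],
                                            to = sub$gene_id[1L])
    }
  }
  if (!length(out)) return(data.frame(from = character(), to = character()))
  do.call(rbind, out)
}

# random small instance for oracle-equivalence tests
random_instance <- function(seed) {
  set.seed(seed)
  n_genes <- sample(4:12, 1L)
  n_replicons <- sample(1:2, 1L)
  circular <- sample(c(TRUE, FALSE), 1L)
  repl <- sort(sample.int(n_replicons, n_genes, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_genes), repl), seq_along),
                use.names = FALSE) - 1L
  genes <- tibble::tibble(
    organism_id = "org", replicon_id = paste0("rep", repl),
    gene_id = sprintf("g%02d", seq_len(n_genes)), position = pos
  )
  n_rxns <- sample(4:10, 1L)
  rxns <- sprintf("r%02d", seq_len(n_rxns))
  pairs <- t(utils::combn(rxns, 2L))
  keep <- stats::runif(nrow(pairs)) < 0.2
  rxn_edges <- tibble::tibble(reaction_a = pairs[keep, 1L],
                              reaction_b = pairs[keep, 2L],
                              main_compound_ids = "c")
  n_assoc <- sample(2:8, 1L)
  all_pairs <- expand.grid(gene_id = genes$gene_id, reaction_id = rxns,
                           stringsAsFactors = FALSE)
  picked <- all_pairs[sample.int(nrow(all_pairs), n_assoc), ]
  assoc <- tibble::tibble(organism_id = "org", gene_id = picked$gene_id,
                          reaction_id = picked$reaction_id, category = "Known")
  list(genes = genes, rxns = rxns, rxn_edges = rxn_edges, assoc = assoc,
       circular = circular)
}
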