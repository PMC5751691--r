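# Test helpers: instances with exact edge costs and node weights, random
# small instances under the study-condition generator, and random trees.

# Instance with the given edge costs and (non-terminal) node weights.
# Confidence scores are chosen as 1/cost under alpha = beta = 1 so the
# cost transform reproduces the requested costs exactly.
make_inst <- function(edges, terminals, weights = NULL, gamma = 1) {
  recs <- data.frame(protein_a = edges$from, protein_b = edges$to,
                     con = 1 / edges$cost, stringsAsFactors = FALSE)
  ann <- pathway_annotation(terminals, character(0))
  inst <- build_instance(recs, ann,
                         nw_params(alpha = 1, beta = 1, gamma = gamma,
                                   boost = 0))
  if (!is.null(weights)) {
    for (v in names(weights)) inst$weight[v] <- weights[[v]]
  }
  inst
}

# The competing-path instance: terminals t1, t2 joined directly (cost 25)
# and through v (costs 10 + 10), with adjustable w(v).
two_path_inst <- function(wv) {
  make_inst(data.frame(from = c("t1", "t1", "t2"),
                       to = c("t2", "v", "v"),
                       cost = c(25, 10, 10)),
            terminals = c("t1", "t2"),
            weights = c(v = wv))
}

# Small random instance under the generator's study conditions
# (costs ~100-300, weights -gamma/degree), <= 10 vertices.
small_random_inst <- function(seed, n = 9, m = 13) {
  sx <- synth_ppi_instance(n_vertices = n, n_edges = m,
                           planted_pathway_size = 5,
                           n_sources = 2, n_terminals = 2, seed = seed)
  build_instance(sx$records, sx$annotation)
}

# Random labelled tree as a solution_tree, with random source/terminal
# sets (possibly overlapping).
random_tree_case <- function(seed, n = 12) {
  set.seed(seed)
  g <- igraph::sample_tree(n)
  ids <- sprintf("V%02d", seq_len(n))
  el <- igraph::as_edgelist(g)
  tr <- solution_tree(ids, data.frame(from = ids[el[, 1L]],
                                      to = ids[el[, 2L]]))
  ns <- sample(1:4, 1L)
  nt <- sample(1:4, 1L)
  list(tree = tr,
       sources = sample(ids, ns),
       terminals = sample(ids, nt))
}

expect_same_report <- function(a, b) {
  expect_identical(a$node_B[sort(names(a$node_B))],
                   b$node_B[sort(names(b$node_B))])
  ka <- paste(a$edge_B$from, a$edge_B$to)
  kb <- paste(b$edge_B$from, b$edge_B$to)
  expect_identical(a$edge_B$B[order(ka)], b$edge_B$B[order(kb)])
}
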