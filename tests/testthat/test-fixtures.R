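test_that("the reference subnetwork is a 29-protein, 28-interaction tree", {
  fx <- pi3k_mapk_subnetwork()
  expect_length(fx$tree$vertices, 29)
  expect_equal(nrow(fx$tree$edges), 28)
  expect_length(fx$sources, 8)
  expect_length(fx$terminals, 14)
  # acyclic + connected is enforced by the solution_tree constructor;
  # double-check through igraph
  g <- igraph::graph_from_data_frame(fx$tree$edges, directed = FALSE,
                                     vertices = fx$tree$vertices)
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::ecount(g), igraph::vcount(g) - 1)
  expect_length(intersect(fx$sources, fx$terminals), 0)
  expect_true(all(names(fx$display_names) %in% fx$tree$vertices))
})

test_that("the derived source/terminal labeling regenerates every
           published betweenness value", {
  fx <- pi3k_mapk_subnetwork()
  rep <- st_betweenness(fx$tree, fx$sources, fx$terminals)
  expect_equal(rep$node_B[names(fx$node_betweenness)],
               fx$node_betweenness)
  key <- paste(rep$edge_B$from, rep$edge_B$to)
  fkey <- paste(fx$edge_betweenness$from, fx$edge_betweenness$to)
  expect_equal(rep$edge_B$B[match(fkey, key)], fx$edge_betweenness$B)
  # and so does the independent path-walk oracle
  oracle <- brute_force_betweenness(fx$tree, fx$sources, fx$terminals)
  expect_same_report(rep, oracle)
})

test_that("the synthetic generator is reproducible and well-formed", {
  a <- synth_ppi_instance(50, 150, seed = 1)
  b <- synth_ppi_instance(50, 150, seed = 1)
  expect_identical(a, b)
  c <- synth_ppi_instance(50, 150, seed = 2)
  expect_false(identical(a$records$con, c$records$con))
  inst <- build_instance(a$records, a$annotation)
  expect_silent(validate_instance(inst))
  expect_equal(nrow(a$records), 150)
  expect_length(unique(c(a$records$protein_a, a$records$protein_b)), 50)
  expect_error(synth_ppi_instance(10, 5), "n_edges")
})

test_that("default-parameter edge costs land in the calibrated band", {
  for (seed in 1:5) {
    sx <- synth_ppi_instance(60, 180, seed = seed)
    inst <- build_instance(sx$records, sx$annotation)
    expect_gte(stats::median(inst$edges$cost), 50)
    expect_lte(stats::median(inst$edges$cost), 600)
  }
})

test_that("the exhaustive Steiner oracle solves elementary cases", {
  # two terminals joined by a single edge: that edge is the optimum
  inst <- make_inst(data.frame(from = "t1", to = "t2", cost = 9),
                    terminals = c("t1", "t2"))
  bf <- brute_force_steiner(inst)
  expect_equal(bf$objective, 9)
  expect_setequal(bf$tree$vertices, c("t1", "t2"))
  # no terminals, all-negative weights: the empty tree at objective 0
  inst2 <- two_path_inst(-1)
  inst2$terminals <- character(0)
  inst2$weight[c("t1", "t2")] <- -1
  bf2 <- brute_force_steiner(inst2)
  expect_equal(bf2$objective, 0)
  expect_length(bf2$tree$vertices, 0)
  # size guard
  sx <- synth_ppi_instance(20, 30, seed = 1)
  big <- build_instance(sx$records, sx$annotation)
  expect_error(brute_force_steiner(big), "12")
})

test_that("star-centre betweenness attains the product bound", {
  n <- 7
  ids <- c("hub", sprintf("L%d", 1:n))
  tr <- solution_tree(ids, data.frame(from = "hub", to = ids[-1]))
  S <- ids[2:4]
  T2 <- ids[5:8]
  rep <- brute_force_betweenness(tr, S, T2)
  expect_equal(unname(rep$node_B["hub"]), length(S) * length(T2))
})
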