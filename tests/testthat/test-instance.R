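test_that("edge costs follow the inverse-power confidence transform", {
  expect_equal(edge_cost(100, alpha = 2e6, beta = 2), 200)
  expect_equal(edge_cost(400, alpha = 2e6, beta = 2, in_pathway = TRUE,
                         boost = 0.5), 2e6 / 600^2)
  expect_equal(edge_cost(1, alpha = 7, beta = 1), 7)
  expect_error(edge_cost(-3), "positive")
  expect_error(edge_cost(0), "positive")
  expect_error(edge_cost(100, alpha = 0), "alpha")
})

test_that("edge cost decreases in confidence and increases in alpha", {
  set.seed(42)
  for (k in 1:50) {
    con <- sort(runif(2, 1, 1000))
    a <- sort(runif(2, 0.1, 1e7))
    b <- runif(1, 0.5, 4)
    expect_lt(edge_cost(con[2], a[1], b), edge_cost(con[1], a[1], b))
    expect_lt(edge_cost(con[1], a[1], b), edge_cost(con[1], a[2], b))
  }
})

test_that("node weights are -gamma/degree with a REQUIRED terminal sentinel", {
  expect_equal(node_weight(10, gamma = 5), -0.5)
  expect_equal(node_weight(5, gamma = 5), -1)
  expect_true(is.na(node_weight(3, gamma = 5, is_terminal = TRUE)))
  expect_error(node_weight(0), "positive integer")
  # strictly negative for every positive gamma and degree
  set.seed(7)
  d <- sample(1:500, 40, replace = TRUE)
  g <- runif(40, 0.01, 100)
  for (k in 1:40) expect_lt(node_weight(d[k], g[k]), 0)
})

test_that("build_instance cleans records and assembles the instance", {
  recs <- data.frame(protein_a = c("a", "b", "b", "a", "a"),
                     protein_b = c("b", "c", "a", "a", "b"),
                     con = c(100, 100, 200, 50, 120))
  ann <- pathway_annotation("a", "c")
  inst <- build_instance(recs, ann, nw_params(gamma = 5))
  expect_s3_class(inst, "nw_instance")
  expect_identical(inst$nodes, c("a", "b", "c"))
  expect_identical(inst$terminals, c("a", "c"))
  # self-loop (a,a) dropped; duplicates (a,b),(b,a),(a,b) collapsed to the
  # cheapest cost, i.e. the most confident score 200
  expect_equal(nrow(inst$edges), 2)
  expect_equal(inst$edges$cost[inst$edges$from == "a"], 2e6 / 200^2)
  # middle vertex of the path has degree 2
  expect_equal(unname(inst$weight["b"]), -5 / 2)
  expect_true(all(is.na(inst$weight[inst$terminals])))
  expect_silent(validate_instance(inst))
})

test_that("disconnected inputs are restricted or rejected", {
  recs <- data.frame(protein_a = c("a", "x"), protein_b = c("b", "y"),
                     con = 100)
  inst <- build_instance(recs, pathway_annotation("a", "b"), nw_params())
  expect_identical(inst$nodes, c("a", "b"))
  expect_error(
    build_instance(recs, pathway_annotation("a", "y"), nw_params()),
    "components")
  expect_error(
    build_instance(recs, pathway_annotation("zz", character(0)),
                   nw_params()),
    "no annotated")
})

test_that("objective value sums edge costs minus non-terminal rewards", {
  inst <- two_path_inst(-1)
  via <- solution_tree(c("t1", "t2", "v"),
                       data.frame(from = c("t1", "t2"), to = c("v", "v")))
  direct <- solution_tree(c("t1", "t2"),
                          data.frame(from = "t1", to = "t2"))
  expect_equal(objective_value(inst, via), 21)
  expect_equal(objective_value(inst, direct), 25)
  # single-terminal singleton tree scores zero
  recs <- data.frame(protein_a = "t", protein_b = "u", con = 1)
  single <- build_instance(recs, pathway_annotation("t", character(0)),
                           nw_params(alpha = 1, beta = 1))
  expect_equal(objective_value(single, solution_tree("t")), 0)
  expect_error(objective_value(inst, solution_tree("t1")), "terminals")
})

test_that("objective matches an element-by-element brute-force sum", {
  for (seed in 1:5) {
    inst <- small_random_inst(seed)
    tr <- nwst_solve(inst, seed = seed)
    manual <- 0
    for (k in seq_len(nrow(tr$edges))) {
      hit <- inst$edges$from == tr$edges$from[k] &
        inst$edges$to == tr$edges$to[k]
      manual <- manual + inst$edges$cost[hit]
    }
    for (v in tr$vertices) {
      if (!(v %in% inst$terminals)) manual <- manual - inst$weight[[v]]
    }
    expect_equal(objective_value(inst, tr), manual)
  }
})

test_that("generated instances satisfy the structural invariants", {
  for (seed in 1:10) {
    sx <- synth_ppi_instance(n_vertices = 30, n_edges = 60, seed = seed)
    inst <- build_instance(sx$records, sx$annotation)
    expect_silent(validate_instance(inst))
    expect_true(all(inst$edges$cost > 0))
    nonterm <- setdiff(inst$nodes, inst$terminals)
    expect_true(all(inst$weight[nonterm] < 0))
  }
})
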