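test_that("terminal degree-1 test contracts pendant terminals", {
  # path t1 - a - t2: both outer edges forced, a absorbs terminal status
  inst <- make_inst(data.frame(from = c("t1", "a"), to = c("a", "t2"),
                               cost = c(5, 7)),
                    terminals = c("t1", "t2"))
  r <- terminal_degree1_test(inst)
  expect_identical(r$instance$nodes, "a")
  expect_identical(r$instance$terminals, "a")
  expect_equal(sort(r$ledger$forced_edges$cost), c(5, 7))
  expect_setequal(r$ledger$forced_edges$terminal, c("t1", "t2"))

  # a lone degree-1 terminal is untouched: it may itself be optimal
  single <- make_inst(data.frame(from = "t", to = "u", cost = 3),
                      terminals = "t")
  r1 <- terminal_degree1_test(single)
  expect_identical(r1$instance$nodes, single$nodes)
  expect_equal(nrow(r1$ledger$forced_edges), 0)

  # no terminals at all: no change
  none <- make_inst(data.frame(from = "x", to = "y", cost = 1),
                    terminals = "x")
  none$terminals <- character(0)
  none$weight["x"] <- -1
  r2 <- terminal_degree1_test(none)
  expect_equal(nrow(r2$ledger$forced_edges), 0)
})

test_that("non-terminal degree-1 test deletes unprofitable leaves", {
  # leaf with w <= c goes; leaf with w > c stays
  inst <- make_inst(data.frame(from = c("t", "t", "t"),
                               to = c("u", "v", "z"),
                               cost = c(100, 3, 2)),
                    terminals = "t",
                    weights = c(u = -0.5, v = 5, z = 1))
  r <- nonterminal_degree1_test(inst)
  expect_false("u" %in% r$instance$nodes)   # -0.5 <= 100
  expect_false("z" %in% r$instance$nodes)   # 1 <= 2
  expect_true("v" %in% r$instance$nodes)    # 5 > 3: keeping v pays
  # chain x - y - t: removing x exposes y as a removable leaf
  chain <- make_inst(data.frame(from = c("x", "y"), to = c("y", "t"),
                                cost = c(4, 4)),
                     terminals = "t", weights = c(x = -1, y = -1))
  rc <- nonterminal_degree1_test(chain)
  expect_identical(rc$instance$nodes, "t")
  # without terminals the test never applies
  chain2 <- chain
  chain2$terminals <- character(0)
  chain2$weight["t"] <- -1
  r2 <- nonterminal_degree1_test(chain2)
  expect_identical(r2$instance$nodes, chain2$nodes)
})

test_that("preprocessing is idempotent and strips terminal-centred stars", {
  # reduction-free instance comes back identical with an empty ledger
  inst <- two_path_inst(-1)
  r <- preprocess_instance(inst)
  expect_identical(r$instance$nodes, inst$nodes)
  expect_equal(nrow(r$ledger$forced_edges) + nrow(r$ledger$removed_vertices),
               0)
  r2 <- preprocess_instance(r$instance)
  expect_identical(r2$instance, r$instance)

  # star with terminal centre and negative-weight leaves: all leaves go
  star <- make_inst(data.frame(from = rep("t", 4),
                               to = c("a", "b", "c", "d"),
                               cost = c(10, 20, 30, 40)),
                    terminals = "t")
  rs <- preprocess_instance(star)
  expect_identical(rs$instance$nodes, "t")
  expect_equal(nrow(rs$ledger$removed_vertices), 4)
})

test_that("ledger replay reproduces the reduced instance exactly", {
  for (seed in 1:8) {
    inst <- small_random_inst(seed)
    r <- preprocess_instance(inst)
    rp <- replay_ledger(inst, r$ledger)
    expect_identical(rp$nodes, r$instance$nodes)
    expect_identical(rp$terminals, r$instance$terminals)
    expect_equal(rp$edges$cost, r$instance$edges$cost)
    expect_identical(rp$edges$from, r$instance$edges$from)
    # monotone shrinkage
    expect_lte(length(r$instance$nodes), length(inst$nodes))
    expect_lte(nrow(r$instance$edges), nrow(inst$edges))
  }
})

test_that("preprocessing preserves the brute-force optimum", {
  for (seed in 1:12) {
    inst <- small_random_inst(seed)
    r <- preprocess_instance(inst)
    b_orig <- brute_force_steiner(inst)$objective
    b_red <- brute_force_steiner(r$instance)$objective
    reassembled <- b_red + sum(r$ledger$forced_edges$cost) -
      sum(r$ledger$forced_edges$absorbed_weight)
    expect_equal(reassembled, b_orig, tolerance = 1e-10)
  }
})

test_that("single-pass mode reduces less than or equal to fixpoint mode", {
  for (seed in c(2, 5)) {
    inst <- small_random_inst(seed)
    fp <- preprocess_instance(inst, mode = "fixpoint")
    sp <- preprocess_instance(inst, mode = "single_pass")
    expect_gte(length(sp$instance$nodes), length(fp$instance$nodes))
  }
})
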