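test_that("a lone terminal among repelling vertices stays alone", {
  inst <- make_inst(data.frame(from = c("t", "a", "a"),
                               to = c("a", "b", "c"),
                               cost = c(5, 5, 5)),
                    terminals = "t",
                    weights = c(a = -1, b = -1, c = -1))
  raw <- gw_grow(inst)
  expect_identical(raw$vertices, "t")
  expect_equal(nrow(raw$edges), 0)
  tr <- nwst_solve(inst, preprocess = FALSE)
  expect_identical(tr$vertices, "t")
})

test_that("the mildly penalised via-path beats the expensive direct edge", {
  inst <- two_path_inst(-1)
  # oracle: optimum is the path through v, objective 21
  bf <- brute_force_steiner(inst)
  expect_equal(bf$objective, 21)
  expect_setequal(bf$tree$vertices, c("t1", "t2", "v"))
  # the heuristic attains the optimum here
  tr <- nwst_solve(inst)
  expect_equal(objective_value(inst, tr), 21)
})

test_that("growth is cost-driven: a heavy penalty on the bridge vertex
           does not reroute it, though the oracle knows better", {
  inst <- two_path_inst(-100)
  bf <- brute_force_steiner(inst)
  expect_equal(bf$objective, 25)       # direct edge is optimal
  expect_setequal(bf$tree$vertices, c("t1", "t2"))
  # the moats meet along the cheaper edge pair (10 + 10 < 25) before the
  # direct edge is paid off, and an internal bridge vertex cannot be
  # strong-pruned, so the heuristic keeps v regardless of its weight
  tr <- nwst_solve(inst)
  expect_setequal(tr$vertices, c("t1", "t2", "v"))
  expect_equal(objective_value(inst, tr), 120)
})

test_that("strong pruning applies the reward-update rule at leaves", {
  # keep: leaf reward 5 covers edge cost 3, parent absorbs 5 - 3 = 2
  inst <- make_inst(data.frame(from = c("t", "j"), to = c("j", "i"),
                               cost = c(1, 3)),
                    terminals = "t", weights = c(j = 10, i = 5))
  raw <- solution_tree(c("i", "j", "t"),
                       data.frame(from = c("t", "j"), to = c("j", "i")))
  pr <- strong_prune(raw, inst, seed = 1)
  expect_setequal(pr$vertices, c("t", "j", "i"))
  # cut: leaf reward 5 cannot pay edge cost 7
  inst2 <- make_inst(data.frame(from = c("t", "j"), to = c("j", "i"),
                                cost = c(1, 7)),
                     terminals = "t", weights = c(j = 10, i = 5))
  pr2 <- strong_prune(raw, inst2, seed = 1)
  expect_setequal(pr2$vertices, c("t", "j"))
  # pruning a tree without terminals is an error
  inst3 <- inst
  inst3$terminals <- character(0)
  expect_error(strong_prune(raw, inst3), "terminal")
})

test_that("every leaf of the final tree is a compulsory terminal when all
           non-terminal weights are negative", {
  for (seed in 1:10) {
    inst <- small_random_inst(seed)
    tr <- nwst_solve(inst, seed = seed)
    expect_true(all(inst$terminals %in% tr$vertices))
    if (nrow(tr$edges) > 0) {
      deg <- table(factor(c(tr$edges$from, tr$edges$to),
                          levels = tr$vertices))
      leaves <- names(deg)[deg == 1]
      expect_true(all(leaves %in% inst$terminals))
    }
  }
})

test_that("solver output is deterministic for a fixed seed", {
  inst <- small_random_inst(4)
  a <- nwst_solve(inst, seed = 11)
  b <- nwst_solve(inst, seed = 11)
  expect_identical(a, b)
})

test_that("solver stays within the factor-2 sanity band across split
           ratios, and preprocessing does not change its reach", {
  for (seed in 1:8) {
    inst <- small_random_inst(seed)
    opt <- brute_force_steiner(inst)$objective
    for (s in c(1.5, 2, 4)) {
      tr <- nwst_solve(inst, s = s, seed = seed)
      expect_lte(objective_value(inst, tr), 2 * opt + 1e-9)
    }
    tr_np <- nwst_solve(inst, preprocess = FALSE, seed = seed)
    expect_true(all(inst$terminals %in% tr_np$vertices))
    expect_lte(objective_value(inst, tr_np), 2 * opt + 1e-9)
  }
})

test_that("an instance without terminals yields an empty tree with a
           warning", {
  inst <- two_path_inst(-1)
  inst$terminals <- character(0)
  inst$weight[c("t1", "t2")] <- -1
  expect_warning(tr <- nwst_solve(inst), "terminals")
  expect_equal(length(tr$vertices), 0)
})
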