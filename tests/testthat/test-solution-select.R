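test_that("disjointness is the empty vertex intersection", {
  expect_true(disjoint(c(0, 1), c(2, 3)))
  expect_false(disjoint(c(0, 1), c(1, 2)))
  expect_false(disjoint(c(0, 1), c(0, 1)))
})

test_that("multi-seed greedy picks the heavier disjoint combination", {
  cycles <- cycle_tbl(list(c(0, 1), c(2, 3), c(1, 2)), c(5, 4, 6))
  sol <- select_solution(cycles)
  expect_equal(sol$total_weight, 9L)
  expect_equal(sol$cycles$vertices, list(c(0L, 1L), c(2L, 3L)))
  expect_equal(brute_force_optimum(cycles)$total_weight, 9L)

  single <- cycle_tbl(list(c(0, 1, 2)), 7)
  expect_equal(select_solution(single)$total_weight, 7L)

  # all cycles share a vertex: the single heaviest survives
  shared <- cycle_tbl(list(c(0, 1), c(0, 2), c(0, 3)), c(3, 9, 5))
  sols <- select_solution(shared)
  expect_equal(sols$total_weight, 9L)
  expect_equal(sols$cycles$vertices, list(c(0L, 2L)))
  expect_equal(brute_force_optimum(shared)$total_weight, 9L)
})

test_that("empty input yields the empty solution", {
  empty <- cycle_tbl(list(), integer())
  expect_equal(select_solution(empty)$total_weight, 0L)
  expect_equal(nrow(select_solution(empty)$cycles), 0)
  expect_equal(brute_force_optimum(empty)$total_weight, 0L)
})

test_that("exhaustive optimum selects everything when cycles are disjoint", {
  cycles <- cycle_tbl(list(c(0, 1), c(2, 3), c(4, 5, 6)), c(4, 6, 9))
  opt <- brute_force_optimum(cycles)
  expect_equal(opt$total_weight, 19L)
  expect_equal(nrow(opt$cycles), 3)
  expect_error(brute_force_optimum(cycle_tbl(
    as.list(seq_len(21)), rep(1, 21))), "at most 20")
})

test_that("greedy is bounded by the optimum and by the heaviest cycle", {
  for (s in 1:30) {
    g <- rand_graph(3 + (s %% 6), p = 0.45, seed = 900 + s)
    L <- 2 + (s %% 2)
    ev <- evaluate_cycles(g, L)
    if (nrow(ev) == 0 || nrow(ev) > 15) next
    greedy <- select_solution(ev)
    opt <- brute_force_optimum(ev)
    expect_lte(greedy$total_weight, opt$total_weight)
    expect_gte(greedy$total_weight, max(ev$weight))
    # solution members are pairwise disjoint and drawn from the input
    verts <- unlist(greedy$cycles$vertices)
    expect_equal(anyDuplicated(verts), 0)
    keys <- vapply(ev$vertices, paste, "", collapse = ",")
    expect_true(all(vapply(greedy$cycles$vertices, paste, "",
                           collapse = ",") %in% keys))
    # maximality: no unused cycle is disjoint from all selected
    unused <- setdiff(seq_len(nrow(ev)),
                      match(vapply(greedy$cycles$vertices, paste, "",
                                   collapse = ","), keys))
    for (j in unused) {
      expect_false(disjoint(ev$vertices[[j]], verts))
    }
    # conflict-free instances: greedy attains the optimum
    if (anyDuplicated(unlist(ev$vertices)) == 0) {
      expect_equal(greedy$total_weight, opt$total_weight)
    }
  }
})

test_that("tidy, glance and the assignment table expose the solution", {
  sol <- kex_solve(engineered_fixture("triangle"), L = 3)
  td <- tidy(sol)
  expect_equal(td$length, 3L)
  gl <- glance(sol)
  expect_equal(gl$n_cycles, 1L)
  expect_equal(gl$n_transplants, 3L)
  at <- assignment_table(sol)
  expect_equal(at$recipient_pair, c(0L, 1L, 2L))
  expect_equal(at$donor_pair, c(2L, 0L, 1L))
})
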