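test_that("cohort generation is deterministic and respects constraints", {
  a <- generate_cohort(6, seed = 42)
  b <- generate_cohort(6, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(6, seed = 43)))
  expect_equal(a$pair_id, 0:5)
  expect_silent(validate_cohort(a))
  for (i in seq_len(6)) {
    expect_true(all(lengths(a$donor_hla[[i]]) <= 2))
    # antibodies never target the recipient's own antigens
    own <- unlist(a$recipient_hla[[i]], use.names = FALSE)
    expect_equal(length(intersect(a$recipient_antibodies[[i]], own)), 0)
  }
  expect_true(all(a$donor_age >= 18 & a$donor_age <= 75))
  expect_true(all(a$donor_weight_kg >= 40 & a$donor_weight_kg <= 150))
  expect_error(generate_cohort(1, seed = 1), "at least|>= 2")
  expect_error(generate_cohort(3, seed = 1, pra = 2), "pra")
})

test_that("pra = 0 passes every crossmatch; pra = 1 blocks every external antigen", {
  co0 <- generate_cohort(5, seed = 7, pra = 0)
  g0 <- compute_compatibility_graph(co0)
  expect_true(all(g0$weights[row(g0$weights) != col(g0$weights)] > 0))

  co1 <- generate_cohort(5, seed = 7, pra = 1)
  donors <- kexmatch:::cohort_profiles(co1, "donor")
  recips <- kexmatch:::cohort_profiles(co1, "recipient")
  for (i in 1:5) {
    for (j in 1:5) {
      if (i == j) next
      dag <- unlist(donors[[i]]$hla, use.names = FALSE)
      outside <- setdiff(dag, unlist(recips[[j]]$hla, use.names = FALSE))
      xm <- hla_crossmatch(dag, recips[[j]]$antibodies)
      if (length(outside) > 0) expect_false(xm)
    }
  }
})

test_that("empirical ABO frequencies track the configured distribution", {
  co <- generate_cohort(2500, seed = 99)
  freqs <- table(factor(c(co$donor_abo, co$recipient_abo),
                        levels = c("O", "A", "B", "AB"))) / (2 * 2500)
  expect_equal(unname(freqs["O"]), 0.43, tolerance = 0.02 / 0.43)
  expect_equal(unname(freqs["A"]), 0.40, tolerance = 0.02 / 0.40)
  expect_lt(abs(freqs["B"] - 0.12), 0.02)
  expect_lt(abs(freqs["AB"] - 0.05), 0.02)
})

test_that("crossmatch pass-rate decreases as the antibody panel grows", {
  pass_rate <- vapply(c(0, 0.1, 0.3, 0.6, 1), function(p) {
    co <- generate_cohort(12, seed = 31, pra = p)
    g <- compute_compatibility_graph(co)
    off <- g$weights[row(g$weights) != col(g$weights)]
    mean(off > 0)
  }, numeric(1))
  expect_true(all(diff(pass_rate) <= 0))
  expect_lt(pass_rate[5], pass_rate[1])
})

test_that("engineered fixtures realise their topologies", {
  expect_error(engineered_fixture("nope"), "two_cycle")
  g2 <- compute_compatibility_graph(engineered_fixture("two_cycle"))
  expect_equal(unname(unweighted_adjacency(g2)),
               matrix(c(0L, 1L, 1L, 0L), 2, 2))
  gs <- compute_compatibility_graph(engineered_fixture("star_conflict"))
  ev <- evaluate_cycles(gs, 2)
  expect_equal(ev$vertices[[1]], c(1L, 2L)) # heaviest cycle conflicts
  sol <- select_solution(ev)
  expect_equal(sol$cycles$vertices, list(c(0L, 1L), c(2L, 3L)))
  expect_gt(sol$total_weight, ev$weight[1])
})
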