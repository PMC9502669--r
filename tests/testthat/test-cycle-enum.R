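test_that("unweighted adjacency thresholds weights at zero", {
  expect_equal(unweighted_adjacency(kex_graph(matrix(0, 3, 3))),
               matrix(0L, 3, 3))
  g <- kex_graph(matrix(c(0, 5, 2, 0), 2, 2, byrow = TRUE))
  expect_equal(unname(unweighted_adjacency(g)),
               matrix(c(0L, 1L, 1L, 0L), 2, 2, byrow = TRUE))
  gr <- rand_graph(6, seed = 9)
  expect_equal(unweighted_adjacency(gr), (gr$weights > 0) * 1L,
               ignore_attr = TRUE)
})

test_that("cycle counting is the trace of the L-th adjacency power", {
  two <- kex_graph(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(count_cycles(two, 2), 2)
  tri <- kex_graph(matrix(c(0, 1, 0, 0, 0, 2, 3, 0, 0), 3, 3,
                          byrow = TRUE))
  expect_equal(count_cycles(tri, 3), 3)
  expect_equal(count_cycles(kex_graph(matrix(0, 4, 4)), 2), 0)
  expect_equal(count_cycles(kex_graph(matrix(0, 4, 4)), 3), 0)
  expect_error(count_cycles(two, 4), "2..3")
  expect_error(count_cycles(two, 1), "2..3")
})

test_that("find_cycles lists every rotation with the traversed weight sum", {
  tri <- kex_graph(matrix(c(0, 1, 0, 0, 0, 2, 3, 0, 0), 3, 3,
                          byrow = TRUE))
  raw <- find_cycles(tri, 3)
  expect_equal(nrow(raw), 3)
  expect_equal(raw$weight, rep(6L, 3))
  two <- kex_graph(matrix(c(0, 1, 1, 0), 2, 2))
  raw2 <- find_cycles(two, 2)
  expect_equal(nrow(raw2), 2)
  expect_equal(raw2$weight, c(2L, 2L))
  expect_setequal(vapply(raw2$vertices, paste, "", collapse = ","),
                  c("0,1", "1,0"))
  none <- find_cycles(kex_graph(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)),
                      2)
  expect_equal(nrow(none), 0)
})

test_that("canonicalisation rotates the minimum vertex to the front", {
  expect_equal(canonicalize(c(2L, 0L, 1L)), c(0L, 1L, 2L))
  expect_equal(canonicalize(c(0L, 1L, 2L)), c(0L, 1L, 2L))
  expect_equal(canonicalize(c(5L, 3L)), c(3L, 5L))
  # rotation only: orientation is preserved
  expect_equal(canonicalize(c(2L, 1L, 0L)), c(0L, 2L, 1L))
})

test_that("evaluate_cycles dedups rotations, sorts by weight then lexicographic", {
  tri <- kex_graph(matrix(c(0, 1, 0, 0, 0, 2, 3, 0, 0), 3, 3,
                          byrow = TRUE))
  ev <- evaluate_cycles(tri, 3, k = 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$vertices[[1]], c(0L, 1L, 2L))
  expect_equal(ev$weight, 6L)

  # two disjoint 2-cycles, weights 4 and 7
  w <- matrix(0L, 4, 4)
  w[1, 2] <- w[2, 1] <- 2L
  w[3, 4] <- 3L; w[4, 3] <- 4L
  ev2 <- evaluate_cycles(kex_graph(w), 2, k = 1)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$vertices[[1]], c(2L, 3L))
  expect_equal(ev2$weight, 7L)

  # equal weights: lexicographically smaller canonical form first
  w3 <- matrix(0L, 4, 4)
  w3[1, 2] <- w3[2, 1] <- 2L
  w3[3, 4] <- w3[4, 3] <- 2L
  ev3 <- evaluate_cycles(kex_graph(w3), 2)
  expect_equal(ev3$vertices, list(c(0L, 1L), c(2L, 3L)))
})

test_that("cycle algebra identities hold on seeded random digraphs", {
  for (s in 1:40) {
    n <- 3 + (s %% 8)
    L <- 2 + (s %% 2)
    g <- rand_graph(n, p = 0.35, seed = 500 + s)
    cnt <- count_cycles(g, L)
    raw <- find_cycles(g, L)
    ev <- evaluate_cycles(g, L)
    expect_equal(cnt, oracle_closed_walks(g$weights, L))
    expect_equal(nrow(raw), cnt)
    expect_equal(nrow(ev), cnt %/% L)
    expect_equal(L * nrow(ev), cnt)
    # independent DFS enumerator agrees including order
    expect_equal(ev$vertices, oracle_simple_cycles(g$weights, L)$vertices)
    expect_equal(ev$weight, oracle_simple_cycles(g$weights, L)$weight)
  }
})

test_that("cycle enumeration commutes with vertex relabelling", {
  g <- rand_graph(6, p = 0.5, seed = 77)
  perm <- c(4, 6, 1, 3, 5, 2)
  g2 <- kex_graph(g$weights[perm, perm])
  for (L in 2:3) {
    ev <- evaluate_cycles(g, L)
    ev2 <- evaluate_cycles(g2, L)
    relabel <- order(perm) # new id of old vertex v
    mapped <- lapply(ev$vertices,
                     function(v) canonicalize(as.integer(relabel[v + 1] - 1)))
    key <- function(vs) sort(vapply(vs, paste, "", collapse = ","))
    expect_equal(key(mapped), key(ev2$vertices))
    expect_equal(sort(ev$weight), sort(ev2$weight))
  }
})
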