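# Independent oracles and generators used across the test files.

# Brute-force count of closed walks of length L: checks every one of the
# n^L vertex sequences against the adjacency structure.
oracle_closed_walks <- function(w, L) {
  n <- nrow(w)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), L)))
  count <- 0L
  for (r in seq_len(nrow(seqs))) {
    v <- seqs[r, ]
    ok <- TRUE
    for (t in seq_len(L)) {
      if (w[v[t], v[if (t == L) 1L else t + 1L]] == 0) {
        ok <- FALSE
        break
      }
    }
    if (ok) count <- count + 1L
  }
  count
}

# Early-pruning DFS enumerator of simple cycles of length exactly L,
# canonical (minimum vertex first), each cycle listed once. Returns a tibble
# with 0-based vertices and the traversed weight, sorted by weight
# descending then lexicographic vertex list.
oracle_simple_cycles <- function(w, L) {
  n <- nrow(w)
  out_v <- list()
  out_w <- integer()
  dfs <- function(path, acc) {
    last <- path[length(path)]
    if (length(path) == L) {
      if (w[last, path[1]] > 0) {
        out_v[[length(out_v) + 1L]] <<- as.integer(path - 1L)
        out_w[[length(out_w) + 1L]] <<- acc + w[last, path[1]]
      }
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (v > path[1] && !(v %in% path) && w[last, v] > 0) {
        dfs(c(path, v), acc + w[last, v])
      }
    }
  }
  for (s in seq_len(n)) dfs(s, 0L)
  ord <- order(-out_w,
               vapply(out_v, function(v) paste(sprintf("%06d", v),
                                               collapse = ","), ""))
  tibble::tibble(vertices = out_v[ord], weight = as.integer(out_w[ord]))
}

# Seeded random weighted digraph (no self-loops).
rand_graph <- function(n, p = 0.4, wmax = 9, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(ifelse(stats::runif(n * n) < p,
                       sample.int(wmax, n * n, replace = TRUE), 0L), n, n)
    diag(w) <- 0L
    kex_graph(w)
  })
}

# Random profile pair for crossmatch property tests.
rand_profiles <- function(seed, catalogue = kex_catalogue()) {
  withr::with_seed(seed, {
    codes <- unlist(catalogue$groups, use.names = FALSE)
    donor <- unlist(lapply(catalogue$groups,
                           function(g) unique(sample(g, 2, replace = TRUE))),
                    use.names = FALSE)
    abs_ <- sample(codes, sample(0:8, 1))
    list(donor = donor, antibodies = abs_)
  })
}

# build an arbitrary cycle tibble for selection tests
cycle_tbl <- function(vertices, weights) {
  out <- tibble::tibble(vertices = lapply(vertices, as.integer),
                        weight = as.integer(weights))
  lex <- vapply(out$vertices,
                function(v) paste(sprintf("%06d", v), collapse = ","), "")
  out[order(-out$weight, lex), ]
}

solution_identical <- function(a, b) {
  identical(a$cycles$vertices, b$cycles$vertices) &&
    identical(a$cycles$weight, b$cycles$weight) &&
    identical(a$total_weight, b$total_weight)
}
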