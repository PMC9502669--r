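#' Unweighted adjacency matrix
#'
#' Thresholds the weighted compatibility matrix at zero: entry 1 iff the
#' corresponding edge exists (weight > 0).
#'
#' @param g A `kex_graph`.
#' @return An n x n 0/1 integer matrix.
#' @export
unweighted_adjacency <- function(g) {
  stopifnot(inherits(g, "kex_graph"))
  a <- (g$weights > 0) * 1L
  storage.mode(a) <- "integer"
  a
}

#' Count exchange cycles of a fixed length
#'
#' The number of closed walks of length `L` equals the trace of the L-th
#' power of the unweighted adjacency matrix: entry (i, j) of A^L counts paths
#' of length L from i to j, so the diagonal counts paths returning to their
#' start. On a loop-free digraph with L in 2..3 every such closed walk visits
#' distinct vertices, so the trace counts each exchange cycle once per start
#' vertex ("congruent" duplicates, removed later by [evaluate_cycles()]).
#'
#' In the secret-sharing pipeline this count is the one intermediate value
#' that is declassified (revealed), as it fixes the size of all subsequent
#' oblivious computations.
#'
#' @param g A `kex_graph`.
#' @param L Cycle length (number of edges), 2 or 3 by default.
#' @param max_len Maximum permitted cycle length.
#' @return Integer count, including congruent duplicates.
#' @export
count_cycles <- function(g, L, max_len = 3L) {
  check_cycle_length(L, max_len)
  a <- unweighted_adjacency(g)
  # naive repeated multiplication, L - 1 matrix products
  p <- a
  for (i in seq_len(L - 1)) p <- p %*% a
  as.integer(sum(diag(p)))
}

check_cycle_length <- function(L, max_len) {
  if (L < 2 || L > max_len) {
    stop("cycle length L must lie in 2..", max_len, call. = FALSE)
  }
  invisible(L)
}

#' Enumerate all exchange cycles of a fixed length, with duplicates
#'
#' Lists every closed walk of length `L` over distinct vertices, i.e. each
#' distinct exchange cycle appears `L` times, once per rotation start. The
#' weight of a cycle is the sum of its traversed edge weights; candidate
#' walks using a missing edge are invalid (weight 0) and dropped. The number
#' of returned rows equals [count_cycles()].
#'
#' @inheritParams count_cycles
#' @return A tibble with columns `vertices` (list of 0-based integer
#'   vectors) and `weight`; attribute `n_raw` carries the duplicate-inclusive
#'   count.
#' @export
find_cycles <- function(g, L, max_len = 3L) {
  check_cycle_length(L, max_len)
  w <- g$weights
  n <- g$n
  verts <- list()
  weights <- integer()
  # recursive extension over all vertex tuples with distinct vertices,
  # keeping walks whose consecutive (and closing) edges all exist
  extend <- function(path, acc) {
    if (length(path) == L) {
      if (w[path[L], path[1]] > 0) {
        verts[[length(verts) + 1L]] <<- path - 1L
        weights[[length(weights) + 1L]] <<- acc + w[path[L], path[1]]
      }
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (!(v %in% path) && w[path[length(path)], v] > 0) {
        extend(c(path, v), acc + w[path[length(path)], v])
      }
    }
  }
  for (start in seq_len(n)) extend(start, 0L)
  out <- tibble::tibble(vertices = verts, weight = as.integer(weights))
  attr(out, "n_raw") <- nrow(out)
  attr(out, "L") <- L
  out
}

#' Canonical rotation of a cycle
#'
#' Rotates the vertex list so the minimum vertex index comes first; the
#' traversal direction is preserved. Congruent duplicates (same cycle found
#' from a different start vertex) share a canonical form.
#'
#' @param vertices Integer vector of distinct vertex ids.
#' @return The rotated integer vector.
#' @examples
#' canonicalize(c(2L, 0L, 1L)) # 0 1 2
#' @export
canonicalize <- function(vertices) {
  k <- which.min(vertices)
  if (k == 1) return(vertices)
  c(vertices[k:length(vertices)], vertices[seq_len(k - 1)])
}

#' Deduplicate, sort and truncate the cycle list
#'
#' Removes congruent duplicates by canonical rotation (on a loop-free
#' digraph, exactly `floor(n_raw / L)` unique cycles remain), sorts by weight
#' descending with ties broken by the lexicographically smaller canonical
#' vertex list, and keeps the top `k`.
#'
#' @inheritParams count_cycles
#' @param k Maximum number of cycles to keep (default all).
#' @return A tibble with columns `vertices` (canonical form) and `weight`,
#'   sorted; attributes `n_raw`, `n_unique`, `k`, `L`.
#' @export
evaluate_cycles <- function(g, L, k = Inf, max_len = 3L) {
  stopifnot(k >= 1)
  raw <- find_cycles(g, L, max_len)
  n_raw <- nrow(raw)
  if (n_raw == 0) {
    out <- tibble::tibble(vertices = list(), weight = integer())
  } else {
    canon <- purrr::map(raw$vertices, canonicalize)
    key <- purrr::map_chr(canon, paste, collapse = ",")
    keep <- !duplicated(key)
    out <- tibble::tibble(vertices = canon[keep],
                          weight = raw$weight[keep])
    lex <- purrr::map_chr(out$vertices, cycle_lex_key)
    out <- out[order(-out$weight, lex), ]
    if (is.finite(k)) out <- dplyr::slice_head(out, n = as.integer(k))
  }
  attr(out, "n_raw") <- n_raw
  attr(out, "n_unique") <- n_raw %/% L
  attr(out, "k") <- k
  attr(out, "L") <- L
  out
}

# Fixed-width key so lexicographic string order matches numeric vector order.
cycle_lex_key <- function(v) paste(sprintf("%06d", v), collapse = ",")
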