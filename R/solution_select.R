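#' Vertex-disjointness of two cycles
#'
#' Two exchange cycles can both be transplanted only if no donor-recipient
#' pair appears in both.
#'
#' @param c1,c2 Integer vectors of vertex ids.
#' @return `TRUE` iff the vertex sets are disjoint.
#' @export
disjoint <- function(c1, c2) {
  length(intersect(c1, c2)) == 0L
}

#' Greedy selection of a vertex-disjoint cycle set
#'
#' The final phase: from the deduplicated, weight-sorted cycle list, build
#' one candidate set per cycle. Candidate i is seeded with cycle i and
#' extended by scanning all remaining cycles in descending-weight order,
#' adding each cycle that is vertex-disjoint from every member so far. The
#' candidate with the largest total weight wins (ties: fewer cycles, then
#' the earliest seed in the sorted order). The result is maximal: no
#' remaining cycle is disjoint from all selected ones. This is a locally
#' optimal (greedy) solution; [brute_force_optimum()] gives the global one
#' on small instances.
#'
#' @param unique_cycles Output of [evaluate_cycles()]: deduplicated,
#'   weight-descending tibble with `vertices` and `weight`.
#' @return An object of class `kex_solution`.
#' @export
select_solution <- function(unique_cycles) {
  m <- nrow(unique_cycles)
  if (m == 0) return(new_kex_solution(unique_cycles[0, ]))
  candidates <- purrr::map(seq_len(m), function(s) {
    members <- s
    used <- unique_cycles$vertices[[s]]
    for (j in seq_len(m)) {
      if (j != s && disjoint(unique_cycles$vertices[[j]], used)) {
        members <- c(members, j)
        used <- c(used, unique_cycles$vertices[[j]])
      }
    }
    members
  })
  totals <- purrr::map_int(candidates, ~ sum(unique_cycles$weight[.x]))
  sizes <- lengths(candidates)
  best <- order(-totals, sizes, seq_len(m))[1]
  members <- sort(candidates[[best]]) # slot order = descending weight
  new_kex_solution(unique_cycles[members, ])
}

#' Exhaustive optimum over disjoint cycle subsets
#'
#' Maximises total weight over all vertex-disjoint subsets of the cycle
#' list by exhaustive enumeration. Intended as the optimality oracle for
#' small instances; refuses lists with more than 20 cycles.
#'
#' @inheritParams select_solution
#' @return A `kex_solution` with the globally optimal total weight.
#' @export
brute_force_optimum <- function(unique_cycles) {
  m <- nrow(unique_cycles)
  if (m > 20) {
    stop("brute_force_optimum supports at most 20 cycles; ",
         "reduce the instance", call. = FALSE)
  }
  if (m == 0) return(new_kex_solution(unique_cycles[0, ]))
  best_members <- integer()
  best_total <- 0L
  for (mask in 0:(2^m - 1)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) > 0)
    verts <- unlist(unique_cycles$vertices[members])
    if (anyDuplicated(verts)) next
    total <- sum(unique_cycles$weight[members])
    if (total > best_total ||
        (total == best_total && length(members) < length(best_members))) {
      best_total <- total
      best_members <- members
    }
  }
  new_kex_solution(unique_cycles[best_members, ])
}

new_kex_solution <- function(cycles, declassified = NULL) {
  cycles <- tibble::as_tibble(cycles[, c("vertices", "weight")])
  structure(
    list(cycles = cycles,
         total_weight = as.integer(sum(cycles$weight)),
         declassified = declassified),
    class = "kex_solution"
  )
}

#' @export
print.kex_solution <- function(x, ...) {
  cat("<kex_solution> ", nrow(x$cycles), " cycle(s), total weight ",
      x$total_weight, "\n", sep = "")
  for (i in seq_len(nrow(x$cycles))) {
    cat("  (", paste(x$cycles$vertices[[i]], collapse = " -> "),
        ")  w = ", x$cycles$weight[i], "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a kidney-exchange solution
#'
#' @param x A `kex_solution`.
#' @param ... Unused.
#' @return `tidy()`: one row per selected cycle with `cycle`, `vertices`,
#'   `length`, `weight`. `glance()`: one row with `total_weight`, `n_cycles`,
#'   `n_transplants`.
#' @method tidy kex_solution
#' @export
tidy.kex_solution <- function(x, ...) {
  tibble::tibble(
    cycle = seq_len(nrow(x$cycles)),
    vertices = x$cycles$vertices,
    length = lengths(x$cycles$vertices),
    weight = x$cycles$weight
  )
}

#' @rdname tidy.kex_solution
#' @method glance kex_solution
#' @export
glance.kex_solution <- function(x, ...) {
  tibble::tibble(
    total_weight = x$total_weight,
    n_cycles = nrow(x$cycles),
    n_transplants = sum(lengths(x$cycles$vertices))
  )
}

#' Per-recipient donor assignment implied by a solution
#'
#' Each selected cycle assigns the donor of every member pair to the
#' recipient of the next pair along the cycle.
#'
#' @param solution A `kex_solution`.
#' @return A tibble with columns `recipient_pair` and `donor_pair`.
#' @export
assignment_table <- function(solution) {
  rows <- purrr::map(solution$cycles$vertices, function(v) {
    tibble::tibble(recipient_pair = c(v[-1], v[1]), donor_pair = v)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(recipient_pair = integer(), donor_pair = integer()))
  }
  dplyr::arrange(out, .data$recipient_pair)
}
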