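#' Build the weighted compatibility digraph
#'
#' Evaluates every ordered combination (donor of pair i, recipient of pair j),
#' i != j, and stores the resulting edge weight in an n x n adjacency matrix.
#' Entry (i, j) > 0 means the donor of pair i can give to the recipient of
#' pair j, with larger weights indicating better expected transplant quality.
#' Diagonal entries are 0: a pair in the exchange pool is by definition
#' incompatible internally.
#'
#' @param cohort A cohort tibble as returned by [generate_cohort()] or
#'   [read_cohort()]; `pair_id` must be the contiguous 0-based vertex ids.
#' @param cfg A [kex_weights()] configuration.
#' @param catalogue A [kex_catalogue()].
#' @return An object of class `kex_graph`: list with `n`, `pair_ids`, and the
#'   integer `weights` matrix.
#' @examples
#' g <- compute_compatibility_graph(engineered_fixture("two_cycle"))
#' g$weights
#' @export
compute_compatibility_graph <- function(cohort, cfg = kex_weights(),
                                        catalogue = kex_catalogue()) {
  cohort <- validate_cohort(cohort, catalogue)
  n <- nrow(cohort)
  donors <- cohort_profiles(cohort, "donor")
  recips <- cohort_profiles(cohort, "recipient")
  w <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        w[i, j] <- edge_weight(donors[[i]], recips[[j]], cfg, catalogue)
      }
    }
  }
  dimnames(w) <- list(cohort$pair_id, cohort$pair_id)
  structure(list(n = n, pair_ids = cohort$pair_id, weights = w),
            class = "kex_graph")
}

#' Construct a compatibility graph from a weight matrix
#'
#' Wraps an already-computed non-negative integer matrix as a `kex_graph`,
#' useful for algorithmic tests that need direct control of the topology.
#'
#' @param weights Square matrix of non-negative integers; diagonal is zeroed.
#' @return A `kex_graph`.
#' @export
kex_graph <- function(weights) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == ncol(weights), all(weights >= 0))
  diag(weights) <- 0L
  storage.mode(weights) <- "integer"
  n <- nrow(weights)
  structure(list(n = n, pair_ids = 0:(n - 1), weights = weights),
            class = "kex_graph")
}

#' @export
print.kex_graph <- function(x, ...) {
  cat("<kex_graph> ", x$n, " pairs, ", sum(x$weights > 0), " edges\n", sep = "")
  print(x$weights)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the edge list of a compatibility graph
#'
#' @param x A `kex_graph`.
#' @param ... Unused.
#' @return A tibble with columns `donor_pair`, `recipient_pair`, `weight`,
#'   one row per existing (weight > 0) edge.
#' @method tidy kex_graph
#' @export
tidy.kex_graph <- function(x, ...) {
  idx <- which(x$weights > 0, arr.ind = TRUE)
  tibble::tibble(
    donor_pair = x$pair_ids[idx[, 1]],
    recipient_pair = x$pair_ids[idx[, 2]],
    weight = x$weights[idx]
  ) |>
    dplyr::arrange(.data$donor_pair, .data$recipient_pair)
}

# Extract per-row profile lists from a cohort tibble.
cohort_profiles <- function(cohort, role = c("donor", "recipient")) {
  role <- match.arg(role)
  purrr::map(seq_len(nrow(cohort)), function(i) {
    p <- list(
      hla = cohort[[paste0(role, "_hla")]][[i]],
      abo = cohort[[paste0(role, "_abo")]][i],
      age = cohort[[paste0(role, "_age")]][i],
      sex = cohort[[paste0(role, "_sex")]][i],
      weight_kg = cohort[[paste0(role, "_weight_kg")]][i]
    )
    if (role == "recipient") p$antibodies <- cohort$recipient_antibodies[[i]]
    p
  })
}
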