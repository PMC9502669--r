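#' Closed-form circuit-cost model
#'
#' The analytic per-phase gate counts of the four-phase protocol, as
#' closed-form functions of the public problem sizes:
#'
#' * HLA crossmatch (`matchHLA`): `2 * hla_size` AND gates total
#'   (one SIMD AND per catalogued antigen plus the OR-reduction tree, ORs
#'   costed as ANDs), circuit depth `log2(hla_size) + 1`.
#' * Compatibility combination: per ordered pair, 5 multiplications,
#'   5 additions, 1 comparison, 1 AND and 1 MUX, times `n_pairs^2`.
#' * Cycle computation: `n_pairs^3` multiplications,
#'   `n_pairs^3 - n_pairs^2` additions, `n_pairs^2` comparisons and MUX
#'   gates (unweighted-adjacency thresholding).
#' * Cycle evaluation (dedup + top-k sort):
#'   `n_cycles * (n_unique + (n_cycles + 1) * L * (L - 1))` comparisons,
#'   `n_cycles * (n_cycles + 1) * L * (L - 1)` AND gates,
#'   `n_cycles * (n_cycles + 1) * (L - 1)` OR gates,
#'   `n_cycles * n_unique * (1 + L) + n_cycles` MUX gates.
#' * Solution evaluation: `n_unique^2` ADD gates,
#'   `n_unique^2 * L^2 + n_unique` comparisons,
#'   `4 * n_unique^2 + n_unique` MUX gates, `n_unique^2 * L^2` OR gates.
#'
#' Communication is charged at the garbled-circuit rate of `1.5 * kappa`
#' bits per AND-equivalent gate (AND, OR, MUX); XOR is free.
#'
#' @param n_pairs Number of donor-recipient pairs.
#' @param hla_size Catalogue size (default 50).
#' @param L Cycle length.
#' @param n_cycles Duplicate-inclusive cycle count (trace of A^L).
#' @param n_unique Number of unique cycles, `floor(n_cycles / L)`.
#' @param k Top-k bound (informational).
#' @param kappa Security parameter.
#' @return A `kex_cost_report` tibble, one row per phase, with gate counts,
#'   depth and `comm_bits`.
#' @examples
#' closed_form_costs(n_pairs = 4, L = 3, n_cycles = 3, n_unique = 1)
#' @export
closed_form_costs <- function(n_pairs, hla_size = 50L, L = 3L,
                              n_cycles = 0L, n_unique = n_cycles %/% L,
                              k = n_unique, kappa = 128L) {
  stopifnot(n_pairs >= 0, hla_size >= 1, n_cycles >= 0, n_unique >= 0)
  np <- n_pairs; cy <- n_cycles; un <- n_unique
  phases <- tibble::tribble(
    ~phase, ~and_gates, ~or_gates, ~mux_gates, ~comparisons,
    ~multiplications, ~additions, ~depth,
    "matchHLA", 2 * hla_size, 0, 0, 0, 0, 0, log2(hla_size) + 1,
    "combine", np^2, 0, np^2, np^2, 5 * np^2, 5 * np^2, NA,
    "cycle_count", 0, 0, np^2, np^2, np^3, np^3 - np^2, NA,
    "cycle_eval", cy * (cy + 1) * L * (L - 1), cy * (cy + 1) * (L - 1),
    cy * un * (1 + L) + cy, cy * (un + (cy + 1) * L * (L - 1)),
    0, 0, NA,
    "solution", 0, un^2 * L^2, 4 * un^2 + un, un^2 * L^2 + un,
    0, un^2, NA
  )
  phases$comm_bits <- 1.5 * kappa *
    (phases$and_gates + phases$or_gates + phases$mux_gates)
  structure(phases, class = c("kex_cost_report", class(phases)),
            kappa = kappa, counted = FALSE)
}

#' Counted cost report of a secret-sharing session
#'
#' Tabulates the gates, comparisons, multiplications, conversions and
#' communication actually executed by a [kex_mpc_session()], per phase.
#' Conversions between arithmetic and Boolean sharing are counted in their
#' own columns (`conversions`, `conversion_ands`) since the closed-form
#' model does not cover them.
#'
#' @param sess A `kex_mpc_session` after a pipeline run.
#' @return A `kex_cost_report` tibble, one row per executed phase.
#' @export
cost_report <- function(sess) {
  stopifnot(inherits(sess, "kex_mpc_session"))
  rows <- purrr::imap(sess$counts, function(cnt, phase) {
    tibble::tibble(phase = phase, !!!as.list(cnt))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("kex_cost_report", class(out)),
            kappa = sess$kappa, bitlen = sess$bitlen, counted = TRUE)
}

#' @export
print.kex_cost_report <- function(x, ...) {
  kind <- if (isTRUE(attr(x, "counted"))) "counted" else "closed-form"
  cat("<kex_cost_report> (", kind, ", kappa = ", attr(x, "kappa"), ")\n",
      sep = "")
  NextMethod()
}
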