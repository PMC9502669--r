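#' Solve a kidney-exchange instance end to end
#'
#' Runs the full four-phase pipeline on a cohort: compatibility matching,
#' cycle counting, cycle evaluation (dedup, sort, top-k) and greedy
#' vertex-disjoint solution selection. With `backend = "clear"` everything
#' runs in cleartext; with `backend = "mpc-sim"` the identical computation
#' is executed on the simulated two-party secret-sharing backend (see
#' [run_pipeline_mpc()]) and the reconstructed solution is returned together
#' with a counted cost report.
#'
#' @param cohort A cohort tibble ([generate_cohort()], [read_cohort()],
#'   [engineered_fixture()]).
#' @param L Cycle length, 2 or 3 by default.
#' @param k Keep only the k heaviest unique cycles (default all).
#' @param cfg A [kex_weights()].
#' @param backend `"clear"` or `"mpc-sim"`.
#' @param seed Share/dealer randomness seed for the mpc-sim backend.
#' @param bitlen,kappa Ring bit length and security parameter (mpc-sim).
#' @param max_len Maximum permitted cycle length (override to exceed 3).
#' @param catalogue A [kex_catalogue()].
#' @return A `kex_solution`; for the mpc-sim backend the counted
#'   `kex_cost_report` is attached as attribute `cost`.
#' @examples
#' sol <- kex_solve(engineered_fixture("triangle"), L = 3)
#' glance(sol)
#' @export
kex_solve <- function(cohort, L = 3L, k = Inf, cfg = kex_weights(),
                      backend = c("clear", "mpc-sim"), seed = 1L,
                      bitlen = 32L, kappa = 128L, max_len = 3L,
                      catalogue = kex_catalogue()) {
  backend <- match.arg(backend)
  if (backend == "clear") {
    g <- compute_compatibility_graph(cohort, cfg, catalogue)
    cycles <- evaluate_cycles(g, L, k, max_len)
    sol <- select_solution(cycles)
    attr(sol, "n_raw") <- attr(cycles, "n_raw")
    sol
  } else {
    res <- run_pipeline_mpc(cohort, cfg, L, k, seed, bitlen, kappa,
                            max_len, catalogue)
    sol <- res$solution
    attr(sol, "cost") <- res$cost
    sol
  }
}
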