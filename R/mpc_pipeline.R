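#' Run the matching pipeline on the simulated secret-sharing backend
#'
#' Executes all four phases on secret shares: HLA crossmatching as a SIMD
#' Boolean circuit (per ordered pair: one AND per catalogued antigen, an OR
#' tree, one inversion), criterion scoring via small Boolean/arithmetic
#' subcircuits, edge-weight combination in the arithmetic domain (five share
#' multiplications, five additions, one multiplexer per ordered pair), cycle
#' counting by naive powers of the shared unweighted adjacency matrix with
#' the trace declassified, oblivious deduplicated top-k sorting by a stable
#' rank circuit, and oblivious multi-seed greedy selection of a
#' vertex-disjoint cycle set. Only two values are ever declassified: the raw
#' cycle count (revealed, as in the underlying protocol design, because it
#' fixes the sizes of all later circuits) and the final solution.
#'
#' The reconstructed solution is bit-for-bit identical to the cleartext
#' backend's ([kex_solve()] with `backend = "clear"`).
#'
#' @param cohort A cohort tibble.
#' @param cfg A [kex_weights()].
#' @param L Cycle length (2 or 3).
#' @param k Keep only the k heaviest unique cycles (default all).
#' @param seed Integer seed for share and dealer randomness.
#' @param bitlen Ring bit length (<= 32); an error is raised if the
#'   analytic value bound for this instance does not fit in signed range.
#' @param kappa Security parameter for the communication cost model.
#' @param max_len Maximum permitted cycle length.
#' @param catalogue A [kex_catalogue()].
#' @return A list with elements `solution` (a `kex_solution`), `cost`
#'   (a [cost_report()] tibble of counted gates), and `session`.
#' @export
run_pipeline_mpc <- function(cohort, cfg = kex_weights(), L = 3L, k = Inf,
                             seed = 1L, bitlen = 32L, kappa = 128L,
                             max_len = 3L, catalogue = kex_catalogue()) {
  check_cycle_length(L, max_len)
  cohort <- validate_cohort(cohort, catalogue)
  n <- nrow(cohort)
  sess <- kex_mpc_session(seed, bitlen, kappa)

  # analytic overflow bound: every intermediate must stay in signed range
  m_bound <- if (L == 2) choose(n, 2) else 2 * choose(n, 3)
  bound <- max(n^L, m_bound, 2000,
               m_bound * L * max_edge_weight(cfg))
  if (bound >= 2^(bitlen - 1)) {
    stop("instance may overflow the ", bitlen,
         "-bit ring; use a larger bitlength", call. = FALSE)
  }

  enc <- encode_cohort_inputs(sess, cohort, catalogue)
  combos <- expand_combos(n)
  edge <- mpc_phase_matching(sess, enc, combos, cfg)
  cc <- mpc_phase_cycle_count(sess, edge, combos, n, L)
  if (cc$count == 0) {
    sol <- new_kex_solution(
      tibble::tibble(vertices = list(), weight = integer()),
      declassified = sess$declassified
    )
    return(list(solution = sol, cost = cost_report(sess), session = sess))
  }
  sl <- mpc_phase_cycle_eval(sess, edge, cc, combos, n, L, k)
  sol <- mpc_phase_solution(sess, sl)
  list(solution = sol, cost = cost_report(sess), session = sess)
}

## ---- input encoding ----------------------------------------------------

# Secret-share the cohort's bit encodings: antigen/antibody incidence
# vectors over the catalogue, ABO one-hot bits, age-category and sex bits,
# and integer weights (0.1 kg resolution).
encode_cohort_inputs <- function(sess, cohort, catalogue) {
  n <- nrow(cohort)
  codes <- catalogue_codes(catalogue)
  H <- length(codes)
  inc <- function(sets) {
    m <- matrix(0, H, n)
    for (i in seq_len(n)) m[, i] <- as.numeric(codes %in% sets[[i]])
    m
  }
  donor_ag <- inc(purrr::map(cohort$donor_hla, unlist, use.names = FALSE))
  recip_ag <- inc(purrr::map(cohort$recipient_hla, unlist,
                             use.names = FALSE))
  recip_ab <- inc(cohort$recipient_antibodies)
  onehot <- function(x) {
    vapply(c("O", "A", "B", "AB"), function(g) as.numeric(x == g),
           numeric(n))
  }
  cfg_rows <- function(m) new_bshares_matrix(sess, m)
  list(
    n = n, H = H,
    group_rows = split(seq_len(H),
                       rep(names(catalogue$groups),
                           lengths(catalogue$groups))),
    donor_ag = cfg_rows(donor_ag),
    recip_ag = cfg_rows(recip_ag),
    recip_ab = cfg_rows(recip_ab),
    donor_abo = cfg_rows(t(onehot(cohort$donor_abo))),
    recip_abo = cfg_rows(t(onehot(cohort$recipient_abo))),
    donor_senior = share_bool(sess, as.numeric(cohort$donor_age >= 55)),
    recip_senior = share_bool(sess,
                              as.numeric(cohort$recipient_age >= 55)),
    donor_male = share_bool(sess, as.numeric(cohort$donor_sex == "M")),
    recip_male = share_bool(sess, as.numeric(cohort$recipient_sex == "M")),
    donor_wt = share_arith(sess, round(cohort$donor_weight_kg * 10)),
    recip_wt = share_arith(sess, round(cohort$recipient_weight_kg * 10))
  )
}

new_bshares_matrix <- function(sess, m) {
  sh <- share_bool(sess, as.numeric(m))
  new_bshares(matrix(sh$b0, nrow(m), ncol(m)),
              matrix(sh$b1, nrow(m), ncol(m)))
}

bmat_row <- function(x, row, cols) {
  new_bshares(x$b0[row, cols], x$b1[row, cols])
}

expand_combos <- function(n) {
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  grid <- grid[grid$i != grid$j, ]
  idx_map <- matrix(0L, n, n)
  idx_map[cbind(grid$i, grid$j)] <- seq_len(nrow(grid))
  list(i = grid$i, j = grid$j, P = nrow(grid), idx_map = idx_map)
}

# sum a list of arithmetic shares element-wise
sum_shares <- function(sess, xs) {
  acc <- xs[[1]]
  for (t in xs[-1]) acc <- add_shares(sess, acc, t)
  acc
}

## ---- phase 1: compatibility matching ----------------------------------

mpc_phase_matching <- function(sess, enc, combos, cfg) {
  P <- combos$P
  i_idx <- combos$i
  j_idx <- combos$j
  M <- sess$M

  # HLA crossmatch: SIMD AND per antigen, OR tree, inversion
  set_phase(sess, "matchHLA")
  hits <- lapply(seq_len(enc$H), function(a) {
    and_shares(sess, bmat_row(enc$donor_ag, a, i_idx),
               bmat_row(enc$recip_ab, a, j_idx))
  })
  xm <- not_share(sess, or_reduce(sess, hits))
  charge(sess, depth = ceiling(log2(enc$H)) + 1)

  # criterion subcircuits (reconstructions of the per-criterion protocols)
  set_phase(sess, "criteria")
  mm_bits <- lapply(seq_len(enc$H), function(a) {
    and_shares(sess, bmat_row(enc$donor_ag, a, i_idx),
               not_share(sess, bmat_row(enc$recip_ag, a, j_idx)))
  })
  mm_count <- sum_shares(sess, lapply(mm_bits, function(b) b2a_bit(sess, b)))
  score_hla <- share_public(sess, rep(cfg$bins_hla[1], P))
  thresholds <- c(1, 3, 5)
  for (t in seq_along(thresholds)) {
    ge <- not_share(sess,
                    msb_bit(sess, add_public(sess, mm_count,
                                             -thresholds[t])))
    delta <- cfg$bins_hla[t + 1] - cfg$bins_hla[t]
    score_hla <- add_shares(sess, score_hla,
                            mul_public(sess, b2a_bit(sess, ge), delta))
  }

  abo_bit <- function(src, class, idx) bmat_row(src, class, idx)
  dO <- abo_bit(enc$donor_abo, 1, i_idx)
  dA <- abo_bit(enc$donor_abo, 2, i_idx)
  dB <- abo_bit(enc$donor_abo, 3, i_idx)
  dAB <- abo_bit(enc$donor_abo, 4, i_idx)
  rA <- abo_bit(enc$recip_abo, 2, j_idx)
  rB <- abo_bit(enc$recip_abo, 3, j_idx)
  rAB <- abo_bit(enc$recip_abo, 4, j_idx)
  compat <- or_shares(sess,
    or_shares(sess, dO, and_shares(sess, dA, or_shares(sess, rA, rAB))),
    or_shares(sess, and_shares(sess, dB, or_shares(sess, rB, rAB)),
              and_shares(sess, dAB, rAB)))
  score_abo <- add_public(
    sess,
    mul_public(sess, b2a_bit(sess, compat),
               cfg$scores_abo[1] - cfg$scores_abo[2]),
    cfg$scores_abo[2])

  three_way <- function(d_bit, r_bit, scores) {
    same <- not_share(sess, xor_shares(sess, d_bit, r_bit))
    fav <- and_shares(sess, not_share(sess, d_bit), r_bit)
    unf <- and_shares(sess, d_bit, not_share(sess, r_bit))
    sum_shares(sess, list(
      mul_public(sess, b2a_bit(sess, same), scores[1]),
      mul_public(sess, b2a_bit(sess, fav), scores[2]),
      mul_public(sess, b2a_bit(sess, unf), scores[3])
    ))
  }
  ds <- bshares_subset(enc$donor_senior, i_idx)
  rs <- bshares_subset(enc$recip_senior, j_idx)
  score_age <- three_way(ds, rs, cfg$scores_age)
  # sex: favourable middle case is male donor -> female recipient
  dm <- bshares_subset(enc$donor_male, i_idx)
  rm_ <- bshares_subset(enc$recip_male, j_idx)
  same_sex <- not_share(sess, xor_shares(sess, dm, rm_))
  mf <- and_shares(sess, dm, not_share(sess, rm_))
  fm <- and_shares(sess, not_share(sess, dm), rm_)
  score_sex <- sum_shares(sess, list(
    mul_public(sess, b2a_bit(sess, same_sex), cfg$scores_sex[1]),
    mul_public(sess, b2a_bit(sess, mf), cfg$scores_sex[2]),
    mul_public(sess, b2a_bit(sess, fm), cfg$scores_sex[3])
  ))
  wdiff <- add_public(
    sess,
    sub_shares(sess, ashares_subset(enc$donor_wt, i_idx),
               ashares_subset(enc$recip_wt, j_idx)),
    round(cfg$weight_margin_kg * 10))
  wge <- not_share(sess, msb_bit(sess, wdiff))
  score_wt <- add_public(
    sess,
    mul_public(sess, b2a_bit(sess, wge),
               cfg$scores_weight[1] - cfg$scores_weight[2]),
    cfg$scores_weight[2])

  # combine: five multiplications, five additions, one multiplexer per pair
  set_phase(sess, "combine")
  wsh <- share_arith(sess, cfg$w)
  wrep <- function(c_) new_ashares(rep(wsh$s0[c_], P), rep(wsh$s1[c_], P),
                                   sess$bitlen)
  scores <- list(score_hla, score_abo, score_age, score_sex, score_wt)
  terms <- lapply(seq_along(scores), function(c_) {
    mul_shares(sess, scores[[c_]], wrep(c_))
  })
  esum <- add_public(sess, sum_shares(sess, terms), cfg$baseline)
  charge(sess, add = P) # baseline addition
  xm_a <- b2a_bit(sess, xm)
  edge <- mul_shares(sess, xm_a, esum, count_as = "mux")
  list(edge = edge, xm = xm)
}

## ---- phase 2: cycle computation ---------------------------------------

mpc_phase_cycle_count <- function(sess, edge, combos, n, L) {
  set_phase(sess, "cycle_count")
  adjb <- nz_bit(sess, edge$edge)
  adjA_flat <- b2a_bit(sess, adjb)
  Am0 <- matrix(0, n, n); Am1 <- matrix(0, n, n)
  Am0[cbind(combos$i, combos$j)] <- adjA_flat$s0
  Am1[cbind(combos$i, combos$j)] <- adjA_flat$s1
  A <- new_ashares(Am0, Am1, sess$bitlen)
  # naive repeated matrix multiplication on shares
  Pm <- A
  for (step in seq_len(L - 1)) Pm <- mat_mul_shares(sess, Pm, A, n)
  diag_idx <- cbind(seq_len(n), seq_len(n))
  tr <- new_ashares(sum(Pm$s0[diag_idx]) %% sess$M,
                    sum(Pm$s1[diag_idx]) %% sess$M, sess$bitlen)
  charge(sess, add = n - 1)
  count <- as.integer(declassify(sess, tr, "cycle_count"))
  list(count = count, adjb = adjb)
}

mat_mul_shares <- function(sess, X, Y, n) {
  i <- rep(rep(seq_len(n), times = n), times = n) # row of X
  j <- rep(seq_len(n), each = n * n)              # col of Y
  k <- rep(rep(seq_len(n), each = n), times = n)  # contraction index
  xs <- new_ashares(X$s0[cbind(i, k)], X$s1[cbind(i, k)], sess$bitlen)
  ys <- new_ashares(Y$s0[cbind(k, j)], Y$s1[cbind(k, j)], sess$bitlen)
  prod <- mul_shares(sess, xs, ys)
  grp <- (j - 1) * n + i
  charge(sess, add = n^3 - n^2)
  s0 <- rowsum(prod$s0, grp)[, 1] %% sess$M
  s1 <- rowsum(prod$s1, grp)[, 1] %% sess$M
  new_ashares(matrix(s0, n, n), matrix(s1, n, n), sess$bitlen)
}

## ---- phase 3: cycle evaluation ----------------------------------------

# canonical cycle candidates (minimum vertex first), lexicographic order
gen_candidates <- function(n, L) {
  if (L == 2) {
    cand <- t(utils::combn(n, 2))
  } else {
    rows <- list()
    for (a in seq_len(n - 2)) {
      rest <- (a + 1):n
      for (b in rest) for (c_ in rest) {
        if (b != c_) rows[[length(rows) + 1L]] <- c(a, b, c_)
      }
    }
    cand <- do.call(rbind, rows)
  }
  cand[do.call(order, as.data.frame(cand)), , drop = FALSE]
}

mpc_phase_cycle_eval <- function(sess, edge, cc, combos, n, L, k) {
  set_phase(sess, "cycle_eval")
  cand <- gen_candidates(n, L)
  m <- nrow(cand)
  u <- cc$count %/% L
  u_eff <- as.integer(min(u, k))
  bl <- sess$bitlen

  # validity bit and weight sum of each candidate closed walk
  edge_pos <- function(col) {
    from <- cand[, col]
    to <- cand[, if (col == L) 1 else col + 1]
    combos$idx_map[cbind(from, to)]
  }
  valid <- bshares_subset(cc$adjb, edge_pos(1))
  wsum <- ashares_subset(edge$edge, edge_pos(1))
  for (col in 2:L) {
    pos <- edge_pos(col)
    valid <- and_shares(sess, valid, bshares_subset(cc$adjb, pos))
    wsum <- add_shares(sess, wsum, ashares_subset(edge$edge, pos))
  }
  W <- mul_shares(sess, b2a_bit(sess, valid), wsum, count_as = "mux")

  # stable descending rank: rank_i = #{j : W_j > W_i} + #{j < i : W_j = W_i}
  if (m == 1) {
    rank <- share_public(sess, 0)
  } else {
    pi <- rep(seq_len(m), times = m)
    pj <- rep(seq_len(m), each = m)
    keep <- pi != pj
    pi <- pi[keep]; pj <- pj[keep]
    diff <- sub_shares(sess, ashares_subset(W, pi), ashares_subset(W, pj))
    charge(sess, cmp = length(pi))
    words <- a2b(sess, diff)
    lt <- bword_bit(words, bl) # [W_i < W_j]
    nzb <- or_reduce(sess,
                     lapply(seq_len(bl), function(r) bword_bit(words, r)))
    eq <- not_share(sess, nzb)
    gt_a <- b2a_bit(sess, lt)
    eq_a <- mul_public_vec(sess, b2a_bit(sess, eq), as.numeric(pj < pi))
    contrib <- add_shares(sess, gt_a, eq_a)
    rank <- rowsum_ashares(sess, contrib, pi, m)
  }

  # oblivious permutation: indicator e[s, i] = [rank_i == s], slots 0..u_eff-1
  rwords <- a2b(sess, rank)
  idx_i <- rep(seq_len(m), times = u_eff)
  s_of <- rep(0:(u_eff - 1), each = m)
  acc <- NULL
  for (r in seq_len(bl)) {
    srow_pub <- bit_decompose(s_of, bl)[r, ]
    bitr <- new_bshares(rwords$m0[r, idx_i], rwords$m1[r, idx_i])
    match_r <- not_share(sess, new_bshares((bitr$b0 + srow_pub) %% 2,
                                           bitr$b1))
    acc <- if (is.null(acc)) match_r else and_shares(sess, acc, match_r)
  }
  E <- b2a_bit(sess, acc) # length u_eff * m, candidate-major within slot

  Wrep <- ashares_subset(W, idx_i)
  prod <- mul_shares(sess, E, Wrep, count_as = "mux")
  Ws <- rowsum_ashares(sess, prod, s_of + 1, u_eff)

  E0 <- matrix(E$s0, nrow = m) # column s+1 holds slot s
  E1 <- matrix(E$s1, nrow = m)
  occ_pub <- matrix(0, m, n)
  for (i in seq_len(m)) occ_pub[i, cand[i, ]] <- 1
  occ <- new_ashares(t(E0) %*% occ_pub %% sess$M,
                     t(E1) %*% occ_pub %% sess$M, bl) # u_eff x n
  vpub <- cand # 1-based row indices, so 0 can encode "absent"; output
               # vertices are shifted back to the 0-based pair ids
  vseq <- new_ashares(t(E0) %*% vpub %% sess$M,
                      t(E1) %*% vpub %% sess$M, bl) # u_eff x L

  list(u_eff = u_eff, n = n, L = L, Ws = Ws, occ = occ, vseq = vseq)
}

mul_public_vec <- function(sess, x, k) {
  new_ashares(ring_mul(x$s0, k %% sess$M, sess$M),
              ring_mul(x$s1, k %% sess$M, sess$M), sess$bitlen)
}

rowsum_ashares <- function(sess, x, group, n_groups) {
  charge(sess, add = ashare_length(x) - n_groups)
  s0 <- rowsum(x$s0, group)[, 1] %% sess$M
  s1 <- rowsum(x$s1, group)[, 1] %% sess$M
  new_ashares(unname(s0), unname(s1), sess$bitlen)
}

## ---- phase 4: solution evaluation -------------------------------------

mpc_phase_solution <- function(sess, sl) {
  set_phase(sess, "solution")
  u <- sl$u_eff
  n <- sl$n
  L <- sl$L
  bl <- sess$bitlen
  M <- sess$M

  # one candidate set per seed slot, all advanced in parallel
  a0 <- diag(u); a1 <- matrix(0, u, u)
  amat <- new_ashares(a0, a1, bl) # u x u membership indicators
  occ <- sl$occ                   # u x n accumulated occupancy
  total <- ashares_subset(sl$Ws, seq_len(u))

  s_idx <- rep(seq_len(u), times = n)
  v_idx <- rep(seq_len(n), each = u)
  for (j in seq_len(u)) {
    occ_j <- new_ashares(sl$occ$s0[j, ], sl$occ$s1[j, ], bl)
    occ_flat <- new_ashares(as.numeric(occ$s0), as.numeric(occ$s1), bl)
    prod <- mul_shares(sess, occ_flat,
                       ashares_subset(occ_j, v_idx))
    dot <- rowsum_ashares(sess, prod, s_idx, u)
    disj <- not_share(sess, nz_bit(sess, dot))
    selfmask <- rep(1, u); selfmask[j] <- 0
    disj <- and_public_bool(disj, selfmask)
    addA <- b2a_bit(sess, disj)
    upd <- mul_shares(sess, ashares_subset(addA, s_idx),
                      ashares_subset(occ_j, v_idx), count_as = "mux")
    occ <- new_ashares((occ$s0 + matrix(upd$s0, u, n)) %% M,
                       (occ$s1 + matrix(upd$s1, u, n)) %% M, bl)
    charge(sess, add = u * n)
    wj <- new_ashares(rep(sl$Ws$s0[j], u), rep(sl$Ws$s1[j], u), bl)
    total <- add_shares(sess, total, mul_shares(sess, addA, wj))
    amat <- new_ashares(`[<-`(amat$s0, cbind(seq_len(u), j),
                              (amat$s0[, j] + addA$s0) %% M),
                        `[<-`(amat$s1, cbind(seq_len(u), j),
                              (amat$s1[, j] + addA$s1) %% M), bl)
    charge(sess, add = u)
  }

  # oblivious argmax over seeds: larger total, then fewer cycles, then
  # earliest seed in sorted order
  ncyc <- rowsum_ashares(
    sess,
    new_ashares(as.numeric(t(amat$s0)), as.numeric(t(amat$s1)), bl),
    rep(seq_len(u), each = u), u)
  best_t <- ashares_subset(total, 1)
  best_n <- ashares_subset(ncyc, 1)
  best_a <- new_ashares(amat$s0[1, ], amat$s1[1, ], bl)
  if (u > 1) {
    for (s in 2:u) {
      tot_s <- ashares_subset(total, s)
      n_s <- ashares_subset(ncyc, s)
      d1 <- sub_shares(sess, best_t, tot_s)
      gt <- msb_bit(sess, d1) # [best_t < tot_s]
      eqb <- not_share(sess, nz_bit(sess, d1))
      ltn <- msb_bit(sess, sub_shares(sess, n_s, best_n))
      better <- or_shares(sess, gt, and_shares(sess, eqb, ltn))
      selA <- b2a_bit(sess, better)
      pick <- function(cur, new_, k_) {
        sel <- new_ashares(rep(selA$s0, k_), rep(selA$s1, k_), bl)
        add_shares(sess, cur,
                   mul_shares(sess, sel, sub_shares(sess, new_, cur),
                              count_as = "mux"))
      }
      best_t <- pick(best_t, tot_s, 1)
      best_n <- pick(best_n, n_s, 1)
      best_a <- pick(best_a, new_ashares(amat$s0[s, ], amat$s1[s, ], bl), u)
    }
  }

  # declassify only the final solution: chosen weights and vertex lists,
  # masked to zero for unchosen slots
  out_w <- mul_shares(sess, best_a, sl$Ws, count_as = "mux")
  arep <- ashares_subset(best_a, rep(seq_len(u), times = L))
  vflat <- new_ashares(as.numeric(sl$vseq$s0), as.numeric(sl$vseq$s1), bl)
  out_v <- mul_shares(sess, arep, vflat, count_as = "mux")
  cw <- declassify(sess, out_w, "solution")
  cv <- matrix(declassify(sess, out_v, "solution"), u, L)
  chosen <- which(cw > 0)
  cycles <- tibble::tibble(
    vertices = purrr::map(chosen, ~ as.integer(cv[.x, ] - 1)),
    weight = as.integer(cw[chosen])
  )
  new_kex_solution(cycles, declassified = sess$declassified)
}
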