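#' Simulated two-party secret-sharing session
#'
#' Creates the state for a simulated semi-honest two-party computation:
#' additive arithmetic shares over `Z_{2^bitlen}`, Boolean (XOR) shares,
#' dealer-supplied correlated randomness (Beaver multiplication triples and
#' share-conversion material), per-phase gate/communication accounting, and
#' an access audit.
#'
#' The simulation runs both parties in one process but respects the
#' protocol's information flow: the only operations that ever combine both
#' shares of a secret are [reconstruct_shares()] (audited) and
#' [declassify()] (logged); protocol-internal openings only ever reveal
#' uniformly masked values. Garbled-circuit ("Yao") phases are executed on
#' the Boolean engine while communication is charged at the garbled-circuit
#' rate of `1.5 * kappa` bits per AND-equivalent gate, with XOR free.
#'
#' @param seed Integer seed for party randomness; the dealer stream is
#'   derived from it.
#' @param bitlen Ring bit length (default 32).
#' @param kappa Symmetric security parameter for the communication model
#'   (default 128).
#' @return An environment of class `kex_mpc_session`.
#' @export
kex_mpc_session <- function(seed, bitlen = 32L, kappa = 128L) {
  M <- ring_modulus(bitlen)
  sess <- new.env(parent = emptyenv())
  sess$bitlen <- as.integer(bitlen)
  sess$M <- M
  sess$kappa <- as.integer(kappa)
  sess$phase <- "setup"
  sess$counts <- list()
  sess$audit <- 0L
  sess$declassify_depth <- 0L
  sess$declassified <- list()
  sess$triples_arith <- 0
  sess$triples_bool <- 0
  # independent RNG streams for party and dealer randomness
  sess$party_state <- rng_state_for(seed)
  sess$dealer_state <- rng_state_for(seed + 1000003)
  class(sess) <- "kex_mpc_session"
  sess
}

rng_state_for <- function(seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed %% .Machine$integer.max)
  st <- get(".Random.seed", globalenv())
  restore_rng(old)
  st
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# draw from one of the session's RNG streams, preserving the caller's RNG
sess_rand <- function(sess, n, stream = c("party", "dealer"), max = sess$M) {
  stream <- match.arg(stream)
  field <- paste0(stream, "_state")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", sess[[field]], envir = globalenv())
  x <- ring_rand(n, max)
  sess[[field]] <- get(".Random.seed", globalenv())
  restore_rng(old)
  x
}

#' @export
print.kex_mpc_session <- function(x, ...) {
  cat("<kex_mpc_session> ring Z_2^", x$bitlen, ", kappa = ", x$kappa,
      ", audit violations = ", x$audit, "\n", sep = "")
  invisible(x)
}

set_phase <- function(sess, phase) {
  sess$phase <- phase
  if (is.null(sess$counts[[phase]])) {
    sess$counts[[phase]] <- c(
      and_gates = 0, or_gates = 0, mux_gates = 0, comparisons = 0,
      multiplications = 0, additions = 0, conversions = 0,
      conversion_ands = 0, depth = 0, comm_bits = 0
    )
  }
  invisible(sess)
}

charge <- function(sess, and = 0, or = 0, mux = 0, cmp = 0, mult = 0,
                   add = 0, conv = 0, conv_and = 0, depth = 0) {
  if (is.null(sess$counts[[sess$phase]])) set_phase(sess, sess$phase)
  cnt <- sess$counts[[sess$phase]]
  cnt["and_gates"] <- cnt["and_gates"] + and
  cnt["or_gates"] <- cnt["or_gates"] + or
  cnt["mux_gates"] <- cnt["mux_gates"] + mux
  cnt["comparisons"] <- cnt["comparisons"] + cmp
  cnt["multiplications"] <- cnt["multiplications"] + mult
  cnt["additions"] <- cnt["additions"] + add
  cnt["conversions"] <- cnt["conversions"] + conv
  cnt["conversion_ands"] <- cnt["conversion_ands"] + conv_and
  cnt["depth"] <- max(cnt["depth"], depth)
  # Yao-rate communication: 1.5 kappa bits per AND-equivalent gate;
  # Beaver multiplication: both parties exchange two masked ring elements
  cnt["comm_bits"] <- cnt["comm_bits"] +
    1.5 * sess$kappa * (and + or + mux + conv_and) +
    4 * sess$bitlen * mult
  sess$counts[[sess$phase]] <- cnt
  invisible(sess)
}

## ---- share containers -------------------------------------------------

new_ashares <- function(s0, s1, bitlen) {
  structure(list(s0 = s0, s1 = s1, bitlen = bitlen), class = "kex_ashares")
}

new_bshares <- function(b0, b1) {
  structure(list(b0 = b0, b1 = b1), class = "kex_bshares")
}

# Boolean-shared words: bitlen x n bit matrices per party, LSB-first rows
new_bwords <- function(m0, m1) {
  structure(list(m0 = m0, m1 = m1), class = "kex_bwords")
}

ashare_length <- function(x) length(x$s0)

#' Secret-share values
#'
#' `share_arith()` splits integers into two additive shares over the ring
#' (`x = s0 + s1 mod 2^bitlen`); `share_bool()` splits bits into two XOR
#' shares. A single share is uniform and carries no information about the
#' secret. `share_public()` encodes a publicly known constant in share form
#' (share 0 holds the value, share 1 holds zero).
#'
#' @param sess A [kex_mpc_session()].
#' @param x Numeric vector of values in `[0, 2^bitlen)` (bits for
#'   `share_bool`).
#' @return A share-pair object (`kex_ashares` / `kex_bshares`).
#' @export
share_arith <- function(sess, x) {
  if (any(x < 0 | x >= sess$M)) {
    stop("value out of ring range [0, 2^bitlen)", call. = FALSE)
  }
  r <- sess_rand(sess, length(x), "party")
  new_ashares(r, ring_sub(x, r, sess$M), sess$bitlen)
}

#' @rdname share_arith
#' @export
share_bool <- function(sess, x) {
  stopifnot(all(x %in% c(0, 1)))
  r <- sess_rand(sess, length(x), "party", max = 2)
  new_bshares(r, (x + r) %% 2)
}

#' @rdname share_arith
#' @export
share_public <- function(sess, x) {
  new_ashares(x %% sess$M, rep(0, length(x)), sess$bitlen)
}

share_public_bool <- function(x) new_bshares(x %% 2, rep(0, length(x)))

#' Reconstruct or declassify shared values
#'
#' `reconstruct_shares()` combines both shares of a secret. Outside of an
#' explicit [declassify()] this counts as a protocol violation and
#' increments the session's audit counter; tests assert the counter stays
#' zero over a full pipeline run. `declassify()` is the explicit, logged
#' reveal step (in the pipeline only the raw cycle count and the final
#' solution are ever declassified).
#'
#' @param sess A [kex_mpc_session()].
#' @param x A share-pair object.
#' @param label Character label under which the revealed value is logged.
#' @return The reconstructed cleartext vector (bit matrix for `kex_bwords`).
#' @export
reconstruct_shares <- function(sess, x) {
  if (sess$declassify_depth == 0L) {
    sess$audit <- sess$audit + 1L
  }
  if (inherits(x, "kex_ashares")) {
    ring_add(x$s0, x$s1, sess$M)
  } else if (inherits(x, "kex_bshares")) {
    (x$b0 + x$b1) %% 2
  } else if (inherits(x, "kex_bwords")) {
    (x$m0 + x$m1) %% 2
  } else {
    stop("not a share object", call. = FALSE)
  }
}

#' @rdname reconstruct_shares
#' @export
declassify <- function(sess, x, label = "value") {
  sess$declassify_depth <- sess$declassify_depth + 1L
  on.exit(sess$declassify_depth <- sess$declassify_depth - 1L)
  v <- reconstruct_shares(sess, x)
  sess$declassified[[length(sess$declassified) + 1L]] <-
    list(label = label, value = v)
  v
}

# protocol-internal opening of a uniformly masked value (a simulated
# message exchange; reveals nothing about the underlying secrets)
open_masked <- function(x, M) {
  if (inherits(x, "kex_ashares")) ring_add(x$s0, x$s1, M)
  else (x$b0 + x$b1) %% 2
}

## ---- dealer: correlated randomness ------------------------------------

#' Beaver multiplication triples
#'
#' Dealer-supplied correlated randomness `(a, b, c)` with `c = a * b` in the
#' ring (or `c = a AND b` for Boolean triples), secret-shared between the
#' parties. Each triple may be consumed exactly once; reuse is a protocol
#' violation and raises an error.
#'
#' @param sess A [kex_mpc_session()].
#' @param n Number of (SIMD) elements in the triple.
#' @param domain `"arith"` or `"bool"`.
#' @return An environment holding the triple shares and a `used` flag.
#' @export
beaver_triple <- function(sess, n = 1, domain = c("arith", "bool")) {
  domain <- match.arg(domain)
  t <- new.env(parent = emptyenv())
  t$domain <- domain
  t$used <- FALSE
  if (domain == "arith") {
    a <- sess_rand(sess, n, "dealer")
    b <- sess_rand(sess, n, "dealer")
    c <- ring_mul(a, b, sess$M)
    ra <- sess_rand(sess, n, "dealer"); rb <- sess_rand(sess, n, "dealer")
    rc <- sess_rand(sess, n, "dealer")
    t$a <- new_ashares(ra, ring_sub(a, ra, sess$M), sess$bitlen)
    t$b <- new_ashares(rb, ring_sub(b, rb, sess$M), sess$bitlen)
    t$c <- new_ashares(rc, ring_sub(c, rc, sess$M), sess$bitlen)
    sess$triples_arith <- sess$triples_arith + n
  } else {
    a <- sess_rand(sess, n, "dealer", max = 2)
    b <- sess_rand(sess, n, "dealer", max = 2)
    c <- a * b
    ra <- sess_rand(sess, n, "dealer", max = 2)
    rb <- sess_rand(sess, n, "dealer", max = 2)
    rc <- sess_rand(sess, n, "dealer", max = 2)
    t$a <- new_bshares(ra, (a + ra) %% 2)
    t$b <- new_bshares(rb, (b + rb) %% 2)
    t$c <- new_bshares(rc, (c + rc) %% 2)
    sess$triples_bool <- sess$triples_bool + n
  }
  t
}

consume_triple <- function(triple) {
  if (triple$used) {
    stop("protocol violation: Beaver triple already consumed", call. = FALSE)
  }
  triple$used <- TRUE
  invisible(triple)
}

## ---- arithmetic operations --------------------------------------------

add_shares <- function(sess, x, y, count = TRUE) {
  if (count) charge(sess, add = ashare_length(x))
  new_ashares(ring_add(x$s0, y$s0, sess$M), ring_add(x$s1, y$s1, sess$M),
              sess$bitlen)
}

sub_shares <- function(sess, x, y, count = TRUE) {
  if (count) charge(sess, add = ashare_length(x))
  new_ashares(ring_sub(x$s0, y$s0, sess$M), ring_sub(x$s1, y$s1, sess$M),
              sess$bitlen)
}

# add/multiply by a public constant: local, no communication
add_public <- function(sess, x, k) {
  new_ashares(ring_add(x$s0, k %% sess$M, sess$M), x$s1, sess$bitlen)
}

mul_public <- function(sess, x, k) {
  k <- k %% sess$M
  new_ashares(ring_mul(x$s0, k, sess$M), ring_mul(x$s1, k, sess$M),
              sess$bitlen)
}

#' Multiply secret-shared values with a Beaver triple
#'
#' Interactive share multiplication: the parties open the uniformly masked
#' differences `d = x - a` and `e = y - b` and locally combine them with the
#' triple to obtain shares of `x * y mod 2^bitlen`. Consumes the triple.
#'
#' @param sess A [kex_mpc_session()].
#' @param x,y `kex_ashares` of equal length.
#' @param triple A fresh [beaver_triple()] of matching length; defaults to a
#'   newly dealt one.
#' @param count_as Cost category: `"mult"` (default) or `"mux"` when the
#'   multiplication realises an oblivious selection.
#' @return `kex_ashares` of the product.
#' @export
mul_shares <- function(sess, x, y, triple = NULL, count_as = "mult") {
  n <- ashare_length(x)
  stopifnot(ashare_length(y) == n)
  if (is.null(triple)) triple <- beaver_triple(sess, n, "arith")
  if (!identical(triple$domain, "arith")) {
    stop("arithmetic multiplication needs an arithmetic triple",
         call. = FALSE)
  }
  consume_triple(triple)
  M <- sess$M
  d <- open_masked(new_ashares(ring_sub(x$s0, triple$a$s0, M),
                               ring_sub(x$s1, triple$a$s1, M), sess$bitlen), M)
  e <- open_masked(new_ashares(ring_sub(y$s0, triple$b$s0, M),
                               ring_sub(y$s1, triple$b$s1, M), sess$bitlen), M)
  z0 <- ring_add(triple$c$s0,
                 ring_add(ring_mul(d, triple$b$s0, M),
                          ring_add(ring_mul(e, triple$a$s0, M),
                                   ring_mul(d, e, M), M), M), M)
  z1 <- ring_add(triple$c$s1,
                 ring_add(ring_mul(d, triple$b$s1, M),
                          ring_mul(e, triple$a$s1, M), M), M)
  if (count_as == "mux") charge(sess, mux = n) else charge(sess, mult = n)
  new_ashares(z0, z1, sess$bitlen)
}

## ---- Boolean operations ------------------------------------------------

#' Boolean gates on XOR-shared bits
#'
#' Gate evaluation on Boolean share pairs. XOR and NOT are local (free);
#' AND consumes one Boolean Beaver triple per element; OR is realised as
#' `NOT(AND(NOT a, NOT b))` and charged as one AND-equivalent; the
#' multiplexer `mux_shares(sel, a, b)` returns `a` where `sel` is 1 and `b`
#' where it is 0, via `b XOR (sel AND (a XOR b))`, charged as one MUX gate.
#'
#' @param sess A [kex_mpc_session()].
#' @param x,y,sel,a,b `kex_bshares` of equal length.
#' @param triple Optional Boolean [beaver_triple()].
#' @return `kex_bshares`.
#' @export
xor_shares <- function(sess, x, y) {
  new_bshares((x$b0 + y$b0) %% 2, (x$b1 + y$b1) %% 2)
}

#' @rdname xor_shares
#' @export
not_share <- function(sess, x) {
  new_bshares((x$b0 + 1) %% 2, x$b1)
}

#' @rdname xor_shares
#' @export
and_shares <- function(sess, x, y, triple = NULL, .charge = c("and", "or",
                                                              "mux",
                                                              "conv_and")) {
  .charge <- match.arg(.charge)
  n <- length(x$b0)
  stopifnot(length(y$b0) == n)
  if (is.null(triple)) triple <- beaver_triple(sess, n, "bool")
  if (!identical(triple$domain, "bool")) {
    stop("Boolean AND needs a Boolean triple", call. = FALSE)
  }
  consume_triple(triple)
  d <- open_masked(new_bshares((x$b0 + triple$a$b0) %% 2,
                               (x$b1 + triple$a$b1) %% 2), 2)
  e <- open_masked(new_bshares((y$b0 + triple$b$b0) %% 2,
                               (y$b1 + triple$b$b1) %% 2), 2)
  z0 <- (triple$c$b0 + d * triple$b$b0 + e * triple$a$b0 + d * e) %% 2
  z1 <- (triple$c$b1 + d * triple$b$b1 + e * triple$a$b1) %% 2
  switch(.charge,
         and = charge(sess, and = n),
         or = charge(sess, or = n),
         mux = charge(sess, mux = n),
         conv_and = charge(sess, conv_and = n))
  new_bshares(z0, z1)
}

#' @rdname xor_shares
#' @export
or_shares <- function(sess, x, y, triple = NULL) {
  not_share(sess, and_shares(sess, not_share(sess, x), not_share(sess, y),
                             triple, .charge = "or"))
}

#' @rdname xor_shares
#' @export
mux_shares <- function(sess, sel, a, b) {
  diff <- xor_shares(sess, a, b)
  xor_shares(sess, b, and_shares(sess, sel, diff, .charge = "mux"))
}

# AND with one public bit vector: local masking, no gate cost
and_public_bool <- function(x, pub) {
  new_bshares(x$b0 * pub, x$b1 * pub)
}

# OR-reduce a list of kex_bshares vectors (balanced tree)
or_reduce <- function(sess, xs) {
  while (length(xs) > 1) {
    nxt <- list()
    i <- 1
    while (i + 1 <= length(xs)) {
      nxt[[length(nxt) + 1L]] <- or_shares(sess, xs[[i]], xs[[i + 1]])
      i <- i + 2
    }
    if (i == length(xs)) nxt[[length(nxt) + 1L]] <- xs[[i]]
    xs <- nxt
  }
  xs[[1]]
}

## ---- share conversions -------------------------------------------------

#' Convert between arithmetic and Boolean sharing
#'
#' `a2b()` converts additive ring shares to Boolean shares of the bit
#' decomposition: the dealer supplies a random ring element `r` both as
#' arithmetic shares and as Boolean shares of its bits; the parties open the
#' uniformly masked value `m = x - r` and add the public `m` to the shared
#' bits of `r` with a ripple-carry adder (one AND-equivalent per bit,
#' charged to the conversion account). `b2a_bit()` converts one Boolean
#' shared bit to arithmetic shares via a dealer random bit and a masked
#' opening, with only local arithmetic afterwards.
#'
#' @param sess A [kex_mpc_session()].
#' @param x `kex_ashares` (for `a2b`) or `kex_bshares` (for `b2a_bit`).
#' @return `a2b()`: `kex_bwords` (bit matrices, LSB-first rows);
#'   `b2a_bit()`: `kex_ashares` with values in \{0, 1\}.
#' @export
a2b <- function(sess, x) {
  n <- ashare_length(x)
  bl <- sess$bitlen
  M <- sess$M
  r <- sess_rand(sess, n, "dealer")
  rr <- sess_rand(sess, n, "dealer")
  r_arith <- new_ashares(rr, ring_sub(r, rr, M), bl)
  rbits <- bit_decompose(r, bl)
  rmask <- matrix(sess_rand(sess, bl * n, "dealer", max = 2), bl, n)
  rb0 <- rmask
  rb1 <- (rbits + rmask) %% 2
  m <- open_masked(new_ashares(ring_sub(x$s0, r_arith$s0, M),
                               ring_sub(x$s1, r_arith$s1, M), bl), M)
  mbits <- bit_decompose(m, bl)
  # x = m + r: ripple-carry addition of public m to Boolean-shared r
  out0 <- matrix(0, bl, n)
  out1 <- matrix(0, bl, n)
  carry <- share_public_bool(rep(0, n))
  for (j in seq_len(bl)) {
    p <- mbits[j, ]
    rbit <- new_bshares(rb0[j, ], rb1[j, ])
    s <- xor_shares(sess, rbit, carry)
    s$b0 <- (s$b0 + p) %% 2 # XOR with public bit: party 0 local
    out0[j, ] <- s$b0
    out1[j, ] <- s$b1
    if (j < bl) {
      # carry' = (rbit AND carry) XOR (p AND (rbit XOR carry))
      rc <- and_shares(sess, rbit, carry, .charge = "conv_and")
      px <- and_public_bool(xor_shares(sess, rbit, carry), p)
      carry <- xor_shares(sess, rc, px)
    }
  }
  charge(sess, conv = n)
  new_bwords(out0, out1)
}

#' @rdname a2b
#' @export
b2a_bit <- function(sess, x) {
  n <- length(x$b0)
  M <- sess$M
  s <- sess_rand(sess, n, "dealer", max = 2)
  smask <- sess_rand(sess, n, "dealer", max = 2)
  sb <- new_bshares(smask, (s + smask) %% 2)
  sa_r <- sess_rand(sess, n, "dealer")
  sa <- new_ashares(sa_r, ring_sub(s, sa_r, M), sess$bitlen)
  t <- open_masked(new_bshares((x$b0 + sb$b0) %% 2, (x$b1 + sb$b1) %% 2), 2)
  # x = t XOR s = t + s - 2 t s; t public
  coef <- ring_sub(1, ring_mul(rep(2, n), t, M), M)
  z0 <- ring_add(t, ring_mul(coef, sa$s0, M), M)
  z1 <- ring_mul(coef, sa$s1, M)
  charge(sess, conv = n)
  new_ashares(z0, z1, sess$bitlen)
}

# Extract one bit row of Boolean-shared words as kex_bshares
bword_bit <- function(words, j) {
  new_bshares(words$m0[j, ], words$m1[j, ])
}

## ---- derived predicates ------------------------------------------------

# Boolean share of [x != 0] (x interpreted as unsigned ring value)
nz_bit <- function(sess, x, count_cmp = TRUE) {
  if (count_cmp) charge(sess, cmp = ashare_length(x))
  words <- a2b(sess, x)
  bits <- lapply(seq_len(sess$bitlen), function(j) bword_bit(words, j))
  or_reduce(sess, bits)
}

# Boolean share of the sign bit of x (1 iff x >= 2^(bitlen-1), i.e. x
# encodes a negative difference)
msb_bit <- function(sess, x, count_cmp = TRUE) {
  if (count_cmp) charge(sess, cmp = ashare_length(x))
  words <- a2b(sess, x)
  bword_bit(words, sess$bitlen)
}

# indexing helpers on share containers
ashares_subset <- function(x, idx) {
  new_ashares(x$s0[idx], x$s1[idx], x$bitlen)
}

bshares_subset <- function(x, idx) {
  new_bshares(x$b0[idx], x$b1[idx])
}

ashares_c <- function(bitlen, ...) {
  parts <- list(...)
  new_ashares(unlist(lapply(parts, `[[`, "s0")),
              unlist(lapply(parts, `[[`, "s1")), bitlen)
}
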