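# Exact arithmetic in Z_{2^bitlen} on doubles (bitlen <= 32).
#
# Sums stay below 2^53 so `%%` is exact; products are reduced via a 16-bit
# split so no intermediate exceeds 2^33.

ring_modulus <- function(bitlen) {
  if (bitlen < 2 || bitlen > 32) {
    stop("ring bit length must lie in 2..32", call. = FALSE)
  }
  2^bitlen
}

ring_add <- function(x, y, M) (x + y) %% M

ring_sub <- function(x, y, M) (x - y) %% M

ring_neg <- function(x, M) (M - x) %% M

# (x * y) mod M, exact for M <= 2^32
ring_mul <- function(x, y, M) {
  x0 <- x %% 65536; x1 <- x %/% 65536
  y0 <- y %% 65536; y1 <- y %/% 65536
  mid <- (x1 * y0 + x0 * y1) %% 65536
  (x0 * y0 + mid * 65536) %% M
}

# n uniform draws from {0, ..., M-1} using the current RNG stream
ring_rand <- function(n, M) {
  floor(stats::runif(n) * M)
}

#' Bit decomposition of ring elements
#'
#' Binary expansion of non-negative integers, least-significant bit first.
#'
#' @param x Numeric vector of values in `[0, 2^bitlen)`.
#' @param bitlen Number of bits.
#' @return A `bitlen` x `length(x)` 0/1 matrix; row j holds bit j-1.
#' @examples
#' bit_decompose(6, 4)[, 1] # 0 1 1 0
#' @export
bit_decompose <- function(x, bitlen) {
  m <- matrix(0, nrow = bitlen, ncol = length(x))
  v <- x
  for (j in seq_len(bitlen)) {
    m[j, ] <- v %% 2
    v <- v %/% 2
  }
  m
}

bits_to_int <- function(bits) {
  drop(crossprod(bits, 2^(seq_len(nrow(bits)) - 1)))
}
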