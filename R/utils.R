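# Internal helpers: seed derivation and bit arithmetic.

#' Derive a child seed from a master seed
#'
#' Deterministic counter-based fan-out: a master seed plus a path of integer
#' indices (generation, genome, trial, ...) is folded through a Lehmer-style
#' multiplicative mix modulo 2^31 - 1, so any single trial of a large run can
#' be replayed in isolation. The result is always a positive 32-bit integer.
#'
#' @param master Integer master seed.
#' @param ... Integer indices identifying the stream (any depth).
#' @return A single positive integer seed, strictly below 2^31.
#' @examples
#' derive_seed(1, 3, 7)
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  x <- (abs(as.numeric(master)) %% m)
  for (k in c(...)) {
    x <- (x * 48271 + abs(as.numeric(k)) + 1) %% m
  }
  # avoid 0, which some generators treat specially
  as.integer(x + 1)
}

# x: non-negative integer scalar; returns 0/1 vector of length n (bit 1 = LSB)
int_to_bits <- function(x, n) {
  as.integer(bitwAnd(bitwShiftR(as.integer(x), 0:(n - 1L)), 1L))
}

bits_to_int <- function(bits) {
  as.integer(sum(as.integer(bits) * 2^(seq_along(bits) - 1L)))
}

# all 2^k states as a matrix (row i = state i-1, little-endian: column 1 = LSB)
states_matrix <- function(k) {
  if (k == 0L) {
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  }
  m <- as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# enumerate all subsets (as integer vectors) of `ids`, sizes min..max
subsets_of <- function(ids, min_size = 1L, max_size = length(ids)) {
  out <- list()
  if (length(ids) == 0L || max_size < min_size) return(out)
  for (k in seq(min_size, min(max_size, length(ids)))) {
    # combn() would treat a length-1 numeric as seq_len(n); index positions
    cmb <- utils::combn(seq_along(ids), k, simplify = FALSE)
    out <- c(out, lapply(cmb, function(ix) ids[ix]))
  }
  out
}

`%||%` <- rlang::`%||%`

stop_animats <- function(...) stop(..., call. = FALSE)
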