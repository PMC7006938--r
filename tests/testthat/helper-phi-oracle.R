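# Independent, naive re-implementation of the integrated-information
# measures, used as a brute-force oracle for systems of up to 3 units.
#
# The oracle follows the same pinned definitions as the package (little-
# endian state indexing, virtual-element cause repertoires, EMD repertoire
# distance with Hamming ground metric, unidirectional cuts, null-concept
# constellation transport, larger-then-lexicographic purview tie-break) but
# derives everything with explicit loops over full joint states, organized
# around bitmask enumeration rather than the package's vectorized subset
# machinery. It shares only the exact-EMD primitive with the package.

oracle_bits <- function(i, k) {
  # state index i (0-based) -> 0/1 vector, bit 1 = LSB
  vapply(seq_len(k), function(b) bitwAnd(bitwShiftR(i, b - 1L), 1L), integer(1))
}

oracle_mask_members <- function(mask, k) {
  which(oracle_bits(mask, k) == 1L)
}

oracle_hamming <- function(k) {
  n <- 2^k
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- sum(oracle_bits(i - 1L, k) != oracle_bits(j - 1L, k))
    }
  }
  m
}

# probability that node j takes value v at t+1 given the full state x0 (index)
oracle_node_prob <- function(tpm, x0, j, v) {
  p1 <- tpm[x0 + 1L, j]
  if (v == 1L) p1 else 1 - p1
}

# cause repertoire of mechanism `mech` (positions) in state s over purview Z
oracle_cause <- function(tpm, k, s, mech, purview) {
  if (length(purview) == 0L) return(1)
  nz <- length(purview)
  out <- numeric(2^nz)
  for (zi in seq_len(2^nz)) {
    z <- oracle_bits(zi - 1L, nz)
    val <- 1
    for (m in mech) {
      acc <- 0
      n_match <- 0L
      for (x in 0:(2^k - 1L)) {
        xb <- oracle_bits(x, k)
        if (all(xb[purview] == z)) {
          acc <- acc + oracle_node_prob(tpm, x, m, s[m])
          n_match <- n_match + 1L
        }
      }
      val <- val * acc / n_match
    }
    out[zi] <- val
  }
  tot <- sum(out)
  if (tot < 1e-300) return(NULL)
  out / tot
}

# effect repertoire of mechanism `mech` in state s over purview Z
oracle_effect <- function(tpm, k, s, mech, purview) {
  if (length(purview) == 0L) return(1)
  nz <- length(purview)
  rows <- integer(0)
  for (x in 0:(2^k - 1L)) {
    xb <- oracle_bits(x, k)
    if (length(mech) == 0L || all(xb[mech] == s[mech])) rows <- c(rows, x)
  }
  out <- numeric(2^nz)
  for (zi in seq_len(2^nz)) {
    z <- oracle_bits(zi - 1L, nz)
    val <- 1
    for (pos in seq_len(nz)) {
      j <- purview[pos]
      pj <- mean(vapply(rows, function(x) oracle_node_prob(tpm, x, j, z[pos]),
                        numeric(1)))
      val <- val * pj
    }
    out[zi] <- val
  }
  out
}

oracle_rep <- function(tpm, k, s, mech, purview, direction) {
  if (direction == "cause") {
    oracle_cause(tpm, k, s, mech, purview)
  } else {
    oracle_effect(tpm, k, s, mech, purview)
  }
}

# tensor two repertoires over disjoint position sets into sort(c(z1, z2))
oracle_combine <- function(r1, z1, r2, z2) {
  if (is.null(r1) || is.null(r2)) return(NULL)
  z <- sort(c(z1, z2))
  if (length(z) == 0L) return(1)
  nz <- length(z)
  out <- numeric(2^nz)
  for (zi in seq_len(2^nz)) {
    bits <- oracle_bits(zi - 1L, nz)
    v1 <- if (length(z1) == 0L) 1 else {
      idx <- sum(bits[match(z1, z)] * 2^(seq_along(z1) - 1L))
      r1[idx + 1L]
    }
    v2 <- if (length(z2) == 0L) 1 else {
      idx <- sum(bits[match(z2, z)] * 2^(seq_along(z2) - 1L))
      r2[idx + 1L]
    }
    out[zi] <- v1 * v2
  }
  out
}

# small phi of one mechanism: exhaustive purview + bipartition search
oracle_small_phi <- function(tpm, k, s, mech) {
  result <- list(phi = 0)
  for (direction in c("cause", "effect")) {
    best_phi <- 0
    best_purview <- NULL
    best_rep <- NULL
    for (pmask in 1:(2^k - 1L)) {
      purview <- oracle_mask_members(pmask, k)
      whole <- oracle_rep(tpm, k, s, mech, purview, direction)
      if (is.null(whole)) next
      cost <- oracle_hamming(length(purview))
      phi_z <- Inf
      nm <- length(mech); np <- length(purview)
      for (ymask in 0:(2^nm - 1L)) {
        y1 <- mech[oracle_mask_members(ymask, nm)]
        y2 <- setdiff(mech, y1)
        for (zmask in 0:(2^np - 1L)) {
          z1 <- purview[oracle_mask_members(zmask, np)]
          z2 <- setdiff(purview, z1)
          if (length(y1) == 0L && length(z1) == 0L) next
          if (length(y2) == 0L && length(z2) == 0L) next
          part <- oracle_combine(oracle_rep(tpm, k, s, y1, z1, direction), z1,
                                 oracle_rep(tpm, k, s, y2, z2, direction), z2)
          if (is.null(part)) next
          d <- animats::emd(whole, part, cost)
          if (d < phi_z) phi_z <- d
          if (phi_z < 1e-10) break
        }
        if (phi_z < 1e-10) break
      }
      if (!is.finite(phi_z)) phi_z <- 0
      better <- phi_z > best_phi + 1e-10 ||
        (abs(phi_z - best_phi) <= 1e-10 && phi_z > 1e-10 &&
           !is.null(best_purview) && length(purview) > length(best_purview))
      if ((is.null(best_purview) && phi_z > 1e-10) || better) {
        best_phi <- phi_z
        best_purview <- purview
        best_rep <- whole
      }
    }
    result[[direction]] <- list(phi = best_phi, purview = best_purview,
                                rep = best_rep)
  }
  result$phi <- min(result$cause$phi, result$effect$phi)
  result
}

# expand a purview repertoire to the full k-unit space
oracle_expand <- function(tpm, k, s, rep, purview, direction) {
  rest <- setdiff(seq_len(k), purview)
  pad <- if (direction == "cause") {
    if (length(rest) == 0L) 1 else rep(1 / 2^length(rest), 2^length(rest))
  } else {
    oracle_effect(tpm, k, s, integer(0), rest)
  }
  oracle_combine(rep, purview, pad, rest)
}

oracle_constellation <- function(tpm, k, s) {
  out <- list()
  for (mmask in 1:(2^k - 1L)) {
    mech <- oracle_mask_members(mmask, k)
    sp <- oracle_small_phi(tpm, k, s, mech)
    if (sp$phi > 1e-10) {
      out[[length(out) + 1L]] <- list(
        mech = mech, phi = sp$phi,
        cause = oracle_expand(tpm, k, s, sp$cause$rep, sp$cause$purview, "cause"),
        effect = oracle_expand(tpm, k, s, sp$effect$rep, sp$effect$purview,
                               "effect"))
    }
  }
  out
}

# unidirectional cut: inputs that nodes outside `part1` receive from `part1`
# are replaced by uniform noise
oracle_cut_tpm <- function(tpm, k, part1) {
  out <- tpm
  for (j in setdiff(seq_len(k), part1)) {
    for (x in 0:(2^k - 1L)) {
      xb <- oracle_bits(x, k)
      vals <- numeric(0)
      for (r in 0:(2^length(part1) - 1L)) {
        rb <- oracle_bits(r, length(part1))
        yb <- xb
        yb[part1] <- rb
        y <- sum(yb * 2^(seq_len(k) - 1L))
        vals <- c(vals, tpm[y + 1L, j])
      }
      out[x + 1L, j] <- mean(vals)
    }
  }
  out
}

oracle_constellation_distance <- function(c0, c1, tpm, k, s) {
  cost_states <- oracle_hamming(k)
  null_cause <- rep(1 / 2^k, 2^k)
  null_effect <- oracle_effect(tpm, k, s, integer(0), seq_len(k))
  pts <- c(c0, c1, list(list(phi = 0, cause = null_cause, effect = null_effect)))
  n0 <- length(c0); n1 <- length(c1); n <- length(pts)
  cdist <- function(a, b) {
    animats::emd(a$cause, b$cause, cost_states) +
      animats::emd(a$effect, b$effect, cost_states)
  }
  cost <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) cost[i, j] <- cdist(pts[[i]], pts[[j]])
  }
  m0 <- if (n0) vapply(c0, `[[`, numeric(1), "phi") else numeric(0)
  m1 <- if (n1) vapply(c1, `[[`, numeric(1), "phi") else numeric(0)
  p <- c(m0, rep(0, n1), max(0, sum(m1) - sum(m0)))
  q <- c(rep(0, n0), m1, max(0, sum(m0) - sum(m1)))
  animats::emd(p, q, cost)
}

# big Phi: minimum over all unidirectional bipartition cuts
oracle_big_phi <- function(tpm, state) {
  k <- ncol(tpm)
  s <- as.integer(state)
  c0 <- oracle_constellation(tpm, k, s)
  if (length(c0) == 0L) {
    return(list(phi = 0, n_concepts = 0L))
  }
  if (k == 1L) {
    ctpm <- matrix(mean(tpm[, 1]), 2, 1)
    c1 <- oracle_constellation(ctpm, k, s)
    return(list(phi = oracle_constellation_distance(c0, c1, tpm, k, s),
                n_concepts = length(c0)))
  }
  best <- Inf
  for (mask in 1:(2^k - 2L)) {
    part1 <- oracle_mask_members(mask, k)
    ctpm <- oracle_cut_tpm(tpm, k, part1)
    c1 <- oracle_constellation(ctpm, k, s)
    d <- oracle_constellation_distance(c0, c1, tpm, k, s)
    if (d < best) best <- d
    if (best < 1e-10) break
  }
  list(phi = best, n_concepts = length(c0))
}

# random deterministic node TPM over k units
random_deterministic_tpm <- function(k) {
  matrix(sample(0:1, 2^k * k, replace = TRUE), ncol = k)
}
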