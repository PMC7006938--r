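# Genome representation, initialization, mutation, and decoding into gates.

GENOME_MIN <- 2000L
GENOME_MAX <- 20000L
CODON <- c(42L, 213L)

new_genome <- function(loci) {
  structure(as.integer(loci), class = "animat_genome")
}

validate_genome <- function(g) {
  if (any(is.na(g)) || any(g < 0L) || any(g > 255L)) {
    stop_animats("genome loci must be integers in [0, 255]")
  }
  if (length(g) < GENOME_MIN || length(g) > GENOME_MAX) {
    stop_animats("genome length must lie in [", GENOME_MIN, ", ", GENOME_MAX,
                 "], got ", length(g))
  }
  invisible(g)
}

#' Create a random genome
#'
#' A genome is a string of integers in \[0, 255\] with length between 2,000
#' and 20,000 loci. Start-codon pairs (42, 213) mark the beginning of a hidden
#' Markov gate. With `seed_gates = TRUE` (the default) a handful of start
#' codons is planted at random positions so that first-generation brains carry
#' a few random gates; with `seed_gates = FALSE` chance codon pairs are
#' scrubbed as well, so first-generation brains have no gates and no
#' connections between units.
#'
#' @param length Genome length in loci, in \[2000, 20000\].
#' @param seed_gates Plant start codons in the fresh genome?
#' @param n_seed_codons Number of codons planted when `seed_gates` is `TRUE`.
#' @return An `animat_genome` (integer vector).
#' @examples
#' set.seed(1)
#' g <- random_genome(2000)
#' range(unclass(g))
#' @export
random_genome <- function(length, seed_gates = TRUE, n_seed_codons = 8L) {
  length <- as.integer(length)
  if (is.na(length) || length < GENOME_MIN || length > GENOME_MAX) {
    stop_animats("genome length must lie in [", GENOME_MIN, ", ", GENOME_MAX, "]")
  }
  loci <- sample(0:255, length, replace = TRUE)
  if (seed_gates) {
    n_seed_codons <- as.integer(n_seed_codons)
    if (n_seed_codons > 0L) {
      # non-overlapping codon starts away from the wrap point
      starts <- sample.int(length - 1L, min(n_seed_codons, length %/% 2L))
      starts <- starts[!duplicated(starts %/% 2L)]
      loci[starts] <- CODON[1L]
      loci[starts + 1L] <- CODON[2L]
    }
  } else {
    loci <- scrub_codons(loci)
  }
  validate_genome(new_genome(loci))
}

# resample the second element of any (42, 213) adjacency (cyclic) so that the
# genome encodes no gates
scrub_codons <- function(loci) {
  repeat {
    nxt <- c(loci[-1L], loci[1L])
    hits <- which(loci == CODON[1L] & nxt == CODON[2L])
    if (length(hits) == 0L) {
      return(loci)
    }
    pos <- ifelse(hits == length(loci), 1L, hits + 1L)
    loci[pos] <- sample(setdiff(0:255, CODON[2L]), length(pos), replace = TRUE)
  }
}

#' Mutation parameters
#'
#' Per-offspring mutation consists of (a) independent per-locus substitutions
#' at rate `point_rate` (the replacement is drawn uniformly from \[0, 255\],
#' so a locus may be "mutated" to its current value), (b) with probability
#' `insert_prob` one contiguous segment duplicated from the parent and
#' inserted at a random position, and (c) with probability `delete_prob` one
#' contiguous segment deleted. Insertions that would push the genome beyond
#' 20,000 loci and deletions that would take it below 2,000 loci are skipped.
#' The default rates are reconstructions of the usual genetic-algorithm
#' settings for Markov-brain genomes, not published values.
#'
#' @param point_rate Per-locus substitution probability.
#' @param insert_prob Probability of one segment insertion per offspring.
#' @param delete_prob Probability of one segment deletion per offspring.
#' @param segment_len_range Inclusive integer range of segment lengths.
#' @return A `mutation_params` list.
#' @export
mutation_params <- function(point_rate = 0.005, insert_prob = 0.05,
                            delete_prob = 0.02, segment_len_range = c(128L, 512L)) {
  stopifnot(point_rate >= 0, point_rate <= 1,
            insert_prob >= 0, insert_prob <= 1,
            delete_prob >= 0, delete_prob <= 1,
            length(segment_len_range) == 2L,
            segment_len_range[1L] >= 1L,
            segment_len_range[1L] <= segment_len_range[2L])
  structure(list(point_rate = point_rate, insert_prob = insert_prob,
                 delete_prob = delete_prob,
                 segment_len_range = as.integer(segment_len_range)),
            class = "mutation_params")
}

#' Mutate a genome
#'
#' Applies point substitutions, at most one segment insertion and at most one
#' segment deletion (see [mutation_params()]). Offspring length always stays
#' within \[2000, 20000\].
#'
#' @param parent An `animat_genome`.
#' @param params A [mutation_params()] object.
#' @return The mutated `animat_genome`.
#' @examples
#' set.seed(1)
#' g <- random_genome(2000)
#' identical(mutate_genome(g, mutation_params(0, 0, 0)), g)
#' @export
mutate_genome <- function(parent, params = mutation_params()) {
  validate_genome(parent)
  loci <- as.integer(parent)

  if (params$point_rate > 0) {
    hit <- stats::runif(length(loci)) < params$point_rate
    n_hit <- sum(hit)
    if (n_hit > 0L) loci[hit] <- sample(0:255, n_hit, replace = TRUE)
  }

  if (params$insert_prob > 0 && stats::runif(1) < params$insert_prob) {
    len <- sample(params$segment_len_range[1L]:params$segment_len_range[2L], 1L)
    if (length(loci) + len <= GENOME_MAX && len < length(loci)) {
      src <- sample.int(length(loci) - len + 1L, 1L)
      seg <- loci[src:(src + len - 1L)]
      at <- sample.int(length(loci) + 1L, 1L)
      loci <- append(loci, seg, after = at - 1L)
    }
  }

  if (params$delete_prob > 0 && stats::runif(1) < params$delete_prob) {
    len <- sample(params$segment_len_range[1L]:params$segment_len_range[2L], 1L)
    if (length(loci) - len >= GENOME_MIN) {
      at <- sample.int(length(loci) - len + 1L, 1L)
      loci <- loci[-(at:(at + len - 1L))]
    }
  }

  validate_genome(new_genome(loci))
}

#' Decode a genome into gate blueprints
#'
#' Every occurrence of the start codon (42, 213) begins one hidden Markov
#' gate. The bytes following the codon are read cyclically (the genome wraps,
#' so a header near the genome end still yields a complete gate): one byte
#' each for the number of inputs and outputs (mapped to 1-4 via modulo 4),
#' four bytes of input ids, four bytes of output ids (the first n_in / n_out
#' are used, reduced modulo the number of units legal in that role under the
#' architecture), then 2^n_in lookup-table bytes, each reduced modulo 2^n_out
#' to an output bit pattern. Table rows are indexed by the gate's input states
#' little-endian (first listed input = least significant bit). Gate inputs may
#' be sensors, memory units, and motors when the architecture allows motor
#' feedback; outputs are always memory or motor units.
#'
#' @param genome An `animat_genome`.
#' @param arch An [arch_spec()].
#' @return A list of gate blueprints, each a list with elements `inputs`,
#'   `outputs` (absolute unit ids), `n_in`, `n_out`, and `table` (integer
#'   vector of length `2^n_in`, each entry an `n_out`-bit pattern).
#' @examples
#' decode_genome(random_genome(2000, seed_gates = FALSE), arch_spec())
#' @export
decode_genome <- function(genome, arch) {
  validate_genome(genome)
  stopifnot(inherits(arch, "animat_arch"))
  loci <- as.integer(genome)
  len <- length(loci)
  nxt <- c(loci[-1L], loci[1L])
  starts <- which(loci == CODON[1L] & nxt == CODON[2L])
  if (length(starts) == 0L) {
    return(list())
  }
  legal_in <- legal_input_units(arch)
  legal_out <- legal_output_units(arch)
  lapply(starts, function(s) {
    # byte k after the codon sits at 0-based position (s - 1 + 1 + k) mod len
    at <- function(k) loci[((s + k) %% len) + 1L]
    n_in <- 1L + at(1L) %% 4L
    n_out <- 1L + at(2L) %% 4L
    inputs <- legal_in[(vapply(3:(2L + n_in), at, integer(1)) %% length(legal_in)) + 1L]
    outputs <- legal_out[(vapply(7:(6L + n_out), at, integer(1)) %% length(legal_out)) + 1L]
    tbl <- vapply(11:(10L + 2L^n_in), at, integer(1)) %% (2L^n_out)
    list(inputs = inputs, outputs = outputs, n_in = n_in, n_out = n_out,
         table = as.integer(tbl))
  })
}

#' Read and write genome files
#'
#' Plain-text format: one integer locus per line. The reader validates locus
#' range and length bounds.
#'
#' @param path File path.
#' @param genome An `animat_genome`.
#' @return `read_genome()` returns an `animat_genome`; `write_genome()`
#'   returns `path` invisibly.
#' @export
read_genome <- function(path) {
  loci <- scan(path, what = integer(), quiet = TRUE)
  validate_genome(new_genome(loci))
}

#' @rdname read_genome
#' @export
write_genome <- function(genome, path) {
  validate_genome(genome)
  writeLines(as.character(as.integer(genome)), path)
  invisible(path)
}

#' @export
print.animat_genome <- function(x, ...) {
  nxt <- c(x[-1L], x[1L])
  cat(sprintf("<animat_genome> %d loci, %d start codons\n",
              length(x), sum(x == CODON[1L] & nxt == CODON[2L])))
  invisible(x)
}
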