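test_that("random genomes respect length bounds and locus range", {
  set.seed(1)
  g <- random_genome(2000)
  expect_length(unclass(g), 2000L)
  expect_true(all(g >= 0L & g <= 255L))
  expect_error(random_genome(1999), "length")
  expect_error(random_genome(20001), "length")
})

test_that("genome initialization is deterministic under a fixed seed", {
  set.seed(7); g1 <- random_genome(3000)
  set.seed(7); g2 <- random_genome(3000)
  expect_identical(g1, g2)
})

test_that("seed_gates = FALSE yields genomes with no gates", {
  arch <- arch_spec()
  set.seed(3)
  for (i in 1:5) {
    g <- random_genome(5000, seed_gates = FALSE)
    expect_length(decode_genome(g, arch), 0L)
  }
  set.seed(3)
  g <- random_genome(5000, seed_gates = TRUE, n_seed_codons = 8)
  expect_gt(length(decode_genome(g, arch)), 0L)
})

test_that("zero-rate mutation returns an identical copy", {
  set.seed(2)
  g <- random_genome(2500)
  expect_identical(mutate_genome(g, mutation_params(0, 0, 0)), g)
})

test_that("point_rate = 1 resamples every locus uniformly", {
  set.seed(5)
  # pool several genomes so the Monte-Carlo sample exceeds 1e5 loci
  n_same <- 0L; n_tot <- 0L
  for (i in 1:6) {
    g <- random_genome(20000, seed_gates = FALSE)
    child <- mutate_genome(g, mutation_params(point_rate = 1, insert_prob = 0,
                                              delete_prob = 0))
    n_same <- n_same + sum(unclass(child) == unclass(g))
    n_tot <- n_tot + length(g)
  }
  p <- 1 / 256
  se <- sqrt(p * (1 - p) / n_tot)
  expect_lt(abs(n_same / n_tot - p), 3 * se)
})

test_that("expected number of point substitutions matches the rate", {
  set.seed(11)
  rate <- 0.01
  changed <- 0L; total <- 0L
  for (i in 1:5) {
    g <- random_genome(20000, seed_gates = FALSE)
    child <- mutate_genome(g, mutation_params(rate, 0, 0))
    changed <- changed + sum(unclass(child) != unclass(g))
    total <- total + length(g)
  }
  # a hit leaves the locus unchanged with prob 1/256
  p_eff <- rate * 255 / 256
  se <- sqrt(p_eff * (1 - p_eff) / total)
  expect_lt(abs(changed / total - p_eff), 3 * se)
})

test_that("deletions never shrink a genome below the minimum length", {
  set.seed(4)
  g <- random_genome(2000)
  p <- mutation_params(0, 0, delete_prob = 1)
  for (i in 1:30) g <- mutate_genome(g, p)
  expect_gte(length(g), 2000L)
})

test_that("insertions never grow a genome beyond the maximum length", {
  set.seed(4)
  g <- random_genome(19900)
  p <- mutation_params(0, insert_prob = 1, 0)
  for (i in 1:10) g <- mutate_genome(g, p)
  expect_lte(length(g), 20000L)
})

test_that("mutation preserves bounds for random parameter settings", {
  set.seed(6)
  g <- random_genome(2100)
  for (i in 1:25) {
    p <- mutation_params(point_rate = runif(1), insert_prob = runif(1),
                         delete_prob = runif(1),
                         segment_len_range = sort(sample(1:600, 2)))
    g <- mutate_genome(g, p)
    expect_true(all(g >= 0L & g <= 255L))
    expect_true(length(g) >= 2000L && length(g) <= 20000L)
  }
})

test_that("a hand-built codon decodes to the expected gate blueprint", {
  arch <- arch_spec("baseline")
  loci <- rep(7L, 2000)
  loci[101:102] <- c(42L, 213L)
  loci[103] <- 0L                      # n_in = 1
  loci[104] <- 1L                      # n_out = 2
  loci[105:108] <- c(2L, 0L, 0L, 0L)   # input id 2 -> third legal input (unit 3)
  loci[109:112] <- c(1L, 3L, 0L, 0L)   # output ids 1, 3 -> units 4 and 6
  loci[113:114] <- c(3L, 6L)           # table: 3 %% 4 = 3, 6 %% 4 = 2
  g <- animats:::new_genome(loci)
  gates <- decode_genome(g, arch)
  expect_length(gates, 1L)
  expect_identical(gates[[1]]$inputs, 3L)
  expect_identical(gates[[1]]$outputs, c(4L, 6L))
  expect_identical(gates[[1]]$table, c(3L, 2L))
})

test_that("decoding is pure and wraps across the genome end", {
  arch <- arch_spec()
  loci <- rep(7L, 2000)
  loci[2000] <- 42L
  loci[1] <- 213L
  g <- animats:::new_genome(loci)
  expect_length(decode_genome(g, arch), 1L)
  expect_identical(decode_genome(g, arch), decode_genome(g, arch))
})

test_that("motor feedback legality restricts decoded gate inputs", {
  set.seed(12)
  loci <- unclass(random_genome(8000, seed_gates = TRUE, n_seed_codons = 40))
  g <- animats:::new_genome(loci)
  with_fb <- decode_genome(g, arch_spec("baseline"))
  motor_inputs <- function(gates, arch) {
    n <- animats:::n_units(arch)
    any(vapply(gates, function(x) any(x$inputs %in% c(n - 1L, n)), logical(1)))
  }
  expect_true(motor_inputs(with_fb, arch_spec("baseline")))
  no_fb <- decode_genome(g, arch_spec("no-feedback"))
  expect_false(motor_inputs(no_fb, arch_spec("no-feedback")))
})

test_that("genome files round-trip and are validated on read", {
  set.seed(8)
  g <- random_genome(2000)
  path <- withr::local_tempfile(fileext = ".txt")
  write_genome(g, path)
  expect_identical(read_genome(path), g)
  writeLines(as.character(rep(300L, 2500)), path)
  expect_error(read_genome(path), "0, 255")
})
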