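test_that("the earth mover's distance matches frozen reference values", {
  h2 <- animats:::hamming_cost(2L)
  h3 <- animats:::hamming_cost(3L)
  # reference values computed once with an LP solver on these fixtures
  expect_equal(emd(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5), h2), 1.0)
  expect_equal(emd(rep(0.25, 4), c(1, 0, 0, 0), h2), 1.0)
  expect_equal(emd(c(0.1, 0.2, 0.3, 0.4), c(0.4, 0.3, 0.2, 0.1), h2), 0.6)
  expect_equal(emd(rep(0.125, 8), c(rep(0, 7), 1), h3), 1.5)
  expect_equal(emd(c(0.3, 0, 0.2, 0, 0.1, 0, 0.4, 0),
                   c(0, 0.25, 0, 0.25, 0, 0.25, 0, 0.25), h3), 1.2)
})

test_that("the EMD is a metric on random distributions", {
  set.seed(61)
  h <- animats:::hamming_cost(3L)
  for (i in 1:5) {
    p <- runif(8); p <- p / sum(p)
    q <- runif(8); q <- q / sum(q)
    r <- runif(8); r <- r / sum(r)
    expect_equal(emd(p, p, h), 0)
    expect_equal(emd(p, q, h), emd(q, p, h), tolerance = 1e-9)
    expect_lte(emd(p, r, h), emd(p, q, h) + emd(q, r, h) + 1e-9)
    expect_gte(emd(p, q, h), 0)
  }
})

test_that("conditioning clamps sensors and freezes background units", {
  # memory 3 copies sensor 1; memory 4 copies memory 3
  b <- markov_brain(arch_spec("smallbrain"),
                    list(identity_gate(1, 3), identity_gate(3, 4)))
  # sensor clamped to 1: unit 3 goes to 1 regardless of subsystem state
  sys1 <- condition_tpm(b, c(3L, 4L), c(1, 0, 0, 0, 0, 0))
  expect_true(all(sys1$tpm[, 1] == 1))
  sys0 <- condition_tpm(b, c(3L, 4L), c(0, 0, 0, 0, 0, 0))
  expect_true(all(sys0$tpm[, 1] == 0))
  # unit 4 copies the subsystem's own unit 3 (the low-order row bit)
  expect_identical(sys1$tpm[, 2], c(0, 1, 0, 1))
  # background freeze: unit 4 outside the system, clamped at its observed state
  sys_b <- condition_tpm(b, 3L, c(1, 0, 0, 1, 0, 0))
  expect_identical(dim(sys_b$tpm), c(2L, 1L))
  expect_true(all(sys_b$tpm[, 1] == 1))
})

test_that("conditioning a no-gate brain gives point-mass effects at zero", {
  b <- markov_brain(arch_spec("smallbrain"), list())
  sys <- condition_tpm(b, 3:5, rep(0L, 6))
  expect_true(all(sys$tpm == 0))
  er <- animats:::effect_repertoire(sys, integer(0), 1:3)
  expect_equal(er, c(1, rep(0, 7)))  # all mass on the all-zero state
})

test_that("the 2-unit swap system conditions to the identity TPM swap", {
  sys <- condition_tpm(copy_loop_brain(), c(3L, 4L), c(0, 0, 1, 0, 0, 0))
  expect_identical(sys$tpm, matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2))
})

test_that("candidate systems exclude sensors and respect the size guard", {
  b <- markov_brain(arch_spec(), list())
  expect_error(condition_tpm(b, c(1L, 3L), rep(0L, 8)), "sensor")
  expect_error(condition_tpm(b, 3:8, rep(0L, 8), max_units = 4), "exceeds")
})

test_that("a mechanism with no inputs or outputs in the system has phi 0", {
  b <- markov_brain(arch_spec("smallbrain"), list())
  sys <- condition_tpm(b, c(3L, 4L), rep(0L, 6))
  expect_equal(small_phi(sys, 3L)$phi, 0)
})

test_that("each unit of the copy loop is an irreducible mechanism", {
  sys <- condition_tpm(copy_loop_brain(), c(3L, 4L), c(0, 0, 1, 0, 0, 0))
  for (u in c(3L, 4L)) {
    sp <- small_phi(sys, u)
    expect_equal(sp$phi, 0.5)
    expect_identical(sp$cause$purview, setdiff(c(3L, 4L), u))
  }
  # the joint mechanism is reducible: the partition into the two copies is lossless
  expect_equal(small_phi(sys, c(3L, 4L))$phi, 0)
})

test_that("mechanisms spanning independent halves are reducible", {
  sys <- condition_tpm(disconnected_brain(), c(3L, 4L), c(0, 0, 1, 0, 0, 0))
  expect_equal(small_phi(sys, c(3L, 4L))$phi, 0)
})

test_that("feed-forward and disconnected systems have big Phi zero", {
  chain_sys <- condition_tpm(chain_brain(), 3:5, c(1, 0, 1, 0, 0, 0))
  expect_equal(big_phi(chain_sys)$phi, 0)
  disc_sys <- condition_tpm(disconnected_brain(), c(3L, 4L), c(0, 0, 1, 1, 0, 0))
  expect_equal(big_phi(disc_sys)$phi, 0)
})

test_that("the mutual copy system integrates with two concepts", {
  sys <- condition_tpm(copy_loop_brain(), c(3L, 4L), c(0, 0, 1, 0, 0, 0))
  res <- big_phi(sys)
  expect_gt(res$phi, 0)
  expect_identical(res$n_concepts, 2L)
  expect_setequal(res$concepts$mechanism, c("3", "4"))
})

test_that("phi agrees with the brute-force oracle on 2-unit systems", {
  set.seed(62)
  for (i in 1:4) {
    tpm <- random_deterministic_tpm(2L)
    state <- sample(0:1, 2, replace = TRUE)
    sys <- animats:::new_candidate_system(tpm, units = c(3L, 4L), state = state)
    for (mech in list(3L, 4L, c(3L, 4L))) {
      expect_equal(small_phi(sys, mech)$phi,
                   oracle_small_phi(tpm, 2L, state, match(mech, c(3L, 4L)))$phi,
                   tolerance = 1e-9)
    }
    expect_equal(big_phi(sys)$phi, oracle_big_phi(tpm, state)$phi,
                 tolerance = 1e-9)
  }
})

test_that("phi agrees with the brute-force oracle on 3-unit systems", {
  set.seed(63)
  units <- c(3L, 4L, 5L)
  for (i in 1:2) {
    tpm <- random_deterministic_tpm(3L)
    state <- sample(0:1, 3, replace = TRUE)
    sys <- animats:::new_candidate_system(tpm, units = units, state = state)
    o <- oracle_big_phi(tpm, state)
    r <- big_phi(sys)
    expect_equal(r$phi, o$phi, tolerance = 1e-9)
    expect_identical(r$n_concepts, o$n_concepts)
  }
  # and on the hand-wired 3-unit loop (unit i copies its predecessor)
  loop_tpm <- matrix(0, 8, 3)
  for (x in 0:7) {
    bits <- animats:::int_to_bits(x, 3L)
    loop_tpm[x + 1, ] <- bits[c(3L, 1L, 2L)]
  }
  state <- c(1L, 0L, 0L)
  sys <- animats:::new_candidate_system(loop_tpm, units, state)
  o <- oracle_big_phi(loop_tpm, state)
  r <- big_phi(sys)
  expect_equal(r$phi, o$phi, tolerance = 1e-9)
  expect_gt(r$phi, 0)
})

test_that("lifetime maximization handles trivial and singleton cases", {
  w <- builtin_world("original")
  b0 <- markov_brain(arch_spec("smallbrain"), list())
  log0 <- run_trial(w, b0, trial_config(group_size = 1, T = 5, seed = 1))
  r0 <- phi_max_over_lifetime(b0, log0, max_units = 3)
  expect_equal(r0$phi_max, 0)
  expect_identical(r0$n_concepts, 0L)

  # a brain visiting a single state: the lifetime result equals big_phi there
  b <- copy_loop_brain()
  st <- animats:::bits_to_int(c(0, 0, 0, 0, 0, 0))
  log1 <- scripted_trial_log(w, data.frame(animat = 1, t = 1:3, x = 5, y = 5))
  log1$state <- st
  r1 <- phi_max_over_lifetime(b, log1, max_units = 2)
  direct <- big_phi(condition_tpm(b, c(3L, 4L), animats:::int_to_bits(st, 6L)))
  expect_equal(r1$phi_max, direct$phi)
})

test_that("adding visited states never decreases the lifetime maximum", {
  w <- builtin_world("original")
  b <- copy_loop_brain()
  mk_log <- function(states) {
    log <- scripted_trial_log(w, data.frame(animat = 1, t = seq_along(states),
                                            x = 5, y = 5))
    log$state <- states
    log
  }
  few <- phi_max_over_lifetime(b, mk_log(c(0L, 4L)), max_units = 2)
  more <- phi_max_over_lifetime(b, mk_log(c(0L, 4L, 8L, 12L)), max_units = 2)
  expect_gte(more$phi_max, few$phi_max)
})

test_that("oversized brains report not-computed rather than an approximation", {
  b <- markov_brain(arch_spec("bigbrain"), list())  # 10 computational units
  w <- builtin_world("original")
  log <- run_trial(w, b, trial_config(group_size = 1, T = 3, seed = 1))
  r <- phi_max_over_lifetime(b, log)
  expect_false(r$computed)
  expect_true(is.na(r$phi_max))
})
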