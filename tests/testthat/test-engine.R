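test_that("sensors have a detection range of exactly one cell", {
  w <- load_world(c("########", "#......#", "#......#", "#......#", "########"))
  occ <- matrix(0L, w$height, w$width)
  arch <- arch_spec("baseline")
  # wall directly ahead (facing up from y = 1)
  expect_identical(sense(w, occ, x = 3, y = 1, orientation = "up", arch), c(1L, 0L))
  # wall two cells ahead: nothing fires
  expect_identical(sense(w, occ, x = 3, y = 2, orientation = "up", arch), c(0L, 0L))
  # another animat ahead fires the agent sensor only
  occ[2, 4] <- 1L  # cell (x=3, y=1)
  expect_identical(sense(w, occ, x = 3, y = 2, orientation = "up", arch), c(0L, 1L))
})

test_that("a universal sensor cannot distinguish walls from animats", {
  w <- load_world(c("########", "#......#", "#......#", "#......#", "########"))
  occ <- matrix(0L, w$height, w$width)
  arch <- arch_spec("w=a")
  expect_identical(sense(w, occ, 3, 1, "up", arch), 1L)     # wall
  occ[3, 4] <- 1L                                           # animat at (3, 2)
  expect_identical(sense(w, occ, 3, 3, "up", arch), 1L)     # animat
  expect_identical(sense(w, occ, 1, 2, "down", arch), 0L)   # empty
})

test_that("motor states resolve to actions and turns close under rotation", {
  expect_identical(resolve_action(c(0, 0)), "none")
  expect_identical(resolve_action(c(1, 1)), "forward")
  expect_identical(resolve_action(c(1, 0)), "left")
  expect_identical(resolve_action(c(0, 1)), "right")
  o <- "up"
  for (i in 1:4) o <- animats:::ORIENTATIONS[
    (animats:::orient_index(o) + 3L) %% 4L + 1L]
  expect_identical(o, "up")
})

test_that("an idle brain stays on its start slot for the whole trial", {
  w <- builtin_world("original")
  b <- markov_brain(arch_spec(), list())
  log <- run_trial(w, b, trial_config(group_size = 5, T = 100, seed = 2))
  expect_identical(sum(log$crossing), 0L)
  expect_true(all(log$action == "none"))
  for (a in 1:5) {
    rows <- log[log$animat == a, ]
    expect_identical(length(unique(rows$x)), 1L)
    expect_identical(length(unique(rows$y)), 1L)
  }
  expect_identical(attr(log, "scores"), rep(0, 5))
})

test_that("scripted gate transits register one crossing per room change", {
  w <- builtin_world("original")
  log <- oscillator_log(w)
  expect_identical(sum(log$crossing), 5L)
  expect_true(all(log$x[log$crossing] %in% c(15L, 17L)))
})

test_that("crossings inside the refractory window are unrewarded", {
  w <- builtin_world("original")
  expect_identical(score_animat(crossing_pair_log(w, 50), animat = 1), 1)
  expect_identical(score_animat(crossing_pair_log(w, 100), animat = 1), 1)
  expect_identical(score_animat(crossing_pair_log(w, 101), animat = 1), 2)
})

test_that("one co-occupancy timestep costs exactly the collision penalty", {
  w <- builtin_world("original")
  log <- collision_log(w)
  expect_identical(sum(log$collided), 2L)
  expect_equal(score_animat(log, animat = 1), -0.075)
  expect_equal(score_animat(log, animat = 2), -0.075)
  # with the penalty off the same log scores zero
  expect_equal(score_animat(log, animat = 1,
                            rules = interaction_rules(penalty_active = FALSE)), 0)
})

test_that("per-trial scores never exceed the reward cap", {
  w <- builtin_world("original")
  log <- oscillator_log(w)
  expect_equal(score_animat(log, animat = 1), 4)
  rules <- attr(log, "rules")
  expect_lte(score_animat(log, animat = 1), 4 * rules$reward)
})

test_that("with the penalty off every score is a whole number of rewards", {
  w <- builtin_world("original")
  set.seed(31)
  b <- genome_brain(random_genome(5000, n_seed_codons = 12), arch_spec())
  log <- run_trial(w, b, trial_config(group_size = 20, T = 300, seed = 4),
                   interaction_rules(penalty_active = FALSE))
  s <- attr(log, "scores")
  expect_true(all(s >= 0))
  expect_true(all(abs(s - round(s)) < 1e-12))
})

test_that("blocking keeps cell occupancy at one everywhere", {
  w <- builtin_world("original")
  set.seed(32)
  b <- genome_brain(random_genome(5000, n_seed_codons = 20), arch_spec())
  log <- run_trial(w, b, trial_config(group_size = 50, T = 150, seed = 5),
                   interaction_rules(blocking = TRUE))
  occ <- dplyr::count(log, t, x, y)
  expect_identical(max(occ$n), 1L)
  expect_false(any(log$collided))
})

test_that("the engine's scores equal the trial-log scoring route", {
  w <- builtin_world("original")
  set.seed(33)
  for (s in 1:4) {
    b <- genome_brain(random_genome(5000, n_seed_codons = 12), arch_spec())
    log <- run_trial(w, b, trial_config(group_size = 15, T = 200, seed = s))
    expect_equal(score_animat(log)$score, attr(log, "scores"))
  }
})

test_that("identical seeds give bit-identical trial logs", {
  w <- builtin_world("original")
  set.seed(34)
  b <- genome_brain(random_genome(5000, n_seed_codons = 12), arch_spec())
  l1 <- run_trial(w, b, trial_config(group_size = 10, T = 100, seed = 9))
  l2 <- run_trial(w, b, trial_config(group_size = 10, T = 100, seed = 9))
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  l3 <- run_trial(w, b, trial_config(group_size = 10, T = 100, seed = 10))
  expect_false(identical(as.data.frame(l1), as.data.frame(l3)))
})

test_that("group sizes beyond the start slots are rejected", {
  w <- builtin_world("original")
  b <- markov_brain(arch_spec(), list())
  expect_error(run_trial(w, b, trial_config(group_size = 73)), "start slots")
})

test_that("a single-animat group's fitness equals that animat's score", {
  w <- builtin_world("original")
  set.seed(35)
  b <- genome_brain(random_genome(5000, n_seed_codons = 12), arch_spec())
  f <- score_genome(w, b, n_trials = 1, group_size = 1, T = 200, seed = 6)
  log <- run_trial(w, b, trial_config(group_size = 1, T = 200,
                                      seed = derive_seed(6, 1)))
  expect_equal(as.numeric(f), attr(log, "scores")[1])
})

test_that("an idle genome in a penalized group scores exactly zero", {
  w <- builtin_world("original")
  b <- markov_brain(arch_spec(), list())
  f <- score_genome(w, b, n_trials = 3, group_size = 36, T = 100, seed = 7)
  expect_identical(as.numeric(f), 0)
})

test_that("random group sizes are drawn from the 21-element vector", {
  w <- builtin_world("original")
  b <- markov_brain(arch_spec(), list())
  f <- score_genome(w, b, n_trials = 25, group_size = "random", T = 10, seed = 8)
  sizes <- attr(f, "group_sizes")
  expect_length(sizes, 25L)
  expect_true(all(sizes %in% group_size_vector()))
  expect_gt(length(unique(sizes)), 3L)
})

test_that("trial logs serialize to tabular text plus a JSON summary", {
  w <- builtin_world("original")
  log <- collision_log(w)
  base <- withr::local_tempfile()
  write_trial_log(log, base)
  tab <- utils::read.delim(paste0(base, ".tsv"))
  expect_identical(nrow(tab), nrow(log))
  js <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(js$scores$score, c(-0.075, -0.075))
})
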