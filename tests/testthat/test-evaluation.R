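test_that("reliability is the unweighted mean of the Original-condition TF", {
  gs <- group_size_vector()
  # constant profile returns the constant
  tab <- tibble::tibble(setup = "a", condition = "Original", group_size = gs,
                        TF = 2.5)
  expect_identical(reliability(tab)$R, 2.5)
  # arithmetic profile returns the closed-form mean
  tab2 <- tibble::tibble(setup = "a", condition = "Original", group_size = gs,
                         TF = seq_along(gs) / 21)
  expect_equal(reliability(tab2)$R, mean(seq_len(21) / 21))
  # independent summation oracle to 1e-12
  set.seed(51)
  tf <- runif(21, 0, 4)
  tab3 <- tibble::tibble(setup = "a", condition = "Original", group_size = gs,
                         TF = tf)
  acc <- 0
  for (v in tf) acc <- acc + v
  expect_lt(abs(reliability(tab3)$R - acc / 21), 1e-12)
  expect_gte(reliability(tab3)$R, min(tf))
  expect_lte(reliability(tab3)$R, max(tf))
})

test_that("reliability names missing group sizes", {
  tab <- tibble::tibble(setup = "a", condition = "Original",
                        group_size = group_size_vector()[-3], TF = 1)
  expect_error(reliability(tab), "group size")
  expect_error(reliability(tibble::tibble(setup = "a", condition = "Blocked",
                                          group_size = 1, TF = 1)), "Original")
})

test_that("an idle brain sweeps to zero task fitness everywhere", {
  b <- markov_brain(arch_spec(), list())
  sw <- task_fitness_sweep(b, sweep_spec(conditions = c("Original", "4 Rooms"),
                                         group_sizes = c(1L, 14L),
                                         trials_per_cell = 2, T = 30, seed = 1),
                           setup = "idle")
  expect_identical(nrow(sw), 4L)
  expect_true(all(sw$TF == 0))
})

test_that("sweeps are deterministic given their seed", {
  set.seed(52)
  b <- genome_brain(random_genome(4000, n_seed_codons = 10), arch_spec())
  spec <- sweep_spec(conditions = "Original", group_sizes = c(4L, 22L),
                     trials_per_cell = 2, T = 50, seed = 3)
  s1 <- task_fitness_sweep(b, spec)
  s2 <- task_fitness_sweep(b, spec)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("behavior profiles pool animat-timesteps and sum to one", {
  w <- builtin_world("original")
  idle <- run_trial(w, markov_brain(arch_spec(), list()),
                    trial_config(group_size = 3, T = 50, seed = 1))
  prof <- behavior_profile(idle)
  expect_equal(prof$fraction[prof$action == "none"], 1)
  expect_equal(sum(prof$fraction), 1, tolerance = 1e-12)
})

test_that("an alternating turn/forward script profiles to (0, 1/2, 1/2)", {
  w <- builtin_world("original")
  steps <- data.frame(animat = 1, t = 1:40, x = 5, y = 5,
                      action = rep(c("left", "forward"), 20))
  log <- scripted_trial_log(w, steps)
  prof <- behavior_profile(log)
  expect_equal(prof$fraction[prof$action == "none"], 0)
  expect_equal(prof$fraction[prof$action == "turn"], 0.5)
  expect_equal(prof$fraction[prof$action == "forward"], 0.5)
})

test_that("transition tables count consecutive SM pairs and rows sum to 1", {
  w <- builtin_world("original")
  # deterministic cycle: (S=0,M=0) -> (0,1) -> (0,0) -> ...
  steps <- data.frame(animat = 1, t = 1:41, x = 5, y = 5,
                      action = rep(c("none", "left"), length.out = 41),
                      sensor_state = 0L)
  tt <- transition_table(scripted_trial_log(w, steps))
  expect_equal(tt["00", "01"], 1)
  expect_equal(tt["01", "00"], 1)
  expect_true(all(is.na(tt["10", ])))  # never sensed: no support
  counts <- attr(tt, "counts")
  expect_identical(sum(counts), 40)
  on <- rowSums(counts) > 0
  expect_equal(unname(rowSums(tt[on, , drop = FALSE])), rep(1, sum(on)))
})

test_that("an always-idle log concentrates transitions at 00 -> 00", {
  w <- builtin_world("original")
  log <- run_trial(w, markov_brain(arch_spec(), list()),
                   trial_config(group_size = 2, T = 30, seed = 2))
  tt <- transition_table(log)
  expect_equal(tt["00", "00"], 1)
})

test_that("table_diff is elementwise and zero against itself", {
  w <- builtin_world("original")
  log <- run_trial(w, markov_brain(arch_spec(), list()),
                   trial_config(group_size = 2, T = 30, seed = 2))
  tt <- transition_table(log)
  d <- table_diff(tt, tt)
  expect_true(all(d[!is.na(d)] == 0))
})

test_that("occupancy maps conserve the group size", {
  w <- builtin_world("original")
  idle <- run_trial(w, markov_brain(arch_spec(), list()),
                    trial_config(group_size = 1, T = 25, seed = 3))
  occ <- occupancy_heatmap(idle, w)
  expect_equal(sum(occ$occupancy), 1)
  expect_identical(sum(occ$occupancy > 0), 1L)  # a single cell, its start slot
  set.seed(53)
  b <- genome_brain(random_genome(4000, n_seed_codons = 10), arch_spec())
  log <- run_trial(w, b, trial_config(group_size = 12, T = 40, seed = 4))
  occ2 <- occupancy_heatmap(log, w)
  expect_equal(sum(occ2$occupancy), 12)
})

test_that("averaging two replicates equals the cellwise mean", {
  w <- builtin_world("original")
  set.seed(54)
  b <- genome_brain(random_genome(4000, n_seed_codons = 10), arch_spec())
  l1 <- run_trial(w, b, trial_config(group_size = 5, T = 30, seed = 5))
  l2 <- run_trial(w, b, trial_config(group_size = 5, T = 30, seed = 6))
  both <- occupancy_heatmap(list(l1, l2), w)
  m1 <- occupancy_heatmap(l1, w)$occupancy
  m2 <- occupancy_heatmap(l2, w)$occupancy
  expect_equal(both$occupancy, (m1 + m2) / 2)
})

test_that("empty inputs raise errors rather than empty results", {
  expect_error(behavior_profile(list()), "no trial logs")
  expect_error(transition_table(list()), "no trial logs")
})
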