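# Post-evolutionary evaluation: task-fitness sweeps, reliability, behavior
# profiles, state-transition tables, occupancy maps.

#' Sweep specification for post-evolutionary tests
#'
#' @param conditions Subset of the condition names in [test_conditions()]
#'   (default: all eight).
#' @param group_sizes Group sizes to test (default: the 21-element
#'   [group_size_vector()]).
#' @param trials_per_cell Trials per (condition, group size) cell.
#' @param T Timesteps per trial.
#' @param seed Master seed for the sweep.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(conditions = NULL, group_sizes = NULL,
                       trials_per_cell = 30L, T = 500L, seed = 1L) {
  all_cond <- test_conditions()
  conditions <- conditions %||% all_cond$condition
  if (!all(conditions %in% all_cond$condition)) {
    stop_animats("unknown condition(s): ",
                 paste(setdiff(conditions, all_cond$condition), collapse = ", "))
  }
  structure(list(conditions = conditions,
                 group_sizes = as.integer(group_sizes %||% group_size_vector()),
                 trials_per_cell = as.integer(trials_per_cell),
                 T = as.integer(T), seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Task-fitness sweep across conditions and group sizes
#'
#' Re-tests evolved brains under every requested (condition, group size)
#' cell: each cell runs `trials_per_cell` trials per brain via
#' [score_genome()] and records the mean task fitness TF, averaged across
#' the supplied brains (the analogue of averaging across evolution
#' replicates).
#'
#' @param brains A single `markov_brain` or a (possibly named) list of them.
#' @param spec A [sweep_spec()].
#' @param setup Label stored in the output (the evolutionary setup the
#'   brains came from).
#' @return A `task_fitness_table` tibble with columns `setup`, `condition`,
#'   `group_size`, `TF`, `n_brains`, `n_trials`, `seed`.
#' @examples
#' b <- markov_brain(arch_spec(), list())
#' sw <- task_fitness_sweep(b, sweep_spec(conditions = "Original",
#'                                        group_sizes = c(1, 4),
#'                                        trials_per_cell = 2, T = 50))
#' sw$TF
#' @export
task_fitness_sweep <- function(brains, spec = sweep_spec(), setup = "unknown") {
  if (inherits(brains, "markov_brain")) brains <- list(brains)
  stopifnot(all(vapply(brains, inherits, logical(1), "markov_brain")))
  conds <- test_conditions()
  conds <- conds[conds$condition %in% spec$conditions, ]
  worlds <- lapply(unique(conds$world), builtin_world)
  names(worlds) <- unique(conds$world)
  grid <- tidyr::expand_grid(ci = seq_len(nrow(conds)), group_size = spec$group_sizes)
  rows <- purrr::pmap_dfr(grid, function(ci, group_size) {
    cond <- conds[ci, ]
    world <- worlds[[cond$world]]
    rules <- condition_rules(cond)
    tf <- vapply(seq_along(brains), function(bi) {
      as.numeric(score_genome(world, brains[[bi]],
                              n_trials = spec$trials_per_cell,
                              group_size = group_size, rules = rules,
                              T = spec$T,
                              seed = derive_seed(spec$seed, ci, group_size, bi)))
    }, numeric(1))
    tibble(setup = setup, condition = cond$condition, group_size = group_size,
           TF = mean(tf), n_brains = length(brains),
           n_trials = spec$trials_per_cell,
           seed = derive_seed(spec$seed, ci, group_size, 0L))
  })
  structure(rows, spec = spec,
            class = c("task_fitness_table", class(tibble())))
}

#' Reliability across group sizes
#'
#' Reliability R is the unweighted mean of the task-fitness values across
#' the swept group sizes in the Original test condition; it always lies
#' between the smallest and largest TF entering the mean.
#'
#' @param table A `task_fitness_table` from [task_fitness_sweep()] (or any
#'   data frame with columns `setup`, `condition`, `group_size`, `TF`).
#' @param n_sizes Number of group sizes that must be present (default 21).
#' @return A tibble with one row per setup: `setup`, `R`, `n_sizes`.
#' @examples
#' tab <- data.frame(setup = "x", condition = "Original",
#'                   group_size = group_size_vector(), TF = 1)
#' reliability(tab)$R
#' @export
reliability <- function(table, n_sizes = 21L) {
  tab <- dplyr::filter(as_tibble(table), .data$condition == "Original")
  if (nrow(tab) == 0L) stop_animats("table has no Original condition")
  expected <- group_size_vector()
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$setup),
    R = mean(.data$TF), n_sizes = dplyr::n(), .groups = "drop")
  if (!is.null(n_sizes)) {
    for (s in unique(tab$setup)) {
      have <- tab$group_size[tab$setup == s]
      missing <- setdiff(expected[seq_len(min(n_sizes, length(expected)))], have)
      if (length(have) < n_sizes) {
        stop_animats("setup '", s, "' misses group size(s) ",
                     paste(missing, collapse = ", "), " in the Original condition")
      }
    }
  }
  out
}

as_log_list <- function(logs) {
  if (inherits(logs, "trial_log")) list(logs) else logs
}

#' Behavior profile: stand still, turn, or move forward
#'
#' Pools all animat-timesteps of the supplied trial logs per group size and
#' reports the fraction of realized actions that were no movement, a turn,
#' or a forward step (a blocked forward attempt counts as no movement). The
#' three fractions sum to 1.
#'
#' @param logs A `trial_log` or a list of them.
#' @return A `behavior_profile` tibble: `group_size`, `action` (none / turn /
#'   forward), `fraction`, `n_steps`.
#' @export
behavior_profile <- function(logs) {
  logs <- as_log_list(logs)
  if (length(logs) == 0L) stop_animats("no trial logs supplied")
  df <- purrr::map_dfr(logs, function(l) {
    tibble(group_size = attr(l, "group_size"),
           action = dplyr::case_match(l$action, "left" ~ "turn", "right" ~ "turn",
                                      .default = l$action))
  })
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$group_size, .data$action),
    n = dplyr::n(), .groups = "drop_last")
  out <- dplyr::mutate(out, fraction = .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  full <- tidyr::expand_grid(group_size = sort(unique(df$group_size)),
                             action = c("none", "turn", "forward"))
  out <- dplyr::left_join(full, out, by = c("group_size", "action"))
  out <- dplyr::mutate(out, n = dplyr::coalesce(.data$n, 0L),
                       fraction = dplyr::coalesce(.data$fraction, 0))
  out <- dplyr::rename(out, n_steps = "n")
  structure(dplyr::arrange(out, .data$group_size,
                           match(.data$action, c("none", "turn", "forward"))),
            class = c("behavior_profile", class(tibble())))
}

#' Sensor/motor state-transition table
#'
#' Classifies each animat-timestep into a two-bit state SM: S = 1 iff any
#' sensor fired, M = 1 iff the animat moved or turned (realized action). The
#' table holds P(SM at t+1 | SM at t) estimated over all consecutive
#' timestep pairs within each animat's lifetime, pooled over the supplied
#' logs. Rows with zero support are reported as `NA` rather than normalized.
#'
#' @param logs A `trial_log` or a list of them.
#' @return A `transition_table`: a 4 x 4 matrix (rows = state at t, columns
#'   = state at t+1, in order 00, 01, 10, 11) with a `counts` attribute.
#' @export
transition_table <- function(logs) {
  logs <- as_log_list(logs)
  if (length(logs) == 0L) stop_animats("no trial logs supplied")
  states <- c("00", "01", "10", "11")
  counts <- matrix(0, 4L, 4L, dimnames = list(states, states))
  for (l in logs) {
    if (nrow(l) == 0L) next
    s <- as.integer(l$sensor_state > 0L)
    m <- as.integer(l$action != "none")
    code <- 2L * s + m + 1L  # "00"=1, "01"=2, "10"=3, "11"=4
    for (a in unique(l$animat)) {
      idx <- which(l$animat == a)
      idx <- idx[order(l$t[idx])]
      if (length(idx) < 2L) next
      from <- code[idx[-length(idx)]]
      to <- code[idx[-1L]]
      tab <- table(factor(from, levels = 1:4), factor(to, levels = 1:4))
      counts <- counts + as.matrix(tab)
    }
  }
  if (sum(counts) == 0L) stop_animats("logs contain no transitions")
  p <- counts / rowSums(counts)
  p[rowSums(counts) == 0L, ] <- NA_real_
  structure(p, counts = counts, class = c("transition_table", "matrix", "array"))
}

#' Difference between two transition tables
#'
#' Elementwise `P(A) - P(B)`; cells lacking support in either table are
#' `NA`. Negative values mean the transition is more frequent in `B`.
#'
#' @param a,b `transition_table` objects (or 4 x 4 matrices).
#' @return A signed 4 x 4 matrix.
#' @export
table_diff <- function(a, b) {
  stopifnot(all(dim(a) == c(4L, 4L)), all(dim(b) == c(4L, 4L)))
  out <- unclass(a) - unclass(b)
  attr(out, "counts") <- NULL
  class(out) <- c("matrix", "array")
  out
}

#' Mean occupancy per cell
#'
#' Average number of animats on each cell, across timesteps and across the
#' supplied logs (replicates). Within one log the per-timestep cell sums
#' equal the group size, so the map's total equals the mean group size.
#'
#' @param logs A `trial_log` or a list of them.
#' @param world The `animat_world` the logs were produced in.
#' @return An `occupancy_map` tibble: `x`, `y`, `occupancy` (one row per
#'   world cell).
#' @export
occupancy_heatmap <- function(logs, world) {
  logs <- as_log_list(logs)
  stopifnot(inherits(world, "animat_world"))
  acc <- matrix(0, world$height, world$width)
  for (l in logs) {
    T <- attr(l, "T")
    counts <- matrix(0, world$height, world$width)
    for (i in seq_len(nrow(l))) {
      counts[l$y[i] + 1L, l$x[i] + 1L] <- counts[l$y[i] + 1L, l$x[i] + 1L] + 1
    }
    acc <- acc + counts / T
  }
  acc <- acc / length(logs)
  grid <- tidyr::expand_grid(y = 0:(world$height - 1L), x = 0:(world$width - 1L))
  structure(tibble(x = grid$x, y = grid$y,
                   occupancy = acc[cbind(grid$y + 1L, grid$x + 1L)]),
            world = world$name,
            class = c("occupancy_map", class(tibble())))
}
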