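# Trial simulation: interaction rules, sensing, actions, logging, scoring.

ORIENTATIONS <- c("up", "right", "down", "left")
ACTIONS <- c("none", "left", "right", "forward")

#' Interaction rules between animats
#'
#' With the penalty active, an animat loses `penalty` points for every
#' timestep it shares a cell with at least one other animat. With blocking
#' active, animats cannot move onto an occupied cell (and so never overlap).
#' A rewarded gate crossing earns `reward` points; after any crossing the
#' same animat earns no further reward for `refractory` timesteps (a repeat
#' crossing within the window is unrewarded and itself restarts the window).
#'
#' @param penalty_active Is the collision penalty imposed?
#' @param penalty Points lost per collision timestep.
#' @param blocking May two animats share a cell?
#' @param reward Points per rewarded gate crossing.
#' @param refractory Refractory period in timesteps.
#' @return An `interaction_rules` list.
#' @export
interaction_rules <- function(penalty_active = TRUE, penalty = 0.075,
                              blocking = FALSE, reward = 1.0, refractory = 100L) {
  stopifnot(penalty >= 0, reward > 0, refractory >= 0)
  structure(list(penalty_active = isTRUE(penalty_active), penalty = penalty,
                 blocking = isTRUE(blocking), reward = reward,
                 refractory = as.integer(refractory)),
            class = "interaction_rules")
}

#' Trial configuration
#'
#' @param group_size Number of clone animats placed in the world.
#' @param T Timesteps per trial.
#' @param seed Integer seed for the trial's random placement, orientations
#'   and serial update order.
#' @param reward_cap Maximum rewarded crossings per animat per trial.
#' @return A `trial_config` list.
#' @export
trial_config <- function(group_size = 36L, T = 500L, seed = 1L, reward_cap = 4L) {
  stopifnot(group_size >= 1L, T >= 1L, reward_cap >= 0L)
  structure(list(group_size = as.integer(group_size), T = as.integer(T),
                 seed = as.integer(seed), reward_cap = as.integer(reward_cap)),
            class = "trial_config")
}

orient_index <- function(orientation) {
  if (is.numeric(orientation)) {
    return(as.integer(orientation))
  }
  m <- match(orientation, ORIENTATIONS) - 1L
  if (anyNA(m)) stop_animats("orientation must be one of ", paste(ORIENTATIONS, collapse = ", "))
  m
}

side_offset <- function(orientation, side) {
  dir <- orient_index(orientation)
  dir <- switch(side, front = dir, left = (dir + 3L) %% 4L, right = (dir + 1L) %% 4L,
                stop_animats("side must be front, left or right"))
  list(dx = c(0L, 1L, 0L, -1L)[dir + 1L], dy = c(-1L, 0L, 1L, 0L)[dir + 1L])
}

#' Read an animat's sensors
#'
#' Each sensor inspects the single cell adjacent to the animat on its side
#' (detection range of one cell, relative to the current orientation). A wall
#' sensor fires iff that cell is a wall or the world boundary; an agent
#' sensor fires iff another animat occupies it; a universal sensor fires on
#' either and cannot tell them apart.
#'
#' @param world An `animat_world`.
#' @param occupancy Integer matrix (height x width) of animat counts per
#'   cell.
#' @param x,y Animat position (0-based).
#' @param orientation `"up"`, `"right"`, `"down"`, or `"left"` (or 0-3).
#' @param arch An [arch_spec()]; its sensor slots determine the reading.
#' @return Integer 0/1 vector of length `n_sensors`.
#' @examples
#' w <- builtin_world("original")
#' occ <- matrix(0L, w$height, w$width)
#' sense(w, occ, x = 1, y = 1, orientation = "up", arch = arch_spec())
#' @export
sense <- function(world, occupancy, x, y, orientation, arch) {
  vapply(seq_len(arch$n_sensors), function(s) {
    off <- side_offset(orientation, arch$sensors$side[s])
    cx <- x + off$dx; cy <- y + off$dy
    wall <- cx < 0L || cx >= world$width || cy < 0L || cy >= world$height ||
      cell_at(world, cx, cy) == 1L
    agent <- !wall && occupancy[cy + 1L, cx + 1L] > 0L
    fired <- switch(arch$sensors$kind[s],
                    wall = wall, agent = agent, universal = wall || agent)
    as.integer(fired)
  }, integer(1))
}

#' Map motor states to an action
#'
#' Both motors on means move forward; one motor on means turn 90 degrees
#' (left motor only = turn left, right motor only = turn right, an arbitrary
#' but fixed labeling); both off means stand still.
#'
#' @param motor_bits Length-2 0/1 vector `(left, right)`.
#' @return One of `"none"`, `"left"`, `"right"`, `"forward"`.
#' @examples
#' resolve_action(c(1, 1))
#' @export
resolve_action <- function(motor_bits) {
  stopifnot(length(motor_bits) == 2L)
  m <- as.integer(motor_bits)
  if (all(m == 1L)) return("forward")
  if (m[1L] == 1L) return("left")
  if (m[2L] == 1L) return("right")
  "none"
}

world_matrices <- function(world) {
  room <- world$room
  room[is.na(room)] <- -1L
  reward_cell <- matrix(0L, world$height, world$width)
  for (k in seq_len(nrow(world$gates))) {
    reward_cell[world$gates$y[k] + 1L, world$gates$x[k] + 1L] <-
      as.integer(world$gates$rewarding[k])
  }
  slots <- cbind(world$start_slots$x, world$start_slots$y)
  storage.mode(slots) <- "integer"
  list(room = room, reward_cell = reward_cell, slots = slots)
}

sensor_codes <- function(arch) {
  list(kind = match(arch$sensors$kind, c("wall", "agent", "universal")) - 1L,
       side = match(arch$sensors$side, c("front", "left", "right")) - 1L)
}

#' Simulate one trial of a clone group
#'
#' Places `group_size` clones of one brain on distinct random start slots
#' with random orientations, then runs `T` timesteps. Animats update
#' serially in a per-trial random order; each animat senses the live
#' occupancy (already-moved animats are seen at their new positions), steps
#' its brain, and acts. Forward moves into walls are no-ops; forward moves
#' into occupied cells are no-ops under blocking. A crossing event is logged
#' when an animat's room label changes after passing through a gate cell.
#'
#' @param world An `animat_world`.
#' @param brain A [markov_brain()].
#' @param config A [trial_config()].
#' @param rules An [interaction_rules()].
#' @return A `trial_log` tibble with one row per animat-timestep: `t`,
#'   `animat`, `x`, `y`, `orientation`, `sensor_state` (sensor bits packed
#'   little-endian), `state` (full brain state as an integer), `action`
#'   (realized: a blocked forward attempt logs as `"none"`), `crossing`,
#'   `gate_rewarding`, `collided`. Per-animat scores are attached as the
#'   `scores` attribute.
#' @examples
#' w <- builtin_world("original")
#' b <- markov_brain(arch_spec(), list())
#' log <- run_trial(w, b, trial_config(group_size = 2, T = 10, seed = 1))
#' attr(log, "scores")
#' @export
run_trial <- function(world, brain, config = trial_config(), rules = interaction_rules()) {
  stopifnot(inherits(world, "animat_world"), inherits(brain, "markov_brain"),
            inherits(config, "trial_config"), inherits(rules, "interaction_rules"))
  if (config$group_size > nrow(world$start_slots)) {
    stop_animats("group_size ", config$group_size, " exceeds the ",
                 nrow(world$start_slots), " start slots of world '", world$name, "'")
  }
  wm <- world_matrices(world)
  sc <- sensor_codes(brain$arch)
  res <- cpp_run_trial(world$cell, wm$room, wm$reward_cell, wm$slots,
                       brain_state_table(brain), brain$n_units,
                       brain$arch$n_sensors, sc$kind, sc$side,
                       config$group_size, config$T,
                       rules$penalty_active, rules$penalty, rules$blocking,
                       rules$reward, rules$refractory, config$reward_cap,
                       config$seed, TRUE)
  log <- as_tibble(res$log)
  log$orientation <- ORIENTATIONS[log$orientation + 1L]
  log$action <- ACTIONS[log$action + 1L]
  log$crossing <- log$crossing == 1L
  log$gate_rewarding <- as.logical(log$gate_rewarding)
  log$collided <- log$collided == 1L
  new_trial_log(log, world = world$name, group_size = config$group_size,
                T = config$T, rules = rules, reward_cap = config$reward_cap,
                seed = config$seed, scores = res$score)
}

new_trial_log <- function(df, world, group_size, T, rules, reward_cap, seed = NA_integer_,
                          scores = NULL) {
  structure(as_tibble(df),
            world = world, group_size = as.integer(group_size), T = as.integer(T),
            rules = rules, reward_cap = as.integer(reward_cap), seed = seed,
            scores = scores,
            class = c("trial_log", class(tibble())))
}

#' Build a trial log from scripted trajectories
#'
#' Turns hand-written per-animat trajectories into a `trial_log`, deriving
#' gate-crossing events (room-label change through a gate cell) and
#' co-occupancy collisions exactly as the simulation engine does. This lets
#' every downstream stage (scoring, behavior profiles, transition tables,
#' occupancy maps, lifetime complexity) be exercised without running a brain.
#'
#' @param world An `animat_world`.
#' @param steps A data frame with columns `animat`, `t` (1..T contiguous per
#'   animat), `x`, `y`, and optionally `orientation`, `action`,
#'   `sensor_state`, `state` (defaults: `"up"`, derived from positions /
#'   `"none"`, 0, NA).
#' @param rules An [interaction_rules()] (stored for scoring defaults).
#' @param reward_cap Maximum rewarded crossings per animat per trial.
#' @return A `trial_log` tibble.
#' @examples
#' w <- builtin_world("original")
#' log <- scripted_trial_log(w, data.frame(animat = 1, t = 1:3,
#'                                         x = c(15, 16, 17), y = 15))
#' log$crossing
#' @export
scripted_trial_log <- function(world, steps, rules = interaction_rules(),
                               reward_cap = 4L) {
  stopifnot(inherits(world, "animat_world"))
  steps <- as_tibble(steps)
  stopifnot(all(c("animat", "t", "x", "y") %in% names(steps)))
  steps <- dplyr::arrange(steps, .data$animat, .data$t)
  if (!"orientation" %in% names(steps)) steps$orientation <- "up"
  if (!"sensor_state" %in% names(steps)) steps$sensor_state <- 0L
  if (!"state" %in% names(steps)) steps$state <- NA_integer_
  if (!"action" %in% names(steps)) {
    steps <- dplyr::mutate(
      dplyr::group_by(steps, .data$animat),
      action = dplyr::if_else(
        dplyr::row_number() > 1L &
          (.data$x != dplyr::lag(.data$x) | .data$y != dplyr::lag(.data$y)),
        "forward", "none"),
      .keep = "all")
    steps <- dplyr::ungroup(steps)
  }
  if (any(cell_at(world, steps$x, steps$y) == 1L)) {
    stop_animats("scripted trajectory enters a wall cell")
  }

  # derive crossings per animat
  steps$crossing <- FALSE
  steps$gate_rewarding <- NA
  for (a in unique(steps$animat)) {
    rows <- which(steps$animat == a)
    xs <- steps$x[rows]; ys <- steps$y[rows]
    cells <- cell_at(world, xs, ys)
    rooms <- room_at(world, xs, ys)
    last_room <- rooms[1L]
    if (is.na(last_room)) stop_animats("scripted trajectories must start inside a room")
    last_gate_rw <- NA
    for (i in seq_along(rows)[-1L]) {
      if (cells[i] == 2L) {
        g <- world$gates
        last_gate_rw <- g$rewarding[g$x == xs[i] & g$y == ys[i]]
      } else if (!is.na(rooms[i]) && rooms[i] != last_room) {
        steps$crossing[rows[i]] <- TRUE
        steps$gate_rewarding[rows[i]] <- last_gate_rw
        last_room <- rooms[i]
      } else {
        last_room <- rooms[i]
      }
    }
  }

  # co-occupancy: more than one animat on a cell at a timestep
  steps <- dplyr::mutate(
    dplyr::group_by(steps, .data$t, .data$x, .data$y),
    collided = dplyr::n() > 1L)
  steps <- dplyr::ungroup(steps)
  steps <- dplyr::arrange(steps, .data$t, .data$animat)

  new_trial_log(
    steps[, c("t", "animat", "x", "y", "orientation", "sensor_state", "state",
              "action", "crossing", "gate_rewarding", "collided")],
    world = world$name, group_size = length(unique(steps$animat)),
    T = max(steps$t), rules = rules, reward_cap = reward_cap)
}

#' Score animats from a trial log
#'
#' Implements the per-animat fitness: each gate crossing on a rewarding gate
#' earns `reward` points provided no crossing of any kind occurred within the
#' preceding `refractory` timesteps and the animat has fewer than
#' `reward_cap` rewarded crossings so far; every timestep spent sharing a
#' cell with another animat costs `penalty` points while the penalty is
#' active.
#'
#' @param log A `trial_log`.
#' @param animat Optional single animat id; if given, the numeric score of
#'   that animat is returned.
#' @param rules An [interaction_rules()]; defaults to the rules stored in
#'   the log.
#' @param reward_cap Maximum rewarded crossings; defaults to the log's.
#' @return A tibble with columns `animat`, `score`, `n_rewarded`,
#'   `n_collisions` (or a single number if `animat` is given).
#' @examples
#' w <- builtin_world("original")
#' log <- run_trial(w, markov_brain(arch_spec(), list()),
#'                  trial_config(group_size = 1, T = 20, seed = 1))
#' score_animat(log, animat = 1)
#' @export
score_animat <- function(log, animat = NULL, rules = NULL, reward_cap = NULL) {
  stopifnot(inherits(log, "trial_log"))
  rules <- rules %||% attr(log, "rules")
  reward_cap <- reward_cap %||% attr(log, "reward_cap")
  ids <- sort(unique(log$animat))
  res <- purrr::map_dfr(ids, function(a) {
    rows <- log[log$animat == a, ]
    rows <- rows[order(rows$t), ]
    last_cross <- -Inf
    n_rew <- 0L
    for (i in which(rows$crossing)) {
      t <- rows$t[i]
      eligible <- isTRUE(rows$gate_rewarding[i]) && (t - last_cross > rules$refractory)
      if (eligible && n_rew < reward_cap) n_rew <- n_rew + 1L
      last_cross <- t
    }
    n_coll <- sum(rows$collided)
    tibble(animat = a, score = rules$reward * n_rew -
             if (rules$penalty_active) rules$penalty * n_coll else 0,
           n_rewarded = n_rew, n_collisions = n_coll)
  })
  if (!is.null(animat)) {
    return(res$score[match(animat, res$animat)])
  }
  res
}

#' Genome fitness: mean over trials of one random animat's score
#'
#' A genome's fitness is evaluated over `n_trials` independent trials with
#' random start positions, orientations and serial update order; in each
#' trial one animat is picked at random and its score recorded. The fitness
#' is the mean of these per-trial scores. For `group_size = "random"` each
#' trial's group size is drawn uniformly from `gs_vector`.
#'
#' @param world An `animat_world`.
#' @param brain A [markov_brain()], or an `animat_genome` (then `arch` is
#'   required).
#' @param arch Architecture used to decode a genome.
#' @param n_trials Trials per evaluation.
#' @param group_size Integer, or `"random"`.
#' @param gs_vector Group-size vector used when `group_size = "random"`;
#'   defaults to [group_size_vector()].
#' @param rules An [interaction_rules()].
#' @param T Timesteps per trial.
#' @param reward_cap Maximum rewarded crossings per animat per trial.
#' @param seed Master seed; per-trial seeds are derived with [derive_seed()].
#' @return The mean score (numeric scalar) with the per-trial scores in
#'   attribute `trial_scores`.
#' @examples
#' w <- builtin_world("original")
#' score_genome(w, markov_brain(arch_spec(), list()), n_trials = 2,
#'              group_size = 4, T = 50, seed = 1)
#' @export
score_genome <- function(world, brain, arch = NULL, n_trials = 30L,
                         group_size = 36L, gs_vector = NULL,
                         rules = interaction_rules(), T = 500L,
                         reward_cap = 4L, seed = 1L) {
  if (inherits(brain, "animat_genome")) {
    if (is.null(arch)) stop_animats("decoding a genome requires an architecture")
    brain <- genome_brain(brain, arch)
  }
  stopifnot(inherits(brain, "markov_brain"))
  gs_vector <- gs_vector %||% group_size_vector()
  if (identical(group_size, "random")) {
    old <- .Random.seed_get()
    set.seed(derive_seed(seed, 424243L))
    sizes <- sample(gs_vector, n_trials, replace = TRUE)
    .Random.seed_restore(old)
  } else {
    sizes <- rep(as.integer(group_size), n_trials)
  }
  if (max(sizes) > nrow(world$start_slots)) {
    stop_animats("group size exceeds available start slots")
  }
  seeds <- vapply(seq_len(n_trials), function(j) derive_seed(seed, j), integer(1))
  wm <- world_matrices(world)
  sc <- sensor_codes(brain$arch)
  scores <- cpp_score_trials(world$cell, wm$room, wm$reward_cell, wm$slots,
                             brain_state_table(brain), brain$n_units,
                             brain$arch$n_sensors, sc$kind, sc$side,
                             as.integer(sizes), as.integer(T),
                             rules$penalty_active, rules$penalty, rules$blocking,
                             rules$reward, rules$refractory, as.integer(reward_cap),
                             seeds)
  structure(mean(scores), trial_scores = scores, group_sizes = sizes)
}

# save/restore the global RNG state so internal draws don't disturb the user's
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Serialize a trial log
#'
#' Writes the per-animat-timestep table as tab-separated text plus a JSON
#' event summary (scores, crossing and collision counts, rules, seed).
#'
#' @param log A `trial_log`.
#' @param path Base path; `<path>.tsv` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  stopifnot(inherits(log, "trial_log"))
  utils::write.table(as.data.frame(log), paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  scores <- score_animat(log)
  jsonlite::write_json(
    list(world = attr(log, "world"), group_size = attr(log, "group_size"),
         T = attr(log, "T"), seed = attr(log, "seed"),
         rules = unclass(attr(log, "rules")), reward_cap = attr(log, "reward_cap"),
         scores = scores),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
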