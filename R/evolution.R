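# Generation-based genetic algorithm (asexual, no crossover).

#' Configure an evolution run
#'
#' @param setup A setup label resolved by [evolutionary_setup()], or a list with
#'   elements `label`, `world`, `arch`, `rules`, `group_size`.
#' @param population_size Genomes per generation.
#' @param generations Number of generations.
#' @param trials_per_genome Trials per fitness evaluation.
#' @param genome_length Initial genome length in loci.
#' @param seed_gates Plant start codons in first-generation genomes? (see
#'   [random_genome()]).
#' @param mutation A [mutation_params()] object.
#' @param selection `"roulette"` (fitness-proportional on shifted fitness) or
#'   `"tournament"`.
#' @param tournament_k Tournament size for tournament selection.
#' @param epsilon Shift floor for roulette selection (keeps strictly positive
#'   selection mass when fitnesses are equal or negative).
#' @param elitism Number of top genomes copied unchanged each generation.
#' @param T Timesteps per trial.
#' @param reward_cap Maximum rewarded crossings per animat per trial.
#' @param seed Master seed; every genome initialization, trial, selection and
#'   mutation draw uses a child seed derived from it, so runs replay
#'   bit-identically.
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(setup = "0.50", population_size = 100L,
                             generations = 10000L, trials_per_genome = 30L,
                             genome_length = 5000L, seed_gates = TRUE,
                             mutation = mutation_params(),
                             selection = c("roulette", "tournament"),
                             tournament_k = 2L, epsilon = 1e-6, elitism = 0L,
                             T = 500L, reward_cap = 4L, seed = 1L) {
  if (is.character(setup)) setup <- evolutionary_setup(setup)
  stopifnot(population_size >= 2L, generations >= 1L, trials_per_genome >= 1L)
  structure(
    list(setup = setup, population_size = as.integer(population_size),
         generations = as.integer(generations),
         trials_per_genome = as.integer(trials_per_genome),
         genome_length = as.integer(genome_length), seed_gates = isTRUE(seed_gates),
         mutation = mutation, selection = match.arg(selection),
         tournament_k = as.integer(tournament_k), epsilon = epsilon,
         elitism = as.integer(elitism), T = as.integer(T),
         reward_cap = as.integer(reward_cap), seed = as.integer(seed)),
    class = "evolution_config")
}

#' Select parents proportional to fitness
#'
#' Default scheme: roulette selection on shifted fitness
#' `f - min(f) + epsilon`, which tolerates the negative scores that collision
#' penalties can produce. When all fitnesses are (numerically) equal the
#' draw is uniform. A tournament-k alternative is available.
#'
#' @param fitnesses Numeric vector of per-genome fitness values.
#' @param n Number of parents to draw (with replacement).
#' @param scheme `"roulette"` or `"tournament"`.
#' @param epsilon Shift floor for roulette selection.
#' @param k Tournament size.
#' @return Integer vector of `n` parent indices.
#' @examples
#' set.seed(1)
#' table(select_parents(c(0, 1), 1000))
#' @export
select_parents <- function(fitnesses, n, scheme = "roulette", epsilon = 1e-6,
                           k = 2L) {
  stopifnot(all(is.finite(fitnesses)), n >= 1L)
  m <- length(fitnesses)
  if (scheme == "tournament") {
    idx <- matrix(sample.int(m, n * k, replace = TRUE), nrow = n)
    return(apply(idx, 1L, function(row) row[which.max(fitnesses[row])]))
  }
  shifted <- fitnesses - min(fitnesses) + epsilon
  if (diff(range(fitnesses)) < .Machine$double.eps) {
    return(sample.int(m, n, replace = TRUE))
  }
  sample.int(m, n, replace = TRUE, prob = shifted / sum(shifted))
}

#' Run the evolutionary algorithm
#'
#' Generation 0 is initialized with [random_genome()]; each later generation
#' is produced by fitness-proportional parent selection followed by
#' [mutate_genome()] (one parent per offspring, no crossover). Every genome
#' is scored with [score_genome()] over `trials_per_genome` trials. The run
#' is fully reproducible from the master seed.
#'
#' @param config An [evolution_config()].
#' @param verbose Print a one-line summary per generation?
#' @return An `animat_lineage`: a tibble with one row per generation
#'   (`generation`, `mean_fitness`, `best_fitness`, `best_index`), carrying
#'   the config, the final-generation population and fitnesses, the best
#'   final genome, and the evolved fitness `EF` (the best fitness of the
#'   final generation) as attributes.
#' @examples
#' cfg <- evolution_config(population_size = 4, generations = 2,
#'                         trials_per_genome = 1, T = 20, seed = 1,
#'                         setup = evolutionary_setup("single"))
#' lin <- evolve(cfg)
#' glance(lin)
#' @export
evolve <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "evolution_config"))
  setup <- config$setup
  world <- setup$world
  arch <- setup$arch
  master <- config$seed
  old_rng <- .Random.seed_get()
  on.exit(.Random.seed_restore(old_rng), add = TRUE)

  pop <- lapply(seq_len(config$population_size), function(i) {
    set.seed(derive_seed(master, 0L, i))
    random_genome(config$genome_length, seed_gates = config$seed_gates)
  })

  lineage <- vector("list", config$generations)
  fitness <- numeric(config$population_size)
  for (gen in seq_len(config$generations)) {
    for (i in seq_len(config$population_size)) {
      fitness[i] <- as.numeric(score_genome(
        world, pop[[i]], arch = arch, n_trials = config$trials_per_genome,
        group_size = setup$group_size, rules = setup$rules, T = config$T,
        reward_cap = config$reward_cap, seed = derive_seed(master, gen, i)))
    }
    lineage[[gen]] <- tibble(generation = gen, mean_fitness = mean(fitness),
                             best_fitness = max(fitness),
                             best_index = which.max(fitness))
    if (verbose) {
      message(sprintf("gen %d: <F> = %.3f, best = %.3f", gen, mean(fitness),
                      max(fitness)))
    }
    if (gen < config$generations) {
      set.seed(derive_seed(master, gen, 0L, 1L))
      parents <- select_parents(fitness, config$population_size,
                                scheme = config$selection,
                                epsilon = config$epsilon, k = config$tournament_k)
      if (config$elitism > 0L) {
        elite <- order(fitness, decreasing = TRUE)[seq_len(config$elitism)]
        parents[seq_len(config$elitism)] <- elite
      }
      new_pop <- vector("list", config$population_size)
      for (i in seq_len(config$population_size)) {
        set.seed(derive_seed(master, gen, 0L, 2L, i))
        new_pop[[i]] <- if (config$elitism > 0L && i <= config$elitism) {
          pop[[parents[i]]]
        } else {
          mutate_genome(pop[[parents[i]]], config$mutation)
        }
      }
      pop <- new_pop
    }
  }
  tab <- dplyr::bind_rows(lineage)
  best_idx <- tab$best_index[config$generations]
  structure(tab,
            config = config,
            final_population = pop,
            final_fitness = fitness,
            best_genome = pop[[best_idx]],
            EF = tab$best_fitness[config$generations],
            class = c("animat_lineage", class(tab)))
}

#' @export
tidy.animat_lineage <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @export
glance.animat_lineage <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(setup = cfg$setup$label, generations = cfg$generations,
         population_size = cfg$population_size,
         EF = attr(x, "EF"),
         final_mean_fitness = x$mean_fitness[nrow(x)],
         seed = cfg$seed)
}

#' Extract the best evolved brain from a lineage
#'
#' @param lineage An `animat_lineage` from [evolve()].
#' @return A `markov_brain` decoded from the best final-generation genome.
#' @export
best_brain <- function(lineage) {
  stopifnot(inherits(lineage, "animat_lineage"))
  cfg <- attr(lineage, "config")
  genome_brain(attr(lineage, "best_genome"), cfg$setup$arch)
}

#' Write a lineage table to CSV
#'
#' @param lineage An `animat_lineage`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(lineage, path) {
  utils::write.csv(as.data.frame(lineage), path, row.names = FALSE)
  invisible(path)
}
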