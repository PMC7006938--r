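# End-to-end orchestration: configuration files, seeds, manifests, outputs.

#' Resolve an experiment configuration
#'
#' Configurations are flat key/value lists (or YAML files with the same
#' keys). `setup` names one of the fifteen evolutionary setups; every other
#' key overrides a default. Recognized keys: `setup`, `population_size`,
#' `generations`, `trials_per_genome`, `genome_length`, `seed_gates`,
#' `T`, `reward_cap`, `seed`, `sweep_conditions`, `sweep_group_sizes`,
#' `sweep_trials`, `complexity` (logical), `complexity_max_units`.
#'
#' @param config A named list, or the path of a YAML file.
#' @return A resolved list with an `evolution_config` in `$evolution`.
#' @export
experiment_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_animats("reading config files requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(setup = "0.50", population_size = 100L, generations = 10000L,
                   trials_per_genome = 30L, genome_length = 5000L,
                   seed_gates = TRUE, T = 500L, reward_cap = 4L, seed = 1L,
                   sweep_conditions = test_conditions()$condition,
                   sweep_group_sizes = group_size_vector(),
                   sweep_trials = 30L, complexity = FALSE,
                   complexity_max_units = 5L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop_animats("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  cfg$evolution <- evolution_config(
    setup = cfg$setup, population_size = cfg$population_size,
    generations = cfg$generations, trials_per_genome = cfg$trials_per_genome,
    genome_length = cfg$genome_length, seed_gates = cfg$seed_gates,
    T = cfg$T, reward_cap = cfg$reward_cap, seed = cfg$seed)
  cfg
}

#' Run a full experiment: evolve, sweep, evaluate
#'
#' Executes the pipeline for one setup: evolution, the post-evolutionary
#' task-fitness sweep of the best final genome, reliability, behavior
#' profile, transition table and occupancy map in the Original condition,
#' and (optionally) the lifetime complexity of the best brain. All outputs
#' are plain text (CSV/TSV/JSON) under `out_dir`, together with a JSON run
#' manifest holding the fully resolved configuration, the master seed and
#' the output inventory, from which the run can be replayed bit-identically.
#'
#' @param config A list or YAML path (see [experiment_config()]).
#' @param out_dir Output directory.
#' @param overwrite Overwrite existing outputs? If `FALSE` and a manifest is
#'   already present, the run refuses to clobber it.
#' @param dry_run Validate the configuration and write only the manifest.
#' @return The manifest, invisibly.
#' @export
run_experiment <- function(config = list(), out_dir = "animats-run",
                           overwrite = FALSE, dry_run = FALSE) {
  cfg <- experiment_config(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop_animats("output in '", out_dir, "' already exists; use overwrite = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("animats")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "evolution")],
    dry_run = dry_run,
    files = character(0))
  if (dry_run) {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
    return(invisible(manifest))
  }

  lineage <- evolve(cfg$evolution)
  write_lineage(lineage, file.path(out_dir, "lineage.csv"))
  brain <- best_brain(lineage)
  write_brain(brain, file.path(out_dir, "best_brain.json"))
  write_genome(attr(lineage, "best_genome"), file.path(out_dir, "best_genome.txt"))

  sw <- task_fitness_sweep(
    brain, sweep_spec(conditions = cfg$sweep_conditions,
                      group_sizes = cfg$sweep_group_sizes,
                      trials_per_cell = cfg$sweep_trials, T = cfg$T,
                      seed = derive_seed(cfg$seed, 2L)),
    setup = cfg$setup)
  utils::write.csv(as.data.frame(sw), file.path(out_dir, "task_fitness.csv"),
                   row.names = FALSE)
  rel <- tryCatch(reliability(sw, n_sizes = length(cfg$sweep_group_sizes)),
                  error = function(e) NULL)

  setup <- cfg$evolution$setup
  logs <- lapply(cfg$sweep_group_sizes, function(gs) {
    run_trial(setup$world, brain,
              trial_config(group_size = gs, T = cfg$T,
                           seed = derive_seed(cfg$seed, 3L, gs)),
              setup$rules)
  })
  prof <- behavior_profile(logs)
  utils::write.csv(as.data.frame(prof), file.path(out_dir, "behavior_profile.csv"),
                   row.names = FALSE)
  tt <- transition_table(logs)
  utils::write.csv(as.data.frame(unclass(tt)), file.path(out_dir, "transitions.csv"))
  occ <- occupancy_heatmap(logs, setup$world)
  utils::write.csv(as.data.frame(occ), file.path(out_dir, "occupancy.csv"),
                   row.names = FALSE)

  summary <- list(EF = attr(lineage, "EF"),
                  R = if (!is.null(rel)) rel$R else NULL)
  if (isTRUE(cfg$complexity)) {
    pr <- phi_max_over_lifetime(brain, logs[[1L]],
                                max_units = cfg$complexity_max_units)
    summary$phi_max <- pr$phi_max
    summary$n_concepts <- pr$n_concepts
    summary$phi_computed <- pr$computed
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest$files <- list.files(out_dir)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
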