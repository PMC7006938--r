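# Markov brains: gate assembly, state update, transition rule, connectivity.

#' Assemble a Markov brain
#'
#' A Markov brain is a set of binary units (sensors, memory, motors in that
#' fixed order) whose non-sensor units are updated by deterministic lookup
#' gates. Several gates may write the same unit; their outputs combine by
#' bitwise OR. A non-sensor unit with no writer falls to 0 at the next step.
#' Sensor units are never written by gates; the environment sets them.
#'
#' @param arch An [arch_spec()].
#' @param gates A list of gate blueprints, as returned by [decode_genome()].
#' @return A `markov_brain` object.
#' @examples
#' b <- markov_brain(arch_spec(), list())
#' b
#' @export
markov_brain <- function(arch, gates = list()) {
  stopifnot(inherits(arch, "animat_arch"))
  legal_in <- legal_input_units(arch)
  legal_out <- legal_output_units(arch)
  for (g in gates) {
    stopifnot(length(g$inputs) == g$n_in, length(g$outputs) == g$n_out,
              g$n_in >= 1L, g$n_in <= 4L, g$n_out >= 1L, g$n_out <= 4L,
              length(g$table) == 2L^g$n_in,
              all(g$table >= 0L), all(g$table < 2L^g$n_out))
    if (!all(g$inputs %in% legal_in)) {
      stop_animats("gate reads a unit that is not a legal input under this architecture")
    }
    if (!all(g$outputs %in% legal_out)) {
      stop_animats("gate writes a unit that is not a legal output (memory/motor)")
    }
  }
  structure(list(arch = arch, gates = gates, n_units = n_units(arch)),
            class = "markov_brain")
}

#' Build a brain from a genome
#'
#' Convenience wrapper: decode the genome under the architecture and assemble
#' the brain.
#'
#' @inheritParams decode_genome
#' @return A `markov_brain`.
#' @export
genome_brain <- function(genome, arch) {
  markov_brain(arch, decode_genome(genome, arch))
}

#' Advance a brain state by one timestep
#'
#' If `sensor_values` is given, sensor units are first overwritten with it
#' (the environment writes sensors); gates then read the resulting state.
#' Each non-sensor unit's next value is the OR over all gates writing it of
#' the gate's table output for the current input combination, or 0 if no gate
#' writes it. Sensor units keep their (possibly just written) values, so a
#' brain stepped without new sensor input sees clamped sensors.
#'
#' @param brain A [markov_brain()].
#' @param state Integer 0/1 vector, one value per unit.
#' @param sensor_values Optional 0/1 vector of length `n_sensors`.
#' @return The next state (integer 0/1 vector).
#' @examples
#' b <- markov_brain(arch_spec(), list())
#' brain_step(b, rep(1L, 8), sensor_values = c(1L, 0L))
#' @export
brain_step <- function(brain, state, sensor_values = NULL) {
  stopifnot(inherits(brain, "markov_brain"))
  if (length(state) != brain$n_units) {
    stop_animats("state length ", length(state), " != unit count ", brain$n_units)
  }
  state <- as.integer(state)
  ns <- brain$arch$n_sensors
  if (!is.null(sensor_values)) {
    if (length(sensor_values) != ns) {
      stop_animats("sensor_values must have length ", ns)
    }
    state[seq_len(ns)] <- as.integer(sensor_values)
  }
  nxt <- integer(brain$n_units)
  for (g in brain$gates) {
    row <- sum(state[g$inputs] * 2L^(seq_len(g$n_in) - 1L))
    val <- g$table[row + 1L]
    out_bits <- int_to_bits(val, g$n_out)
    nxt[g$outputs] <- bitwOr(nxt[g$outputs], out_bits)
  }
  if (ns > 0L) nxt[seq_len(ns)] <- state[seq_len(ns)]
  nxt
}

#' Derive the deterministic transition rule of a unit subset
#'
#' Enumerates all `2^k` states of the chosen unit subset while the remaining
#' units are held clamped, and records the next state of the subset under
#' [brain_step()]. Probabilities are interventional: each row is obtained by
#' perturbing the subset into that state, not by observing trajectories.
#'
#' @param brain A [markov_brain()].
#' @param subset Integer vector of unit ids (default: all units). At most 16.
#' @param clamp Clamped 0/1 values for the excluded units: either a single
#'   value recycled, or a named vector keyed by unit id. Default all 0.
#' @return A `brain_tpm`: integer matrix with `2^k` rows and `k` columns;
#'   row `i` is the next subset state when the subset is in state `i - 1`
#'   (little-endian over `sort(subset)`). Attribute `units` records the
#'   subset.
#' @examples
#' derive_tpm(markov_brain(arch_spec("smallbrain"), list()), subset = 3:4)
#' @export
derive_tpm <- function(brain, subset = NULL, clamp = 0L) {
  stopifnot(inherits(brain, "markov_brain"))
  subset <- sort(as.integer(subset %||% seq_len(brain$n_units)))
  if (length(subset) == 0L) stop_animats("subset must be non-empty")
  if (length(subset) > 16L) {
    stop_animats("subset of ", length(subset), " units exceeds the 2^16 enumeration guard")
  }
  if (!all(subset %in% seq_len(brain$n_units))) stop_animats("unknown unit id in subset")
  excluded <- setdiff(seq_len(brain$n_units), subset)
  base <- integer(brain$n_units)
  if (length(excluded) > 0L) {
    if (!is.null(names(clamp))) {
      base[as.integer(names(clamp))] <- as.integer(clamp)
    } else {
      base[excluded] <- as.integer(clamp)
    }
  }
  k <- length(subset)
  states <- states_matrix(k)
  out <- matrix(0L, nrow = 2L^k, ncol = k)
  for (i in seq_len(2L^k)) {
    full <- base
    full[subset] <- states[i, ]
    out[i, ] <- brain_step(brain, full)[subset]
  }
  structure(out, units = subset, class = c("brain_tpm", class(out)))
}

#' Unit-level connectivity of a brain
#'
#' There is an edge u -> v iff some gate lists u among its inputs and v among
#' its outputs.
#'
#' @param brain A [markov_brain()].
#' @return A tibble with columns `from` and `to` (unit ids), one row per
#'   distinct edge.
#' @examples
#' connectivity(markov_brain(arch_spec(), list()))
#' @export
connectivity <- function(brain) {
  stopifnot(inherits(brain, "markov_brain"))
  edges <- purrr::map_dfr(brain$gates, function(g) {
    tidyr::expand_grid(from = g$inputs, to = g$outputs)
  })
  if (nrow(edges) == 0L) {
    return(tibble(from = integer(0), to = integer(0)))
  }
  dplyr::distinct(dplyr::arrange(edges, .data$from, .data$to))
}

#' Is a brain's wiring feed-forward?
#'
#' A brain is classified feed-forward when its unit connectivity graph
#' contains no directed cycle (self-loops count as cycles). Feed-forward
#' systems cannot integrate information: any partition that cuts only
#' absent feedback connections leaves them unchanged.
#'
#' @param brain A [markov_brain()].
#' @return `TRUE` or `FALSE`.
#' @export
is_feedforward <- function(brain) {
  edges <- connectivity(brain)
  if (nrow(edges) == 0L) return(TRUE)
  if (any(edges$from == edges$to)) return(FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  igraph::is_dag(g)
}

#' Export a brain's wiring diagram
#'
#' Writes the unit connectivity in GraphML, a standard graph exchange text
#' format, for external inspection.
#'
#' @param brain A [markov_brain()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wiring <- function(brain, path) {
  ut <- unit_table(brain$arch)
  edges <- connectivity(brain)
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = ut$id, role = ut$role, label = ut$label)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read and write brain files
#'
#' A brain file is JSON holding the architecture (preset name or full custom
#' spec) and the gate list; the round trip is lossless.
#'
#' @param brain A [markov_brain()].
#' @param path File path.
#' @return `read_brain()` returns a `markov_brain`; `write_brain()` returns
#'   `path` invisibly.
#' @export
write_brain <- function(brain, path) {
  stopifnot(inherits(brain, "markov_brain"))
  arch <- brain$arch
  obj <- list(
    arch = list(name = arch$name,
                sensors = as.data.frame(arch$sensors),
                n_memory = arch$n_memory,
                motor_feedback = arch$motor_feedback),
    gates = lapply(brain$gates, function(g) {
      list(inputs = g$inputs, outputs = g$outputs, n_in = g$n_in,
           n_out = g$n_out, table = g$table)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_brain
#' @export
read_brain <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  a <- obj$arch
  arch <- if (a$name %in% names(arch_presets())) {
    arch_spec(a$name)
  } else {
    arch_spec("custom", sensors = a$sensors, n_memory = a$n_memory,
              motor_feedback = a$motor_feedback)
  }
  gates <- obj$gates
  if (is.data.frame(gates)) {
    gates <- lapply(seq_len(nrow(gates)), function(i) as.list(gates[i, ]))
  }
  gates <- lapply(gates, function(g) {
    list(inputs = as.integer(unlist(g$inputs)), outputs = as.integer(unlist(g$outputs)),
         n_in = as.integer(g$n_in), n_out = as.integer(g$n_out),
         table = as.integer(unlist(g$table)))
  })
  markov_brain(arch, gates)
}

#' @export
print.markov_brain <- function(x, ...) {
  cat(sprintf("<markov_brain> %s, %d gates, %d units\n",
              format(x$arch), length(x$gates), x$n_units))
  invisible(x)
}

#' @export
tidy.markov_brain <- function(x, ...) {
  purrr::map_dfr(seq_along(x$gates), function(i) {
    g <- x$gates[[i]]
    tibble(gate = i, n_in = g$n_in, n_out = g$n_out,
           inputs = paste(g$inputs, collapse = ","),
           outputs = paste(g$outputs, collapse = ","))
  })
}

#' @export
glance.markov_brain <- function(x, ...) {
  tibble(arch = x$arch$name, n_units = x$n_units, n_gates = length(x$gates),
         n_edges = nrow(connectivity(x)), feed_forward = is_feedforward(x))
}

# full-state lookup table used by the C++ engine: integer vector of length
# 2^n_units mapping each full state (sensors in the low bits) to the next
# state of the non-sensor units (sensor bits zero)
brain_state_table <- function(brain) {
  if (brain$n_units > 16L) {
    stop_animats("state-table engine supports at most 16 units")
  }
  gates_flat <- lapply(brain$gates, function(g) {
    c(g$n_in, g$n_out, g$inputs - 1L, g$outputs - 1L, g$table)
  })
  cpp_build_state_table(gates_flat, brain$n_units, brain$arch$n_sensors)
}
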