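#' Animat cognitive architectures
#'
#' An architecture fixes the unit layout of a Markov brain: the sensor slots
#' (each sensing one adjacent cell on a side of the animat, and reacting to
#' walls, fellow animats, or both), the number of recurrent memory units, and
#' two motor units. Units are indexed sensors first, then memory, then motors;
#' this ordering is used for all state encodings and serializations.
#'
#' Seven named presets cover the designs studied with this task:
#' \describe{
#'   \item{baseline}{front wall sensor + front agent sensor, 4 memory units,
#'     motor feedback enabled.}
#'   \item{3sides}{wall and agent sensors on front, left and right (6 sensors).}
#'   \item{no-agent}{a single front wall sensor.}
#'   \item{w=a}{a single universal front sensor that cannot distinguish walls
#'     from animats.}
#'   \item{smallbrain}{baseline sensors but only 2 memory units.}
#'   \item{bigbrain}{baseline sensors with 8 memory units.}
#'   \item{no-feedback}{baseline layout, but motor states may not be read back
#'     as gate inputs, reducing usable memory from six to four binary units.}
#' }
#'
#' @param preset Name of a preset (see Details), or `"custom"` together with
#'   the remaining arguments.
#' @param sensors A data frame with columns `kind` (one of `"wall"`,
#'   `"agent"`, `"universal"`) and `side` (one of `"front"`, `"left"`,
#'   `"right"`); only used for custom architectures.
#' @param n_memory Number of memory units (custom only).
#' @param motor_feedback Logical; may motor units feed back as gate inputs?
#' @return An object of class `animat_arch`.
#' @examples
#' arch_spec("baseline")
#' arch_spec("custom", sensors = data.frame(kind = "wall", side = "front"),
#'           n_memory = 2, motor_feedback = FALSE)
#' @export
arch_spec <- function(preset = "baseline", sensors = NULL, n_memory = NULL,
                      motor_feedback = NULL) {
  presets <- arch_presets()
  if (preset != "custom") {
    if (!preset %in% names(presets)) {
      stop_animats("unknown architecture preset '", preset, "'; valid: ",
                   paste(c(names(presets), "custom"), collapse = ", "))
    }
    p <- presets[[preset]]
    sensors <- p$sensors
    n_memory <- p$n_memory
    motor_feedback <- p$motor_feedback
  } else {
    if (is.null(sensors) || is.null(n_memory) || is.null(motor_feedback)) {
      stop_animats("custom architectures need sensors, n_memory and motor_feedback")
    }
  }
  sensors <- as_tibble(sensors)
  stopifnot(all(c("kind", "side") %in% names(sensors)))
  if (!all(sensors$kind %in% c("wall", "agent", "universal"))) {
    stop_animats("sensor kind must be wall, agent or universal")
  }
  if (!all(sensors$side %in% c("front", "left", "right"))) {
    stop_animats("sensor side must be front, left or right")
  }
  n_memory <- as.integer(n_memory)
  stopifnot(n_memory >= 0L)
  structure(
    list(name = preset,
         sensors = sensors[, c("kind", "side")],
         n_sensors = nrow(sensors),
         n_memory = n_memory,
         n_motors = 2L,
         motor_feedback = isTRUE(motor_feedback)),
    class = "animat_arch"
  )
}

arch_presets <- function() {
  base_sensors <- tibble(kind = c("wall", "agent"), side = c("front", "front"))
  list(
    "baseline"    = list(sensors = base_sensors, n_memory = 4L, motor_feedback = TRUE),
    "3sides"      = list(sensors = tibble(kind = rep(c("wall", "agent"), each = 3),
                                          side = rep(c("front", "left", "right"), 2)),
                         n_memory = 4L, motor_feedback = TRUE),
    "no-agent"    = list(sensors = tibble(kind = "wall", side = "front"),
                         n_memory = 4L, motor_feedback = TRUE),
    "w=a"         = list(sensors = tibble(kind = "universal", side = "front"),
                         n_memory = 4L, motor_feedback = TRUE),
    "smallbrain"  = list(sensors = base_sensors, n_memory = 2L, motor_feedback = TRUE),
    "bigbrain"    = list(sensors = base_sensors, n_memory = 8L, motor_feedback = TRUE),
    "no-feedback" = list(sensors = base_sensors, n_memory = 4L, motor_feedback = FALSE)
  )
}

n_units <- function(arch) arch$n_sensors + arch$n_memory + arch$n_motors

#' Unit layout of an architecture
#'
#' @param arch An [arch_spec()] object.
#' @return A tibble with one row per unit: `id` (1-based index in the fixed
#'   sensors-memory-motors ordering), `role`, and a human-readable `label`.
#' @examples
#' unit_table(arch_spec("baseline"))
#' @export
unit_table <- function(arch) {
  stopifnot(inherits(arch, "animat_arch"))
  labels <- c(
    sprintf("s%d_%s_%s", seq_len(arch$n_sensors), arch$sensors$kind, arch$sensors$side),
    sprintf("m%d", seq_len(arch$n_memory)),
    c("motor_l", "motor_r")
  )
  tibble(
    id = seq_len(n_units(arch)),
    role = rep(c("sensor", "memory", "motor"),
               times = c(arch$n_sensors, arch$n_memory, arch$n_motors)),
    label = labels
  )
}

# unit ids legal as gate inputs / outputs under an architecture
legal_input_units <- function(arch) {
  n <- n_units(arch)
  ids <- seq_len(n - arch$n_motors)
  if (arch$motor_feedback) ids <- c(ids, n - 1L, n)
  ids
}

legal_output_units <- function(arch) {
  seq(arch$n_sensors + 1L, n_units(arch))
}

#' @export
print.animat_arch <- function(x, ...) {
  cat(sprintf("<animat_arch '%s'>: %d sensors, %d memory, %d motors (feedback %s)\n",
              x$name, x$n_sensors, x$n_memory, x$n_motors,
              if (x$motor_feedback) "on" else "off"))
  invisible(x)
}

#' @export
format.animat_arch <- function(x, ...) {
  sprintf("%s[%ds/%dm/%dmo%s]", x$name, x$n_sensors, x$n_memory, x$n_motors,
          if (x$motor_feedback) "" else ",nofb")
}
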