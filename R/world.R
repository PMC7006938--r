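# Grid worlds: ASCII map parsing, rooms, gates, start slots.

#' Parse an ASCII grid-world map
#'
#' Map legend: `#` wall, `.` empty, `G` rewarding gate, `g` non-rewarding
#' gate, `S` start slot (an empty cell that animats may start on). The map
#' must be rectangular with an all-wall outer boundary. Room labels are
#' computed by flood fill (4-connectivity) over empty cells with gate cells
#' acting as separators; every gate must adjoin exactly two distinct rooms.
#'
#' Coordinates are 0-based with `x` the column and `y` the row, origin at the
#' top-left; orientation `up` means decreasing `y`.
#'
#' @param map_text A single string with newlines, or a character vector of
#'   map rows.
#' @param name Optional world name.
#' @return An `animat_world` object: a list holding the cell grid, room
#'   labels, gates (tibble with `x`, `y`, `rewarding`), and start slots
#'   (tibble with `x`, `y`).
#' @examples
#' w <- load_world(c("####", "#..#", "#S.#", "####"))
#' w$n_rooms
#' @export
load_world <- function(map_text, name = "custom") {
  rows <- if (length(map_text) == 1L && grepl("\n", map_text)) {
    strsplit(map_text, "\n", fixed = TRUE)[[1]]
  } else {
    map_text
  }
  rows <- rows[nzchar(rows)]
  if (length(rows) < 3L) stop_animats("map must have at least 3 rows")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop_animats("map is not rectangular: row widths ", paste(unique(widths), collapse = ", "))
  }
  height <- length(rows)
  width <- widths[1L]
  chars <- matrix(unlist(strsplit(rows, "", fixed = TRUE)),
                  nrow = height, ncol = width, byrow = TRUE)
  bad <- which(!chars %in% c("#", ".", "G", "g", "S"))
  if (length(bad) > 0L) {
    pos <- arrayInd(bad[1L], dim(chars))
    stop_animats(sprintf("unknown map character '%s' at line %d, column %d",
                         chars[pos[1L, 1L], pos[1L, 2L]], pos[1L, 1L], pos[1L, 2L]))
  }
  # cell codes: 0 empty, 1 wall, 2 gate
  cell <- matrix(0L, height, width)
  cell[chars == "#"] <- 1L
  cell[chars %in% c("G", "g")] <- 2L
  boundary <- c(cell[1L, ], cell[height, ], cell[, 1L], cell[, width])
  if (any(boundary != 1L)) stop_animats("outer boundary must be all wall")

  room <- flood_fill_rooms(cell)

  gi <- which(chars == "G" | chars == "g", arr.ind = TRUE)
  gates <- tibble(
    x = as.integer(gi[, 2L] - 1L), y = as.integer(gi[, 1L] - 1L),
    rewarding = chars[gi] == "G"
  )
  for (k in seq_len(nrow(gates))) {
    r <- gi[k, 1L]; c <- gi[k, 2L]
    nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    labs <- room[nb]
    labs <- unique(labs[!is.na(labs)])
    if (length(labs) != 2L) {
      stop_animats(sprintf("gate at line %d, column %d does not separate two rooms", r, c))
    }
  }

  si <- which(chars == "S", arr.ind = TRUE)
  slots <- if (nrow(si) > 0L) {
    tibble(x = as.integer(si[, 2L] - 1L), y = as.integer(si[, 1L] - 1L))
  } else {
    tibble(x = integer(0), y = integer(0))
  }

  structure(
    list(name = name, width = width, height = height, cell = cell,
         room = room, gates = gates, start_slots = slots,
         n_rooms = max(c(room[!is.na(room)], 0L))),
    class = "animat_world"
  )
}

# label connected components of empty cells (gates excluded) with 4-connectivity
flood_fill_rooms <- function(cell) {
  height <- nrow(cell); width <- ncol(cell)
  room <- matrix(NA_integer_, height, width)
  label <- 0L
  for (r0 in seq_len(height)) {
    for (c0 in seq_len(width)) {
      if (cell[r0, c0] == 0L && is.na(room[r0, c0])) {
        label <- label + 1L
        queue <- matrix(c(r0, c0), ncol = 2L)
        room[r0, c0] <- label
        while (nrow(queue) > 0L) {
          r <- queue[1L, 1L]; c <- queue[1L, 2L]
          queue <- queue[-1L, , drop = FALSE]
          nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
          for (j in seq_len(4L)) {
            rr <- nb[j, 1L]; cc <- nb[j, 2L]
            if (rr >= 1L && rr <= height && cc >= 1L && cc <= width &&
                cell[rr, cc] == 0L && is.na(room[rr, cc])) {
              room[rr, cc] <- label
              queue <- rbind(queue, c(rr, cc))
            }
          }
        }
      }
    }
  }
  room
}

#' Bundled grid worlds
#'
#' Five worlds are bundled: the `original` two-room 32 x 32 world with one
#' rewarding gate and 72 uniformly distributed start slots, and four modified
#' variants used only for post-evolutionary testing: `noisy_corners` (extra
#' wall blocks in the corners), `small_gate` (a narrowed gate approach),
#' `four_rooms` (two dividing walls, all four gates rewarding), and
#' `four_messy_rooms` (four rooms with scattered wall blocks; only the gates
#' on the vertical mid-line are rewarding). The modified geometries are
#' best-effort reconstructions drawn from small published figures; the ASCII
#' map format lets users substitute their own.
#'
#' @param name One of `"original"`, `"noisy_corners"`, `"small_gate"`,
#'   `"four_rooms"`, `"four_messy_rooms"`.
#' @return An `animat_world`.
#' @examples
#' builtin_world("original")$n_rooms
#' @export
builtin_world <- function(name) {
  valid <- c("original", "noisy_corners", "small_gate", "four_rooms",
             "four_messy_rooms")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    stop_animats("unknown world '", paste(name, collapse = ","), "'; valid names: ",
                 paste(valid, collapse = ", "))
  }
  path <- system.file("extdata", "worlds", paste0(name, ".map"),
                      package = "animats", mustWork = TRUE)
  load_world(readLines(path), name = name)
}

#' Write a world back to ASCII
#'
#' Emits the same map dialect accepted by [load_world()].
#'
#' @param world An `animat_world`.
#' @param path Optional file path; if `NULL` the character vector of rows is
#'   returned.
#' @return The map rows (invisibly when written to a file).
#' @export
write_world <- function(world, path = NULL) {
  stopifnot(inherits(world, "animat_world"))
  chars <- matrix(".", world$height, world$width)
  chars[world$cell == 1L] <- "#"
  for (k in seq_len(nrow(world$gates))) {
    chars[world$gates$y[k] + 1L, world$gates$x[k] + 1L] <-
      if (world$gates$rewarding[k]) "G" else "g"
  }
  for (k in seq_len(nrow(world$start_slots))) {
    chars[world$start_slots$y[k] + 1L, world$start_slots$x[k] + 1L] <- "S"
  }
  rows <- apply(chars, 1L, paste0, collapse = "")
  if (is.null(path)) {
    return(rows)
  }
  writeLines(rows, path)
  invisible(rows)
}

#' Cells of a world as a tibble
#'
#' @param x An `animat_world`.
#' @param ... Unused.
#' @return A tibble with one row per cell: `x`, `y`, `type` (empty / wall /
#'   gate), `room` (NA outside rooms), `rewarding` (gates only), and
#'   `start_slot`.
#' @export
tidy.animat_world <- function(x, ...) {
  grid <- tidyr::expand_grid(y = 0:(x$height - 1L), x2 = 0:(x$width - 1L))
  idx <- cbind(grid$y + 1L, grid$x2 + 1L)
  cell_type <- c("empty", "wall", "gate")[x$cell[idx] + 1L]
  room_lab <- x$room[idx]
  out <- tibble(x = grid$x2, y = grid$y, type = cell_type, room = room_lab)
  out$rewarding <- NA
  for (k in seq_len(nrow(x$gates))) {
    out$rewarding[out$x == x$gates$x[k] & out$y == x$gates$y[k]] <- x$gates$rewarding[k]
  }
  out$start_slot <- paste(out$x, out$y) %in% paste(x$start_slots$x, x$start_slots$y)
  out
}

#' @export
print.animat_world <- function(x, ...) {
  cat(sprintf("<animat_world '%s'> %dx%d, %d rooms, %d gates (%d rewarding), %d start slots\n",
              x$name, x$width, x$height, x$n_rooms, nrow(x$gates),
              sum(x$gates$rewarding), nrow(x$start_slots)))
  invisible(x)
}

# room label of a 0-based (x, y) position, NA on walls/gates
room_at <- function(world, x, y) {
  world$room[cbind(y + 1L, x + 1L)]
}

cell_at <- function(world, x, y) {
  world$cell[cbind(y + 1L, x + 1L)]
}

# TRUE iff every start slot can reach every rewarding gate through empty/gate cells
slots_reach_gates <- function(world) {
  pass <- world$cell != 1L
  height <- nrow(pass); width <- ncol(pass)
  # BFS from the first rewarding gate
  g <- world$gates[world$gates$rewarding, , drop = FALSE]
  if (nrow(g) == 0L) return(FALSE)
  seen <- matrix(FALSE, height, width)
  queue <- matrix(c(g$y[1L] + 1L, g$x[1L] + 1L), ncol = 2L)
  seen[queue] <- TRUE
  while (nrow(queue) > 0L) {
    r <- queue[1L, 1L]; c <- queue[1L, 2L]
    queue <- queue[-1L, , drop = FALSE]
    nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    for (j in seq_len(4L)) {
      rr <- nb[j, 1L]; cc <- nb[j, 2L]
      if (rr >= 1L && rr <= height && cc >= 1L && cc <= width &&
          pass[rr, cc] && !seen[rr, cc]) {
        seen[rr, cc] <- TRUE
        queue <- rbind(queue, c(rr, cc))
      }
    }
  }
  all(seen[cbind(world$start_slots$y + 1L, world$start_slots$x + 1L)])
}
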