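# Named evolutionary setups and post-evolutionary test conditions.

#' The 21-element group-size vector
#'
#' Group sizes used both for the randomized-group-size evolutionary setup and
#' for the post-evolutionary sweep; approximately uniform between 1 and 72
#' (72 animats = 100% coverage of the start slots).
#'
#' @return An integer vector of length 21.
#' @export
group_size_vector <- function() {
  c(1L, 4L, 7L, 11L, 14L, 18L, 22L, 25L, 29L, 32L, 36L, 40L, 43L, 47L, 50L,
    54L, 58L, 61L, 65L, 68L, 72L)
}

#' Resolve a named evolutionary setup
#'
#' The fifteen named setups vary the group size (`"1.00"` = 72 animats,
#' `"0.75"` = 54, `"0.50"` = 36 (the baseline), `"0.25"` = 18, `"single"` =
#' 1, `"random"` = drawn per trial from [group_size_vector()]), the cognitive
#' architecture (`"bigbrain"`, `"smallbrain"`, `"no-feedback"`), the
#' interaction conditions (`"no-penalty"`, `"blocked"`,
#' `"blocked/no-penalty"`), or the sensor configuration (`"no-agent"`,
#' `"3sides"`, `"w=a"`). All setups evolve in the original two-room world.
#'
#' @param label One of the fifteen setup names.
#' @return A list with elements `label`, `world` (an `animat_world`), `arch`,
#'   `rules`, and `group_size` (integer or `"random"`).
#' @examples
#' evolutionary_setup("0.50")$group_size
#' @export
evolutionary_setup <- function(label) {
  labels <- c("1.00", "0.75", "0.50", "0.25", "single", "random",
              "bigbrain", "smallbrain", "no-feedback",
              "no-penalty", "blocked/no-penalty", "blocked",
              "no-agent", "3sides", "w=a")
  if (!is.character(label) || length(label) != 1L || !label %in% labels) {
    stop_animats("unknown setup label '", paste(label, collapse = ","),
                 "'; valid labels: ", paste(labels, collapse = ", "))
  }
  group_size <- switch(label,
    "1.00" = 72L, "0.75" = 54L, "0.50" = 36L, "0.25" = 18L,
    "single" = 1L, "random" = "random", 36L)
  arch_name <- switch(label,
    "bigbrain" = "bigbrain", "smallbrain" = "smallbrain",
    "no-feedback" = "no-feedback", "no-agent" = "no-agent",
    "3sides" = "3sides", "w=a" = "w=a", "baseline")
  rules <- switch(label,
    "no-penalty" = interaction_rules(penalty_active = FALSE, blocking = FALSE),
    "blocked/no-penalty" = interaction_rules(penalty_active = FALSE, blocking = TRUE),
    "blocked" = interaction_rules(penalty_active = TRUE, blocking = TRUE),
    interaction_rules(penalty_active = TRUE, blocking = FALSE))
  list(label = label, world = builtin_world("original"),
       arch = arch_spec(arch_name), rules = rules, group_size = group_size)
}

#' The eight post-evolutionary test conditions
#'
#' Four interaction-rule variants on the original world (Original, No
#' Penalty, Blocked, Blocked and no Penalty) and four modified worlds tested
#' under the original rules (Noisy Corners, Small Gates, 4 Rooms, 4 Messy
#' Rooms).
#'
#' @return A tibble with columns `condition`, `world`, `penalty_active`,
#'   `blocking`.
#' @export
test_conditions <- function() {
  tibble(
    condition = c("Original", "No Penalty", "Blocked", "Blocked and no Penalty",
                  "Noisy Corners", "Small Gates", "4 Rooms", "4 Messy Rooms"),
    world = c(rep("original", 4L), "noisy_corners", "small_gate",
              "four_rooms", "four_messy_rooms"),
    penalty_active = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    blocking = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

condition_rules <- function(cond_row) {
  interaction_rules(penalty_active = cond_row$penalty_active,
                    blocking = cond_row$blocking)
}
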