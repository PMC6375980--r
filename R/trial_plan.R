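#' Generate the balanced 504-trial session plan
#'
#' A session comprises 7 blocks of 72 trials. Every `3n+2` slot is an
#' uncertainty trial; `3n+1` slots are standard trials with pre-assigned
#' offers; `3n+3` slots are standard follow-up trials whose offers are
#' resolved at run time from the preceding uncertainty trial's choice and
#' nomination (only their labels are planned). Balancing is global across the
#' session: each of the 4 standard pairs appears 42 times among `3n+1` slots,
#' each of the 2 uncertainty pairings 84 times among `3n+2` slots, and each
#' follow-up label (`repeat`/`switch`/`clash`) 56 times among `3n+3` slots,
#' all in seed-controlled random order. Display geometry (left/right of
#' options, top/bottom within pairs) is randomized uniformly and recorded;
#' companion relations never depend on it.
#'
#' @param structure a [build_task_structure()] result.
#' @param seed integer seed or `NULL`.
#' @param n_blocks,trials_per_block session geometry; `trials_per_block` must
#'   be a multiple of 3 and the slot-type counts must divide evenly by the
#'   category counts (the defaults 7 x 72 do).
#' @return a data frame of class `trial_plan` with one row per trial and
#'   columns `trial`, `block`, `slot_type`, `std_pair` (index into
#'   `structure$standard_pairs`), `pairing` (index into
#'   `structure$uncertainty_pairings`), `left_pair` (which pairing member is
#'   shown left), `top_left`/`top_right` (which member of each shown pair is
#'   on top), `left_object` (which standard-pair member is shown left) and
#'   `followup_label`.
#' @export
generate_trial_plan <- function(structure, seed = NULL,
                                n_blocks = 7L, trials_per_block = 72L) {
  stopifnot(inherits(structure, "task_structure"))
  n <- as.integer(n_blocks * trials_per_block)
  if (n %% 3L != 0L) stop("trials_per_block must make the session a multiple of 3")
  n_each <- n %/% 3L
  local_seed(seed)

  n_std_pairs <- length(structure$standard_pairs)
  n_pairings <- length(structure$uncertainty_pairings)
  if (n_each %% n_std_pairs != 0L || n_each %% n_pairings != 0L ||
      n_each %% 3L != 0L) {
    stop("slot counts do not divide evenly among offer categories")
  }

  plan <- data.frame(
    trial = seq_len(n),
    block = rep(seq_len(n_blocks), each = trials_per_block),
    slot_type = rep(c("standard_3n1", "uncertainty_3n2", "followup_3n3"),
                    length.out = n),
    std_pair = NA_integer_,
    pairing = NA_integer_,
    left_pair = NA_integer_,
    top_left = NA_integer_,
    top_right = NA_integer_,
    left_object = NA_integer_,
    followup_label = NA_character_,
    stringsAsFactors = FALSE
  )

  std_idx <- which(plan$slot_type == "standard_3n1")
  unc_idx <- which(plan$slot_type == "uncertainty_3n2")
  fol_idx <- which(plan$slot_type == "followup_3n3")

  plan$std_pair[std_idx] <- sample(rep(seq_len(n_std_pairs), n_each %/% n_std_pairs))
  plan$left_object[std_idx] <- sample(1:2, n_each, replace = TRUE)
  plan$pairing[unc_idx] <- sample(rep(seq_len(n_pairings), n_each %/% n_pairings))
  plan$left_pair[unc_idx] <- sample(1:2, n_each, replace = TRUE)
  plan$top_left[unc_idx] <- sample(1:2, n_each, replace = TRUE)
  plan$top_right[unc_idx] <- sample(1:2, n_each, replace = TRUE)
  plan$followup_label[fol_idx] <-
    sample(rep(c("repeat", "switch", "clash"), n_each %/% 3L))

  class(plan) <- c("trial_plan", "data.frame")
  plan
}

#' Draw a ghost nomination position
#'
#' The ghost nominates the vertically upper or lower object of the chosen pair
#' by a fair coin, independently across trials.
#'
#' @param n number of draws.
#' @param seed integer seed or `NULL`.
#' @return character vector of `"top"`/`"bottom"`.
#' @export
ghost_nominate <- function(n = 1L, seed = NULL) {
  local_seed(seed)
  ifelse(runif(n) < 0.5, "top", "bottom")
}

#' Draw the two room outcomes of an executed object
#'
#' Each opened room pays 1 point independently with its current walk
#' probability. Room order follows the trial type: on standard trials the room
#' unique to the executed object (relative to the alternative offer) opens
#' first and the common room second; on uncertainty trials the room common to
#' the chosen pair opens first and the nominee's unique room second.
#'
#' @param executed_object the object whose rooms are visited (the chosen
#'   object on standard trials, the ghost's nominee on uncertainty trials).
#' @param other_object the other offered object (standard) or the other
#'   chosen-pair member (uncertainty).
#' @param structure a `task_structure`.
#' @param walk_row numeric vector of the 4 current room probabilities.
#' @param type `"standard"` or `"uncertainty"`.
#' @param seed integer seed or `NULL`.
#' @return list with `first_room`, `r1`, `second_room`, `r2`.
#' @export
draw_outcomes <- function(executed_object, other_object, structure, walk_row,
                          type = c("standard", "uncertainty"), seed = NULL) {
  type <- match.arg(type)
  if (length(walk_row) != 4L || any(walk_row < 0 | walk_row > 1)) {
    stop("walk_row must hold 4 probabilities in [0, 1]")
  }
  local_seed(seed)
  uniq <- unique_room(structure, executed_object, other_object)
  comm <- common_room(structure, executed_object, other_object)
  rooms <- if (type == "standard") c(uniq, comm) else c(comm, uniq)
  rewards <- as.integer(runif(2) < walk_row[rooms])
  list(first_room = rooms[1], r1 = rewards[1],
       second_room = rooms[2], r2 = rewards[2])
}
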