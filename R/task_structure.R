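#' Build the object-room transition structure
#'
#' Constructs the bipartite map between the four choice objects and the four
#' outcome rooms. Each object opens exactly two rooms and each room is opened
#' by exactly two objects, so the incidence graph is a single 8-node cycle.
#' The canonical form has object `i` opening rooms `{i, i mod 4 + 1}`; the
#' per-participant randomization permutes object and room labels, which is the
#' only freedom the constraints leave (all such structures are isomorphic).
#'
#' @param seed integer seed controlling the label permutation, or `NULL` to
#'   draw from the current RNG stream.
#' @return an object of class `task_structure`: a list with
#'   \describe{
#'     \item{opens}{4 x 2 integer matrix; row `i` gives the two rooms opened
#'       by object `i`.}
#'     \item{standard_pairs}{list of the 4 unordered object pairs that share
#'       exactly one room (the eligible standard-trial offers).}
#'     \item{uncertainty_pairings}{list of the 2 partitions of the objects
#'       into two room-sharing pairs (the eligible uncertainty-trial offers);
#'       each partition is a list of two integer pairs.}
#'     \item{labels}{display names for objects and rooms.}
#'     \item{seed}{the seed used.}
#'   }
#' @export
build_task_structure <- function(seed = NULL) {
  local_seed(seed)
  canonical <- cbind(1:4, c(2:4, 1L))          # object i -> rooms {i, i+1 mod 4}
  perm_obj <- sample(4L)                        # canonical object i gets label perm_obj[i]
  perm_room <- sample(4L)
  opens <- matrix(0L, 4, 2)
  for (i in 1:4) {
    opens[perm_obj[i], ] <- sort(perm_room[canonical[i, ]])
  }
  structure_ <- list(
    opens = opens,
    standard_pairs = NULL,
    uncertainty_pairings = NULL,
    labels = list(objects = paste0("O", 1:4), rooms = paste0("R", 1:4)),
    seed = seed
  )
  structure_$standard_pairs <- derive_standard_pairs(opens)
  structure_$uncertainty_pairings <- derive_uncertainty_pairings(opens)
  class(structure_) <- "task_structure"
  structure_
}

derive_standard_pairs <- function(opens) {
  pairs <- list()
  for (a in 1:3) for (b in (a + 1):4) {
    if (length(intersect(opens[a, ], opens[b, ])) == 1L) {
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  pairs
}

derive_uncertainty_pairings <- function(opens) {
  # the three perfect matchings of 4 objects into 2 pairs
  matchings <- list(
    list(c(1L, 2L), c(3L, 4L)),
    list(c(1L, 3L), c(2L, 4L)),
    list(c(1L, 4L), c(2L, 3L))
  )
  keep <- vapply(matchings, function(m) {
    all(vapply(m, function(p)
      length(intersect(opens[p[1], ], opens[p[2], ])) == 1L, logical(1)))
  }, logical(1))
  matchings[keep]
}

#' @export
print.task_structure <- function(x, ...) {
  cat("Task structure (object -> rooms):\n")
  for (i in 1:4) {
    cat(sprintf("  %s -> {%s, %s}\n", x$labels$objects[i],
                x$labels$rooms[x$opens[i, 1]], x$labels$rooms[x$opens[i, 2]]))
  }
  cat(sprintf("%d standard pairs, %d uncertainty pairings\n",
              length(x$standard_pairs), length(x$uncertainty_pairings)))
  invisible(x)
}

#' Room shared by two objects
#'
#' @param structure a `task_structure`.
#' @param a,b object indices (1-4).
#' @return the shared room index; errors if the objects share no room or all
#'   rooms (impossible in a valid structure).
#' @export
common_room <- function(structure, a, b) {
  shared <- intersect(structure$opens[a, ], structure$opens[b, ])
  if (length(shared) != 1L) {
    stop("objects ", a, " and ", b, " do not share exactly one room")
  }
  shared
}

#' Room unique to one object relative to another
#'
#' @inheritParams common_room
#' @return the room opened by `a` but not by `b`.
#' @export
unique_room <- function(structure, a, b) {
  u <- setdiff(structure$opens[a, ], structure$opens[b, ])
  if (length(u) != 1L) {
    stop("object ", a, " has no single room unique relative to object ", b)
  }
  u
}

# The other object (not `obj`) opening `room`; unique in a valid structure.
other_opener <- function(structure, room, obj) {
  openers <- which(apply(structure$opens, 1, function(r) room %in% r))
  out <- setdiff(openers, obj)
  if (length(out) != 1L) stop("room ", room, " lacks a unique second opener")
  out
}

#' Infer the ghost's nominee from the second opened room
#'
#' On uncertainty trials the room common to the chosen pair opens first and the
#' room unique to the ghost-nominated object opens second, so a learner with
#' the transition model can identify the nominee with certainty once the second
#' room is revealed. This is the retrospective-inference step; fitting code
#' uses it rather than trusting any logged nominee column.
#'
#' @param structure a `task_structure`.
#' @param chosen_pair integer vector of the two chosen-pair objects.
#' @param second_room the room opened second.
#' @return the nominated object's index.
#' @export
infer_nomination <- function(structure, chosen_pair, second_room) {
  stopifnot(length(chosen_pair) == 2L)
  shared <- common_room(structure, chosen_pair[1], chosen_pair[2])
  if (second_room == shared) {
    stop("second room ", second_room,
         " is the pair's common room; the nominee cannot be inferred from it")
  }
  hit <- chosen_pair[vapply(chosen_pair, function(o)
    second_room %in% structure$opens[o, ], logical(1))]
  if (length(hit) != 1L) {
    stop("second room ", second_room,
         " is not the unique room of exactly one pair member")
  }
  hit
}

#' Resolve the offer of a follow-up trial from the preceding uncertainty trial
#'
#' Every third trial is a standard trial whose offer depends on the choice and
#' nomination of the uncertainty trial just played: a `repeat` trial offers the
#' ghost-nominated object alongside the other-pair object that shares the
#' nominee's unique (informative) room; a `switch` trial offers the
#' ghost-rejected object alongside the other-pair object sharing a room with
#' it; a `clash` trial re-offers the previously chosen pair.
#'
#' @param structure a `task_structure`.
#' @param prev a list describing the preceding uncertainty trial with elements
#'   `chosen_pair` (integer 2-vector) and `nominated` (integer), as found in a
#'   simulated trial record; alternatively a one-row data frame slice of a
#'   session's `trials` with `type == "uncertainty"`.
#' @param label one of `"repeat"`, `"switch"`, `"clash"`.
#' @return integer vector of the two offered objects (focal object first).
#' @export
realize_followup_offer <- function(structure, prev, label) {
  prev <- as_uncertainty_info(structure, prev)
  nominated <- prev$nominated
  rejected <- setdiff(prev$chosen_pair, nominated)
  switch(match.arg(label, c("repeat", "switch", "clash")),
    "repeat" = {
      inf_room <- unique_room(structure, nominated, rejected)
      c(nominated, other_opener(structure, inf_room, nominated))
    },
    "switch" = {
      rej_room <- unique_room(structure, rejected, nominated)
      c(rejected, other_opener(structure, rej_room, rejected))
    },
    "clash" = prev$chosen_pair
  )
}

as_uncertainty_info <- function(structure, prev) {
  if (is.list(prev) && !is.data.frame(prev) &&
      !is.null(prev$chosen_pair) && !is.null(prev$nominated)) {
    return(prev)
  }
  if (is.data.frame(prev)) {
    if (!identical(prev$type, "uncertainty")) {
      stop("previous trial is not an uncertainty trial")
    }
    pair <- if (prev$choice == 1L) c(prev$o1, prev$o2) else c(prev$o3, prev$o4)
    nominated <- infer_nomination(structure, pair, prev$room_2)
    return(list(chosen_pair = pair, nominated = nominated))
  }
  stop("cannot interpret `prev` as an uncertainty trial record")
}
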