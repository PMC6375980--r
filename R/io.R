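SESSION_COLUMNS <- c("trial", "block", "type", "offer_1", "offer_2",
                     "offer_3", "offer_4", "choice", "ghost_nominated",
                     "room_1", "reward_1", "room_2", "reward_2",
                     "p_room1", "p_room2", "p_room3", "p_room4",
                     "followup_label", "missing")

#' Write a session to CSV with a sidecar structure JSON
#'
#' One CSV row per trial (columns `trial`, `block`, `type`,
#' `offer_1..offer_4`, `choice`, `ghost_nominated`, `room_1`, `reward_1`,
#' `room_2`, `reward_2`, `p_room0..p_room3` as `p_room1..p_room4`,
#' `followup_label`, `missing`) plus a JSON sidecar holding the object-room
#' map, labels, participant id and seeds. Floats are serialized at 12
#' significant digits; the write/read round trip is the identity on all
#' fields.
#'
#' @param session a `ghost_session`.
#' @param path CSV output path.
#' @param structure_path sidecar path; defaults to the CSV path with a
#'   `_structure.json` suffix.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, structure_path = NULL) {
  structure_path <- structure_path %||% default_structure_path(path)
  tr <- session$trials
  out <- data.frame(
    trial = tr$trial, block = tr$block, type = tr$type,
    offer_1 = tr$o1, offer_2 = tr$o2, offer_3 = tr$o3, offer_4 = tr$o4,
    choice = tr$choice, ghost_nominated = tr$ghost_nominated,
    room_1 = tr$room_1, reward_1 = tr$reward_1,
    room_2 = tr$room_2, reward_2 = tr$reward_2,
    p_room1 = signif(tr$p_room1, 12), p_room2 = signif(tr$p_room2, 12),
    p_room3 = signif(tr$p_room3, 12), p_room4 = signif(tr$p_room4, 12),
    followup_label = tr$followup_label, missing = tr$missing,
    stringsAsFactors = FALSE)
  extra <- setdiff(names(tr), c("o1", "o2", "o3", "o4", "chosen_object",
                                names(out)))
  for (col in extra) out[[col]] <- tr[[col]]
  write.csv(out, path, row.names = FALSE, na = "")
  sidecar <- list(participant = session$participant,
                  opens = apply(session$structure$opens, 1, identity,
                                simplify = FALSE),
                  labels = session$structure$labels,
                  structure_seed = session$structure$seed,
                  seeds = session$seeds)
  jsonlite::write_json(sidecar, structure_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

default_structure_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_structure.json")
}

#' Read a session written by [write_session()]
#'
#' Validates the schema — required columns, contiguous 1-based trial indices,
#' the every-third-trial uncertainty pattern, room/object/choice ranges —
#' and reports violations with their row numbers. Unknown columns are
#' preserved. The sidecar is required: there is no silent default structure.
#'
#' @param path CSV path.
#' @param structure_path sidecar path (default as in [write_session()]).
#' @return a `ghost_session`.
#' @export
read_session <- function(path, structure_path = NULL) {
  structure_path <- structure_path %||% default_structure_path(path)
  if (!file.exists(structure_path)) {
    stop("structure sidecar not found: ", structure_path,
         " (a session cannot be read without its object-room map)")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  miss_cols <- setdiff(SESSION_COLUMNS, names(raw))
  if (length(miss_cols)) {
    stop("session file ", path, " lacks required columns: ",
         paste(miss_cols, collapse = ", "))
  }
  side <- jsonlite::read_json(structure_path, simplifyVector = TRUE)
  opens <- matrix(as.integer(t(side$opens)), 4, 2, byrow = TRUE)
  structure_ <- list(opens = opens,
                     standard_pairs = derive_standard_pairs(opens),
                     uncertainty_pairings = derive_uncertainty_pairings(opens),
                     labels = side$labels, seed = side$structure_seed)
  class(structure_) <- "task_structure"

  n <- nrow(raw)
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, paste0(msg, " (rows ",
                                      paste(head(rows, 5L), collapse = ", "),
                                      if (length(rows) > 5L) ", ..." else "",
                                      ")"))
    }
  }
  note(which(raw$trial != seq_len(n)), "trial indices not contiguous from 1")
  expected_unc <- seq_len(n) %% 3L == 2L
  note(which(expected_unc & raw$type != "uncertainty"),
       "3n+2 trial is not an uncertainty trial")
  note(which(!expected_unc & raw$type != "standard"),
       "trial outside the 3n+2 slots is not a standard trial")
  ok_obj <- function(x, allow_na = FALSE) {
    bad <- !(x %in% 1:4); if (allow_na) bad <- bad & !is.na(x); which(bad)
  }
  note(ok_obj(raw$offer_1), "offer_1 outside 1..4")
  note(ok_obj(raw$offer_2), "offer_2 outside 1..4")
  live <- !raw$missing
  note(which(live & !(raw$choice %in% 1:2)), "choice outside {1, 2}")
  note(which(live & !(raw$room_1 %in% 1:4 & raw$room_2 %in% 1:4)),
       "opened room outside 1..4")
  note(which(live & !(raw$reward_1 %in% 0:1 & raw$reward_2 %in% 0:1)),
       "reward outside {0, 1}")
  if (length(problems)) {
    stop("schema violations in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  }

  trials <- data.frame(
    trial = as.integer(raw$trial), block = as.integer(raw$block),
    type = raw$type,
    o1 = as.integer(raw$offer_1), o2 = as.integer(raw$offer_2),
    o3 = as.integer(raw$offer_3), o4 = as.integer(raw$offer_4),
    choice = as.integer(raw$choice),
    chosen_object = NA_integer_,
    ghost_nominated = as.integer(raw$ghost_nominated),
    room_1 = as.integer(raw$room_1), reward_1 = as.integer(raw$reward_1),
    room_2 = as.integer(raw$room_2), reward_2 = as.integer(raw$reward_2),
    p_room1 = raw$p_room1, p_room2 = raw$p_room2,
    p_room3 = raw$p_room3, p_room4 = raw$p_room4,
    followup_label = ifelse(raw$followup_label == "", NA_character_,
                            raw$followup_label),
    missing = as.logical(raw$missing),
    stringsAsFactors = FALSE)
  std <- trials$type == "standard" & !trials$missing
  trials$chosen_object[std] <- ifelse(trials$choice[std] == 1L,
                                      trials$o1[std], trials$o2[std])
  for (col in setdiff(names(raw), SESSION_COLUMNS)) trials[[col]] <- raw[[col]]

  session <- list(participant = side$participant, structure = structure_,
                  trials = trials, seeds = side$seeds)
  class(session) <- "ghost_session"
  session
}

#' Read a run configuration
#'
#' YAML with keys `n_blocks`, `trials_per_block`, `step_sd`,
#' `walk_init_range`, `seed`; absent keys take the study defaults
#' (7, 72, 0.025, `[0.25, 0.75]`, 1).
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path) %||% list()
  defaults <- list(n_blocks = 7L, trials_per_block = 72L, step_sd = 0.025,
                   walk_init_range = c(0.25, 0.75), seed = 1L)
  out <- utils::modifyList(defaults, cfg)
  out$n_blocks <- as.integer(out$n_blocks)
  out$trials_per_block <- as.integer(out$trials_per_block)
  out$walk_init_range <- as.numeric(out$walk_init_range)
  if (out$step_sd < 0) stop("step_sd must be non-negative")
  if (length(out$walk_init_range) != 2L) {
    stop("walk_init_range must have two elements")
  }
  class(out) <- "run_config"
  out
}
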