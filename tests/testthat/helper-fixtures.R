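# Canonical structure (object i opens rooms {i, i mod 4 + 1}) and a 12-trial
# deterministic mini-session with fixed choices and outcomes, used to anchor
# the hand-trace likelihood oracle.

canonical_structure <- function() {
  opens <- cbind(1:4, c(2L, 3L, 4L, 1L))
  st <- list(opens = opens,
             standard_pairs = ghostrl:::derive_standard_pairs(opens),
             uncertainty_pairings = ghostrl:::derive_uncertainty_pairings(opens),
             labels = list(objects = paste0("O", 1:4),
                           rooms = paste0("R", 1:4)),
             seed = NULL)
  class(st) <- "task_structure"
  st
}

fixture_session <- function() {
  st <- canonical_structure()
  trials <- data.frame(
    trial = 1:12, block = 1L,
    type = rep(c("standard", "uncertainty", "standard"), 4),
    o1 = c(1L, 1L, 1L, 2L, 4L, 1L, 3L, 1L, 3L, 4L, 2L, 2L),
    o2 = c(2L, 2L, 4L, 3L, 1L, 2L, 4L, 2L, 4L, 1L, 3L, 1L),
    o3 = c(NA, 3L, NA, NA, 2L, NA, NA, 3L, NA, NA, 4L, NA),
    o4 = c(NA, 4L, NA, NA, 3L, NA, NA, 4L, NA, NA, 1L, NA),
    choice = c(1L, 1L, 2L, 2L, 1L, 1L, 1L, 2L, 2L, 2L, 1L, 1L),
    chosen_object = c(1L, NA, 4L, 3L, NA, 1L, 3L, NA, 4L, 1L, NA, 2L),
    ghost_nominated = c(NA, 1L, NA, NA, 4L, NA, NA, 3L, NA, NA, 2L, NA),
    room_1 = c(1L, 2L, 4L, 4L, 1L, 1L, 3L, 4L, 1L, 2L, 3L, 3L),
    reward_1 = c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L, 0L, 1L, 1L),
    room_2 = c(2L, 1L, 1L, 3L, 4L, 2L, 4L, 3L, 4L, 1L, 2L, 2L),
    reward_2 = c(0L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L),
    p_room1 = 0.5, p_room2 = 0.5, p_room3 = 0.5, p_room4 = 0.5,
    followup_label = c(NA, NA, "repeat", NA, NA, "switch", NA, NA, "clash",
                       NA, NA, "repeat"),
    missing = FALSE,
    stringsAsFactors = FALSE)
  session <- list(participant = "fixture", structure = st, trials = trials,
                  seeds = list())
  class(session) <- "ghost_session"
  session
}

# short simulated sessions for randomized cross-checks
random_short_session <- function(seed, family = "mb_room",
                                 constraint = "full", n_blocks = 1L,
                                 trials_per_block = 36L) {
  sp <- model_spec(family, constraint)
  st <- build_task_structure(derive_seed(seed, 1L))
  plan <- generate_trial_plan(st, derive_seed(seed, 2L),
                              n_blocks = n_blocks,
                              trials_per_block = trials_per_block)
  w <- generate_walks(nrow(plan), 0.025, derive_seed(seed, 3L))
  p <- random_params(derive_seed(seed, 4L))
  list(session = simulate_session(st, plan, w, p, sp,
                                  seed = derive_seed(seed, 5L)),
       params = p, spec = sp)
}

random_params <- function(seed) {
  set.seed(seed)
  model_params(w_mb = runif(1), beta = runif(1, 0.5, 10),
               persev = runif(1, -1, 1), lr_mb = runif(1),
               lr_standard = runif(1), lr_ghost_nom = runif(1),
               lr_ghost_rej = runif(1), lam = runif(1), lr_mf = runif(1))
}
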