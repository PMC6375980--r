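#' Initialize agent state
#'
#' MF object values start at 1 (the expected two-room total under a 0.5
#' reward-probability prior), MB room values at 0.5, MB object values (object
#' value family) at 1.0, eligibility traces at 0, and no object is marked as
#' previously chosen.
#'
#' @param spec a [model_spec()].
#' @return an object of class `agent_state`: list with `q_mf`, `q_mb_rooms`,
#'   `q_mb_objects`, `elig` (numeric 4-vectors) and `last_chosen` (integer
#'   vector, empty before trial 1; on "either" perseverance bookkeeping it can
#'   hold both chosen-pair members).
#' @export
init_state <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  out <- list(q_mf = rep(1, 4), q_mb_rooms = rep(0.5, 4),
              q_mb_objects = rep(1, 4), elig = rep(0, 4),
              last_chosen = integer(0))
  class(out) <- "agent_state"
  out
}

#' Model-free value of an option
#'
#' Single objects retrieve their cached MF value; pairs take the arithmetic
#' mean of their members' values.
#'
#' @param state an `agent_state`.
#' @param option integer vector of 1 (object) or 2 (pair) object indices.
#' @return numeric scalar.
#' @export
mf_option_value <- function(state, option) {
  if (!all(option %in% 1:4)) stop("unknown object id in option")
  mean(state$q_mf[option])
}

#' Model-based value of an option
#'
#' In the room-value family, an object's MB value is computed prospectively as
#' the sum of its two rooms' values; in the object-value family it is the
#' cached object value. Pairs take the mean of member values. Eligibility
#' families have no MB system; their MB value is 0 (and `w_mb` is pinned to 0).
#'
#' @param state an `agent_state`.
#' @param spec a `model_spec`.
#' @param structure a `task_structure`.
#' @param option integer vector of 1 or 2 object indices.
#' @return numeric scalar.
#' @export
mb_option_value <- function(state, spec, structure, option) {
  if (!all(option %in% 1:4)) stop("unknown object id in option")
  obj_val <- switch(spec$family,
    mb_room = vapply(option, function(o)
      sum(state$q_mb_rooms[structure$opens[o, ]]), numeric(1)),
    mb_object = state$q_mb_objects[option],
    rep(0, length(option))
  )
  mean(obj_val)
}

persev_indicator <- function(state, option) {
  as.numeric(length(state$last_chosen) > 0 &&
             any(option %in% state$last_chosen))
}

#' Net option values for a two-option trial
#'
#' Combines the MB and MF values with weight `w_mb`, plus the perseverance
#' bonus `persev` for the option (or pair) containing the previously selected
#' object.
#'
#' @param state an `agent_state`.
#' @param spec a `model_spec`.
#' @param params a `model_params`.
#' @param structure a `task_structure`.
#' @param options list of two integer vectors (the offered objects or pairs).
#' @return list of two lists, each with `option`, `v_mf`, `v_mb`, `v_net`.
#' @export
net_values <- function(state, spec, params, structure, options) {
  stopifnot(length(options) == 2L)
  lapply(options, function(opt) {
    v_mf <- mf_option_value(state, opt)
    v_mb <- mb_option_value(state, spec, structure, opt)
    v_net <- params[["w_mb"]] * v_mb + (1 - params[["w_mb"]]) * v_mf +
      params[["persev"]] * persev_indicator(state, opt)
    list(option = opt, v_mf = v_mf, v_mb = v_mb, v_net = v_net)
  })
}

#' Softmax probability of choosing an option
#'
#' Logistic of `beta * (v_chosen - v_other)`, computed stably for large
#' magnitude arguments.
#'
#' @param v_chosen,v_other net values of the two options.
#' @param beta inverse temperature, > 0.
#' @return probability in (0, 1).
#' @export
choice_prob <- function(v_chosen, v_other, beta) {
  if (any(beta <= 0)) stop("beta must be positive")
  d <- beta * (v_chosen - v_other)
  ifelse(d >= 0, 1 / (1 + exp(-d)), exp(d) / (1 + exp(d)))
}

# log choice probability, stable
log_choice_prob <- function(v_chosen, v_other, beta) {
  d <- beta * (v_chosen - v_other)
  ifelse(d >= 0, -log1p(exp(-d)), d - log1p(exp(d)))
}

mb_learn <- function(state, spec, params, structure, executed, r1, r2, rooms) {
  if (spec$family == "mb_room") {
    lr <- params[["lr_mb"]]
    state$q_mb_rooms[rooms[1]] <- state$q_mb_rooms[rooms[1]] +
      lr * (r1 - state$q_mb_rooms[rooms[1]])
    state$q_mb_rooms[rooms[2]] <- state$q_mb_rooms[rooms[2]] +
      lr * (r2 - state$q_mb_rooms[rooms[2]])
  } else if (spec$family == "mb_object") {
    lr <- params[["lr_mb"]]
    total <- r1 + r2
    state$q_mb_objects[executed] <- state$q_mb_objects[executed] +
      lr * (total - state$q_mb_objects[executed])
    rewards <- c(r1, r2)
    for (j in setdiff(1:4, executed)) {
      shared <- intersect(structure$opens[j, ], rooms)
      if (length(shared) == 1L) {
        rr <- rewards[match(shared, rooms)]
        state$q_mb_objects[j] <- state$q_mb_objects[j] +
          lr * (rr - 0.5 * state$q_mb_objects[j])
      }
    }
  }
  state
}

#' Learning update after a standard trial
#'
#' The MF system updates the chosen object's value toward the total trial
#' reward with rate `lr_standard`; credit assignment is restricted to the
#' chosen object. The MB system updates each observed room's value toward its
#' own reward (room-value family) or performs the full/half object updates
#' (object-value family). The chosen object becomes "last chosen".
#'
#' @param state an `agent_state`.
#' @param spec,params,structure model specification, parameters, structure.
#' @param chosen the chosen object.
#' @param r1,r2 rewards of the first and second opened rooms.
#' @param rooms integer 2-vector: the first and second opened rooms.
#' @return the updated `agent_state`.
#' @export
update_after_standard <- function(state, spec, params, structure, chosen,
                                  r1, r2, rooms) {
  if (grepl("^elig", spec$family)) {
    stop("use eligibility_trial_step() for eligibility-trace families")
  }
  total <- r1 + r2
  state$q_mf[chosen] <- state$q_mf[chosen] +
    params[["lr_standard"]] * (total - state$q_mf[chosen])
  state <- mb_learn(state, spec, params, structure, chosen, r1, r2, rooms)
  state$last_chosen <- as.integer(chosen)
  state
}

#' Learning update after an uncertainty trial
#'
#' The MF system updates both chosen-pair members toward the total reward, the
#' ghost-nominated object with rate `lr_ghost_nom` and the ghost-rejected
#' object with `lr_ghost_rej`. MB updates are identical to standard trials
#' with the nominee in the executed role. The "last chosen" marker becomes the
#' nominee (or both members under `persev_after_ghost = "either"`).
#'
#' @inheritParams update_after_standard
#' @param chosen_pair integer 2-vector of the chosen pair.
#' @param nominated the ghost-nominated member.
#' @return the updated `agent_state`.
#' @export
update_after_uncertainty <- function(state, spec, params, structure,
                                     chosen_pair, nominated, r1, r2, rooms) {
  if (grepl("^elig", spec$family)) {
    stop("use eligibility_trial_step() for eligibility-trace families")
  }
  if (!nominated %in% chosen_pair) stop("nominated object not in chosen pair")
  rejected <- setdiff(chosen_pair, nominated)
  total <- r1 + r2
  state$q_mf[nominated] <- state$q_mf[nominated] +
    params[["lr_ghost_nom"]] * (total - state$q_mf[nominated])
  state$q_mf[rejected] <- state$q_mf[rejected] +
    params[["lr_ghost_rej"]] * (total - state$q_mf[rejected])
  state <- mb_learn(state, spec, params, structure, nominated, r1, r2, rooms)
  state$last_chosen <- if (spec$persev_after_ghost == "either") {
    as.integer(chosen_pair)
  } else {
    as.integer(nominated)
  }
  state
}

#' One full trial step of an eligibility-trace model
#'
#' Per-trial sequence: all four traces decay by `lam`; the chosen object's
#' trace (both chosen-pair members' traces on ghost trials) is incremented —
#' `e <- 1 + e` for accumulating traces, `e <- 1` for replacing traces; then
#' every object's value moves toward the total trial reward with effective
#' rate `(1 - lam) * lr_mf * e` (accumulating) or `lr_mf * e` (replacing).
#' The decay is applied at trial start per the explicit per-trial sequence;
#' traces start at 0, so this is equivalent to end-of-trial decay.
#'
#' @param state an `agent_state`.
#' @param spec,params model specification and parameters.
#' @param chosen_objects integer vector: the chosen object (standard trials)
#'   or both chosen-pair members (ghost trials).
#' @param total_reward total points earned this trial (0, 1 or 2).
#' @return the updated `agent_state` (the caller maintains `last_chosen`).
#' @export
eligibility_trial_step <- function(state, spec, params, chosen_objects,
                                   total_reward) {
  if (!grepl("^elig", spec$family)) {
    stop("eligibility_trial_step() requires an eligibility-trace family")
  }
  lam <- params[["lam"]]
  lr <- params[["lr_mf"]]
  state$elig <- lam * state$elig
  if (spec$family == "elig_accumulating") {
    state$elig[chosen_objects] <- 1 + state$elig[chosen_objects]
    rate <- (1 - lam) * lr * state$elig
  } else {
    state$elig[chosen_objects] <- 1
    rate <- lr * state$elig
  }
  state$q_mf <- state$q_mf + rate * (total_reward - state$q_mf)
  state
}

# Advance the agent state through one observed trial (shared by the simulator
# and the R likelihood engine). `info` carries: type ("standard"/"uncertainty"),
# chosen (object for standard), chosen_pair + nominated (uncertainty),
# r1, r2, rooms.
advance_state <- function(state, spec, params, structure, info) {
  if (grepl("^elig", spec$family)) {
    if (info$type == "standard") {
      state <- eligibility_trial_step(state, spec, params, info$chosen,
                                      info$r1 + info$r2)
      state$last_chosen <- as.integer(info$chosen)
    } else {
      state <- eligibility_trial_step(state, spec, params, info$chosen_pair,
                                      info$r1 + info$r2)
      state$last_chosen <- if (spec$persev_after_ghost == "either") {
        as.integer(info$chosen_pair)
      } else {
        as.integer(info$nominated)
      }
    }
    return(state)
  }
  if (info$type == "standard") {
    update_after_standard(state, spec, params, structure, info$chosen,
                          info$r1, info$r2, info$rooms)
  } else {
    update_after_uncertainty(state, spec, params, structure, info$chosen_pair,
                             info$nominated, info$r1, info$r2, info$rooms)
  }
}
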