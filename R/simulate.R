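#' Simulate a full session of the ghost-bandit task
#'
#' Runs a learning agent through a planned session: on each trial the net
#' option values are computed, a choice is drawn from the softmax rule, the
#' ghost's nomination (uncertainty trials) and room outcomes are drawn from
#' the task, and the family's learning update is applied. Follow-up offers
#' are resolved from the actual preceding uncertainty trial. The whole
#' session is reproducible from its seed.
#'
#' @param structure a [build_task_structure()] result.
#' @param plan a [generate_trial_plan()] result for the same structure.
#' @param walks a [generate_walks()] result with at least `nrow(plan)` rows.
#' @param params a [model_params()] vector (constrained to `spec` before use).
#' @param spec a [model_spec()].
#' @param seed integer seed or `NULL`.
#' @param participant participant identifier stored in the session.
#' @param engine `"cpp"` (compiled, the default) or `"r"` (pure-R reference
#'   loop). The two consume the RNG stream in the same order and produce
#'   bitwise-identical sessions from the same seed; tests enforce this.
#' @return an object of class `ghost_session`: list with `participant`,
#'   `structure`, `trials` (one row per trial: `trial`, `block`, `type`,
#'   offered objects `o1..o4` (`o3`/`o4` `NA` on standard trials), `choice`
#'   (1 = first/left option, 2 = second/right), `chosen_object` (executed
#'   object on standard trials, `NA` on uncertainty trials),
#'   `ghost_nominated`, opened rooms and rewards `room_1`, `reward_1`,
#'   `room_2`, `reward_2`, walk probabilities `p_room1..p_room4`,
#'   `followup_label`, `missing`, and `choice_p` — the model's probability of
#'   option 1 at the moment of choice, recorded for diagnostics) and `seeds`.
#' @export
simulate_session <- function(structure, plan, walks, params, spec,
                             seed = NULL, participant = "sim",
                             engine = c("cpp", "r")) {
  stopifnot(inherits(structure, "task_structure"),
            inherits(plan, "trial_plan") || is.data.frame(plan))
  engine <- match.arg(engine)
  params <- as_model_params(params)
  par_full <- constrain_params(params, spec)
  probs <- if (inherits(walks, "reward_walks")) walks$probs else walks
  n <- nrow(plan)
  if (nrow(probs) < n) stop("walks shorter than the trial plan")
  local_seed(seed)

  opens <- structure$opens
  comm <- uniq <- matrix(0L, 4, 4)
  for (a in 1:4) for (b in 1:4) if (a != b) {
    s <- intersect(opens[a, ], opens[b, ])
    if (length(s) == 1L) {
      comm[a, b] <- s
      uniq[a, b] <- setdiff(opens[a, ], s)
    }
  }
  slot_i <- match(plan$slot_type,
                  c("standard_3n1", "uncertainty_3n2", "followup_3n3"))

  if (engine == "cpp") {
    std1 <- std2 <- ul1 <- ul2 <- ur1 <- ur2 <- flab <- integer(n)
    s1 <- which(slot_i == 1L)
    pairs_mat <- do.call(rbind, structure$standard_pairs)
    pm <- pairs_mat[plan$std_pair[s1], , drop = FALSE]
    lo <- plan$left_object[s1]
    std1[s1] <- pm[cbind(seq_along(s1), lo)]
    std2[s1] <- pm[cbind(seq_along(s1), 3L - lo)]
    s2 <- which(slot_i == 2L)
    P <- array(0L, c(2, 2, 2))          # [pairing, pair-within, member]
    for (pg in 1:2) for (sd_ in 1:2) {
      P[pg, sd_, ] <- structure$uncertainty_pairings[[pg]][[sd_]]
    }
    pg <- plan$pairing[s2]; lp <- plan$left_pair[s2]
    tl <- plan$top_left[s2]; tr_ <- plan$top_right[s2]
    ul1[s2] <- P[cbind(pg, lp, tl)]
    ul2[s2] <- P[cbind(pg, lp, 3L - tl)]
    ur1[s2] <- P[cbind(pg, 3L - lp, tr_)]
    ur2[s2] <- P[cbind(pg, 3L - lp, 3L - tr_)]
    s3 <- which(slot_i == 3L)
    flab[s3] <- match(plan$followup_label[s3], c("repeat", "switch", "clash"))
    res <- sim_session_cpp(par_full, FAMILY_CODES[[spec$family]],
                           as.integer(spec$persev_after_ghost == "either"),
                           slot_i, std1, std2, ul1, ul2, ur1, ur2, flab,
                           probs[seq_len(n), , drop = FALSE],
                           opens, comm, uniq)
    trials <- data.frame(
      trial = plan$trial, block = plan$block,
      type = ifelse(slot_i == 2L, "uncertainty", "standard"),
      o1 = res$o1, o2 = res$o2, o3 = res$o3, o4 = res$o4,
      choice = res$choice, chosen_object = res$chosen_object,
      ghost_nominated = res$ghost_nominated,
      room_1 = res$room_1, reward_1 = res$reward_1,
      room_2 = res$room_2, reward_2 = res$reward_2,
      p_room1 = probs[seq_len(n), 1], p_room2 = probs[seq_len(n), 2],
      p_room3 = probs[seq_len(n), 3], p_room4 = probs[seq_len(n), 4],
      followup_label = plan$followup_label,
      missing = FALSE, choice_p = res$choice_p,
      stringsAsFactors = FALSE)
    session <- list(participant = participant, structure = structure,
                    trials = trials, seeds = list(session = seed),
                    generator = list(spec = spec, params = params))
    class(session) <- "ghost_session"
    return(session)
  }

  # pure-R reference loop; the per-trial arithmetic mirrors the update
  # operators exactly (tests replay recorded sessions through
  # net_values()/choice_prob() and assert identical probabilities)
  fam <- match(spec$family, FAMILIES)    # 1 room, 2 object, 3 acc, 4 rep
  pe <- spec$persev_after_ghost == "either"
  wmb <- par_full[["w_mb"]]; beta <- par_full[["beta"]]
  persev <- par_full[["persev"]]; lr_mb <- par_full[["lr_mb"]]
  lr_std <- par_full[["lr_standard"]]; lr_gn <- par_full[["lr_ghost_nom"]]
  lr_gr <- par_full[["lr_ghost_rej"]]; lam <- par_full[["lam"]]
  lr_mf <- par_full[["lr_mf"]]
  qmf <- rep(1, 4); qr <- rep(0.5, 4); qo <- rep(1, 4); e <- rep(0, 4)
  last1 <- 0L; last2 <- 0L
  slot <- match(plan$slot_type,
                c("standard_3n1", "uncertainty_3n2", "followup_3n3"))

  o1 <- o2 <- o3 <- o4 <- rep(NA_integer_, n)
  choice <- chosen_object <- nominated <- rep(NA_integer_, n)
  room_1 <- room_2 <- reward_1 <- reward_2 <- rep(NA_integer_, n)
  choice_p <- rep(NA_real_, n)
  type <- rep("standard", n)

  mbv <- function(o) {
    if (fam == 1L) qr[opens[o, 1]] + qr[opens[o, 2]]
    else if (fam == 2L) qo[o] else 0
  }
  mb_half_updates <- function(executed, fr, sr, r1t, r2t) {
    # object-value family: full update for the executed object, half updates
    # for the two objects sharing exactly one observed room
    qo[executed] <<- qo[executed] + lr_mb * (r1t + r2t - qo[executed])
    for (j in (1:4)[-executed]) {
      s1 <- fr %in% opens[j, ]; s2 <- sr %in% opens[j, ]
      if (xor(s1, s2)) {
        rr <- if (s1) r1t else r2t
        qo[j] <<- qo[j] + lr_mb * (rr - 0.5 * qo[j])
      }
    }
  }

  for (t in seq_len(n)) {
    if (fam > 2L) e <- lam * e
    if (slot[t] == 2L) {
      type[t] <- "uncertainty"
      pairing <- structure$uncertainty_pairings[[plan$pairing[t]]]
      left <- pairing[[plan$left_pair[t]]]
      right <- pairing[[3L - plan$left_pair[t]]]
      # order each displayed pair as (top, bottom)
      left <- c(left[plan$top_left[t]], left[3L - plan$top_left[t]])
      right <- c(right[plan$top_right[t]], right[3L - plan$top_right[t]])
      o1[t] <- left[1]; o2[t] <- left[2]; o3[t] <- right[1]; o4[t] <- right[2]
      in1 <- (left[1] == last1 || left[2] == last1 ||
              (pe && (left[1] == last2 || left[2] == last2)))
      in2 <- (right[1] == last1 || right[2] == last1 ||
              (pe && (right[1] == last2 || right[2] == last2)))
      v1 <- wmb * 0.5 * (mbv(left[1]) + mbv(left[2])) +
        (1 - wmb) * 0.5 * (qmf[left[1]] + qmf[left[2]]) + persev * in1
      v2 <- wmb * 0.5 * (mbv(right[1]) + mbv(right[2])) +
        (1 - wmb) * 0.5 * (qmf[right[1]] + qmf[right[2]]) + persev * in2
      d <- beta * (v1 - v2)
      p1 <- if (d >= 0) 1 / (1 + exp(-d)) else exp(d) / (1 + exp(d))
      choice_p[t] <- p1
      choice[t] <- if (runif(1) < p1) 1L else 2L
      pair <- if (choice[t] == 1L) left else right
      nom <- if (runif(1) < 0.5) pair[1] else pair[2]   # fair ghost coin
      rej <- pair[1] + pair[2] - nom
      fr <- comm[nom, rej]; sr <- uniq[nom, rej]
      r1t <- as.integer(runif(1) < probs[t, fr])
      r2t <- as.integer(runif(1) < probs[t, sr])
      nominated[t] <- nom
      tot <- r1t + r2t
      if (fam > 2L) {
        e[pair] <- if (fam == 3L) 1 + e[pair] else 1
        f <- if (fam == 3L) (1 - lam) * lr_mf else lr_mf
        qmf <- qmf + f * e * (tot - qmf)
      } else {
        qmf[nom] <- qmf[nom] + lr_gn * (tot - qmf[nom])
        qmf[rej] <- qmf[rej] + lr_gr * (tot - qmf[rej])
        if (fam == 1L) {
          qr[fr] <- qr[fr] + lr_mb * (r1t - qr[fr])
          qr[sr] <- qr[sr] + lr_mb * (r2t - qr[sr])
        } else {
          mb_half_updates(nom, fr, sr, r1t, r2t)
        }
      }
      last1 <- nom; last2 <- if (pe) rej else 0L
    } else {
      if (slot[t] == 1L) {
        pair <- structure$standard_pairs[[plan$std_pair[t]]]
        offer <- c(pair[plan$left_object[t]], pair[3L - plan$left_object[t]])
      } else {  # followup: offer depends on the previous uncertainty trial
        prev <- list(chosen_pair = if (choice[t - 1] == 1L)
                       c(o1[t - 1], o2[t - 1]) else c(o3[t - 1], o4[t - 1]),
                     nominated = nominated[t - 1])
        offer <- realize_followup_offer(structure, prev, plan$followup_label[t])
        if (runif(1) < 0.5) offer <- rev(offer)
      }
      A <- offer[1]; B <- offer[2]
      o1[t] <- A; o2[t] <- B
      v1 <- wmb * mbv(A) + (1 - wmb) * qmf[A] +
        persev * (A == last1 || (pe && A == last2))
      v2 <- wmb * mbv(B) + (1 - wmb) * qmf[B] +
        persev * (B == last1 || (pe && B == last2))
      d <- beta * (v1 - v2)
      p1 <- if (d >= 0) 1 / (1 + exp(-d)) else exp(d) / (1 + exp(d))
      choice_p[t] <- p1
      choice[t] <- if (runif(1) < p1) 1L else 2L
      ch <- offer[choice[t]]
      other <- offer[3L - choice[t]]
      fr <- uniq[ch, other]; sr <- comm[ch, other]
      r1t <- as.integer(runif(1) < probs[t, fr])
      r2t <- as.integer(runif(1) < probs[t, sr])
      chosen_object[t] <- ch
      tot <- r1t + r2t
      if (fam > 2L) {
        e[ch] <- if (fam == 3L) 1 + e[ch] else 1
        f <- if (fam == 3L) (1 - lam) * lr_mf else lr_mf
        qmf <- qmf + f * e * (tot - qmf)
      } else {
        qmf[ch] <- qmf[ch] + lr_std * (tot - qmf[ch])
        if (fam == 1L) {
          qr[fr] <- qr[fr] + lr_mb * (r1t - qr[fr])
          qr[sr] <- qr[sr] + lr_mb * (r2t - qr[sr])
        } else {
          mb_half_updates(ch, fr, sr, r1t, r2t)
        }
      }
      last1 <- ch; last2 <- 0L
    }
    room_1[t] <- fr; room_2[t] <- sr
    reward_1[t] <- r1t; reward_2[t] <- r2t
  }

  trials <- data.frame(
    trial = plan$trial, block = plan$block, type = type,
    o1 = o1, o2 = o2, o3 = o3, o4 = o4,
    choice = choice, chosen_object = chosen_object,
    ghost_nominated = nominated,
    room_1 = room_1, reward_1 = reward_1,
    room_2 = room_2, reward_2 = reward_2,
    p_room1 = probs[seq_len(n), 1], p_room2 = probs[seq_len(n), 2],
    p_room3 = probs[seq_len(n), 3], p_room4 = probs[seq_len(n), 4],
    followup_label = plan$followup_label,
    missing = FALSE,
    choice_p = choice_p,
    stringsAsFactors = FALSE
  )
  session <- list(participant = participant, structure = structure,
                  trials = trials, seeds = list(session = seed),
                  generator = list(spec = spec, params = params))
  class(session) <- "ghost_session"
  session
}

#' @export
print.ghost_session <- function(x, ...) {
  cat(sprintf("Session %s: %d trials (%d uncertainty), %d blocks\n",
              x$participant, nrow(x$trials),
              sum(x$trials$type == "uncertainty"), max(x$trials$block)))
  invisible(x)
}

#' Simulate a cohort of synthetic participants
#'
#' Each participant gets a fresh object-room mapping and plays
#' `n_sessions_per_participant` sessions generated by the given model, each
#' on novel trial sequences (fresh plans and reward walks), as in the
#' experiment. Multiple sessions per participant correspond to the
#' model-prediction procedure in which each fitted participant is simulated
#' 25 times and the synthetic data analysed like the empirical data.
#'
#' @param params_list list of `model_params`, one per participant (e.g. from
#'   [sample_cohort_params()]).
#' @param spec a `model_spec` shared by the cohort.
#' @param seed integer seed; per-participant and per-session seeds are
#'   derived from it.
#' @param n_blocks,trials_per_block session geometry.
#' @param step_sd walk step standard deviation.
#' @param n_sessions_per_participant sessions simulated per participant; the
#'   sessions of one participant share the participant id (analyses pool
#'   them) and the object-room mapping.
#' @return flat list of `ghost_session` objects, participant-major.
#' @export
simulate_cohort <- function(params_list, spec, seed = 1L,
                            n_blocks = 7L, trials_per_block = 72L,
                            step_sd = 0.025,
                            n_sessions_per_participant = 1L) {
  out <- vector("list", length(params_list) * n_sessions_per_participant)
  j <- 0L
  for (i in seq_along(params_list)) {
    s <- derive_seed(seed, i, "participant")
    structure <- build_task_structure(derive_seed(s, 1L, "structure"))
    for (k in seq_len(n_sessions_per_participant)) {
      b <- if (k == 1L) s else derive_seed(s, k, "session")
      plan <- generate_trial_plan(structure, derive_seed(b, 2L, "plan"),
                                  n_blocks, trials_per_block)
      walks <- generate_walks(nrow(plan), step_sd,
                              derive_seed(b, 3L, "walks"))
      j <- j + 1L
      out[[j]] <- simulate_session(structure, plan, walks, params_list[[i]],
                                   spec, seed = derive_seed(b, 4L, "choices"),
                                   participant = sprintf("sim%02d", i))
    }
  }
  out
}

# Fresh synthetic session for bootstrap methods: same structure as `session`,
# novel plan and walks, choices generated by (spec, params).
resim_session <- function(session, params, spec, seed,
                          step_sd = 0.025) {
  structure <- session$structure
  n <- nrow(session$trials)
  n_blocks <- max(session$trials$block)
  plan <- generate_trial_plan(structure, derive_seed(seed, 1L, "plan"),
                              n_blocks, n %/% n_blocks)
  walks <- generate_walks(n, step_sd, derive_seed(seed, 2L, "walks"))
  simulate_session(structure, plan, walks, params, spec,
                   seed = derive_seed(seed, 3L, "choices"),
                   participant = session$participant)
}
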