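# Standalone hand-trace of the session likelihood, written directly from the
# learning equations and deliberately independent of the package's value /
# update functions. Naive style on purpose: explicit searches instead of
# lookup tables, softmax via explicit normalization.

oracle_nll <- function(pars, family, session, persev_either = FALSE) {
  tr <- session$trials
  opens <- session$structure$opens
  rooms_of <- function(o) opens[o, ]
  shared_room <- function(a, b) intersect(rooms_of(a), rooms_of(b))

  q_mf <- c(1, 1, 1, 1)
  q_room <- c(0.5, 0.5, 0.5, 0.5)
  q_obj <- c(1, 1, 1, 1)
  e <- c(0, 0, 0, 0)
  last <- integer(0)
  nll <- 0

  obj_value_mb <- function(o) {
    if (family == "mb_room") sum(q_room[rooms_of(o)])
    else if (family == "mb_object") q_obj[o]
    else 0
  }
  option_value <- function(objs) {
    v_mb <- mean(sapply(objs, obj_value_mb))
    v_mf <- mean(q_mf[objs])
    bonus <- if (any(objs %in% last)) pars[["persev"]] else 0
    pars[["w_mb"]] * v_mb + (1 - pars[["w_mb"]]) * v_mf + bonus
  }
  softmax_log_p <- function(v_ch, v_other) {
    z <- pars[["beta"]] * c(v_ch, v_other)
    z <- z - max(z)
    z[1] - log(sum(exp(z)))
  }
  mb_update <- function(executed, rooms, rewards) {
    if (family == "mb_room") {
      for (k in 1:2) {
        rm <- rooms[k]
        q_room[rm] <<- q_room[rm] + pars[["lr_mb"]] * (rewards[k] - q_room[rm])
      }
    } else if (family == "mb_object") {
      tot <- sum(rewards)
      q_obj[executed] <<- q_obj[executed] +
        pars[["lr_mb"]] * (tot - q_obj[executed])
      for (j in setdiff(1:4, executed)) {
        obs <- rooms_of(j)[rooms_of(j) %in% rooms]
        if (length(obs) == 1) {
          rr <- rewards[which(rooms == obs)]
          q_obj[j] <<- q_obj[j] + pars[["lr_mb"]] * (rr - 0.5 * q_obj[j])
        }
      }
    }
  }

  for (t in seq_len(nrow(tr))) {
    if (tr$missing[t]) next
    elig <- family %in% c("elig_accumulating", "elig_replacing")
    if (elig) e <- pars[["lam"]] * e
    if (tr$type[t] == "standard") {
      offer <- list(tr$o1[t], tr$o2[t])
      v <- sapply(offer, option_value)
      ch_i <- tr$choice[t]
      nll <- nll - softmax_log_p(v[ch_i], v[3 - ch_i])
      chosen <- offer[[ch_i]]
      rooms <- c(tr$room_1[t], tr$room_2[t])
      rewards <- c(tr$reward_1[t], tr$reward_2[t])
      tot <- sum(rewards)
      if (elig) {
        if (family == "elig_accumulating") {
          e[chosen] <- 1 + e[chosen]
          q_mf <- q_mf + (1 - pars[["lam"]]) * pars[["lr_mf"]] * e * (tot - q_mf)
        } else {
          e[chosen] <- 1
          q_mf <- q_mf + pars[["lr_mf"]] * e * (tot - q_mf)
        }
      } else {
        q_mf[chosen] <- q_mf[chosen] + pars[["lr_standard"]] * (tot - q_mf[chosen])
        mb_update(chosen, rooms, rewards)
      }
      last <- chosen
    } else {
      pairs <- list(c(tr$o1[t], tr$o2[t]), c(tr$o3[t], tr$o4[t]))
      v <- sapply(pairs, option_value)
      ch_i <- tr$choice[t]
      nll <- nll - softmax_log_p(v[ch_i], v[3 - ch_i])
      pair <- pairs[[ch_i]]
      # the nominee is whichever pair member opens the second room
      nom <- pair[sapply(pair, function(o) tr$room_2[t] %in% rooms_of(o))]
      stopifnot(length(nom) == 1)
      rej <- setdiff(pair, nom)
      rooms <- c(tr$room_1[t], tr$room_2[t])
      rewards <- c(tr$reward_1[t], tr$reward_2[t])
      tot <- sum(rewards)
      if (elig) {
        if (family == "elig_accumulating") {
          e[pair] <- 1 + e[pair]
          q_mf <- q_mf + (1 - pars[["lam"]]) * pars[["lr_mf"]] * e * (tot - q_mf)
        } else {
          e[pair] <- 1
          q_mf <- q_mf + pars[["lr_mf"]] * e * (tot - q_mf)
        }
      } else {
        q_mf[nom] <- q_mf[nom] + pars[["lr_ghost_nom"]] * (tot - q_mf[nom])
        q_mf[rej] <- q_mf[rej] + pars[["lr_ghost_rej"]] * (tot - q_mf[rej])
        mb_update(nom, rooms, rewards)
      }
      last <- if (persev_either) pair else nom
    }
  }
  nll
}
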