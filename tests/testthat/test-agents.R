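test_that("state initialization matches the learning-model priors", {
  s <- init_state(model_spec("mb_room"))
  expect_equal(s$q_mf, rep(1, 4))
  expect_equal(s$q_mb_rooms, rep(0.5, 4))
  expect_length(s$last_chosen, 0)
  se <- init_state(model_spec("elig_accumulating"))
  expect_equal(se$elig, rep(0, 4))
  so <- init_state(model_spec("mb_object"))
  expect_equal(so$q_mb_objects, rep(1, 4))
})

test_that("option values follow the prospective-sum and pair-mean rules", {
  st <- canonical_structure()
  sp <- model_spec("mb_room")
  s <- init_state(sp)
  s$q_mf <- c(1, 0, 0.7, 0.2)
  expect_equal(mf_option_value(s, c(1, 2)), 0.5)
  expect_equal(mf_option_value(s, 3), 0.7)
  expect_equal(mf_option_value(s, c(3, 3)), 0.7)  # pair of equal values
  s$q_mb_rooms <- c(0.2, 0.3, 0.4, 0.5)
  # object 1 opens rooms {1, 2}: 0.2 + 0.3
  expect_equal(mb_option_value(s, sp, st, 1), 0.5)
  # object 2 opens rooms {2, 3}: 0.3 + 0.4 = 0.7; pair mean = 0.6
  expect_equal(mb_option_value(s, sp, st, c(1, 2)), 0.6)
  s$q_mb_rooms <- rep(0.5, 4)
  for (o in 1:4) expect_equal(mb_option_value(s, sp, st, o), 1)
  expect_error(mf_option_value(s, 5), "unknown")
})

test_that("net values mix MB and MF with the perseverance bonus", {
  st <- canonical_structure()
  sp <- model_spec("mb_room")
  p <- model_params(w_mb = 0.5, beta = 1, persev = 0)
  s <- init_state(sp)
  s$q_mf <- c(0.6, 1, 1, 1)
  s$q_mb_rooms <- c(0.5, 0.5, 0.2, 0.2)   # object 1 -> 1.0
  v <- net_values(s, sp, p, st, list(1, 2))
  expect_equal(v[[1]]$v_net, 0.5 * 1.0 + 0.5 * 0.6)
  # perseverance adds exactly persev to the option holding last_chosen
  p2 <- model_params(w_mb = 0.5, persev = 0.3)
  s$last_chosen <- 1L
  v2 <- net_values(s, sp, p2, st, list(1, 2))
  expect_equal(v2[[1]]$v_net - v[[1]]$v_net, 0.3)
  expect_equal(v2[[2]]$v_net, v[[2]]$v_net)
  # a pair containing last_chosen also receives the bonus
  v3 <- net_values(s, sp, p2, st, list(c(1, 2), c(3, 4)))
  expect_equal(v3[[1]]$v_net -
                 net_values(s, sp, p, st, list(c(1, 2), c(3, 4)))[[1]]$v_net,
               0.3)
  # w_mb = 1 makes values independent of MF caches
  p3 <- model_params(w_mb = 1)
  s2 <- s; s2$q_mf <- c(9, 9, 9, 9)
  expect_equal(net_values(s, sp, p3, st, list(1, 2))[[1]]$v_net,
               net_values(s2, sp, p3, st, list(1, 2))[[1]]$v_net)
})

test_that("softmax choice probabilities are symmetric, limit-correct and stable", {
  expect_equal(choice_prob(1, 1, 3), 0.5)
  expect_equal(choice_prob(0.3, 0.9, 1e-8), 0.5, tolerance = 1e-6)
  expect_equal(choice_prob(1, 0, 2), 1 / (1 + exp(-2)))
  expect_equal(choice_prob(1, 0, 2) + choice_prob(0, 1, 2), 1)
  # no overflow at extreme value differences
  expect_equal(choice_prob(100, -100, 20), 1)
  expect_false(is.nan(choice_prob(-100, 100, 20)))
  expect_gte(choice_prob(-100, 100, 20), 0)
  expect_error(choice_prob(1, 0, 0), "beta")
})

test_that("standard-trial updates assign credit as the equations specify", {
  st <- canonical_structure()
  p <- model_params(lr_mb = 0.4, lr_standard = 0.5)
  # room-value family: each observed room moves toward its own reward
  sp <- model_spec("mb_room")
  s <- init_state(sp)
  s2 <- update_after_standard(s, sp, p, st, chosen = 1, r1 = 1, r2 = 1,
                              rooms = c(1, 2))
  expect_equal(s2$q_mb_rooms[1], 0.5 + 0.4 * (1 - 0.5))  # 0.7
  expect_equal(s2$q_mb_rooms[2], 0.7)
  expect_equal(s2$q_mb_rooms[3:4], c(0.5, 0.5))
  # MF: chosen object only, toward the 2-point total
  expect_equal(s2$q_mf[1], 1 + 0.5 * (2 - 1))            # 1.5
  expect_equal(s2$q_mf[2:4], rep(1, 3))                  # frame property
  expect_equal(s2$last_chosen, 1L)
  # object-value family: full update for chosen, half updates for sharers
  spo <- model_spec("mb_object")
  p2 <- model_params(lr_mb = 0.5, lr_standard = 0.5)
  so <- init_state(spo)
  so$q_mb_objects <- c(1, 1, 1, 1)
  so2 <- update_after_standard(so, spo, p2, st, chosen = 1, r1 = 1, r2 = 1,
                               rooms = c(1, 2))
  expect_equal(so2$q_mb_objects[1], 1 + 0.5 * (2 - 1))   # full update
  # object 2 shares room 2 (reward 1): 1 + 0.5 * (1 - 0.5) = 1.25
  expect_equal(so2$q_mb_objects[2], 1.25)
  # object 4 shares room 1 (reward 1): 1.25; object 3 untouched
  expect_equal(so2$q_mb_objects[4], 1.25)
  expect_equal(so2$q_mb_objects[3], 1)
  expect_error(update_after_standard(init_state(model_spec("elig_replacing")),
                                     model_spec("elig_replacing"), p, st,
                                     1, 1, 1, c(1, 2)),
               "eligibility_trial_step")
})

test_that("uncertainty-trial updates split credit by nomination", {
  st <- canonical_structure()
  sp <- model_spec("mb_room")
  # no-learning-for-rejected: nominee moves, rejected frozen
  p <- model_params(lr_ghost_nom = 0.5, lr_ghost_rej = 0)
  s <- init_state(sp)
  s2 <- update_after_uncertainty(s, sp, p, st, chosen_pair = c(1, 2),
                                 nominated = 1, r1 = 1, r2 = 1,
                                 rooms = c(2, 1))
  expect_equal(s2$q_mf[1], 1.5)
  expect_equal(s2$q_mf[2], 1)
  expect_equal(s2$last_chosen, 1L)
  # zero total reward with rates 0.5/0.1
  p2 <- model_params(lr_ghost_nom = 0.5, lr_ghost_rej = 0.1)
  s3 <- update_after_uncertainty(init_state(sp), sp, p2, st, c(1, 2), 1,
                                 0, 0, c(2, 1))
  expect_equal(s3$q_mf[1], 0.5)
  expect_equal(s3$q_mf[2], 0.9)
  # equal rates move both members by the same fraction of the same error
  p3 <- model_params(lr_ghost_nom = 0.3, lr_ghost_rej = 0.3)
  s4 <- update_after_uncertainty(init_state(sp), sp, p3, st, c(1, 2), 1,
                                 0, 1, c(2, 1))
  expect_equal(s4$q_mf[1], s4$q_mf[2])
  # "either" bookkeeping marks both pair members as last chosen
  spe <- model_spec("mb_room", persev_after_ghost = "either")
  s5 <- update_after_uncertainty(init_state(spe), spe, p2, st, c(1, 2), 1,
                                 1, 0, c(2, 1))
  expect_setequal(s5$last_chosen, c(1L, 2L))
  expect_error(update_after_uncertainty(init_state(sp), sp, p, st, c(1, 2),
                                        3, 1, 1, c(2, 1)), "not in chosen pair")
})

test_that("eligibility traces decay, accumulate/replace and gate learning", {
  st <- canonical_structure()
  # replacing traces with lam = 0 reduce to chosen-object-only learning
  spr <- model_spec("elig_replacing")
  p <- model_params(lam = 0, lr_mf = 0.5)
  s <- init_state(spr)
  s2 <- eligibility_trial_step(s, spr, p, chosen_objects = 1, total_reward = 2)
  expect_equal(s2$q_mf[1], 1.5)
  expect_equal(s2$q_mf[2:4], rep(1, 3))
  # accumulating traces with lam = 1: the (1 - lam) factor nulls learning
  spa <- model_spec("elig_accumulating")
  p1 <- model_params(lam = 1, lr_mf = 0.5)
  s3 <- eligibility_trial_step(init_state(spa), spa, p1, 1, 2)
  expect_equal(s3$q_mf, rep(1, 4))
  # trace bookkeeping: chosen twice in a row with lam = 0.5 -> 1 + 0.5
  p5 <- model_params(lam = 0.5, lr_mf = 0.3)
  sa <- init_state(spa)
  sa <- eligibility_trial_step(sa, spa, p5, 1, 1)
  expect_equal(sa$elig[1], 1)
  sa <- eligibility_trial_step(sa, spa, p5, 1, 1)
  expect_equal(sa$elig[1], 1.5)
  # ghost trials update both chosen-pair traces
  sb <- eligibility_trial_step(init_state(spa), spa, p5, c(1, 2), 2)
  expect_equal(sb$elig[1:2], c(1, 1))
  expect_error(eligibility_trial_step(init_state(model_spec("mb_room")),
                                      model_spec("mb_room"), p5, 1, 1),
               "eligibility")
})
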