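test_that("regression rows match a hand classification of the fixture", {
  ses <- fixture_session()
  # trials 3->4: followup (standard) then 3n+1 standard; trial 4 offers
  # {2, 3}, previous chosen was 4 -> std_generalize candidate; object 3
  # shares room 4 with object 4 (the previous choice)
  gen <- build_regression_rows(ses, "std_generalize")
  expect_equal(nrow(gen), 2)  # transitions 3->4 and 6->7
  row34 <- gen[1, ]
  # trial 3 chose object 4 (rooms 4, 1; rewards r(R4)=0, r(R1)=1);
  # shared room with target 3 is R4 -> C = -0.5, U (room 1) = +0.5
  expect_equal(row34$C, -0.5)
  expect_equal(row34$U, 0.5)
  expect_equal(row34$P, 0)           # fixture walks pinned at 0.5
  expect_equal(row34$outcome, 1L)    # trial 4 chose object 3
  # trial 6 chose object 1 with both rooms unrewarded; trial 7 offers
  # {3, 4}, sharer with object 1 is object 4, which was not chosen
  expect_equal(gen$C[2], -0.5)
  expect_equal(gen$outcome[2], 0L)
  # std_repeat: only transition 9->10 offers the previously chosen object 4
  rep_std <- build_regression_rows(ses, "std_repeat")
  expect_equal(nrow(rep_std), 1)
  expect_equal(rep_std$C, 0.5)   # trial 9 rewarded the shared room R1
  expect_equal(rep_std$U, 0.5)   # and object 4's other room R4
  expect_equal(rep_std$outcome, 0L)  # trial 10 switched to object 1
  # uncertainty follow-ups
  rep_rows <- build_regression_rows(ses, "unc_repeat")
  expect_equal(nrow(rep_rows), 2)    # trials 3 and 12
  # trial 2: N = reward_1 = 1 -> +0.5, I = reward_2 = 1 -> +0.5; trial 3
  # chose object 4, nominee was 1 -> outcome 0
  expect_equal(rep_rows$N[1], 0.5)
  expect_equal(rep_rows$I[1], 0.5)
  expect_equal(rep_rows$outcome[1], 0L)
  # trial 12 chose object 2 = nominee of trial 11 -> outcome 1
  expect_equal(rep_rows$outcome[2], 1L)
  sw <- build_regression_rows(ses, "unc_switch")
  expect_equal(nrow(sw), 1)
  # trial 5 nominee 4, rejected 1; trial 6 chose 1 -> generalization = 1
  expect_equal(sw$outcome, 1L)
  expect_equal(sw$N, 0.5)   # trial 5 reward_1 = 1
  expect_equal(sw$I, -0.5)  # trial 5 reward_2 = 0
  cl <- build_regression_rows(ses, "unc_clash")
  expect_equal(nrow(cl), 1)
  # trial 8 nominee 3; trial 9 chose 4 -> repeat = 0
  expect_equal(cl$outcome, 0L)
  expect_error(build_regression_rows(ses, "bogus"))
})

test_that("row counts from full sessions respect the design ceilings", {
  out <- random_short_session(41, n_blocks = 7, trials_per_block = 72)
  kinds <- c("unc_repeat", "unc_switch", "unc_clash")
  counts <- vapply(kinds, function(k)
    nrow(build_regression_rows(out$session, k)), numeric(1))
  expect_true(all(counts <= 56))
  expect_lte(sum(counts), 168)
  rep_rows <- build_regression_rows(out$session, "std_repeat")
  tr <- out$session$trials
  # every std_repeat row comes from an offer containing the previous choice
  std_t <- which(tr$type == "standard" &
                 c("", tr$type[-nrow(tr)]) == "standard")
  n_manual <- sum(vapply(std_t, function(t)
    tr$chosen_object[t - 1] %in% c(tr$o1[t], tr$o2[t]), logical(1)))
  expect_equal(nrow(rep_rows), n_manual)
})

test_that("hierarchical logistic recovers a planted effect and nulls", {
  set.seed(5)
  n_part <- 30; n_rows <- 80
  mk_rows <- function(b_c, b_u) {
    do.call(rbind, lapply(seq_len(n_part), function(i) {
      C <- sample(c(-0.5, 0.5), n_rows, TRUE)
      U <- sample(c(-0.5, 0.5), n_rows, TRUE)
      eta <- 0.2 + b_c * C + b_u * U
      data.frame(participant = sprintf("p%02d", i), outcome = rbinom(n_rows, 1, plogis(eta)),
                 C = C, U = U, stringsAsFactors = FALSE)
    }))
  }
  rows <- mk_rows(b_c = 1.2, b_u = 0)
  fit <- hier_logit(rows, c("C", "U"), mode = "summary_stats")
  cf <- fit$coefficients
  expect_gt(cf$estimate[cf$term == "C"], 0)
  expect_lt(cf$p[cf$term == "C"], 0.001)
  expect_gt(cf$p[cf$term == "U"], 0.05)
  # relabeling rewarded/unrewarded flips the main effects, not the interaction
  rows_flip <- rows
  rows_flip$C <- -rows_flip$C
  rows_flip$U <- -rows_flip$U
  fit_flip <- hier_logit(rows_flip, c("C", "U"), mode = "summary_stats")
  est <- function(f, term) f$coefficients$estimate[f$coefficients$term == term]
  expect_equal(est(fit_flip, "C"), -est(fit, "C"), tolerance = 1e-8)
  expect_equal(est(fit_flip, "U"), -est(fit, "U"), tolerance = 1e-8)
  expect_equal(est(fit_flip, "C:U"), est(fit, "C:U"), tolerance = 1e-8)
  # outcome independent of regressors: estimates near zero
  rows0 <- mk_rows(0, 0)
  fit0 <- hier_logit(rows0, c("C", "U"), mode = "summary_stats")
  expect_true(all(abs(fit0$coefficients$statistic[-1]) < 3.5))
})

test_that("random-effects mode runs on a well-behaved problem", {
  set.seed(6)
  rows <- do.call(rbind, lapply(1:12, function(i) {
    C <- sample(c(-0.5, 0.5), 60, TRUE)
    data.frame(participant = i, outcome = rbinom(60, 1, plogis(1 * C)),
               C = C)
  }))
  fit <- hier_logit(rows, "C", mode = "auto")
  expect_true(fit$mode %in% c("random_effects", "summary_stats"))
  expect_gt(fit$coefficients$estimate[fit$coefficients$term == "C"], 0)
})

test_that("informative contrasts equal the within-cell probability differences", {
  pars <- sample_cohort_params(4, seed = 51)
  sessions <- simulate_cohort(pars, model_spec("mb_room"), seed = 52)
  res <- informative_contrast_test(sessions)
  expect_equal(res$df, length(res$contrast_repeat) - 1)
  expect_true(is.finite(res$p))
  # recompute one participant's repeat contrast by hand
  rows <- build_regression_rows(sessions[[1]], "unc_repeat")
  manual <- mean(rows$outcome[rows$I == 0.5]) -
    mean(rows$outcome[rows$I == -0.5])
  expect_equal(unname(res$contrast_repeat[sessions[[1]]$participant]), manual)
})

test_that("learning-rate comparison degenerates correctly and is exchangeable", {
  df <- data.frame(participant = paste0("p", 1:8),
                   lr_standard = c(0.4, 0.5, 0.35, 0.45, 0.42, 0.5, 0.38, 0.41),
                   lr_ghost_nom = c(0.5, 0.6, 0.45, 0.52, 0.5, 0.62, 0.47, 0.5),
                   lr_ghost_rej = c(0.1, 0.2, 0.12, 0.15, 0.11, 0.22, 0.1, 0.13))
  res <- lr_comparison(df)
  expect_gt(res$omnibus$F, 0)
  expect_lt(res$omnibus$p, 0.05)
  expect_equal(res$pairwise$estimate[1],
               mean(df$lr_ghost_nom - df$lr_ghost_rej))
  # permuting participant order changes nothing
  res_perm <- lr_comparison(df[sample(8), ])
  expect_equal(res$omnibus$F, res_perm$omnibus$F)
  expect_equal(res$means, res_perm$means)
  # all three rates identical for every participant: zero omnibus signal
  df_eq <- data.frame(participant = paste0("p", 1:5),
                      lr_standard = 1:5 / 10, lr_ghost_nom = 1:5 / 10,
                      lr_ghost_rej = 1:5 / 10)
  res_eq <- lr_comparison(df_eq)
  expect_equal(res_eq$omnibus$F, 0, tolerance = 1e-10)
})

test_that("permutation correlation matches exhaustive enumeration", {
  df <- data.frame(participant = paste0("p", 1:5),
                   lr_standard = 0.4,
                   lr_ghost_nom = c(0.52, 0.48, 0.61, 0.55, 0.43),
                   lr_ghost_rej = c(0.12, 0.2, 0.05, 0.1, 0.3))
  df$w_mb <- c(0.7, 0.4, 0.85, 0.6, 0.2)
  exact <- wmb_lrdiff_correlation(df, exact = TRUE)
  expect_equal(exact$n_perm, 120)
  sampled <- wmb_lrdiff_correlation(df, n_perm = 20000, seed = 8)
  expect_equal(sampled$p, exact$p, tolerance = 0.02)
  # perfectly correlated vectors: no shuffle beats the identity beyond ties
  df2 <- df
  df2$w_mb <- df2$lr_ghost_nom - df2$lr_ghost_rej
  ex2 <- wmb_lrdiff_correlation(df2, exact = TRUE)
  expect_equal(ex2$r, 1)
  expect_lte(ex2$p, 1 / 120 + 1e-9)
  expect_error(wmb_lrdiff_correlation(transform(df, w_mb = 0.5)),
               "zero-variance")
})

test_that("densest interval matches a brute-force window scan", {
  brute <- function(v, anchor, mass = 0.5) {
    v <- sort(v); n <- length(v); k <- max(1, ceiling(mass * n))
    best <- NULL
    for (i in seq_len(n - k + 1)) {
      lo <- min(v[i], anchor); hi <- max(v[i + k - 1], anchor)
      cand <- c(lo, hi)
      if (is.null(best) || diff(cand) < diff(best) - 1e-12 ||
          (abs(diff(cand) - diff(best)) <= 1e-12 &&
           abs(mean(cand) - anchor) < abs(mean(best) - anchor) - 1e-12)) {
        best <- cand
      }
    }
    best
  }
  # frozen example: values 1..100 with anchor 50 -> a width-49 window
  # containing 50, centered as closely as possible on it
  iv <- densest_interval(1:100, 50)
  expect_equal(diff(iv), 49)
  expect_true(iv[1] <= 50 && 50 <= iv[2])
  expect_equal(iv, brute(1:100, 50))
  set.seed(99)
  for (i in 1:50) {
    v <- rnorm(sample(5:40, 1))
    anchor <- rnorm(1)
    expect_equal(densest_interval(v, anchor), brute(v, anchor))
    iv <- densest_interval(v, anchor)
    expect_true(iv[1] <= anchor && anchor <= iv[2])
  }
  # degenerate: all mass at the anchor
  expect_equal(densest_interval(rep(2, 10), 2), c(2, 2))
})

test_that("calibrated null correlation runs end-to-end at reduced scale", {
  pars <- sample_cohort_params(3, seed = 71)
  sessions <- simulate_cohort(pars, model_spec("mb_room"), seed = 72,
                              n_blocks = 2)
  o <- fit_options(n_starts = 2, seed = 73, maxit = 60, factr = 1e9)
  ni <- lapply(sessions, fit_participant,
               spec = model_spec("mb_room", "non_inference"), options = o)
  fu <- lapply(sessions, fit_participant,
               spec = model_spec("mb_room", "full"), options = o)
  res <- calibrated_null_correlation(
    sessions, ni, fu, n_sessions_per_participant = 3, n_resample = 500,
    options = fit_options(n_starts = 1, maxit = 60, factr = 1e9), seed = 74)
  expect_true(res$p >= 0 && res$p <= 1)
  expect_length(res$null_correlations, 500)
  expect_equal(dim(res$sim_estimates$w_mb), c(3, 3))
  # p convention: proportion of null correlations strictly larger
  expect_equal(res$p, mean(res$null_correlations > res$r_empirical))
})

test_that("the permutation correlation test is calibrated on independent inputs", {
  set.seed(81)
  ps <- replicate(40, {
    df <- data.frame(participant = paste0("p", 1:30),
                     w_mb = runif(30),
                     lr_standard = 0.4,
                     lr_ghost_nom = runif(30, 0.3, 0.7),
                     lr_ghost_rej = runif(30, 0, 0.3))
    wmb_lrdiff_correlation(df, n_perm = 200)$p
  })
  # one-sided p-values should spread over [0, 1] with no mass pile-up
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
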