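small_opts <- function(seed = 1) {
  fit_options(n_starts = 2, seed = seed, maxit = 60, factr = 1e9)
}

test_that("individual BGLRT is reproducible and p respects its definition", {
  out <- random_short_session(21, n_blocks = 2, trials_per_block = 72)
  full <- model_spec("mb_room", "full")
  sub <- model_spec("mb_room", "non_inference")
  r1 <- bglrt_individual(out$session, full, sub, n_boot = 10,
                         options = small_opts(1), seed = 5)
  r2 <- bglrt_individual(out$session, full, sub, n_boot = 10,
                         options = small_opts(1), seed = 5)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_equal(r1$p_individual,
               mean(r1$null_stats >= r1$empirical_stat))
  expect_gte(r1$empirical_stat, -1e-3)
  expect_error(bglrt_individual(out$session, full,
                                model_spec("mb_object", "non_inference"),
                                n_boot = 2, options = small_opts()),
               "same family")
  expect_error(bglrt_individual(out$session, full, full, n_boot = 2,
                                options = small_opts()), "strict constraint")
})

test_that("group BGLRT matches brute-force enumeration on tiny null sets", {
  # two participants with 3-element null pools: enumerate all 9 sums
  mk <- function(id, emp, nulls) {
    structure(list(participant = id, empirical_stat = emp,
                   null_stats = nulls, p_individual = mean(nulls >= emp),
                   n_boot = length(nulls)), class = "bglrt_result")
  }
  r1 <- mk("a", 2.0, c(0.5, 1.5, 3.0))
  r2 <- mk("b", 1.0, c(0.2, 0.8, 2.5))
  g <- bglrt_group(list(r1, r2), n_resample = 40000, seed = 9)
  sums <- as.vector(outer(r1$null_stats, r2$null_stats, `+`))
  p_exact <- mean(sums >= r1$empirical_stat + r2$empirical_stat)
  expect_equal(g$p_group, p_exact, tolerance = 0.02)
  expect_equal(g$empirical_sum, 3.0)
  # all empirical stats zero with nonnegative nulls: group p = 1
  r3 <- mk("c", 0, c(0, 1, 2))
  expect_equal(bglrt_group(list(r3), n_resample = 1000, seed = 1)$p_group, 1)
  expect_error(bglrt_group(list()), "at least one")
})

test_that("group BGLRT for one participant redraws that participant's null", {
  nulls <- c(0.1, 0.9, 2.2, 3.7)
  r <- structure(list(participant = "a", empirical_stat = 2.0,
                      null_stats = nulls, p_individual = 0.5, n_boot = 4L),
                 class = "bglrt_result")
  g <- bglrt_group(list(r), n_resample = 20000, seed = 2)
  expect_equal(g$p_group, mean(nulls >= 2.0), tolerance = 0.02)
})

test_that("PBCM classifies by sign, is antisymmetric, and matches enumeration", {
  pars <- sample_cohort_params(2, seed = 31)
  sessions <- simulate_cohort(pars, model_spec("mb_room"), seed = 32,
                              n_blocks = 2)
  room <- model_spec("mb_room", "full")
  object <- model_spec("mb_object", "full")
  res <- pbcm(sessions, room, object, n_sim = 2, n_resample = 20000,
              options = small_opts(3), seed = 33)
  swapped <- pbcm(sessions, object, room, n_sim = 2, n_resample = 20000,
                  options = small_opts(3), seed = 33)
  # antisymmetric up to multi-start optimizer tolerance
  expect_equal(res$empirical_diff, -swapped$empirical_diff, tolerance = 1e-3)
  expect_equal(res$classification, if (res$empirical_diff > 0) "room"
                                   else "object")
  # the resampled group-mean distribution has 2 participants x 2 sims = 4
  # equally likely support points per generator; enumerate them exactly
  for (gen in c("room", "object")) {
    d <- res$sim_diffs[[gen]]
    support <- sort(as.vector(outer(d[1, ], d[2, ], `+`)) / 2)
    expect_setequal(round(unique(res$null_diffs[[gen]]), 9),
                    round(unique(support), 9))
    freq <- table(round(res$null_diffs[[gen]], 9)) / 20000
    expect_true(all(abs(freq - 1 / 4) < 0.02))
  }
})

test_that("BH step-up matches a brute-force scan on random p-vectors", {
  brute_bh <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    k <- 0
    for (i in seq_len(m)) if (p[ord[i]] <= i * q / m) k <- i
    if (k == 0) integer(0) else sort(ord[seq_len(k)])
  }
  expect_equal(bh_fdr(c(0.001, 0.9, 0.9), 0.05), 1L)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04), 0.05), 1:3)
  expect_length(bh_fdr(rep(1, 5), 0.05), 0)
  set.seed(77)
  for (i in 1:1000) {
    m <- sample(1:8, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_equal(bh_fdr(p, q), brute_bh(p, q))
  }
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "0, 1")
  expect_error(bh_fdr(0.5, 1.5), "q must")
})

test_that("BGLRT has power against preferential-learning generation", {
  # cohorts generated with a large nominated/rejected rate gap should yield
  # a smaller group p for the tied-rate test than matched null cohorts
  full <- model_spec("mb_room", "full")
  sub <- model_spec("mb_room", "non_inference")
  boot_opts <- fit_options(n_starts = 1, maxit = 60, factr = 1e9)
  emp_opts <- fit_options(n_starts = 4, maxit = 100, factr = 1e8)
  run_group <- function(gen_spec, pars, seed) {
    sessions <- simulate_cohort(pars, gen_spec, seed = seed)
    res <- lapply(seq_along(sessions), function(i) {
      o <- emp_opts; o$seed <- derive_seed(seed, i, "f")
      bglrt_individual(sessions[[i]], full, sub, n_boot = 19, options = o,
                       boot_options = boot_opts,
                       seed = derive_seed(seed, i, "b"))
    })
    bglrt_group(res, n_resample = 2000, seed = derive_seed(seed, 0L, "g"))
  }
  pars_alt <- sample_cohort_params(3, seed = 401)   # lr 0.5 vs 0.1
  pars_null <- lapply(sample_cohort_params(3, seed = 402), function(p) {
    p[["lr_ghost_rej"]] <- p[["lr_ghost_nom"]]
    p
  })
  g_alt <- run_group(full, pars_alt, 403)
  g_null <- run_group(sub, pars_null, 404)
  expect_lt(g_alt$p_group, g_null$p_group)
  expect_lt(g_alt$p_group, 0.2)
})
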