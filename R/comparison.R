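#' Bootstrap generalized likelihood-ratio test for one participant
#'
#' Fits the nested sub-model to the session, simulates `n_boot` synthetic
#' sessions from the sub-model at its ML parameters on novel trial sequences
#' (fresh plans and reward walks, same object-room mapping), refits both
#' models to every synthetic session, and compares the empirical twice
#' log-likelihood improvement of the full model against the resulting null
#' distribution. The p-value is the proportion of synthetic improvements at
#' least as large as the empirical one; a zero count is reported as 0 with
#' resolution bound `1/n_boot`.
#'
#' Synthetic-session refits are warm-started at the generating (sub-model ML)
#' parameters in addition to the random starts, which stabilizes the null
#' statistics at reduced `n_starts` presets.
#'
#' @param session a `ghost_session`.
#' @param full_spec,sub_spec nested [model_spec()]s of the same family.
#' @param n_boot number of bootstrap sessions (study scale: 1001).
#' @param options a [fit_options()] for the two empirical fits.
#' @param boot_options a [fit_options()] for the synthetic refits; defaults
#'   to `options`. A reduced-start warm-started preset here keeps the
#'   empirical and synthetic fit quality comparable while containing cost.
#' @param seed integer seed; per-iteration seeds are derived from it.
#' @param step_sd walk step SD used for the synthetic sessions.
#' @return an object of class `bglrt_result`: list with `participant`,
#'   `empirical_stat` (2 * log-likelihood improvement), `null_stats`,
#'   `p_individual`, `n_boot`, `sub_fit`, `full_fit`.
#' @export
bglrt_individual <- function(session, full_spec, sub_spec, n_boot = 1001L,
                             options = fit_options(),
                             boot_options = options, seed = 1L,
                             step_sd = 0.025) {
  if (!identical(full_spec$family, sub_spec$family)) {
    stop("full and sub model must belong to the same family")
  }
  if (identical(full_spec$constraint, sub_spec$constraint)) {
    stop("sub model must be a strict constraint of the full model")
  }
  sub_fit <- fit_participant(session, sub_spec, options)
  full_opts <- options
  full_opts$init <- sub_fit$params
  full_fit <- fit_participant(session, full_spec, full_opts)
  empirical <- 2 * (sub_fit$neg_loglik - full_fit$neg_loglik)

  null_stats <- vapply(seq_len(n_boot), function(b) {
    sb <- derive_seed(seed, b, "bglrt")
    sim <- resim_session(session, sub_fit$params, sub_spec, sb, step_sd)
    o_sub <- boot_options; o_sub$seed <- derive_seed(sb, 1L, "fit_sub")
    o_sub$init <- sub_fit$params
    fs <- fit_participant(sim, sub_spec, o_sub)
    o_full <- boot_options; o_full$seed <- derive_seed(sb, 2L, "fit_full")
    o_full$init <- fs$params
    ff <- fit_participant(sim, full_spec, o_full)
    2 * (fs$neg_loglik - ff$neg_loglik)
  }, numeric(1))

  out <- list(participant = session$participant,
              empirical_stat = empirical, null_stats = null_stats,
              p_individual = mean(null_stats >= empirical),
              n_boot = as.integer(n_boot),
              sub_fit = sub_fit, full_fit = full_fit)
  class(out) <- "bglrt_result"
  out
}

#' @export
print.bglrt_result <- function(x, ...) {
  p_str <- if (x$p_individual == 0) sprintf("< %.4g", 1 / x$n_boot)
           else sprintf("= %.4g", x$p_individual)
  cat(sprintf("BGLRT participant %s: 2*dLL = %.3f, p %s (%d bootstrap sessions)\n",
              x$participant, x$empirical_stat, p_str, x$n_boot))
  invisible(x)
}

#' Group-level bootstrap likelihood-ratio test
#'
#' Repeats `n_resample` times: draw one null statistic per participant
#' (uniformly from that participant's bootstrap pool) and sum across
#' participants. The group p-value is the proportion of resampled sums at
#' least as large as the summed empirical statistics.
#'
#' @param results list of [bglrt_individual()] results.
#' @param n_resample number of group resamples (study scale: 10,000).
#' @param seed integer seed.
#' @return list with `p_group`, `empirical_sum`, `null_sums`.
#' @export
bglrt_group <- function(results, n_resample = 10000L, seed = 1L) {
  if (length(results) < 1L) stop("need at least one participant")
  local_seed(seed)
  empirical_sum <- sum(vapply(results, `[[`, numeric(1), "empirical_stat"))
  draws <- vapply(results, function(r)
    sample(r$null_stats, n_resample, replace = TRUE), numeric(n_resample))
  null_sums <- if (is.matrix(draws)) rowSums(draws) else draws
  list(p_group = mean(null_sums >= empirical_sum),
       empirical_sum = empirical_sum, null_sums = null_sums)
}

#' Parametric bootstrap cross-fitting of the two model-based families
#'
#' Non-nested classification of the room-value versus object-value full
#' models. Both models are fitted to every session; then, for each generating
#' model in turn, `n_sim` synthetic sessions per participant are simulated at
#' that model's ML parameters and refitted with both models. Group
#' distributions of the mean twice log-likelihood difference
#' (room minus object) are built by `n_resample` draws of one synthetic
#' difference per participant; the empirical group difference is classified
#' against a criterion of 0 (positive favors the room-value family).
#'
#' @param sessions list of `ghost_session`s.
#' @param spec_room,spec_object the two full `model_spec`s being compared.
#' @param n_sim synthetic sessions per participant per generator (study
#'   scale: 100).
#' @param n_resample group resamples (study scale: 10,000).
#' @param options a [fit_options()].
#' @param seed integer seed.
#' @param step_sd walk step SD for synthetic sessions.
#' @return an object of class `pbcm_result`: list with `empirical_diff`
#'   (group mean of 2 * (LL_room - LL_object)), `classification`,
#'   `null_diffs` (named list of the two generator distributions),
#'   `sim_diffs` (the underlying participant-by-simulation difference
#'   matrices), `per_participant` (empirical differences), `fits_room`,
#'   `fits_object`.
#' @export
pbcm <- function(sessions, spec_room, spec_object, n_sim = 100L,
                 n_resample = 10000L, options = fit_options(), seed = 1L,
                 step_sd = 0.025) {
  n_part <- length(sessions)
  fits_room <- vector("list", n_part)
  fits_object <- vector("list", n_part)
  emp <- numeric(n_part)
  for (i in seq_len(n_part)) {
    o1 <- options; o1$seed <- derive_seed(seed, i, "fit_room")
    o2 <- options; o2$seed <- derive_seed(seed, i, "fit_object")
    fits_room[[i]] <- fit_participant(sessions[[i]], spec_room, o1)
    fits_object[[i]] <- fit_participant(sessions[[i]], spec_object, o2)
    emp[i] <- 2 * (fits_object[[i]]$neg_loglik - fits_room[[i]]$neg_loglik)
  }

  gen_diffs <- function(gen) {
    diffs <- matrix(NA_real_, n_part, n_sim)
    for (i in seq_len(n_part)) {
      gen_fit <- if (gen == "room") fits_room[[i]] else fits_object[[i]]
      gen_spec <- if (gen == "room") spec_room else spec_object
      for (b in seq_len(n_sim)) {
        sb <- derive_seed(seed, i * 100000L + b, gen)
        sim <- resim_session(sessions[[i]], gen_fit$params, gen_spec, sb,
                             step_sd)
        o_r <- options; o_r$seed <- derive_seed(sb, 1L, "r")
        o_r$init <- fits_room[[i]]$params
        o_o <- options; o_o$seed <- derive_seed(sb, 2L, "o")
        o_o$init <- fits_object[[i]]$params
        fr <- fit_participant(sim, spec_room, o_r)
        fo <- fit_participant(sim, spec_object, o_o)
        diffs[i, b] <- 2 * (fo$neg_loglik - fr$neg_loglik)
      }
    }
    diffs
  }
  diffs_room <- gen_diffs("room")
  diffs_object <- gen_diffs("object")

  local_seed(derive_seed(seed, 0L, "resample"))
  resample_means <- function(diffs) {
    picks <- matrix(sample.int(n_sim, n_part * n_resample, replace = TRUE),
                    n_part, n_resample)
    colMeans(matrix(diffs[cbind(rep(seq_len(n_part), n_resample),
                                as.vector(picks))],
                    n_part, n_resample))
  }
  null_diffs <- list(room = resample_means(diffs_room),
                     object = resample_means(diffs_object))
  out <- list(empirical_diff = mean(emp),
              classification = if (mean(emp) > 0) "room" else "object",
              null_diffs = null_diffs,
              sim_diffs = list(room = diffs_room, object = diffs_object),
              per_participant = emp,
              fits_room = fits_room, fits_object = fits_object)
  class(out) <- "pbcm_result"
  out
}

#' @export
print.pbcm_result <- function(x, ...) {
  cat(sprintf(
    "PBCM: empirical group 2*dLL (room - object) = %.3f -> %s-value family\n",
    x$empirical_diff, x$classification))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up rule at level `q`: reject all hypotheses with order
#' statistic `p_(i) <= k q / m` for the largest such `k`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q target FDR level in (0, 1).
#' @return integer indices of rejected hypotheses (possibly empty).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  which(p.adjust(pvals, method = "BH") <= q)
}
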