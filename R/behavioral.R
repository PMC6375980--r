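#' Build trial-transition regression rows for the model-agnostic analyses
#'
#' Classifies trial transitions and codes the outcome/regressor variables of
#' the five behavioral analyses:
#' \describe{
#'   \item{std_repeat}{Standard-to-standard transitions whose focal trial
#'     offers the previously chosen object. `C`/`U` code the previous trial's
#'     rewards of the room shared by the focal offer (Common) and of the
#'     previous chosen object's other room (Unique), +0.5 for reward and
#'     -0.5 for non-reward; the outcome is choice repetition.}
#'   \item{std_generalize}{Standard-to-standard transitions whose focal trial
#'     excludes the previously chosen object and offers exactly one object
#'     sharing a room with it. `C` codes that shared room's previous reward,
#'     `P` its reward probability on the previous trial (centered by
#'     subtracting 0.5), `U` the previous chosen object's other room; the
#'     outcome is generalization (choice of the room-sharing object).}
#'   \item{unc_repeat, unc_switch, unc_clash}{Uncertainty-to-standard
#'     transitions of the matching follow-up label. `N` and `I` code the
#'     uncertainty trial's first (common, non-informative) and second
#'     (unique, informative) outcomes; the outcome is choice of the
#'     ghost-nominated object (repeat, clash) or of the ghost-rejected
#'     object (switch). The nominee is re-inferred from the recorded second
#'     room.}
#' }
#' Transitions involving missing trials are dropped.
#'
#' @param sessions a `ghost_session` or list of them.
#' @param analysis_kind one of `"std_repeat"`, `"std_generalize"`,
#'   `"unc_repeat"`, `"unc_switch"`, `"unc_clash"`.
#' @return data frame with columns `participant`, `outcome` (0/1), the coded
#'   regressors (`C`, `U`, `P`, `N`, `I`; `NA` where not applicable) and
#'   `analysis_kind`.
#' @export
build_regression_rows <- function(sessions, analysis_kind) {
  kinds <- c("std_repeat", "std_generalize", "unc_repeat", "unc_switch",
             "unc_clash")
  analysis_kind <- match.arg(analysis_kind, kinds)
  if (inherits(sessions, "ghost_session")) sessions <- list(sessions)
  rows <- lapply(sessions, session_rows, analysis_kind = analysis_kind)
  do.call(rbind, rows)
}

session_rows <- function(session, analysis_kind) {
  tr <- session$trials
  st <- session$structure
  n <- nrow(tr)
  code <- function(r) r - 0.5
  k <- 0L
  outcome <- integer(n); C <- U <- P <- N <- I <- rep(NA_real_, n)
  for (t in 2:n) {
    if (tr$missing[t] || tr$missing[t - 1]) next
    if (startsWith(analysis_kind, "std")) {
      if (tr$type[t] != "standard" || tr$type[t - 1] != "standard") next
      prev_ch <- tr$chosen_object[t - 1]
      offer <- c(tr$o1[t], tr$o2[t])
      prev_rooms <- c(tr$room_1[t - 1], tr$room_2[t - 1])
      prev_rewards <- c(tr$reward_1[t - 1], tr$reward_2[t - 1])
      if (analysis_kind == "std_repeat") {
        if (!prev_ch %in% offer) next
        other <- offer[offer != prev_ch]
        c_room <- common_room(st, offer[1], offer[2])
        u_room <- unique_room(st, prev_ch, other)
        k <- k + 1L
        outcome[k] <- as.integer(tr$chosen_object[t] == prev_ch)
        C[k] <- code(prev_rewards[match(c_room, prev_rooms)])
        U[k] <- code(prev_rewards[match(u_room, prev_rooms)])
      } else {
        if (prev_ch %in% offer) next
        shares <- vapply(offer, function(o)
          length(intersect(st$opens[o, ], st$opens[prev_ch, ])) == 1L,
          logical(1))
        if (sum(shares) != 1L) next
        target <- offer[shares]
        c_room <- common_room(st, target, prev_ch)
        u_room <- setdiff(st$opens[prev_ch, ], c_room)
        p_cols <- c("p_room1", "p_room2", "p_room3", "p_room4")
        k <- k + 1L
        outcome[k] <- as.integer(tr$chosen_object[t] == target)
        C[k] <- code(prev_rewards[match(c_room, prev_rooms)])
        U[k] <- code(prev_rewards[match(u_room, prev_rooms)])
        P[k] <- tr[[p_cols[c_room]]][t - 1] - 0.5
      }
    } else {
      if (tr$type[t] != "standard" || tr$type[t - 1] != "uncertainty") next
      label <- switch(analysis_kind, unc_repeat = "repeat",
                      unc_switch = "switch", unc_clash = "clash")
      if (is.na(tr$followup_label[t]) || tr$followup_label[t] != label) next
      pair <- if (tr$choice[t - 1] == 1L) c(tr$o1[t - 1], tr$o2[t - 1])
              else c(tr$o3[t - 1], tr$o4[t - 1])
      nom <- infer_nomination(st, pair, tr$room_2[t - 1])
      rej <- pair[pair != nom]
      focal <- if (analysis_kind == "unc_switch") rej else nom
      k <- k + 1L
      outcome[k] <- as.integer(tr$chosen_object[t] == focal)
      N[k] <- code(tr$reward_1[t - 1])
      I[k] <- code(tr$reward_2[t - 1])
    }
  }
  if (k == 0L) return(NULL)
  idx <- seq_len(k)
  data.frame(participant = session$participant, outcome = outcome[idx],
             C = C[idx], U = U[idx], P = P[idx], N = N[idx], I = I[idx],
             analysis_kind = analysis_kind, stringsAsFactors = FALSE)
}

#' Hierarchical logistic regression of transition outcomes
#'
#' Fits the requested fixed effects (main effects and interactions of
#' `terms`) with per-participant random effects on the same terms and an
#' unconstrained random-effect covariance (via `lme4::glmer`). If the
#' random-effects fit fails or does not converge, a summary-statistics mode
#' is used instead — per-participant unregularized logistic fits followed by
#' across-participant one-sample t-tests on each coefficient — and the mode
#' is recorded in the result. The two modes agree at the sign/significance
#' level, which is the contract surface of these analyses.
#'
#' @param rows a [build_regression_rows()] data frame.
#' @param terms character vector of regressor columns (e.g. `c("C", "U")`
#'   fits `outcome ~ C * U`); use `interactions = FALSE` for main effects
#'   only.
#' @param mode `"auto"` (try random effects, fall back), `"random_effects"`,
#'   or `"summary_stats"`.
#' @param interactions include interaction terms.
#' @return an object of class `hier_logit_result`: list with `coefficients`
#'   (data frame: term, estimate, se, statistic, df, p), `mode`, `n_rows`,
#'   `n_participants`.
#' @export
hier_logit <- function(rows, terms, mode = c("auto", "random_effects",
                                             "summary_stats"),
                       interactions = TRUE) {
  mode <- match.arg(mode)
  stopifnot(all(terms %in% names(rows)))
  rows <- rows[stats::complete.cases(rows[, c("outcome", "participant", terms)]), ]
  if (length(unique(rows$participant)) < 2L) {
    stop("need at least 2 participants")
  }
  op <- if (interactions) " * " else " + "
  fixed <- paste(terms, collapse = op)

  if (mode %in% c("auto", "random_effects")) {
    f <- stats::as.formula(paste0("outcome ~ ", fixed,
                                  " + (", fixed, " | participant)"))
    fit <- tryCatch({
      m <- lme4::glmer(f, data = rows, family = binomial(),
                       control = lme4::glmerControl(optimizer = "bobyqa",
                                                    calc.derivs = FALSE))
      if (length(unlist(m@optinfo$conv$lme4)) > 0) stop("did not converge")
      m
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      cf <- summary(fit)$coefficients
      res <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                        statistic = cf[, 3], df = NA_real_, p = cf[, 4],
                        row.names = NULL, stringsAsFactors = FALSE)
      out <- list(coefficients = res, mode = "random_effects",
                  n_rows = nrow(rows),
                  n_participants = length(unique(rows$participant)))
      class(out) <- "hier_logit_result"
      return(out)
    }
    if (mode == "random_effects") stop("random-effects fit failed to converge")
  }

  # summary-statistics mode
  f1 <- stats::as.formula(paste0("outcome ~ ", fixed))
  parts <- split(rows, rows$participant)
  coefs <- lapply(parts, function(d) {
    if (length(unique(d$outcome)) < 2L) return(NULL)  # complete separation
    m <- tryCatch(suppressWarnings(glm(f1, data = d, family = binomial())),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    b <- coef(m)
    if (any(is.na(b))) return(NULL)
    b
  })
  coefs <- coefs[!vapply(coefs, is.null, logical(1))]
  if (length(coefs) < 2L) {
    stop("logistic fits degenerate (complete separation) in nearly every participant")
  }
  B <- do.call(rbind, coefs)
  res <- do.call(rbind, lapply(colnames(B), function(term) {
    tt <- t.test(B[, term])
    data.frame(term = term, estimate = unname(tt$estimate),
               se = sd(B[, term]) / sqrt(nrow(B)),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  out <- list(coefficients = res, mode = "summary_stats", n_rows = nrow(rows),
              n_participants = nrow(B))
  class(out) <- "hier_logit_result"
  out
}

#' @export
print.hier_logit_result <- function(x, ...) {
  cat(sprintf("Hierarchical logistic fit (%s mode, %d rows, %d participants)\n",
              x$mode, x$n_rows, x$n_participants))
  print(transform(x$coefficients, estimate = round(estimate, 3),
                  se = round(se, 3), statistic = round(statistic, 2),
                  p = signif(p, 3)))
  invisible(x)
}

#' Paired contrast of the informative outcome's effect on repeat vs switch trials
#'
#' For each participant, computes the informative-outcome contrast — the
#' probability of the focal choice when the informative room was rewarded
#' minus when it was not — separately on repeat follow-ups (choice of the
#' ghost-nominated object) and switch follow-ups (choice of the
#' ghost-rejected object), and compares the two by a paired two-sided t-test.
#' A larger repeat contrast indicates preferential model-free credit
#' assignment to the retrospectively inferred nominee.
#'
#' @param sessions a `ghost_session` or list of them.
#' @return an object of class `contrast_result`: per-participant contrast
#'   vectors, their means and standard errors, the paired `t`, `df`, `p`, and
#'   the ids of participants excluded for empty condition cells.
#' @export
informative_contrast_test <- function(sessions) {
  rep_rows <- build_regression_rows(sessions, "unc_repeat")
  sw_rows <- build_regression_rows(sessions, "unc_switch")
  cell_contrast <- function(d) {
    if (is.null(d) || !all(c(-0.5, 0.5) %in% d$I)) return(NA_real_)
    mean(d$outcome[d$I == 0.5]) - mean(d$outcome[d$I == -0.5])
  }
  ids <- union(unique(rep_rows$participant), unique(sw_rows$participant))
  cr <- vapply(ids, function(id)
    cell_contrast(rep_rows[rep_rows$participant == id, ]), numeric(1))
  cs <- vapply(ids, function(id)
    cell_contrast(sw_rows[sw_rows$participant == id, ]), numeric(1))
  ok <- !is.na(cr) & !is.na(cs)
  excluded <- ids[!ok]
  if (length(excluded)) {
    warning("excluding participants lacking a condition cell: ",
            paste(excluded, collapse = ", "))
  }
  cr <- setNames(cr[ok], ids[ok]); cs <- setNames(cs[ok], ids[ok])
  tt <- t.test(cr, cs, paired = TRUE)
  out <- list(contrast_repeat = cr, contrast_switch = cs,
              mean_repeat = mean(cr), mean_switch = mean(cs),
              se_repeat = sd(cr) / sqrt(length(cr)),
              se_switch = sd(cs) / sqrt(length(cs)),
              statistic = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, excluded = excluded)
  class(out) <- "contrast_result"
  out
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "Informative-outcome contrast: repeat M = %.3f (SE %.3f), switch M = %.3f (SE %.3f)\n",
    x$mean_repeat, x$se_repeat, x$mean_switch, x$se_switch))
  cat(sprintf("paired t(%d) = %.2f, p = %.4g\n", x$df, x$statistic, x$p))
  invisible(x)
}

fits_to_df <- function(fits) {
  if (is.data.frame(fits)) return(fits)
  do.call(rbind, lapply(fits, function(f) data.frame(
    participant = f$participant,
    w_mb = f$params[["w_mb"]],
    lr_standard = f$params[["lr_standard"]],
    lr_ghost_nom = f$params[["lr_ghost_nom"]],
    lr_ghost_rej = f$params[["lr_ghost_rej"]],
    stringsAsFactors = FALSE)))
}

#' Compare the three fitted model-free learning rates
#'
#' Tests whether the fitted learning rates for standard trials, the
#' ghost-nominated object and the ghost-rejected object differ. With exactly
#' one rate per participant per context the random-effects regression on
#' context indicators degenerates, so the equivalent repeated-measures form
#' is used: a within-participant ANOVA for the omnibus test plus the three
#' pairwise paired t-tests.
#'
#' @param fits list of full-model [fit_participant()] results (or a data
#'   frame with columns `participant`, `lr_standard`, `lr_ghost_nom`,
#'   `lr_ghost_rej`).
#' @return list with `means`, the omnibus `F`, `df` and `p`, and a `pairwise`
#'   data frame of paired contrasts.
#' @export
lr_comparison <- function(fits) {
  df <- fits_to_df(fits)
  if (nrow(df) < 2L) stop("need full-model fits for at least 2 participants")
  long <- data.frame(
    participant = factor(rep(df$participant, 3L)),
    context = factor(rep(c("standard", "ghost_nom", "ghost_rej"),
                         each = nrow(df)),
                     levels = c("standard", "ghost_nom", "ghost_rej")),
    lr = c(df$lr_standard, df$lr_ghost_nom, df$lr_ghost_rej))
  fit <- aov(lr ~ context + Error(participant), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  omnibus <- list(F = tab["context", "F value"],
                  df1 = tab["context", "Df"], df2 = tab["Residuals", "Df"],
                  p = tab["context", "Pr(>F)"])
  if (tab["context", "Sum Sq"] < 1e-12) {   # no context signal at all
    omnibus$F <- 0
    omnibus$p <- 1
  }
  pairs <- list(c("lr_ghost_nom", "lr_ghost_rej"),
                c("lr_standard", "lr_ghost_rej"),
                c("lr_standard", "lr_ghost_nom"))
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    tt <- t.test(df[[pr[1]]], df[[pr[2]]], paired = TRUE)
    data.frame(contrast = paste(pr, collapse = " - "),
               estimate = mean(df[[pr[1]]] - df[[pr[2]]]),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  list(means = c(standard = mean(df$lr_standard),
                 ghost_nom = mean(df$lr_ghost_nom),
                 ghost_rej = mean(df$lr_ghost_rej)),
       omnibus = omnibus, pairwise = pairwise, n = nrow(df))
}

#' Correlation between model-basedness and preferential MF learning
#'
#' Pearson correlation across participants between the fitted relative MB
#' contribution `w_mb` and the preferential learning-rate difference
#' `lr_ghost_nom - lr_ghost_rej`, with a one-sided permutation test in which
#' `w_mb` is shuffled across participants. The p-value is the proportion of
#' shuffles whose correlation is at least as large as the empirical one.
#'
#' @param fits as in [lr_comparison()].
#' @param n_perm number of random shuffles (ignored when `exact = TRUE`).
#' @param seed integer seed.
#' @param exact enumerate all permutations (participant count must be <= 8).
#' @return list with `r`, `p`, `n_perm` and `method`.
#' @export
wmb_lrdiff_correlation <- function(fits, n_perm = 10000L, seed = NULL,
                                   exact = FALSE) {
  df <- fits_to_df(fits)
  if (nrow(df) < 3L) stop("need at least 3 participants")
  w <- df$w_mb
  d <- df$lr_ghost_nom - df$lr_ghost_rej
  if (sd(w) == 0 || sd(d) == 0) stop("zero-variance inputs")
  r <- cor(w, d)
  if (exact) {
    if (nrow(df) > 8L) stop("exact enumeration limited to 8 participants")
    perms <- all_permutations(nrow(df))
    r_perm <- apply(perms, 1, function(idx) cor(w[idx], d))
    return(list(r = r, p = mean(r_perm >= r), n_perm = nrow(perms),
                method = "exact"))
  }
  local_seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(i) cor(sample(w), d), numeric(1))
  list(r = r, p = mean(r_perm >= r), n_perm = n_perm, method = "sampled")
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Parametric-bootstrap calibration of the model-basedness correlation
#'
#' The permutation test in [wmb_lrdiff_correlation()] destroys the increase
#' in learning-rate estimation noise with model-basedness, which could by
#' itself produce a spurious positive correlation. This control simulates
#' sessions from each participant's fitted non-inference model (in which the
#' preferential learning difference is zero by construction), refits the full
#' model to every synthetic session, and builds the null distribution of the
#' group correlation by repeatedly drawing one synthetic fit per participant.
#' The p-value is the proportion of null correlations larger than the
#' empirical one.
#'
#' @param sessions list of `ghost_session`s (supplies structures and trial
#'   geometry for resimulation).
#' @param non_inference_fits,full_fits per-participant [fit_participant()]
#'   results under the non-inference and full specs.
#' @param n_sessions_per_participant synthetic sessions per participant
#'   (study scale: 1000).
#' @param n_resample group resamples (study scale: 100,000).
#' @param options a [fit_options()] for the synthetic refits.
#' @param seed integer seed.
#' @param step_sd walk step SD for synthetic sessions.
#' @return list with `r_empirical`, `p`, `null_correlations` and
#'   `sim_estimates` (per-participant matrices of refitted `w_mb` and
#'   learning-rate differences).
#' @export
calibrated_null_correlation <- function(sessions, non_inference_fits,
                                        full_fits,
                                        n_sessions_per_participant = 1000L,
                                        n_resample = 100000L,
                                        options = fit_options(), seed = 1L,
                                        step_sd = 0.025) {
  n_part <- length(sessions)
  stopifnot(length(non_inference_fits) == n_part,
            length(full_fits) == n_part)
  emp <- fits_to_df(full_fits)
  r_emp <- cor(emp$w_mb, emp$lr_ghost_nom - emp$lr_ghost_rej)

  sim_w <- sim_d <- matrix(NA_real_, n_part, n_sessions_per_participant)
  for (i in seq_len(n_part)) {
    ni <- non_inference_fits[[i]]
    for (s in seq_len(n_sessions_per_participant)) {
      sb <- derive_seed(seed, i * 10000L + s, "nullcorr")
      sim <- resim_session(sessions[[i]], ni$params, ni$spec, sb, step_sd)
      o <- options; o$seed <- derive_seed(sb, 1L, "fit")
      o$init <- ni$params
      ff <- fit_participant(sim, full_fits[[i]]$spec, o)
      sim_w[i, s] <- ff$params[["w_mb"]]
      sim_d[i, s] <- ff$params[["lr_ghost_nom"]] - ff$params[["lr_ghost_rej"]]
    }
  }
  local_seed(derive_seed(seed, 0L, "resample"))
  null_r <- vapply(seq_len(n_resample), function(b) {
    pick <- sample.int(n_sessions_per_participant, n_part, replace = TRUE)
    idx <- cbind(seq_len(n_part), pick)
    cor(sim_w[idx], sim_d[idx])
  }, numeric(1))
  list(r_empirical = r_emp, p = mean(null_r > r_emp),
       null_correlations = null_r,
       sim_estimates = list(w_mb = sim_w, lr_diff = sim_d))
}

#' Narrowest interval holding a given mass, anchored at a value
#'
#' Scans contiguous windows of the sorted values covering `mass` of them and
#' returns the narrowest interval that also contains `anchor` (a window is
#' extended to the anchor when needed). Ties are broken toward minimal width,
#' then toward centering on the anchor.
#'
#' @param values numeric vector (e.g. bootstrap estimates).
#' @param anchor value the interval must contain (e.g. the empirical
#'   estimate).
#' @param mass fraction of the values to cover (default 0.5).
#' @return numeric `c(lower, upper)`.
#' @export
densest_interval <- function(values, anchor, mass = 0.5) {
  v <- sort(values)
  n <- length(v)
  k <- max(1L, ceiling(mass * n))
  best <- NULL
  for (i in seq_len(n - k + 1L)) {
    lo <- min(v[i], anchor)
    hi <- max(v[i + k - 1L], anchor)
    width <- hi - lo
    off <- abs((lo + hi) / 2 - anchor)
    if (is.null(best) || width < best$width - 1e-12 ||
        (abs(width - best$width) <= 1e-12 && off < best$off - 1e-12)) {
      best <- list(lo = lo, hi = hi, width = width, off = off)
    }
  }
  c(best$lo, best$hi)
}

#' Parametric-bootstrap interval for the preferential learning-rate difference
#'
#' Simulates `n_boot` sessions from a participant's fitted full model, refits
#' the full model to each, and summarizes the distribution of
#' `lr_ghost_nom - lr_ghost_rej` by the densest (narrowest) interval holding
#' 50% of its mass, conditional on containing the empirical difference.
#'
#' @param session the participant's `ghost_session`.
#' @param full_fit the participant's full-model [fit_participant()] result.
#' @param n_boot number of bootstrap sessions (study scale: 100; at least 4).
#' @param options a [fit_options()] for refits.
#' @param seed integer seed.
#' @param step_sd walk step SD for synthetic sessions.
#' @return list with `interval` (`c(lower, upper)`), `empirical` and the
#'   bootstrap `diffs`.
#' @export
bootstrap_lr_interval <- function(session, full_fit, n_boot = 100L,
                                  options = fit_options(), seed = 1L,
                                  step_sd = 0.025) {
  if (n_boot < 4L) stop("n_boot must be at least 4")
  emp <- full_fit$params[["lr_ghost_nom"]] - full_fit$params[["lr_ghost_rej"]]
  diffs <- vapply(seq_len(n_boot), function(b) {
    sb <- derive_seed(seed, b, "lrint")
    sim <- resim_session(session, full_fit$params, full_fit$spec, sb, step_sd)
    o <- options; o$seed <- derive_seed(sb, 1L, "fit")
    o$init <- full_fit$params
    ff <- fit_participant(sim, full_fit$spec, o)
    ff$params[["lr_ghost_nom"]] - ff$params[["lr_ghost_rej"]]
  }, numeric(1))
  list(interval = densest_interval(diffs, emp, 0.5), empirical = emp,
       diffs = diffs)
}
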