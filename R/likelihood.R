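FAMILY_CODES <- c(mb_room = 0L, mb_object = 1L,
                  elig_accumulating = 2L, elig_replacing = 3L)

# Flatten a session into the integer arrays consumed by the compiled
# likelihood. The ghost's nominee on uncertainty trials is re-inferred from
# the recorded second room (the fit never trusts a logged nominee column).
session_arrays <- function(session) {
  tr <- session$trials
  structure <- session$structure
  n <- nrow(tr)
  unc <- tr$type == "uncertainty"
  nominee <- rep(0L, n)
  idx <- which(unc & !tr$missing)
  if (length(idx)) {
    # vectorized form of infer_nomination(): the nominee is the chosen-pair
    # member whose room set contains the second opened room
    left <- tr$choice[idx] == 1L
    m1 <- ifelse(left, tr$o1[idx], tr$o3[idx])
    m2 <- ifelse(left, tr$o2[idx], tr$o4[idx])
    r2 <- tr$room_2[idx]
    opens <- structure$opens
    in1 <- r2 == opens[m1, 1] | r2 == opens[m1, 2]
    in2 <- r2 == opens[m2, 1] | r2 == opens[m2, 2]
    bad <- in1 == in2
    if (any(bad)) {
      stop("second room does not identify a unique nominee at trial(s) ",
           paste(head(idx[bad], 5L), collapse = ", "))
    }
    nominee[idx] <- as.integer(ifelse(in1, m1, m2))
  }
  na0 <- function(x) { x[is.na(x)] <- 0L; as.integer(x) }
  mat <- cbind(type = as.integer(unc),
               a1 = na0(tr$o1), a2 = na0(tr$o2),
               b1 = na0(tr$o3), b2 = na0(tr$o4),
               choice = na0(tr$choice), nominee = nominee,
               room1 = na0(tr$room_1), room2 = na0(tr$room_2),
               r1 = na0(tr$reward_1), r2 = na0(tr$reward_2),
               missing = as.integer(tr$missing))
  list(mat = mat, opens = structure$opens)
}

#' Negative log-likelihood of a session's choices
#'
#' Evolves the agent state along the observed trial sequence and accumulates
#' `-log Pr(observed choice)` over all non-missing trials — standard object
#' choices and uncertainty pair choices alike. Missing trials contribute no
#' likelihood term and trigger no learning update. Parameters are first
#' projected onto the spec's constraint surface, so e.g. a `pure_MB` model is
#' invariant to whatever MF learning rates the vector carries.
#'
#' @param params a [model_params()] vector.
#' @param spec a [model_spec()].
#' @param session a `ghost_session`.
#' @param engine `"cpp"` (compiled, used for fitting) or `"r"` (readable
#'   reference path built from the exported update operations). The two agree
#'   to near machine precision; tests enforce 1e-10.
#' @return the negative log-likelihood (finite for in-bounds `beta`).
#' @export
session_neg_loglik <- function(params, spec, session, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  params <- as_model_params(params)
  par_full <- constrain_params(params, spec)
  if (engine == "cpp") {
    arr <- session_arrays(session)
    return(nll_session_cpp(par_full, FAMILY_CODES[[spec$family]],
                           as.integer(spec$persev_after_ghost == "either"),
                           arr$mat, arr$opens))
  }
  nll_session_r(par_full, spec, session)
}

nll_session_r <- function(par_full, spec, session) {
  tr <- session$trials
  structure <- session$structure
  state <- init_state(spec)
  beta <- par_full[["beta"]]
  nll <- 0
  for (t in seq_len(nrow(tr))) {
    if (tr$missing[t]) next
    if (tr$type[t] == "uncertainty") {
      left <- c(tr$o1[t], tr$o2[t]); right <- c(tr$o3[t], tr$o4[t])
      vals <- net_values(state, spec, par_full, structure, list(left, right))
      chosen_i <- tr$choice[t]
      nll <- nll - log_choice_prob(vals[[chosen_i]]$v_net,
                                   vals[[3L - chosen_i]]$v_net, beta)
      pair <- if (chosen_i == 1L) left else right
      nom <- infer_nomination(structure, pair, tr$room_2[t])
      state <- advance_state(state, spec, par_full, structure, list(
        type = "uncertainty", chosen_pair = pair, nominated = nom,
        r1 = tr$reward_1[t], r2 = tr$reward_2[t],
        rooms = c(tr$room_1[t], tr$room_2[t])))
    } else {
      offer <- c(tr$o1[t], tr$o2[t])
      vals <- net_values(state, spec, par_full, structure,
                         list(offer[1], offer[2]))
      chosen_i <- tr$choice[t]
      nll <- nll - log_choice_prob(vals[[chosen_i]]$v_net,
                                   vals[[3L - chosen_i]]$v_net, beta)
      state <- advance_state(state, spec, par_full, structure, list(
        type = "standard", chosen = offer[chosen_i],
        r1 = tr$reward_1[t], r2 = tr$reward_2[t],
        rooms = c(tr$room_1[t], tr$room_2[t])))
    }
  }
  nll
}

#' Options controlling maximum-likelihood fitting
#'
#' @param n_starts number of random starting points (the study-scale default
#'   is 200; reduced presets are appropriate for bootstrap refits).
#' @param seed integer seed for the start draws.
#' @param init optional `model_params` used as the first (warm) start, e.g.
#'   the generating parameters of a bootstrap session.
#' @param maxit optimizer iteration cap per start.
#' @param factr `L-BFGS-B` convergence tolerance factor (times machine
#'   epsilon; 1e8 targets ~1e-8 relative change in the objective).
#' @return an object of class `fit_options`.
#' @export
fit_options <- function(n_starts = 200L, seed = NULL, init = NULL,
                        maxit = 200L, factr = 1e8) {
  stopifnot(n_starts >= 1L)
  out <- list(n_starts = as.integer(n_starts), seed = seed, init = init,
              maxit = as.integer(maxit), factr = factr)
  class(out) <- "fit_options"
  out
}

#' Fit a model to one session by multi-start maximum likelihood
#'
#' Runs bounded (`L-BFGS-B`) local optimizations of the choice
#' log-likelihood from `n_starts` uniform-random starting points within the
#' parameter bounds (see [param_bounds()]), retaining the best. Deterministic
#' given `options$seed`.
#'
#' @param session a `ghost_session`.
#' @param spec a [model_spec()].
#' @param options a [fit_options()].
#' @return an object of class `fit_result`: list with `spec`, `params` (the
#'   best-fitting full parameter vector), `neg_loglik`, `n_free_params`,
#'   `start_nlls` (final objective per start), `converged` and `participant`.
#' @export
fit_participant <- function(session, spec, options = fit_options()) {
  stopifnot(inherits(options, "fit_options"))
  cinfo <- apply_constraint(spec)
  bounds <- param_bounds()
  lower <- bounds$lower[cinfo$free]
  upper <- bounds$upper[cinfo$free]
  arr <- session_arrays(session)
  fam <- FAMILY_CODES[[spec$family]]
  pe <- as.integer(spec$persev_after_ghost == "either")
  # integer index bookkeeping keeps the per-evaluation overhead small
  template <- expand_params(rep(0, length(cinfo$free)), cinfo)
  free_idx <- match(cinfo$free, PARAM_NAMES)
  tie_to <- match(names(cinfo$ties), PARAM_NAMES)
  tie_from <- match(unname(cinfo$ties), PARAM_NAMES)
  mat <- arr$mat
  opens <- arr$opens
  objective <- function(free_values) {
    p <- template
    p[free_idx] <- free_values
    if (length(tie_to)) p[tie_to] <- p[tie_from]
    nll_session_cpp(p, fam, pe, mat, opens)
  }

  local_seed(options$seed)
  k <- length(cinfo$free)
  starts <- matrix(runif(options$n_starts * k, rep(lower, each = options$n_starts),
                         rep(upper, each = options$n_starts)),
                   options$n_starts, k)
  if (!is.null(options$init)) {
    warm <- constrain_params(as_model_params(options$init), spec)[cinfo$free]
    starts[1, ] <- pmin(pmax(warm, lower), upper)
  }

  best <- NULL
  start_nlls <- rep(NA_real_, options$n_starts)
  any_conv <- FALSE
  for (s in seq_len(options$n_starts)) {
    res <- tryCatch(
      optim(starts[s, ], objective, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = options$maxit, factr = options$factr)),
      error = function(e) NULL)
    if (is.null(res)) next
    start_nlls[s] <- res$value
    if (res$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("optimizer failed on all ", options$n_starts, " starts for participant ",
         session$participant)
  }
  params <- expand_params(best$par, cinfo)
  class(params) <- "model_params"
  out <- list(spec = spec, params = params, neg_loglik = best$value,
              n_free_params = k, start_nlls = start_nlls,
              converged = any_conv, participant = session$participant)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s/%s) participant %s: -logL = %.3f, %d free params\n",
              x$spec$family, x$spec$constraint, x$participant,
              x$neg_loglik, x$n_free_params))
  free <- apply_constraint(x$spec)$free
  print(round(unclass(x$params)[free], 4))
  invisible(x)
}
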