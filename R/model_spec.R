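PARAM_NAMES <- c("w_mb", "beta", "persev", "lr_mb", "lr_standard",
                 "lr_ghost_nom", "lr_ghost_rej", "lam", "lr_mf")

FAMILIES <- c("mb_room", "mb_object", "elig_accumulating", "elig_replacing")
CONSTRAINTS <- c("full", "pure_MB", "pure_MF_action", "non_inference",
                 "no_ghost_rej", "none")

#' Specify a learning model
#'
#' A model specification names the family (which model-based system operates,
#' or which eligibility-trace pure model-free variant) and the nested
#' constraint applied to the hybrid parameter set.
#'
#' Families:
#' \describe{
#'   \item{mb_room}{hybrid; the MB system caches room values and evaluates
#'     objects prospectively as the sum of their two rooms' values.}
#'   \item{mb_object}{hybrid; the MB system caches object values and uses the
#'     transition structure at learning time (full update for the executed
#'     object, half updates for the two single-room sharers).}
#'   \item{elig_accumulating, elig_replacing}{pure MF with eligibility traces;
#'     the MB choice contribution is silenced (`w_mb = 0`, no `lr_mb`) and a
#'     single MF learning rate `lr_mf` plus decay `lam` operate.}
#' }
#'
#' Constraints (hybrid families): `pure_MB` fixes `w_mb = 1` and all three MF
#' learning rates to 0; `pure_MF_action` fixes `w_mb = 0` and `lr_mb = 0`
#' (model-based inference of the nominee still guides MF learning);
#' `non_inference` ties `lr_ghost_nom = lr_ghost_rej`; `no_ghost_rej` fixes
#' `lr_ghost_rej = 0`; `full`/`none` leave all 7 parameters free.
#'
#' @param family model family.
#' @param constraint nested sub-model constraint.
#' @param persev_after_ghost which object counts as "last chosen" for the
#'   perseverance bonus on the trial after an uncertainty trial: the ghost's
#'   `"nominee"` (default) or `"either"` chosen-pair member.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = "mb_room", constraint = "full",
                       persev_after_ghost = c("nominee", "either")) {
  family <- match.arg(family, FAMILIES)
  constraint <- match.arg(constraint, CONSTRAINTS)
  if (grepl("^elig", family) && !constraint %in% c("full", "none")) {
    stop("eligibility-trace families take no nested constraint")
  }
  out <- list(family = family, constraint = constraint,
              persev_after_ghost = match.arg(persev_after_ghost))
  class(out) <- "model_spec"
  out
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec: family = %s, constraint = %s\n", x$family, x$constraint))
  invisible(x)
}

#' Construct a full parameter vector
#'
#' Parameters: `w_mb` (relative MB contribution, in `[0,1]`), `beta` (softmax
#' inverse temperature, > 0), `persev` (perseverance bonus for the previously
#' selected option), `lr_mb` (MB learning rate), `lr_standard`,
#' `lr_ghost_nom`, `lr_ghost_rej` (MF learning rates for standard trials and
#' for the ghost-nominated/-rejected objects on uncertainty trials), `lam`
#' (eligibility decay) and `lr_mf` (eligibility-family MF rate). Parameters
#' irrelevant to a family are carried but ignored.
#'
#' @param w_mb,beta,persev,lr_mb,lr_standard,lr_ghost_nom,lr_ghost_rej,lam,lr_mf
#'   numeric scalars; see Description.
#' @return a named numeric vector of class `model_params`.
#' @export
model_params <- function(w_mb = 0.5, beta = 5, persev = 0.2, lr_mb = 0.35,
                         lr_standard = 0.4, lr_ghost_nom = 0.5,
                         lr_ghost_rej = 0.1, lam = 0.5, lr_mf = 0.4) {
  p <- c(w_mb = w_mb, beta = beta, persev = persev, lr_mb = lr_mb,
         lr_standard = lr_standard, lr_ghost_nom = lr_ghost_nom,
         lr_ghost_rej = lr_ghost_rej, lam = lam, lr_mf = lr_mf)
  rate_names <- setdiff(PARAM_NAMES, c("beta", "persev"))
  if (any(p[rate_names] < 0 | p[rate_names] > 1)) {
    stop("rates, w_mb and lam must lie in [0, 1]")
  }
  if (beta <= 0) stop("beta must be positive")
  class(p) <- "model_params"
  p
}

as_model_params <- function(p) {
  if (inherits(p, "model_params")) return(p)
  stopifnot(all(PARAM_NAMES %in% names(p)))
  do.call(model_params, as.list(unclass(p)[PARAM_NAMES]))
}

#' Resolve a nested constraint into fixed, free and tied parameters
#'
#' @param spec a [model_spec()].
#' @return list with `free` (character vector of free parameter names, in a
#'   stable order), `fixed` (named numeric of pinned values) and `ties`
#'   (named character; `ties[a] = b` means parameter `a` copies free
#'   parameter `b`).
#' @export
apply_constraint <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (grepl("^elig", spec$family)) {
    return(list(free = c("beta", "persev", "lr_mf", "lam"),
                fixed = c(w_mb = 0, lr_mb = 0, lr_standard = 0,
                          lr_ghost_nom = 0, lr_ghost_rej = 0),
                ties = character(0)))
  }
  base_free <- c("w_mb", "beta", "persev", "lr_mb", "lr_standard",
                 "lr_ghost_nom", "lr_ghost_rej")
  fixed <- c(lam = 0, lr_mf = 0)   # inert in hybrid families
  ties <- character(0)
  switch(spec$constraint,
    full = , none = NULL,
    pure_MB = {
      fixed <- c(fixed, w_mb = 1, lr_standard = 0, lr_ghost_nom = 0,
                 lr_ghost_rej = 0)
    },
    pure_MF_action = {
      fixed <- c(fixed, w_mb = 0, lr_mb = 0)
    },
    non_inference = {
      ties <- c(lr_ghost_rej = "lr_ghost_nom")
    },
    no_ghost_rej = {
      fixed <- c(fixed, lr_ghost_rej = 0)
    }
  )
  free <- setdiff(base_free, c(names(fixed), names(ties)))
  list(free = free, fixed = fixed, ties = ties)
}

#' Default parameter bounds for fitting
#'
#' Learning rates, `w_mb` and `lam` are bounded to `[0, 1]`; `beta` to
#' `[1e-3, 20]`; `persev` to `[-5, 5]`. These cover the behaviorally
#' plausible range without flat-likelihood plateaus at the extremes.
#'
#' @return list with numeric vectors `lower` and `upper` named by parameter.
#' @export
param_bounds <- function() {
  lower <- c(w_mb = 0, beta = 1e-3, persev = -5, lr_mb = 0, lr_standard = 0,
             lr_ghost_nom = 0, lr_ghost_rej = 0, lam = 0, lr_mf = 0)
  upper <- c(w_mb = 1, beta = 20, persev = 5, lr_mb = 1, lr_standard = 1,
             lr_ghost_nom = 1, lr_ghost_rej = 1, lam = 1, lr_mf = 1)
  list(lower = lower, upper = upper)
}

# Expand a free-parameter vector into a full 9-parameter vector.
expand_params <- function(free_values, cinfo) {
  p <- setNames(numeric(length(PARAM_NAMES)), PARAM_NAMES)
  p[cinfo$free] <- free_values
  if (length(cinfo$fixed)) p[names(cinfo$fixed)] <- cinfo$fixed
  if (length(cinfo$ties)) p[names(cinfo$ties)] <- p[unname(cinfo$ties)]
  p
}

# Project a full parameter vector onto the constraint surface (used for warm
# starts and for evaluating a constrained likelihood at given params).
constrain_params <- function(params, spec) {
  cinfo <- apply_constraint(spec)
  expand_params(unclass(params)[cinfo$free], cinfo)
}

#' Draw heterogeneous generating parameters for a synthetic cohort
#'
#' Participant-level parameters are drawn uniformly from ranges chosen to
#' emulate a behaviorally plausible cohort: mixed MB/MF reliance
#' (`w_mb` in `[0.2, 0.8]`), moderately deterministic choice
#' (`beta` in `[3, 8]`), mild perseverance, intermediate learning rates, and
#' preferential credit assignment to the ghost-nominated object
#' (`lr_ghost_nom` about 0.5 vs `lr_ghost_rej` about 0.1).
#'
#' @param n number of participants.
#' @param seed integer seed or `NULL`.
#' @param ranges named list of length-2 numeric ranges overriding the
#'   defaults (a degenerate range pins the parameter).
#' @return list of `model_params`, one per participant.
#' @export
sample_cohort_params <- function(n, seed = NULL, ranges = list()) {
  local_seed(seed)
  defaults <- list(
    w_mb = c(0.2, 0.8), beta = c(3, 8), persev = c(0, 0.3),
    lr_mb = c(0.2, 0.5), lr_standard = c(0.3, 0.6),
    lr_ghost_nom = c(0.5, 0.5), lr_ghost_rej = c(0.1, 0.1),
    lam = c(0.3, 0.7), lr_mf = c(0.3, 0.6)
  )
  defaults[names(ranges)] <- ranges
  lapply(seq_len(n), function(i) {
    vals <- lapply(defaults, function(r) runif(1, r[1], r[2]))
    do.call(model_params, vals)
  })
}
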