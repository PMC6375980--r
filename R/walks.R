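#' Generate the drifting room reward probabilities
#'
#' Four independent Gaussian-increment random walks with reflecting boundaries
#' at 0 and 1 govern the per-room reward probabilities across trials. The
#' per-trial increment standard deviation defaults to 0.025. Reflection is an
#' iterated fold (`x > 1 -> 2 - x`, `x < 0 -> -x`) so that arbitrarily large
#' configured step sizes still land inside the unit interval. Initial
#' probabilities are drawn uniformly from `init_range` (default
#' `[0.25, 0.75]`), keeping early trials informative and away from the
#' boundaries; pass `init` to pin them.
#'
#' @param n_trials number of trials (rows), at least 1.
#' @param step_sd standard deviation of the raw Gaussian increments
#'   (probability per trial). Must be non-negative; `0` freezes the walks.
#' @param seed integer seed or `NULL`.
#' @param init_range length-2 numeric range for the uniform initial draw.
#' @param init optional numeric vector of 4 starting probabilities,
#'   overriding `init_range`.
#' @return an object of class `reward_walks`: list with `probs`
#'   (`n_trials` x 4 matrix in `[0, 1]`), `increments` (the raw pre-reflection
#'   Gaussian steps, `(n_trials - 1)` x 4), `step_sd` and `seed`.
#' @export
generate_walks <- function(n_trials, step_sd = 0.025, seed = NULL,
                           init_range = c(0.25, 0.75), init = NULL) {
  if (!is.numeric(n_trials) || n_trials < 1) stop("n_trials must be >= 1")
  if (!is.numeric(step_sd) || step_sd < 0) stop("step_sd must be non-negative")
  n_trials <- as.integer(n_trials)
  local_seed(seed)
  start <- if (!is.null(init)) {
    stopifnot(length(init) == 4L, all(init >= 0 & init <= 1))
    init
  } else {
    runif(4, init_range[1], init_range[2])
  }
  probs <- matrix(NA_real_, n_trials, 4)
  probs[1, ] <- start
  increments <- matrix(numeric(0), 0, 4)
  if (n_trials > 1) {
    increments <- matrix(rnorm((n_trials - 1) * 4, 0, step_sd), n_trials - 1, 4)
    for (t in 2:n_trials) {
      probs[t, ] <- fold_reflect(probs[t - 1, ] + increments[t - 1, ])
    }
  }
  out <- list(probs = probs, increments = increments,
              step_sd = step_sd, seed = seed)
  class(out) <- "reward_walks"
  out
}

#' @export
print.reward_walks <- function(x, ...) {
  cat(sprintf("Reward walks: %d trials x 4 rooms, step SD %.4g\n",
              nrow(x$probs), x$step_sd))
  invisible(x)
}
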