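# Single decisions and Monte-Carlo choice probabilities.
#
# Both simulation paths (the compiled core and the pure-R mirror) implement
# the same dynamics and consume the same RNG stream: one uniform per step to
# pick the sampled attribute, plus one uniform only when several preference
# nodes cross the threshold on the same step.

# Weighted sublayer equilibria for the considered alternatives (n x M).
weighted_alpha <- function(choice_set, params, alpha = NULL, warn = TRUE) {
  if (is.null(alpha)) {
    alpha <- attribute_equilibria(choice_set, params, warn = warn)$alpha
  }
  cons <- which(choice_set$available)
  aw <- alpha[cons, , drop = FALSE]
  sweep(aw, 2L, choice_set$weights, `*`)
}

# Pure-R mirror of sim_choices_cpp for a single decision, optionally
# recording the preference trajectory and the sampled attributes.
sim_one_r <- function(aw, s_P, l_P, Q, T_max, cum_probs, record = FALSE) {
  n <- nrow(aw)
  M <- ncol(aw)
  x <- numeric(n)
  traj <- if (record) vector("list", 0L) else NULL
  attrs <- if (record) integer(0L) else NULL
  chosen <- NA_integer_
  t_done <- T_max
  for (t in seq_len(T_max)) {
    u <- runif(1)
    j <- min(findInterval(u, cum_probs) + 1L, M)
    total <- sum(x)
    v <- s_P * x - l_P * (total - x) + aw[, j]
    x_new <- pmin(1, pmax(0, v))
    if (record) {
      traj[[t]] <- x_new
      attrs[t] <- j
    }
    crossers <- which(x_new >= Q)
    if (length(crossers)) {
      pick <- crossers[1L]
      if (length(crossers) > 1L) {
        idx <- as.integer(runif(1) * length(crossers)) + 1L
        pick <- crossers[min(idx, length(crossers))]
      }
      chosen <- pick
      t_done <- t
      break
    }
    x <- x_new
  }
  list(chosen = chosen, time = t_done,
       trajectory = if (record) do.call(rbind, traj) else NULL,
       sampled_attributes = attrs)
}

#' Simulate a single decision
#'
#' Runs one threshold-terminated decision: preference nodes of the
#' considered alternatives start at zero; each step one attribute sublayer
#' is sampled at random and its weighted equilibrium activations feed the
#' preference layer, which updates with self-feedback `s_P`, lateral
#' inhibition `l_P` and the bounded activation function. The first
#' alternative whose preference reaches `Q` (inclusive) is chosen;
#' simultaneous crossings are broken uniformly at random; a decision still
#' running after `T_max` samples is censored.
#'
#' @param choice_set a [choice_set()].
#' @param params a [network_params()].
#' @param record record the preference trajectory and sampled attributes.
#' @param alpha optional precomputed equilibrium matrix from
#'   [attribute_equilibria()] (they are constant within a decision, so
#'   callers running many decisions on one set should compute them once).
#' @return an object of class `decision_outcome`: `chosen` (alternative
#'   index, `NA` if censored), `censored`, `decision_time` (number of
#'   attribute samples), and when `record = TRUE` the `trajectory` (steps x
#'   considered alternatives) and `sampled_attributes`.
#' @examples
#' cs <- choice_set(rbind(c(0.8, 0.2), c(0.4, 0.9)), weights = c(0.03, 0.015))
#' p <- heuristic_preset("LEX", weights = c(0.03, 0.015))$params
#' set.seed(1)
#' simulate_decision(cs, p)
#' @export
simulate_decision <- function(choice_set, params, record = FALSE,
                              alpha = NULL) {
  stopifnot(inherits(choice_set, "choice_set"),
            inherits(params, "network_params"))
  ap <- expand_attr_params(params, choice_set$n_attributes)
  aw <- weighted_alpha(choice_set, params, alpha)
  res <- sim_one_r(aw, params$s_P, params$l_P, params$Q, params$T_max,
                   cumsum(ap$sampling_probs), record = record)
  cons <- which(choice_set$available)
  chosen <- if (is.na(res$chosen)) NA_integer_ else cons[res$chosen]
  structure(
    list(chosen = chosen, censored = is.na(chosen),
         decision_time = res$time, trajectory = res$trajectory,
         sampled_attributes = res$sampled_attributes),
    class = "decision_outcome"
  )
}

#' @export
print.decision_outcome <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Decision censored after %d attribute samples\n",
                x$decision_time))
  } else {
    cat(sprintf("Chose alternative %d after %d attribute sample(s)\n",
                x$chosen, x$decision_time))
  }
  invisible(x)
}

#' Monte-Carlo choice probabilities
#'
#' Estimates per-alternative choice probabilities and the mean decision time
#' from `n_reps` independent simulated decisions. Censored decisions are
#' resolved by a uniform random choice among the considered alternatives
#' (keeping the probability vector normalized); the censoring rate is
#' reported.
#'
#' @param choice_set a [choice_set()].
#' @param params a [network_params()].
#' @param n_reps number of simulated decisions (>= 1).
#' @param method `"compiled"` (default) runs the Rcpp core; `"r"` runs the
#'   pure-R mirror, which consumes an identical RNG stream and exists mainly
#'   for cross-checking.
#' @param alpha optional precomputed equilibrium matrix.
#' @param warn warn on non-converged sublayers.
#' @return an object of class `choice_probabilities`: `prob` (length
#'   `n_alternatives`, summing to 1, zero for unavailable alternatives),
#'   `mean_decision_time`, `censor_rate`, `n_reps`.
#' @examples
#' cs <- choice_set(rbind(c(0.8, 0.2), c(0.4, 0.9)), weights = c(0.03, 0.015))
#' p <- heuristic_preset("WAD", weights = c(0.03, 0.015))$params
#' set.seed(1)
#' estimate_choice_probabilities(cs, p, n_reps = 500)
#' @export
estimate_choice_probabilities <- function(choice_set, params, n_reps,
                                          method = c("compiled", "r"),
                                          alpha = NULL, warn = TRUE) {
  stopifnot(inherits(choice_set, "choice_set"),
            inherits(params, "network_params"))
  method <- match.arg(method)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  ap <- expand_attr_params(params, choice_set$n_attributes)
  aw <- weighted_alpha(choice_set, params, alpha, warn = warn)
  cum <- cumsum(ap$sampling_probs)
  if (method == "compiled") {
    res <- sim_choices_cpp(aw, params$s_P, params$l_P, params$Q,
                           params$T_max, cum, n_reps)
  } else {
    chosen <- integer(n_reps)
    dtime <- integer(n_reps)
    for (r in seq_len(n_reps)) {
      one <- sim_one_r(aw, params$s_P, params$l_P, params$Q, params$T_max, cum)
      chosen[r] <- one$chosen
      dtime[r] <- one$time
    }
    res <- list(chosen = chosen, time = dtime)
  }
  n <- nrow(aw)
  chosen <- res$chosen
  cens <- is.na(chosen)
  if (any(cens)) {
    u <- runif(sum(cens))
    chosen[cens] <- pmin(as.integer(u * n) + 1L, n)
  }
  cons <- which(choice_set$available)
  counts <- tabulate(chosen, nbins = n)
  prob <- numeric(choice_set$n_alternatives)
  prob[cons] <- counts / n_reps
  structure(
    list(prob = prob, mean_decision_time = mean(res$time),
         censor_rate = mean(cens), n_reps = n_reps),
    class = "choice_probabilities"
  )
}

#' @export
print.choice_probabilities <- function(x, ...) {
  cat(sprintf("Choice probabilities (%d simulated decisions)\n", x$n_reps))
  print(round(stats::setNames(x$prob, paste0("alt_", seq_along(x$prob))), 4))
  cat(sprintf("mean decision time: %.2f samples; censoring rate: %.4f\n",
              x$mean_decision_time, x$censor_rate))
  invisible(x)
}

# Modal choice of a probability vector; strict ties give NA.
modal_choice <- function(prob) {
  m <- max(prob)
  idx <- which(prob == m)
  if (length(idx) == 1L) idx else NA_integer_
}
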