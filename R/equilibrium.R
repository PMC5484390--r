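# Attribute sublayers operate on a much faster timescale than attribute
# sampling, so only their stable equilibrium activations matter. We obtain
# them by synchronous fixed-point iteration of the layer update from the
# all-zero state (all nodes are off before the decision starts), with the
# external inputs held constant.

# Fast internal iteration. Synchronous updates with strong inhibition can
# settle into an exact period-2 cycle instead of a fixed point; we detect
# that (state equal to the state two steps back) and stop early, reporting
# non-convergence with the final state.
equilibrium_iterate <- function(inputs, s, l, tol = 1e-10, max_iter = 10000L) {
  state <- numeric(length(inputs))
  prev2 <- state
  iter <- 0L
  residual <- Inf
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    total <- sum(state)
    new <- pmin(1, pmax(0, s * state - l * (total - state) + inputs))
    residual <- max(abs(new - state))
    if (residual < tol) {
      state <- new
      converged <- TRUE
      break
    }
    if (iter >= 2L && max(abs(new - prev2)) < tol) {
      state <- new  # period-2 limit cycle
      break
    }
    if (iter >= max_iter) {
      state <- new
      break
    }
    prev2 <- state
    state <- new
  }
  list(alpha = state, converged = converged, iterations = iter,
       residual = residual)
}

#' Equilibrium activation of one attribute sublayer
#'
#' Iterates the synchronous layer update from the all-zero state, with
#' constant inputs equal to the considered alternatives' values on the given
#' attribute (zero for unavailable alternatives), until the largest absolute
#' update falls below `tol` or `max_iter` is reached. Non-convergence --
#' including exact period-2 limit cycles, which synchronous updates can
#' produce under strong inhibition -- is reported in the returned profile,
#' never raised as an error.
#'
#' @param choice_set a [choice_set()].
#' @param attribute attribute (column) index.
#' @param s,l sublayer self-feedback and lateral inhibition.
#' @param tol convergence tolerance on the max absolute update.
#' @param max_iter iteration cap.
#' @return an object of class `equilibrium_profile`: `alpha` (stable
#'   activations, length `n_alternatives`), `converged`, `iterations`,
#'   `residual`, and the constant `inputs` used.
#' @examples
#' cs <- choice_set(matrix(c(0.75, 0.5, 0.25), ncol = 1), weights = 1)
#' sublayer_equilibrium(cs, 1, s = 0.5, l = 0.7)$alpha  # winner-take-all
#' @export
sublayer_equilibrium <- function(choice_set, attribute, s, l,
                                 tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(choice_set, "choice_set"))
  attribute <- as.integer(attribute)
  if (attribute < 1L || attribute > choice_set$n_attributes) {
    stop("`attribute` out of range", call. = FALSE)
  }
  if (tol <= 0 || max_iter < 1L) stop("`tol` must be > 0 and `max_iter` >= 1",
                                      call. = FALSE)
  inputs <- choice_set$values[, attribute]
  inputs[!choice_set$available] <- 0
  res <- equilibrium_iterate(inputs, s, l, tol, max_iter)
  structure(c(res, list(inputs = inputs, attribute = attribute, s = s, l = l)),
            class = "equilibrium_profile")
}

#' @export
print.equilibrium_profile <- function(x, ...) {
  cat(sprintf("Sublayer equilibrium (s = %g, l = %g): %s after %d iteration(s), residual %.3g\n",
              x$s, x$l, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  cat("  inputs:", paste(format(x$inputs, digits = 4), collapse = ", "), "\n")
  cat("  alpha: ", paste(format(x$alpha, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Equilibrium activations of all attribute sublayers
#'
#' Computes [sublayer_equilibrium()] for every attribute under the
#' per-attribute parameters in `params`. The result is what the preference
#' layer sees each time an attribute is sampled (the equilibria are constant
#' within a decision, so they are computed once and reused).
#'
#' @param choice_set a [choice_set()].
#' @param params a [network_params()].
#' @param tol,max_iter passed to the fixed-point iteration.
#' @param warn warn if any sublayer failed to converge.
#' @return list with `alpha` (`n_alternatives` x `n_attributes` matrix) and
#'   `converged` (logical per attribute).
#' @export
attribute_equilibria <- function(choice_set, params, tol = 1e-10,
                                 max_iter = 10000L, warn = TRUE) {
  stopifnot(inherits(choice_set, "choice_set"),
            inherits(params, "network_params"))
  M <- choice_set$n_attributes
  ap <- expand_attr_params(params, M)
  alpha <- matrix(0, choice_set$n_alternatives, M)
  converged <- logical(M)
  for (j in seq_len(M)) {
    prof <- sublayer_equilibrium(choice_set, j, ap$s_A[j], ap$l_A[j],
                                 tol = tol, max_iter = max_iter)
    alpha[, j] <- prof$alpha
    converged[j] <- prof$converged
  }
  if (warn && !all(converged)) {
    warning(sprintf("%d attribute sublayer(s) did not reach a stable equilibrium; using final states",
                    sum(!converged)), call. = FALSE)
  }
  list(alpha = alpha, converged = converged)
}

#' Closed-form normalization coefficients of an interior equilibrium
#'
#' When no node is saturated at 0 or 1, the sublayer equilibrium is linear in
#' the inputs: `alpha_i = omega1 * x_i - omega2 * sum(x_k, k != i)`. Solving
#' the linear fixed point for `n` interacting nodes gives
#' `omega1 = (1 - l / (1 - s + (n-1) l)) / (1 - s - l)` and
#' `omega2 = l / ((1 - s - l) (1 - s + (n-1) l))`. This is the regime in
#' which the sublayer normalizes each alternative's value against the rest
#' of the choice set.
#'
#' @param s,l sublayer self-feedback and inhibition (interior regime requires
#'   `s + l < 1`).
#' @param n number of interacting (considered) nodes.
#' @return named numeric vector `c(omega1, omega2)`.
#' @export
transform_omega <- function(s, l, n) {
  stopifnot(n >= 1)
  denom <- 1 - s - l
  if (denom <= 0) stop("interior equilibrium requires s + l < 1", call. = FALSE)
  d2 <- 1 - s + (n - 1) * l
  c(omega1 = (1 - l / d2) / denom, omega2 = l / (denom * d2))
}
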