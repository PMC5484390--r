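#' Network parameters for both layers
#'
#' Bundles the recurrent parameters of the preference accumulation layer
#' (self-feedback `s_P`, lateral inhibition `l_P`), the per-attribute
#' sublayer parameters (`s_A`, `l_A`; scalars are recycled across
#' attributes), the acceptance threshold `Q`, the censoring horizon `T_max`
#' (maximum number of attribute samples per decision), and the attribute
#' sampling distribution.
#'
#' Because every preference node also runs through the bounded activation
#' function, accumulated preference cannot exceed 1, so `Q` must lie in
#' (0, 1].
#'
#' @param s_P preference-layer self-feedback (>= 0); 0 means each sample is
#'   evaluated on its own, 1 means perfect memory.
#' @param l_P preference-layer lateral inhibition (>= 0).
#' @param s_A sublayer self-feedback, scalar or vector of length
#'   `n_attributes`.
#' @param l_A sublayer lateral inhibition, scalar or vector.
#' @param Q acceptance threshold in (0, 1].
#' @param T_max censoring horizon in attribute samples (>= 1).
#' @param sampling_probs probability of sampling each attribute; default
#'   uniform. Must be positive and sum to 1.
#' @return an object of class `network_params`.
#' @examples
#' network_params(s_P = 1, l_P = 0, s_A = 1, l_A = 1, Q = 0.99)
#' @export
network_params <- function(s_P, l_P, s_A, l_A, Q, T_max = 10000L,
                           sampling_probs = NULL) {
  stopifnot(is.numeric(s_P), length(s_P) == 1L, is.finite(s_P), s_P >= 0,
            is.numeric(l_P), length(l_P) == 1L, is.finite(l_P), l_P >= 0,
            is.numeric(s_A), all(is.finite(s_A)), all(s_A >= 0),
            is.numeric(l_A), all(is.finite(l_A)), all(l_A >= 0))
  if (!is.numeric(Q) || length(Q) != 1L || !is.finite(Q) || Q <= 0 || Q > 1) {
    stop("`Q` must lie in (0, 1]", call. = FALSE)
  }
  T_max <- as.integer(T_max)
  if (is.na(T_max) || T_max < 1L) stop("`T_max` must be >= 1", call. = FALSE)
  if (!is.null(sampling_probs)) {
    sampling_probs <- as.numeric(sampling_probs)
    if (any(sampling_probs <= 0) ||
        abs(sum(sampling_probs) - 1) > 1e-12) {
      stop("`sampling_probs` must be positive and sum to 1", call. = FALSE)
    }
  }
  structure(
    list(s_P = s_P, l_P = l_P, s_A = as.numeric(s_A), l_A = as.numeric(l_A),
         Q = Q, T_max = T_max, sampling_probs = sampling_probs),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat("Accumulator network parameters\n")
  cat(sprintf("  preference layer: s_P = %g, l_P = %g, Q = %g, T_max = %d\n",
              x$s_P, x$l_P, x$Q, x$T_max))
  cat(sprintf("  attribute sublayers: s_A = %s, l_A = %s\n",
              paste(format(x$s_A), collapse = ", "),
              paste(format(x$l_A), collapse = ", ")))
  if (!is.null(x$sampling_probs)) {
    cat("  sampling probs:", paste(format(x$sampling_probs), collapse = ", "), "\n")
  } else {
    cat("  sampling probs: uniform\n")
  }
  invisible(x)
}

# Recycle per-attribute parameter vectors to length M, with validation.
expand_attr_params <- function(params, n_attributes) {
  s_A <- params$s_A
  l_A <- params$l_A
  if (length(s_A) == 1L) s_A <- rep(s_A, n_attributes)
  if (length(l_A) == 1L) l_A <- rep(l_A, n_attributes)
  if (length(s_A) != n_attributes || length(l_A) != n_attributes) {
    stop("`s_A` and `l_A` must be scalars or have one entry per attribute",
         call. = FALSE)
  }
  probs <- params$sampling_probs
  if (is.null(probs)) probs <- rep(1 / n_attributes, n_attributes)
  if (length(probs) != n_attributes) {
    stop("`sampling_probs` must have one entry per attribute", call. = FALSE)
  }
  list(s_A = s_A, l_A = l_A, sampling_probs = probs)
}
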