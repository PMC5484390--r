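#' Piecewise-linear activation function
#'
#' Activation function shared by every node in the network: linear with unit
#' slope on \[0, 1\] and hard-bounded outside, so activations can saturate at
#' exactly 0 or 1.
#'
#' @param y numeric vector of net inputs; must be finite.
#' @return numeric vector of the same length with values in \[0, 1\].
#' @examples
#' piecewise_linear(c(-0.2, 0.3, 1.5))
#' @export
piecewise_linear <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y))) {
    stop("`y` must be a finite numeric vector", call. = FALSE)
  }
  pmin(1, pmax(0, y))
}

#' One synchronous update of a leaky competitive layer
#'
#' Every node receives self-feedback `s` times its own previous activation,
#' lateral inhibition `l` times the summed previous activation of all other
#' nodes, plus its external input, and the result is passed through
#' [piecewise_linear()]. All nodes update simultaneously.
#'
#' @param state numeric vector of current activations, each in \[0, 1\].
#' @param inputs numeric vector of external inputs, same length as `state`.
#' @param s self-feedback weight (scalar, >= 0).
#' @param l lateral inhibition weight (scalar, >= 0).
#' @return numeric vector of updated activations.
#' @examples
#' layer_step(c(0.75, 0.5, 0.25), c(0.75, 0.5, 0.25), s = 0.5, l = 0.7)
#' @export
layer_step <- function(state, inputs, s, l) {
  if (length(state) != length(inputs)) {
    stop("`state` and `inputs` must have the same length", call. = FALSE)
  }
  if (any(state < 0 | state > 1)) {
    stop("`state` entries must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(is.numeric(s), length(s) == 1L, is.numeric(l), length(l) == 1L)
  total <- sum(state)
  piecewise_linear(s * state - l * (total - state) + inputs)
}
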