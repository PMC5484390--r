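# Heuristic presets (network parameterizations that mimic classic choice
# rules) and the idealized symbolic versions of those rules, used as ground
# truth in the identification study.

HEURISTIC_NAMES <- c("LEX", "CONF", "K_CONF", "WP", "MCD", "EW", "WAD",
                     "ITW", "K_MCD")
EQUAL_WEIGHT_RULES <- c("CONF", "K_CONF", "MCD", "EW", "K_MCD")
ORDINAL_RULES <- c("LEX", "CONF", "K_CONF", "WP", "MCD")

#' Network parameter preset mimicking a heuristic choice rule
#'
#' Returns the network parameterization under which the accumulator mimics a
#' given rule:
#' \describe{
#'   \item{LEX}{`s_P = l_P = 0`, `Q = max(w)`, identify-best sublayers: only
#'     the top-weighted attribute's winner can reach the threshold.}
#'   \item{CONF / K_CONF}{`s_P = 1`, equal weights `w < 1/k`, `Q = k w`
#'     (`k = 2` for CONF): the first alternative best on `k` sampled
#'     attributes crosses.}
#'   \item{WP / MCD}{`s_P = 1`, high `Q`, identify-best sublayers;
#'     proportional weights for WP, equal for MCD (tallying).}
#'   \item{EW / WAD}{`s_A = l_A = 0` (identity sublayers), `s_P = 1`, high
#'     `Q`; equal weights for EW, proportional for WAD.}
#'   \item{ITW}{identify-worst sublayers (found by grid search for the given
#'     choice set), `s_P = 1`, high `Q`: accumulates values of everything
#'     but each attribute's worst alternative.}
#'   \item{K_MCD}{identify-k-best sublayers, equal weights, high `Q`.}
#' }
#' Ordinal rules default to `s_A = l_A = 1` on every sublayer (the values
#' used in the identification study); when a `choice_set` is supplied the
#' preset verifies that those values actually yield an identify-best
#' equilibrium for each attribute and falls back to
#' [find_params_for_transform()] otherwise. ITW and K_MCD always require a
#' `choice_set` because their sublayer parameters depend on the attribute
#' values.
#'
#' @param name heuristic name (see above).
#' @param weights attribute weights; rules marked "equal" reject unequal
#'   weights.
#' @param choice_set optional [choice_set()] used to tailor/verify sublayer
#'   parameters.
#' @param Q_high acceptance threshold for the sample-everything rules
#'   (default 0.99, i.e. nearly noiseless).
#' @param k rank cutoff for K_CONF / K_MCD.
#' @param T_max censoring horizon.
#' @return object of class `heuristic_preset`: `name`, `params`
#'   ([network_params()]), `weights`, `k`.
#' @examples
#' heuristic_preset("WP", weights = c(0.03, 0.015, 0.01))
#' @export
heuristic_preset <- function(name, weights, choice_set = NULL, Q_high = 0.99,
                             k = 2L, T_max = 10000L) {
  name <- match.arg(toupper(name), HEURISTIC_NAMES)
  weights <- as.numeric(weights)
  if (any(weights <= 0)) stop("preset weights must be positive", call. = FALSE)
  M <- length(weights)
  k <- as.integer(k)
  if (name == "CONF") k <- 2L
  if (name %in% EQUAL_WEIGHT_RULES && length(unique(weights)) != 1L) {
    stop(sprintf("%s requires equal attribute weights", name), call. = FALSE)
  }
  if (name %in% c("CONF", "K_CONF")) {
    if (k < 1L || k > M) stop("`k` must be in 1..n_attributes", call. = FALSE)
    if (weights[1L] >= 1 / k) {
      stop(sprintf("%s requires w < 1/k so that Q = k*w stays within (0, 1]",
                   name), call. = FALSE)
    }
  }
  Q <- switch(name,
              LEX = max(weights),
              CONF = ,
              K_CONF = k * weights[1L],
              Q_high)
  s_P <- if (name == "LEX") 0 else 1
  if (name %in% ORDINAL_RULES) {
    s_A <- rep(1, M)
    l_A <- rep(1, M)
    if (!is.null(choice_set)) {
      sl <- sublayer_params_for(choice_set, "IDENTIFY_BEST", s_A, l_A)
      s_A <- sl$s_A
      l_A <- sl$l_A
    }
  } else if (name %in% c("EW", "WAD")) {
    s_A <- rep(0, M)
    l_A <- rep(0, M)
  } else {
    if (is.null(choice_set)) {
      stop(sprintf("%s needs a `choice_set` to determine its sublayer parameters",
                   name), call. = FALSE)
    }
    target <- if (name == "ITW") "IDENTIFY_WORST" else "IDENTIFY_K_BEST"
    sl <- sublayer_params_for(choice_set, target, rep(NA_real_, M),
                              rep(NA_real_, M), k = k)
    s_A <- sl$s_A
    l_A <- sl$l_A
  }
  structure(
    list(name = name,
         params = network_params(s_P = s_P, l_P = 0, s_A = s_A, l_A = l_A,
                                 Q = Q, T_max = T_max),
         weights = weights, k = k),
    class = "heuristic_preset"
  )
}

# Per-attribute sublayer parameters achieving `target` on a concrete choice
# set. Defaults (if not NA) are kept when they already classify correctly.
sublayer_params_for <- function(choice_set, target, s_A, l_A, k = 2L,
                                grid_step = 0.02) {
  M <- choice_set$n_attributes
  for (j in seq_len(M)) {
    inputs <- choice_set$values[, j]
    inputs[!choice_set$available] <- 0
    ok <- FALSE
    if (!is.na(s_A[j])) {
      eq <- equilibrium_iterate(inputs, s_A[j], l_A[j])
      if (eq$converged) {
        prof <- structure(c(eq, list(inputs = inputs, s = s_A[j], l = l_A[j])),
                          class = "equilibrium_profile")
        cl <- classify_transform(inputs, prof)
        ok <- cl$label == target &&
          (target != "IDENTIFY_K_BEST" || identical(cl$k, as.integer(k)))
      }
    }
    if (!ok) {
      hit <- find_params_for_transform(inputs, target, k = k,
                                       grid_step = grid_step)
      if (is.null(hit)) {
        stop(sprintf("no sublayer parameters found for %s on attribute %d",
                     target, j), call. = FALSE)
      }
      s_A[j] <- hit$s
      l_A[j] <- hit$l
    }
  }
  list(s_A = s_A, l_A = l_A)
}

#' @export
print.heuristic_preset <- function(x, ...) {
  cat(sprintf("Heuristic preset: %s%s\n", x$name,
              if (x$name %in% c("K_CONF", "K_MCD")) sprintf(" (k = %d)", x$k) else ""))
  cat("weights:", paste(format(x$weights), collapse = ", "), "\n")
  print(x$params)
  invisible(x)
}

#' Idealized (symbolic) heuristic choice
#'
#' The deterministic, rule-based choice each heuristic prescribes, used as
#' ground truth when judging how well the network presets mimic the rules:
#' LEX picks the argmax on the highest-weighted attribute; WP the argmax of
#' the weighted sum of best-on-attribute indicators; MCD the argmax of
#' best-on-attribute counts; EW the argmax of unweighted attribute sums; WAD
#' the argmax of weighted sums; ITW the argmax of weighted sums excluding
#' each attribute's worst alternative; K_MCD the argmax of top-`k` counts.
#' Any tie at the top (or a tied per-attribute extreme for the rules that
#' need one) makes the prediction undefined, returned as `NA` -- ties are
#' never broken silently. CONF has no deterministic prediction and is
#' rejected.
#'
#' @param name heuristic name (CONF/K_CONF excluded).
#' @param choice_set a [choice_set()].
#' @param k rank cutoff for K_MCD.
#' @return the chosen alternative's index, or `NA_integer_` when the rule's
#'   prediction is not unique.
#' @examples
#' cs <- choice_set(rbind(c(0.8, 0.2), c(0.4, 0.9)), weights = c(0.03, 0.015))
#' idealized_choice("LEX", cs)
#' idealized_choice("WAD", cs)
#' @export
idealized_choice <- function(name, choice_set, k = 2L) {
  name <- match.arg(toupper(name),
                    setdiff(HEURISTIC_NAMES, c("CONF", "K_CONF")))
  stopifnot(inherits(choice_set, "choice_set"))
  cons <- which(choice_set$available)
  x <- choice_set$values[cons, , drop = FALSE]
  w <- choice_set$weights
  strict_argmax <- function(v) {
    idx <- which(v == max(v))
    if (length(idx) == 1L) idx else NA_integer_
  }
  col_extreme <- function(f) apply(x, 2L, function(col) {
    idx <- which(col == f(col))
    if (length(idx) == 1L) idx else NA_integer_
  })
  pick <- switch(
    name,
    LEX = strict_argmax(x[, which.max(w)]),
    WP = {
      best <- col_extreme(max)
      if (anyNA(best)) NA_integer_ else {
        scores <- vapply(seq_len(nrow(x)),
                         function(i) sum(w[best == i]), numeric(1))
        strict_argmax(scores)
      }
    },
    MCD = {
      best <- col_extreme(max)
      if (anyNA(best)) NA_integer_ else
        strict_argmax(tabulate(best, nbins = nrow(x)))
    },
    EW = strict_argmax(rowSums(x)),
    WAD = strict_argmax(drop(x %*% w)),
    ITW = {
      worst <- col_extreme(min)
      if (anyNA(worst)) NA_integer_ else {
        keep <- outer(seq_len(nrow(x)), worst, `!=`)
        strict_argmax(drop((x * keep) %*% w))
      }
    },
    K_MCD = {
      kk <- as.integer(k)
      stopifnot(kk >= 1L, kk < nrow(x))
      counts <- integer(nrow(x))
      for (j in seq_len(ncol(x))) {
        ord <- order(x[, j], decreasing = TRUE)
        if (x[ord[kk], j] == x[ord[kk + 1L], j]) return(NA_integer_)
        counts[ord[seq_len(kk)]] <- counts[ord[seq_len(kk)]] + 1L
      }
      strict_argmax(counts)
    }
  )
  if (is.na(pick)) NA_integer_ else cons[pick]
}
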