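# The two Monte-Carlo simulation studies: heuristic identification
# (accuracy of each preset's modal choices against each idealized rule) and
# parameter recovery (uniqueness of grid combinations under MSE fitting).

#' Parameter grid for the recovery study
#'
#' Enumerates shared sublayer self-feedback `s_A`, inhibition `l_A` and
#' threshold `Q` over a common grid with `s_P = 1`, `l_P = 0` (the
#' accumulate-everything regime), plus one extra lexicographic combination
#' (`s_P = l_P = 0`, `s_A = l_A = 1`, `Q = w1`) that the grid itself cannot
#' express. The default grid 0.1 to 0.9 in steps of 0.1 yields
#' `9^3 + 1 = 730` combinations.
#'
#' @param grid_values grid for `s_A`, `l_A` and `Q`.
#' @param lex_Q threshold of the extra lexicographic combination (the
#'   attribute weight used in the study).
#' @return data frame with columns `s_P`, `l_P`, `s_A`, `l_A`, `Q`.
#' @examples
#' nrow(recovery_grid())  # 730
#' @export
recovery_grid <- function(grid_values = seq(0.1, 0.9, by = 0.1),
                          lex_Q = 0.01) {
  g <- expand.grid(s_A = grid_values, l_A = grid_values, Q = grid_values,
                   KEEP.OUT.ATTRS = FALSE)
  g <- cbind(s_P = 1, l_P = 0, g)
  rbind(g, data.frame(s_P = 0, l_P = 0, s_A = 1, l_A = 1, Q = lex_Q))
}

# Simulated choice probabilities of one parameter combination on a list of
# choice sets; returns a (sets x alternatives) matrix flattened by rows.
combo_probabilities <- function(combo, sets, weights, n_reps, T_max = 10000L) {
  params <- network_params(s_P = combo$s_P, l_P = combo$l_P,
                           s_A = combo$s_A, l_A = combo$l_A,
                           Q = combo$Q, T_max = T_max)
  unlist(lapply(sets, function(cs) {
    cs$weights <- weights
    alpha <- attribute_equilibria(cs, params, warn = FALSE)$alpha
    estimate_choice_probabilities(cs, params, n_reps, alpha = alpha,
                                  warn = FALSE)$prob
  }))
}

#' Heuristic identification study
#'
#' Applies the idealized LEX, WP, MCD, EW and WAD rules to random uniform
#' choice sets and simulates the corresponding network presets on the same
#' sets (proportional weights for LEX/WP/WAD, equal weights for MCD/EW).
#' Accuracy of preset P against idealized rule H is the fraction of sets --
#' restricted to those where H's prediction is unique -- on which P's modal
#' simulated choice equals H's choice; a tied modal choice counts as a
#' mismatch. The diagonal of the resulting matrix measures how faithfully
#' each preset implements its own rule; off-diagonal cells measure how
#' confusable the rules are.
#'
#' @param n_sets number of random choice sets (ignored when `choice_sets`
#'   is given).
#' @param n_reps simulated decisions per probability estimate.
#' @param weights proportional attribute weights (the equal-weight rules use
#'   `rep(min(weights), M)`).
#' @param n_alternatives alternatives per set.
#' @param choice_sets optional pregenerated list of [choice_set()]s.
#' @param presets which presets/rules to cross.
#' @param Q_high acceptance threshold of the sample-everything presets.
#' @return object of class `identification_study`: `accuracy` (preset x
#'   idealized matrix), `evaluated_sets` (per idealized rule, after
#'   excluding sets with non-unique predictions), `n_sets`, `n_reps`,
#'   `config`.
#' @examples
#' set.seed(42)
#' run_identification_study(n_sets = 4, n_reps = 200)
#' @export
run_identification_study <- function(n_sets = 100, n_reps = 10000,
                                     weights = c(0.03, 0.015, 0.01),
                                     n_alternatives = 3,
                                     choice_sets = NULL,
                                     presets = c("LEX", "WP", "MCD", "EW", "WAD"),
                                     Q_high = 0.99) {
  presets <- match.arg(presets, c("LEX", "WP", "MCD", "EW", "WAD"),
                       several.ok = TRUE)
  if ("CONF" %in% presets) stop("CONF has no deterministic idealized choice",
                                call. = FALSE)
  M <- length(weights)
  if (is.null(choice_sets)) {
    if (n_sets < 1L) stop("`n_sets` must be positive", call. = FALSE)
    choice_sets <- generate_choice_sets(n_sets, n_alternatives, M,
                                        weights = weights)
  }
  n_sets <- length(choice_sets)
  equal_w <- rep(min(weights), M)

  oracle <- sapply(presets, function(h)
    vapply(choice_sets, function(cs) {
      cs$weights <- weights
      idealized_choice(h, cs)
    }, integer(1)))

  modal <- sapply(presets, function(p) {
    w <- if (p %in% EQUAL_WEIGHT_RULES) equal_w else weights
    preset <- heuristic_preset(p, weights = w, Q_high = Q_high)
    vapply(choice_sets, function(cs) {
      cs$weights <- w
      alpha <- attribute_equilibria(cs, preset$params, warn = FALSE)$alpha
      cp <- estimate_choice_probabilities(cs, preset$params, n_reps,
                                          alpha = alpha, warn = FALSE)
      modal_choice(cp$prob)
    }, integer(1))
  })

  acc <- matrix(NA_real_, length(presets), length(presets),
                dimnames = list(implemented = presets, idealized = presets))
  evaluated <- stats::setNames(colSums(!is.na(oracle)), presets)
  for (h in presets) {
    keep <- !is.na(oracle[, h])
    for (p in presets) {
      agree <- !is.na(modal[keep, p]) & modal[keep, p] == oracle[keep, h]
      acc[p, h] <- mean(agree)
    }
  }
  structure(
    list(accuracy = acc, evaluated_sets = evaluated, n_sets = n_sets,
         n_reps = n_reps,
         config = list(weights = weights, equal_weights = equal_w,
                       n_alternatives = n_alternatives, Q_high = Q_high)),
    class = "identification_study"
  )
}

#' @export
print.identification_study <- function(x, ...) {
  cat(sprintf("Heuristic identification study: %d choice sets, %d reps/estimate\n",
              x$n_sets, x$n_reps))
  cat("Accuracy (rows: implemented preset; columns: idealized rule):\n")
  print(round(x$accuracy, 2))
  cat("Evaluated sets per idealized rule (non-unique predictions excluded):\n")
  print(x$evaluated_sets)
  invisible(x)
}

#' Parameter recovery study
#'
#' Measures how uniquely the grid of parameter combinations can be recovered
#' from the choice probabilities they generate. For each requested number of
#' choice sets: random uniform sets are drawn; every combination is
#' simulated twice on every set with independent randomness (a "data" run
#' and a "model" run, so recovery is judged against fresh simulation noise);
#' and each combination's data is fit by every combination's model run using
#' the mean squared error over all (set, alternative) probability cells. A
#' combination counts as uniquely recovered when it is the strict, sole
#' minimizer of the MSE on its own data -- exact ties count as failures.
#'
#' @param n_sets_list numbers of choice sets to evaluate (the uniqueness
#'   curve is reported for each).
#' @param n_reps simulated decisions per probability estimate.
#' @param grid parameter grid, by default [recovery_grid()] (730 rows).
#' @param n_alternatives,n_attributes choice-set dimensions.
#' @param weights attribute weights used by every combination.
#' @param T_max censoring horizon.
#' @return object of class `recovery_study`: `uniqueness` data frame
#'   (`n_sets`, `n_unique`, `n_combos`, `proportion`), `grid`, `n_reps`,
#'   `config`.
#' @examples
#' set.seed(7)
#' small <- recovery_grid(grid_values = c(0.2, 0.8))
#' run_recovery_study(n_sets_list = 2, n_reps = 200, grid = small)
#' @export
run_recovery_study <- function(n_sets_list = c(2, 10, 25), n_reps = 2000,
                               grid = recovery_grid(),
                               n_alternatives = 3, n_attributes = 2,
                               weights = rep(0.01, n_attributes),
                               T_max = 10000L) {
  stopifnot(nrow(grid) >= 2L, length(weights) == n_attributes)
  n_combos <- nrow(grid)
  res <- vector("list", length(n_sets_list))
  for (ii in seq_along(n_sets_list)) {
    n_sets <- n_sets_list[ii]
    sets <- generate_choice_sets(n_sets, n_alternatives, n_attributes,
                                 weights = weights)
    p_data <- matrix(0, n_combos, n_sets * n_alternatives)
    p_model <- matrix(0, n_combos, n_sets * n_alternatives)
    for (ci in seq_len(n_combos)) {
      combo <- grid[ci, ]
      p_data[ci, ] <- combo_probabilities(combo, sets, weights, n_reps, T_max)
      p_model[ci, ] <- combo_probabilities(combo, sets, weights, n_reps, T_max)
    }
    # cellwise MSE between every data row and every model row
    cross <- tcrossprod(p_data, p_model)
    sq_d <- rowSums(p_data^2)
    sq_m <- rowSums(p_model^2)
    sse <- outer(sq_d, sq_m, `+`) - 2 * cross
    n_unique <- 0L
    for (d in seq_len(n_combos)) {
      own <- sse[d, d]
      if (all(sse[d, -d] > own)) n_unique <- n_unique + 1L
    }
    res[[ii]] <- data.frame(n_sets = n_sets, n_unique = n_unique,
                            n_combos = n_combos,
                            proportion = n_unique / n_combos)
  }
  structure(
    list(uniqueness = do.call(rbind, res), grid = grid, n_reps = n_reps,
         config = list(n_alternatives = n_alternatives,
                       n_attributes = n_attributes, weights = weights)),
    class = "recovery_study"
  )
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter recovery study: %d combinations, %d reps/estimate\n",
              nrow(x$grid), x$n_reps))
  print(x$uniqueness, row.names = FALSE)
  invisible(x)
}
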