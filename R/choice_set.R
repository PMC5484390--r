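#' Construct a multi-attribute choice set
#'
#' A choice set holds the attribute values of `N` possible alternatives on
#' `M` attributes, the importance weight of each attribute, and an
#' availability mask selecting the alternatives actually under consideration.
#' Attribute values of considered alternatives must lie strictly inside the
#' unit interval; nodes of unavailable alternatives receive zero input and
#' stay silent throughout a decision.
#'
#' @param values numeric matrix (`N` rows = alternatives, `M` columns =
#'   attributes). Values of considered alternatives must be in (0, 1).
#' @param weights nonnegative attribute weights, length `M`, at least one
#'   positive.
#' @param available logical vector of length `N` marking the considered
#'   alternatives; defaults to all available.
#' @return an object of class `choice_set` with fields `values`, `weights`,
#'   `available`, `n_alternatives` (`N`) and `n_attributes` (`M`).
#' @examples
#' cs <- choice_set(rbind(c(0.8, 0.2), c(0.4, 0.9)), weights = c(0.03, 0.015))
#' utility(cs)
#' @seealso [utility()], [generate_choice_sets()], [read_choice_set()]
#' @export
choice_set <- function(values, weights, available = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("`values` must be a finite numeric matrix", call. = FALSE)
  }
  n_alt <- nrow(values)
  n_att <- ncol(values)
  if (n_alt < 1L || n_att < 1L) {
    stop("`values` must have at least one row and one column", call. = FALSE)
  }
  if (is.null(available)) available <- rep(TRUE, n_alt)
  available <- as.logical(available)
  if (length(available) != n_alt || any(is.na(available))) {
    stop("`available` must be a logical vector with one entry per alternative",
         call. = FALSE)
  }
  if (!any(available)) {
    stop("at least one alternative must be available", call. = FALSE)
  }
  bad <- which(available & (apply(values <= 0 | values >= 1, 1, any)))
  if (length(bad)) {
    ij <- which(values[bad[1L], , drop = TRUE] <= 0 |
                  values[bad[1L], , drop = TRUE] >= 1)[1L]
    stop(sprintf(
      "attribute values of considered alternatives must lie strictly in (0, 1); first violation at alternative %d, attribute %d (value %g)",
      bad[1L], ij, values[bad[1L], ij]), call. = FALSE)
  }
  weights <- as.numeric(weights)
  if (length(weights) != n_att) {
    stop(sprintf("`weights` must have length %d (one per attribute), got %d",
                 n_att, length(weights)), call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0) || all(weights == 0)) {
    stop("`weights` must be nonnegative with at least one positive entry",
         call. = FALSE)
  }
  structure(
    list(values = values, weights = weights, available = available,
         n_alternatives = n_alt, n_attributes = n_att),
    class = "choice_set"
  )
}

#' @export
print.choice_set <- function(x, ...) {
  cat(sprintf("Choice set: %d alternative(s) (%d considered) x %d attribute(s)\n",
              x$n_alternatives, sum(x$available), x$n_attributes))
  m <- cbind(x$values, utility = utility(x))
  rownames(m) <- paste0(ifelse(x$available, "  ", "- "), "alt_",
                        seq_len(x$n_alternatives))
  colnames(m)[seq_len(x$n_attributes)] <- paste0("attr_", seq_len(x$n_attributes))
  print(round(m, 4))
  cat("weights:", paste(format(x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Weighted additive utility of each alternative
#'
#' The weighted sum of attribute values, the quantity maximized by a fully
#' rational (weighted additive) decision maker. Unavailable alternatives get
#' `NA`.
#'
#' @param choice_set a [choice_set()].
#' @return numeric vector of length `n_alternatives`.
#' @export
utility <- function(choice_set) {
  stopifnot(inherits(choice_set, "choice_set"))
  u <- drop(choice_set$values %*% choice_set$weights)
  u[!choice_set$available] <- NA_real_
  u
}

#' Generate random choice sets
#'
#' Draws attribute values independently from the uniform distribution on
#' (0, 1) (draws are nudged off exact 0/1 by machine epsilon so the
#' open-interval invariant holds). Uses the current R random number stream;
#' call `set.seed()` beforehand for reproducibility.
#'
#' @param n_sets number of choice sets.
#' @param n_alternatives alternatives per set.
#' @param n_attributes attributes per alternative.
#' @param weights attribute weights stored in each set (default: equal
#'   weights `1/n_attributes`).
#' @return list of [choice_set()] objects.
#' @examples
#' set.seed(1)
#' sets <- generate_choice_sets(3, n_alternatives = 3, n_attributes = 3)
#' @export
generate_choice_sets <- function(n_sets, n_alternatives, n_attributes,
                                 weights = NULL) {
  if (n_sets < 1L || n_alternatives < 1L || n_attributes < 1L) {
    stop("`n_sets`, `n_alternatives` and `n_attributes` must be positive",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1 / n_attributes, n_attributes)
  eps <- .Machine$double.eps
  lapply(seq_len(n_sets), function(k) {
    x <- matrix(runif(n_alternatives * n_attributes),
                nrow = n_alternatives, ncol = n_attributes)
    x <- pmin(pmax(x, eps), 1 - eps)
    choice_set(x, weights = weights)
  })
}
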