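# Classification of sublayer equilibria into transform regimes, and sweeps
# of the (s, l) plane.

TRANSFORM_LABELS <- c("IDENTITY", "IDENTIFY_BEST", "IDENTIFY_K_BEST",
                      "IDENTIFY_WORST", "NORMALIZED", "OTHER")

#' Classify a sublayer equilibrium into a transform regime
#'
#' Given the constant inputs of a sublayer and its converged equilibrium,
#' decides which computation the sublayer performed on the considered
#' alternatives (nodes with positive input):
#' \describe{
#'   \item{IDENTITY}{activations equal the inputs.}
#'   \item{IDENTIFY_BEST}{the input-maximal node saturates at 1, all others
#'     at 0 (ordinal "best on the attribute" computation).}
#'   \item{IDENTIFY_K_BEST}{the top `k` nodes saturate at 1, the rest at 0,
#'     for some `1 < k < n`.}
#'   \item{IDENTIFY_WORST}{the input-minimal node is suppressed to 0 while
#'     every other node stays positive.}
#'   \item{NORMALIZED}{all nodes strictly interior and the activations fit
#'     the linear relative form `alpha_i = omega1 x_i - omega2 sum(x_k, k != i)`
#'     exactly; the fitted `(omega1, omega2)` are returned.}
#'   \item{OTHER}{anything else, including tied inputs.}
#' }
#' Saturation is judged within `tol` of 0/1; geometric convergence at the
#' equilibrium tolerance makes saturated activations numerically exact, so
#' the default `tol = 1e-9` is comfortable.
#'
#' @param inputs the sublayer's constant input vector (zeros mark
#'   unavailable alternatives).
#' @param profile an `equilibrium_profile` from [sublayer_equilibrium()];
#'   must have converged.
#' @param tol saturation/identity tolerance.
#' @return object of class `transform_label`: `label`, `k` (for
#'   IDENTIFY_K_BEST), `omega` (for NORMALIZED).
#' @examples
#' cs <- choice_set(matrix(c(0.75, 0.5, 0.25), ncol = 1), weights = 1)
#' classify_transform(c(0.75, 0.5, 0.25),
#'                    sublayer_equilibrium(cs, 1, s = 0.5, l = 0.7))
#' @export
classify_transform <- function(inputs, profile, tol = 1e-9) {
  stopifnot(inherits(profile, "equilibrium_profile"))
  if (!profile$converged) {
    stop("cannot classify an unconverged equilibrium profile", call. = FALSE)
  }
  cons <- which(inputs > 0)
  x <- inputs[cons]
  a <- profile$alpha[cons]
  n <- length(cons)
  out <- function(label, k = NA_integer_, omega = NULL) {
    structure(list(label = label, k = k, omega = omega, considered = cons),
              class = "transform_label")
  }
  if (n == 0L) return(out("OTHER"))
  # tied extremes carry no unique ordinal answer
  if (n >= 2L && (sum(x == max(x)) > 1L || sum(x == min(x)) > 1L)) {
    return(out("OTHER"))
  }
  if (all(abs(a - x) <= tol)) return(out("IDENTITY"))
  ord <- order(x, decreasing = TRUE)
  for (k in seq_len(max(n - 1L, 1L))) {
    top <- ord[seq_len(k)]
    if (all(a[top] >= 1 - tol) && all(a[-top] <= tol) && k < n) {
      return(out(if (k == 1L) "IDENTIFY_BEST" else "IDENTIFY_K_BEST", k = k))
    }
  }
  worst <- ord[n]
  if (n >= 2L && a[worst] <= tol && all(a[-match(worst, seq_len(n))] > tol)) {
    return(out("IDENTIFY_WORST"))
  }
  if (all(a > tol & a < 1 - tol)) {
    X <- cbind(x, -(sum(x) - x))
    fit <- qr.coef(qr(X), a)
    resid <- max(abs(drop(X %*% fit) - a))
    if (resid <= max(tol, 1e-8) && fit[1L] > 0 && fit[2L] >= -1e-12) {
      return(out("NORMALIZED",
                 omega = c(omega1 = unname(fit[1L]), omega2 = unname(fit[2L]))))
    }
  }
  out("OTHER")
}

#' @export
print.transform_label <- function(x, ...) {
  lab <- x$label
  if (lab == "IDENTIFY_K_BEST") lab <- sprintf("IDENTIFY_K_BEST (k = %d)", x$k)
  cat("Transform:", lab, "\n")
  if (!is.null(x$omega)) {
    cat(sprintf("  omega1 = %.6g, omega2 = %.6g\n", x$omega[1], x$omega[2]))
  }
  invisible(x)
}

#' Map transform regimes over the (s, l) plane
#'
#' Computes the sublayer equilibrium for a fixed input vector at every
#' combination of self-feedback and inhibition in the supplied grids and
#' classifies each cell. This reproduces, as a labeled grid, the region maps
#' showing where a sublayer acts as identity, identify-best, identify-worst
#' or normalization.
#'
#' @param inputs input vector (considered alternatives' attribute values).
#' @param s_grid,l_grid grids of self-feedback / inhibition values
#'   (default 0 to 1 in steps of 0.01, endpoints included).
#' @param tol,max_iter equilibrium iteration controls.
#' @param class_tol classification tolerance.
#' @return a long-format data frame with columns `s`, `l`, `label`, `k`,
#'   `converged` and `alpha_1 ... alpha_n` (one per considered node).
#'   Unconverged cells are labeled OTHER with `converged = FALSE`.
#' @examples
#' head(region_map(c(0.75, 0.5, 0.25), s_grid = c(0, 0.5), l_grid = c(0, 0.7)))
#' @export
region_map <- function(inputs, s_grid = seq(0, 1, by = 0.01),
                       l_grid = seq(0, 1, by = 0.01),
                       tol = 1e-10, max_iter = 10000L, class_tol = 1e-9) {
  stopifnot(all(inputs >= 0), all(inputs < 1))
  n <- sum(inputs > 0)
  rows <- vector("list", length(s_grid) * length(l_grid))
  r <- 0L
  for (s in s_grid) {
    for (l in l_grid) {
      eq <- equilibrium_iterate(inputs, s, l, tol, max_iter)
      r <- r + 1L
      if (eq$converged) {
        prof <- structure(c(eq, list(inputs = inputs, s = s, l = l)),
                          class = "equilibrium_profile")
        cl <- classify_transform(inputs, prof, tol = class_tol)
        lab <- cl$label
        k <- cl$k
      } else {
        lab <- "OTHER"
        k <- NA_integer_
      }
      alpha <- eq$alpha[inputs > 0]
      row <- c(list(s = s, l = l, label = lab, k = k,
                    converged = eq$converged),
               stats::setNames(as.list(alpha), paste0("alpha_", seq_len(n))))
      rows[[r]] <- row
    }
  }
  do.call(rbind.data.frame, c(rows, list(stringsAsFactors = FALSE)))
}

#' Search for sublayer parameters implementing a target transform
#'
#' Grid search over the (s, l) plane, in lexicographic order (s outer, l
#' inner, smallest first), returning the first parameter pair whose
#' converged equilibrium classifies as the target transform. Existence of
#' identify-best / identify-worst parameters for any input vector with
#' distinct entries is a structural property of the dynamics; this verifies
#' it numerically.
#'
#' @param inputs input vector.
#' @param target one of `"IDENTITY"`, `"IDENTIFY_BEST"`, `"IDENTIFY_K_BEST"`,
#'   `"IDENTIFY_WORST"`, `"NORMALIZED"`.
#' @param k top-k size when `target = "IDENTIFY_K_BEST"`.
#' @param grid_step grid resolution in (0, 1).
#' @param s_max,l_max upper grid limits (the default unit square suffices for
#'   the standard regimes).
#' @param tol,max_iter,class_tol iteration and classification controls.
#' @return `list(s, l, profile)` for the first match, or `NULL` if the
#'   target is not attainable on the grid.
#' @examples
#' find_params_for_transform(c(0.75, 0.5, 0.25), "IDENTIFY_WORST",
#'                           grid_step = 0.05)[c("s", "l")]
#' @export
find_params_for_transform <- function(inputs, target, k = 2L,
                                      grid_step = 0.01, s_max = 1, l_max = 1,
                                      tol = 1e-10, max_iter = 10000L,
                                      class_tol = 1e-9) {
  target <- match.arg(target, setdiff(TRANSFORM_LABELS, "OTHER"))
  if (grid_step <= 0 || grid_step >= 1) {
    stop("`grid_step` must lie in (0, 1)", call. = FALSE)
  }
  for (s in seq(0, s_max, by = grid_step)) {
    for (l in seq(0, l_max, by = grid_step)) {
      eq <- equilibrium_iterate(inputs, s, l, tol, max_iter)
      if (!eq$converged) next
      prof <- structure(c(eq, list(inputs = inputs, s = s, l = l)),
                        class = "equilibrium_profile")
      cl <- classify_transform(inputs, prof, tol = class_tol)
      hit <- cl$label == target &&
        (target != "IDENTIFY_K_BEST" || identical(cl$k, as.integer(k)))
      if (hit) return(list(s = s, l = l, profile = prof))
    }
  }
  NULL
}
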