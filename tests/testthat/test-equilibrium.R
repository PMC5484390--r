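# Sublayer equilibria: worked values, closed forms, and order/monotonicity
# properties of the leaky competitive fixed point.

test_that("zero feedback and inhibition give the identity transform exactly", {
  cs <- canonical_set()
  prof <- sublayer_equilibrium(cs, 1, s = 0, l = 0)
  expect_true(prof$converged)
  expect_identical(prof$alpha, canonical_inputs)
})

test_that("strong recurrence yields winner-take-all; moderate inhibition suppresses only the worst", {
  cs <- canonical_set()
  wta <- sublayer_equilibrium(cs, 1, s = 0.5, l = 0.7)
  expect_true(wta$converged)
  expect_equal(wta$alpha, c(1, 0, 0), tolerance = 1e-9)

  # with the worst clamped at zero the two surviving nodes solve a 2x2
  # linear system; compare against its closed-form solution
  prof <- sublayer_equilibrium(cs, 1, s = 0, l = 0.3)
  expect_true(prof$converged)
  expected <- two_node_equilibrium(0.75, 0.5, 0.3)
  expect_equal(prof$alpha, c(expected, 0), tolerance = 1e-8)
})

test_that("synchronous updates report period-2 limit cycles as non-convergence", {
  cs <- canonical_set()
  prof <- sublayer_equilibrium(cs, 1, s = 0, l = 1)
  expect_false(prof$converged)
  expect_lt(prof$iterations, 100)  # cycle detected early, not at max_iter
})

test_that("equilibria preserve the input order", {
  set.seed(202)
  for (rep in 1:40) {
    x <- sort(runif(4, 0.05, 0.95), decreasing = TRUE)
    s <- runif(1, 0, 1.2)
    l <- runif(1, 0, 1.2)
    eq <- lcanet:::equilibrium_iterate(x, s, l)
    if (!eq$converged) next
    expect_true(all(diff(eq$alpha) <= 1e-12),
                info = sprintf("s=%.3f l=%.3f", s, l))
  }
})

test_that("equilibrium activations are nondecreasing in self-feedback", {
  # without inhibition every node solves alpha = min(1, x/(1-s)), so all
  # activations rise with s; with inhibition active only the top node is
  # guaranteed to rise (stronger competitors can push weaker nodes down as
  # their own activation grows)
  set.seed(303)
  x <- c(0.7, 0.45, 0.2)
  prev <- NULL
  for (s in seq(0, 0.9, by = 0.1)) {
    eq <- lcanet:::equilibrium_iterate(x, s, l = 0)
    expect_true(eq$converged)
    expect_equal(eq$alpha, pmin(1, x / (1 - s)), tolerance = 1e-8)
    if (!is.null(prev)) expect_true(all(eq$alpha - prev >= -1e-9))
    prev <- eq$alpha
  }
  for (l in c(0.15, 0.35)) {
    prev_top <- -Inf
    for (s in seq(0, 0.9, by = 0.1)) {
      eq <- lcanet:::equilibrium_iterate(x, s, l)
      if (!eq$converged) break
      expect_gte(eq$alpha[1], prev_top - 1e-9)
      prev_top <- eq$alpha[1]
    }
  }
})

test_that("saturation thresholds match the closed forms s* = 1 - x1, l* = x2", {
  set.seed(404)
  for (rep in 1:10) {
    x <- sort(runif(3, 0.1, 0.9), decreasing = TRUE)
    if (min(abs(diff(x))) < 0.05) next
    s_star <- 1 - x[1]
    s_lo <- max(s_star - 0.08, 0)
    # inhibition strong enough to silence the non-top nodes even at the
    # lower, unsaturated top activation x1/(1-s_lo)
    l <- max(x[2], x[2] * (1 - s_lo) / x[1]) + 0.05
    above <- lcanet:::equilibrium_iterate(x, s_star + 0.03, l)
    below <- lcanet:::equilibrium_iterate(x, s_lo, l)
    # synchronous updates can cycle for near-tied inputs under strong
    # inhibition; the closed forms speak only about actual equilibria
    if (!above$converged || !below$converged) next
    expect_equal(above$alpha, c(1, 0, 0), tolerance = 1e-9)
    # below the threshold the top node sits at x1/(1-s), strictly inside
    expect_equal(below$alpha[1], x[1] / (1 - s_lo), tolerance = 1e-8)
    expect_lt(below$alpha[1], 1)
    # at the state (1, 0, 0), inhibition below x2 cannot hold node 2 down
    weak_l <- lcanet:::equilibrium_iterate(x, s_star + 0.03, x[2] - 0.05)
    if (weak_l$converged) expect_gt(weak_l$alpha[2], 0)
  }
})

test_that("interior equilibria satisfy the linear normalization form with derived omegas", {
  set.seed(505)
  for (rep in 1:20) {
    x <- runif(3, 0.2, 0.8)
    if (min(abs(diff(sort(x)))) < 0.02) next
    s <- runif(1, 0.02, 0.25)
    l <- runif(1, 0.02, 0.2)
    eq <- lcanet:::equilibrium_iterate(x, s, l)
    expect_true(eq$converged)
    if (any(eq$alpha <= 0 | eq$alpha >= 1)) next  # not interior, skip case
    om <- transform_omega(s, l, 3)
    pred <- om["omega1"] * x - om["omega2"] * (sum(x) - x)
    expect_lt(max(abs(pred - eq$alpha)), 1e-8)
    expect_gt(om["omega1"], 0)
    expect_gt(om["omega2"], 0)
  }
})

test_that("unavailable alternatives stay silent in every sublayer", {
  cs <- choice_set(rbind(c(0.75, 0.3), c(0.5, 0.6), c(0.25, 0.9)),
                   weights = c(1, 1), available = c(TRUE, FALSE, TRUE))
  for (j in 1:2) {
    for (sl in list(c(0, 0), c(0.5, 0.7), c(0.1, 0.1))) {
      prof <- sublayer_equilibrium(cs, j, sl[1], sl[2])
      expect_identical(prof$alpha[2], 0)
    }
  }
})
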