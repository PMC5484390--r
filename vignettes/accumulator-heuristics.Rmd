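---
title: "Heuristic choice rules in a leaky competitive accumulator network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heuristic choice rules in a leaky competitive accumulator network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcanet)
```

## The model and its assumptions

`lcanet` models choice between `n` alternatives described on `M`
attributes, with values `x_ij` strictly inside the unit interval and
attribute weights `w_j`. Two recurrent layers share one bounded
piecewise-linear activation `f` (linear on `[0, 1]`, clamped outside) and
one synchronous update rule: each node receives `s` times its own previous
activation, minus `l` times the summed activation of its layer-mates, plus
its external input.

The key structural assumptions are:

* **Timescale separation.** Attribute sublayers equilibrate "immediately"
  relative to attribute sampling, so only their stable activations matter.
  We compute them by synchronous fixed-point iteration from the all-zero
  state (all nodes are off before a decision starts), with tolerance
  `1e-10` and an iteration cap of 10,000.
* **Stochastic sampling.** Each preference-layer step samples one attribute
  i.i.d. (uniformly by default); the weighted sublayer equilibria `w_j·α_ij`
  are the preference inputs. There is no neural noise inside nodes:
  sampling order and tie-breaks are the only random elements.
* **Threshold decision.** The first alternative whose preference reaches
  the threshold `Q` is chosen. Because preferences also pass through `f`,
  accumulated preference cannot exceed 1 and `Q` must lie in `(0, 1]`.
* **No feedback** from preferences to attribute representations, and no
  dependence of sampling on the choice set.

## Sublayer transform regimes

For a sublayer with inputs `x_1 > x_2 > ... > x_n` (considered
alternatives; unavailable nodes get zero input and provably stay at zero):

* `s = l = 0` reproduces the inputs exactly (identity).
* With all non-top nodes suppressed, the top node solves
  `α_1 = min(1, x_1/(1−s))`, so it saturates at 1 exactly when
  `s ≥ 1 − x_1`; at the state `(1, 0, ..., 0)` the second node stays
  suppressed exactly when `l ≥ x_2`. High `(s, l)` therefore implement the
  ordinal *identify-the-best* computation.
* Moderate inhibition suppresses only the input-minimal node
  (*identify-the-worst*); nodes leave the competition in input order as `l`
  grows.
* When no node saturates, the equilibrium is linear in the inputs:
  `α_i = ω1·x_i − ω2·Σ_{k≠i} x_k` with
  `ω1 = (1 − l/(1−s+(n−1)l))/(1−s−l)` and `ω2 = l/((1−s−l)(1−s+(n−1)l))`.
  These closed forms are derived by solving the linear fixed point and are
  verified numerically in the tests (`transform_omega()`); the package
  treats them as its own derivation, with residuals below `1e-8` required
  for a NORMALIZED classification.

`classify_transform()` applies these definitions with a saturation
tolerance of `1e-9` (geometric convergence at tolerance `1e-10` makes
saturated activations numerically exact, and truly saturated nodes are
clamped to exactly 0/1 by `f`). `region_map()` sweeps an inclusive grid
(default step 0.01 on the unit square) and labels every cell.

Two numerical caveats are deliberate design choices. First, synchronous
updates with strong inhibition can enter exact period-2 cycles (for inputs
0.75/0.5/0.25 this happens, e.g., at `s = 0, l = 1`); the iteration detects
a state equal to the state two steps back, stops early, and reports
`converged = FALSE` with the final state rather than hiding the issue.
Unconverged cells are labeled OTHER in region maps and rejected by
`classify_transform()`. Second, monotonicity of equilibria in `s` holds for
all nodes only when `l = 0` (where `α = min(1, x/(1−s))`); with competition
active, a rising stronger node can push weaker nodes down, so only the top
node is monotone in general. The tests assert exactly these two versions.

Ties in attribute values (probability zero under the uniform generator, but
possible in files) are classified OTHER, and the idealized rules return an
undefined (`NA`) prediction rather than breaking ties silently.

## Heuristic presets and their tunables

`heuristic_preset()` encodes the parameter mappings: LEX (`s_P = 0`,
`Q = max(w_j)`), CONF/k-CONF (`s_P = 1`, equal `w < 1/k`, `Q = k·w`), WP
and MCD (`s_P = 1`, `Q` high, identify-best sublayers), EW and WAD
(identity sublayers, `s_P = 1`, `Q` high), ITW (identify-worst sublayers)
and k-MCD (identify-k-best sublayers). Defaults follow the simulation
studies: "high" `Q = 0.99`, proportional weights `0.03/0.015/0.01`, equal
weights `0.01`; `l_P = 0` throughout (the preference layer supports lateral
inhibition, but the studies do not use it). Ordinal presets use
`s_A = l_A = 1` on *all* sublayers, which saturates exact 1/0 equilibria;
note the threshold crossing is inclusive (`≥ Q`), which LEX requires since
`Q = max(w_j)` exactly equals the attainable input `w_j·1`. Given a
concrete choice set, presets verify their sublayer regime and fall back to
a grid search when the default parameters do not achieve it (ITW and k-MCD
always search, because their regimes depend on the attribute values).

One known representational gap: the network's ITW accumulates the
*equilibrium* activations of the surviving alternatives, which inhibition
attenuates relative to the raw values, whereas the idealized ITW oracle
sums raw values excluding each attribute's worst. The tests exercise the
oracle and the preset separately rather than pretending the two coincide.

Censored decisions (no crossing within `T_max = 10,000` samples by
default) are resolved in probability estimates by a uniform random choice
among the considered alternatives, keeping the probability vector
normalized; the censoring rate is reported on the result object.
Simultaneous crossings are broken uniformly at random.

## The synthetic choice-set generator

`generate_choice_sets()` draws attribute values i.i.d. uniform on (0, 1)
(nudged off the endpoints by machine epsilon), matching the ensembles used
in both studies: 3 alternatives × 3 attributes with weights 0.03/0.015/0.01
for heuristic identification, and 3 × 2 with weights 0.01/0.01 for
parameter recovery. The generator emulates *uncorrelated* attribute
structure only; real multi-attribute options typically have correlated
attributes (negatively, under market competition) and non-uniform marginal
distributions, so passing tests demonstrate correctness of the mechanism
under the studied ensemble, not descriptive adequacy for any particular
empirical domain.

An analytic property of this ensemble worth knowing: the three
per-attribute winners of a 3 × 3 uniform set are all distinct with
probability 6/27, so the tallying (MCD) rule has a unique prediction on
7/9 of sets; study accuracies for MCD are computed only over those.

## The simulation studies

**Heuristic identification** (`run_identification_study()`): 100 random
sets; idealized LEX/WP/MCD/EW/WAD choices versus each preset's *modal*
simulated choice at 10,000 decisions per estimate; accuracy restricted to
sets where the idealized rule is unique, with tied modal choices counted
as mismatches. CONF is excluded (no deterministic prediction).

**Parameter recovery** (`run_recovery_study()`): the grid
`s_A, l_A, Q ∈ {0.1, ..., 0.9}` with `s_P = 1, l_P = 0` plus one extra
lexicographic combination — 730 in all (`recovery_grid()`). Every
combination is simulated twice per set (independent "data" and "model"
runs); fits minimize the mean squared error over all (set, alternative)
probability cells — the natural cellwise reading of "mean squared error on
the data" — and a combination counts as recovered only when it is the
strict, sole minimizer on its own data (exact ties, which arise when
predictions are identical, count as failures).

Uniqueness at two choice sets is dominated by which sets are drawn: about a
third of uniform sets have one alternative best on every attribute, and
since every transform regime preserves within-attribute order, *all* 730
combinations then make the same near-deterministic prediction and tie.
Consequently the two-set uniqueness count varies by an order of magnitude
across draws. The package's headline script therefore reports the mean over
three independent two-set replications, and this vignette treats single-draw
values as realizations, not constants.

## Problem sizes and defaults

Monte-Carlo defaults mirror the studies (10,000 repetitions per
probability estimate for headline numbers). The test suite runs reduced
sizes chosen to keep the full check quick while leaving Monte-Carlo error
well inside the asserted tolerances: identification at 100 sets × 10,000
reps, recovery at two replications of the two-set study at 10,000 reps
plus a scaled uniqueness-vs-sets shape check at 2,000 reps, and smaller
ensembles (tens of sets, hundreds to thousands of reps) for unit
properties. `run_recovery_study()` defaults to `n_reps = 2000` and
`n_sets_list = c(2, 10, 25)` for quick exploration; full-scale runs (200
sets) are hours on one CPU and are exposed through the same function and
the CLI rather than run by default.

## Known limitations

* Synchronous-update limit cycles mean some `(s, l)` cells have no
  well-defined transform; these are surfaced, not resolved.
* The recovery study's strict-tie rule makes uniqueness conservative:
  behaviorally identical parameter combinations can never be recovered.
* Continuous-time dynamics, asynchronous updates, within-node noise,
  preference-to-attribute feedback, and elimination-style rules
  (fast-and-frugal trees, elimination by aspects, dominance detection) are
  out of scope; the network provably cannot express the latter family.
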