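---
title: "Methods: fate-probability corridors and underlying-field factors for CSC stabilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fate-probability corridors and underlying-field factors for CSC stabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscstab)
```

## The biological problem and the model

Many cancer cell lines keep a characteristic, low basal fraction of cancer
stem cells (CSC) over years of passaging, and a sorted, initially pure CSC
population regenerates that basal fraction within days.  `cscstab` models
this stabilization with two compartments — stem cells $S$ and non-stem
daughter cells $D$ — whose behavior at each division/transition event is
drawn from a small set of scenarios with probabilities:

| stem cell scenario | prob. | daughter cell scenario | prob. |
|---|---|---|---|
| $S \to S + D$ (asymmetric)      | $p_1$ | $D \to D + D$ (symmetric) | $q_1$ |
| $S \to D + D$ (symm. diff.)     | $p_2$ | $D \to S + D$ (dedifferentiating) | $q_2$ |
| $S \to S + S$ (symm. renewal)   | $p_3$ | | |
| $S \to D$ (direct transition)   | $p_4$ | | |

with $\sum_i p_i = 1$, $q_1 + q_2 = 1$ and every probability in $[0,1]$.
The two remaining theoretically possible daughter fates ($D \to S+S$,
$D \to S$) are held at probability zero: dedifferentiation is represented
by the single scenario $D \to S+D$.  Events occur at constant rates
$\lambda_1$ (stem) and $\lambda_2$ (non-stem), with death rates $\gamma_1,
\gamma_2$.  The abundances then obey the linear system

$$\dot S = \big[(p_1 + 2p_3 - 1)\lambda_1 - \gamma_1\big] S + q_2\lambda_2 D,
\qquad
\dot D = (p_1 + 2p_2 + p_4)\lambda_1 S + (q_1\lambda_2 - \gamma_2) D,$$

and the observable is the stem fraction $s(t) = S/(S+D)$, which satisfies a
scalar quadratic velocity law
$\dot s = c_0(q_2) + c_1(\mathbf p, q_2)\, s + c_2(\mathbf p)\, s^2$
(`steady_state_fractions()` returns its stationary fractions).  Units are
arbitrary but documented as days, matching the typical 10-day window of a
stabilization experiment; abundances are continuous and scale-free — only
$s(t)$ matters downstream.

## Stage 1: corridors of scenario probabilities

The inverse question: given a measured $s(t)$ (with $\dot s$, $\ddot s$)
and fixed rates, which time-varying probabilities are consistent with it?
A single scalar constraint cannot pin six unknowns, so the package adopts
a *minimal-change principle*: among all consistent evolutions, prefer the
one minimizing $\sum_i \dot p_i^2 + \sum_j \dot q_j^2$ — biologically,
switching division programs is costly, so cells change them as little as
the data force.  Three reductions follow:

1. **Closure.**  The velocity law plus the two simplex identities express
   $p_3$, $p_4$, $q_1$ algebraically in terms of $(p_1, p_2, q_2)$ and the
   curve (`close_probabilities()`).  Substituting the closed state back
   into the velocity law reproduces $\dot s$ *identically* — we verified
   this symbolically before implementation, and it is asserted to
   $10^{-10}$ over $10^4$ random states in the tests.
2. **Minimal-change ODEs.**  Minimizing the change functional under the
   differentiated constraint yields explicit right-hand sides for
   $(\dot p_1, \dot p_2, \dot q_2)$ (`minimal_change_rhs()`).  All three
   share one affine numerator factor that vanishes when
   $\dot s = \ddot s = 0$: a constant curve demands, and gets, constant
   probabilities.  Along data generated by *constant* probabilities the
   factor vanishes identically (verified symbolically), which is why
   forward-simulated ground truth is recovered essentially exactly.
3. **Integration and sweep.**  The ODEs are advanced by an implicit
   second-order midpoint scheme: each update is linear in the new
   $(p_1,p_2,q_2)$ through half-step averages, so a step is one exact
   $3\times 3$ solve (no fixed-point iteration), with curve values taken
   analytically at half steps for parametric/simulated curves and by
   interpolating spline otherwise.  $p_3, p_4, q_1$ are then closed at the
   node, making both simplex sums exact at machine precision by
   construction.  Initial conditions $(p_{10}, p_{20}, q_{20})$ are swept
   over $[0,1]^3$; any triple whose trajectory leaves $[0,1]$ in any
   channel is discarded; the pointwise min/max over survivors are the
   *corridors* (`scan_corridors()`), and `extremal_trajectory()` picks the
   unique trajectory whose initial triple minimizes $q_{20}$ (can
   dedifferentiation be absent?) or maximizes $p_{10}$ (how much
   asymmetric division is sustainable?).

### Numerical choices

* Default sweep resolution 0.05 (9,261 triples) with finer resolutions
  available; the sweep is vectorized — every triple shares each step's
  $3\times 3$ matrix, so one set takes under a second at the default
  sizes.  Because corridors are unions over survivors, a coarse sweep
  bounds the fine-sweep corridor from inside.
* Two sweep passes are made: survivors are determined first, envelopes
  accumulated second, so a trajectory that dies late never contributes to
  early envelope values.
* Feasibility is checked with slack $10^{-9}$ to absorb roundoff at the
  0/1 boundary.  Feasibility of triples that start *exactly on* the
  simplex boundary with the minimal-change field initially pointing
  outward is step-size sensitive: a coarse step can jump over a
  $\sim 10^{-5}$ excursion.  Default step 0.01 for sweeps, $10^{-3}$ for
  single trajectories; halving the step quarters the global error
  (second order), which the tests assert by Richardson ratios.
* The closure is singular at $s = 0$ (division by $s(2-s)$); $s = 1$ — the
  sorted pure-CSC start — is regular, and the $(s-1)$ factors in the
  $p_1$/$q_2$ right-hand sides need no special-casing.
* The degenerate all-zero velocity quadratic returns an explicit
  "any fraction is stationary" sentinel rather than fake roots.

## Stage 2: underlying-field factor decomposition

The recovered probability trajectories are interpreted as responses to a
small set of secreted signaling factors ("underlying field").  Each factor
is a bump $u_k(t) = b_k e^{-a_k (t-c_k)^{m}}$ — width $a_k^{-1/m}$, center
$c_k$, even sharpness $m$ — and each probability channel is a weighted sum
$y_i(t) = \sum_k b_{ik} e^{-a_k(t-c_k)^m}$, the reported factor height
$b_k = \max_i |b_{ik}|$ acting as a relative-concentration proxy.  $m = 6$
by default (near-trapezoid plateaus; exposed as an even-integer
parameter).  Coefficients minimize the total quadratic deviation; fit
quality is reported as $\varepsilon$, the mean absolute deviation over all
channels and time points in percent of the unit probability scale
(`epsilon_deviation()`).

The stationarity system is solved by pseudo-time relaxation
(`fit_factors()`): repeated moves down the objective gradients in the
width, center and amplitude blocks.  We verified by re-derivation that the
printed stationarity conditions are the exact gradients of the objective
(including the amplitude equation, which needs no extra weighting factor),
so the relaxation is plain gradient descent in disguise.  Design choices
where the procedure was open:

* **Initialization** is deterministic: centers equispaced over the time
  span, widths sized so each bump covers span$/K$, amplitudes from linear
  least squares given that basis.  Seeded random restarts are available
  (`relaxation_config(n_restarts=)`), but the default path is
  reproducible bit-for-bit.
* **Step sizes** are adaptive rather than fixed: widths and centers move
  by per-coordinate backtracking line searches (a step that would increase
  the objective is halved; accepted steps restart at twice the previous
  one), and the amplitude block — whose subproblem is quadratic — moves by
  the closed-form exact step along its gradient direction.  The objective
  is therefore non-increasing across iterations by construction.
* **Stationarity** is declared when the scale-adjusted gradient magnitudes
  (width gradients weighted by $a$, i.e. measured on the width's own
  scale) fall below `tol` relative to the objective; hitting the
  iteration cap returns the best-so-far fit with a non-converged flag.
* **Factor count** (`select_factor_count()`): starting from
  $K_{\text{start}}$, $K$ is incremented until $\varepsilon <
  \varepsilon_p$ (default 1%).  The accepted set is then reduced by
  backward elimination: factors with height below 0.01 (1% of the
  probability scale) are dropped outright, and beyond that the
  smallest-height factor is removed and the set refitted for as long as
  the reduced fit still satisfies $\varepsilon_p$.  This finds the minimal
  essential set independently of the starting $K$ — entering 3-factor
  data at $K=4$ ends at 3 factors, while 5-factor data escalates to 5.
  Pure height thresholding is not enough on its own, because a good
  optimizer will happily share amplitude between redundant bumps.

## Stage 3: attribution to producing cell type

Each factor may be produced by stem cells, by non-stem cells, or without
explicit cell-type dependence.  `rank_attributions()` encodes an
assignment by multiplying each factor's basis by $s(t)$, $d(t) = 1 - s(t)$
or 1, refits widths/centers/amplitudes under the modulated basis
(warm-started from the unmodulated optimum), and ranks all $3^K$ variants
by $\varepsilon$.  The all-1 variant is always present and, refit from the
converged warm start, reproduces the unmodulated deviation — a built-in
consistency check.  Variants within $10^{-4}$ percentage points share a
tie group; when $s \equiv 1/2$ the S and D modulations coincide, S/D
labels are provably non-identifiable, and the ranking carries an explicit
degeneracy flag.  A `refit = FALSE` mode skips refitting (multiplication
only) for quick comparisons.  Enumeration is refused beyond $K = 8$
(6,561 variants).

## What the synthetic generator emulates — and what it does not

No public tabulated stabilization curve exists, so all validation inputs
are generated:

* `make_reference_curve()` produces the canonical monotone relaxation
  $s(t) = s_{eq} + (s_0 - s_{eq})e^{-kt}$ with analytic derivatives;
  defaults $s_0 = 1$, $s_{eq} = 0.1$, $k = 1$, a 10-day window sampled at
  201 points — a sorted pure-CSC population relaxing to a 10% basal
  fraction, stabilized well within the window.  Overshooting
  (non-monotone) stabilization is representable through the simulated
  provenance but is not the default.
* `make_ground_truth_bundle()` forward-simulates constant-probability
  dynamics in closed form (eigen-decomposition of the $2\times2$ system)
  and returns the curve with exact analytic $\dot s$, $\ddot s$, plus the
  generating probabilities — the closed-loop fixture behind the
  round-trip tests.
* `differentiate_sampled_curve()` mimics the measured-data path: an
  interpolating spline when `smoothing = 0` (exact for polynomial data up
  to degree 3), otherwise a smoothing spline with generalized
  cross-validation — the second derivative is noise-amplifying, and raw
  finite differences would be unusable on real FACS time series.  Noise
  fixtures use explicit seeds.

Passing tests on these fixtures show that the inverse machinery is
self-consistent (simulate → invert → recover truth; decompose → refit →
recover factors and assignments) under ideal, noise-free or mildly noisy
conditions on smooth monotone curves.  They do *not* show robustness to
real measured curves: FACS sampling is sparse (daily), marker-based CSC
calls are noisy and possibly biased, rates are assumed constant over the
window, and the bump family is one parametric choice among many.

## Problem sizes and reproducibility

The packaged validation (test suite and `scripts/acceptance.R`) uses: a
201-point, 10-day curve; sweep resolution 0.05 with step 0.01 (single
trajectories at $10^{-3}$); six rate sets $\lambda_1 = 1$,
$\lambda_2 \in \{1, 5, 10\}$, $\gamma_1 = 0.1$,
$\gamma_2 \in \{0.1, 0.5\}$ (measured non-stem proliferation and death
rates, with the stem rate varied over 1:1, 1:5, 1:10 division-rate
ratios); 3-factor fixtures over 20 seeds for recovery and 10 seeds for
attribution, on 101- and 61-point grids.  Every stochastic path is seeded;
identical configurations reproduce identical outputs, which the pipeline
tests assert byte-for-byte.

Under these conditions the q2 corridor floor rises strictly above zero at
some time points in all six rate sets — the model's signature claim that
dedifferentiation ($D \to S$) is *necessary* to reproduce stabilization.
The analogous ceiling on the asymmetric-division trajectory is curve
dependent: at $s_0 = 1$, $\lambda_1 = 1$ the feasible ceiling on $p_{10}$
is exactly $-\dot s(0) = k(s_0 - s_{eq})$, i.e. 0.9 for the default
generator, relaxing to $\approx 0.75$ under faster non-stem division; a
reported ceiling near 60% corresponds to a curve with a gentler initial
slope, not to a universal bound.

## Known limitations

* Rates $\lambda_i, \gamma_i$ are constants; time-varying rates are out of
  scope (the probabilities absorb all time dependence).
* The $D \to S+S$ and $D \to S$ scenarios are fixed at zero.
* The decomposition is not identifiable in general; near-ties in the
  attribution ranking (flagged via tie groups) signal that the best
  variant is unstable, and restart spread is a diagnostic, not a test.
* Corridors are pointwise envelopes: their boundaries are typically
  composed of pieces of different feasible trajectories, so a boundary
  curve need not itself be feasible.
* Stochastic single-cell effects and mixed per-factor production (partly
  S, partly D) are not modeled.
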