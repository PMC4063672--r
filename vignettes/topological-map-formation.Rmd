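---
title: "Topological map formation from place-cell coactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological map formation from place-cell coactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A rodent exploring an arena activates hippocampal place cells: each cell `c`
fires at a peak rate `f_c` when the animal is at the centre `r_c` of its
place field, with a Gaussian fall-off of width `s_c`,

    lambda_c(r) = f_c * exp(-|r - r_c|^2 / (2 s_c^2)).

The downstream read-out is assumed to see only *coactivity*: cells whose
spikes arrive within one integration window `w` are treated as simultaneous.
Every coactive group of `k + 1` cells contributes a `k`-simplex, stamped with
the first time the group was observed. The result is a *temporal complex*
`T(t)` that only grows with session time — a filtered simplicial complex
whose filtration parameter is elapsed experience, not a geometric radius.
The topology available to the animal at time `t` is summarised by the Betti
numbers `beta_0(t)` (connected components) and `beta_1(t)` (independent
loops), computed by persistent homology over Z/2. When `(beta_0, beta_1)`
first equals the arena's true values and stays there for the rest of the
session, the map has formed; that first time is the minimal learning time
`T_min`. Loops that appear and later die are topological noise — *spurious
loops* — whose lifetimes, counts and decay are diagnostics of the learning
process.

An ensemble is parameterised by its size `N`, mean peak rate `f` and mean
field width `s`; per-cell rates and widths are log-normal around the means
with sd `a*f` and `b*s` (`a = b = 0.3` by default, moment-matched so that the
arithmetic mean and sd equal the nominal values). Field centres are
re-scattered uniformly at every simulation repeat while the trajectory stays
fixed; the fraction of repeats that converge is `rho` and the relative spread
of the learning time is `xi = sd(T_min)/mean(T_min)`. The *learning region*
is the set of `(N, f, s)` with reliable map formation; its core is defined by
`rho >= 0.7` and `xi <= 0.3`.

## Theta-phase precession

A theta signal (6–12 Hz) modulates spiking. As the animal crosses a field of
extent `L = 3 s`, the cell's preferred phase falls linearly from `2*pi` at
entry to `0` at exit (`preferred_phase()`), and the rate is multiplied by a
wrapped-Gaussian factor in phase whose width is `2*pi*epsilon` with
`epsilon = v / (L f_theta)` — the fraction of the field crossed per theta
cycle, evaluated with the locally smoothed (200 ms) running speed.

By default the factor is *rate-preserving*: it is divided by its average
over a uniform phase cycle (capped at 3), so precession redistributes spikes
within the theta cycle without changing a cell's excitability. This choice
is forced by the physics of the model: the raw peak-1 factor has a cycle
average of roughly `sqrt(2*pi)*epsilon` (about 0.5 at our field sizes and
far smaller for large fields), so a non-normalized factor would simply thin
every spike train several-fold and slow all learning — the opposite of the
phenomenon under study. With the rate-preserving factor, phase-bunching
leaves saturated in-field coactivity intact while suppressing weak
incidental coincidences (the detection probability `1 - exp(-x)` is concave
in the per-bin intensity `x`, so a mean-preserving spread of `x` lowers it),
which is precisely the mechanism by which precession protects the map from
spurious attachments. The raw `[0, 1]` factor remains available
(`renormalize = FALSE`), and `precession_factor()` itself is the plain
peak-1 bump. Supported rhythms: a pure 8 Hz sinusoid, a band-passed
four-sinusoid mixture (6.5, 8.65, 10.0, 11.5 Hz), or any externally sampled
trace, band-passed 6–12 Hz with a zero-phase FFT filter (full gain inside
the band, half-cosine transitions 0.5 Hz wide placed just inside the
corners, so out-of-band power is fully removed — an IIR band-pass of modest
order leaves several percent of power in the transition skirts, violating
the ≤1% out-of-band contract); instantaneous phase comes from the analytic
signal.

## Geometry, units and the learning region's location

Lengths are metres internally (field widths accepted in cm), times in
seconds; a theta-period is fixed at 125 ms for window-width conversions.
The default arena is 1×1 m with a 0.3×0.3 m central hole, so the true
signature is `(beta_0, beta_1) = (1, 1)`.

With `s` the *Gaussian width* and extent `L = 3 s`, a hole is resolvable
only when fields are several times smaller than the hole: at `s` around
20 cm the rate at cross-hole distances is still ~half the peak, cross-hole
groups form in any window, and the hole's loop is destroyed — no parameter
choice can recover `(1, 1)`. The learning region of this implementation
therefore sits at `s ≈ 5–6 cm` with `f ≈ 20–30 Hz` and `N ≈ 250–500`,
rather than spanning field widths up to 30 cm. Consequences worth knowing:

* connectivity indices at `T_min` (`eta_1 = f_1 / choose(N, 2)`, `eta_2`)
  land in the ~5–25% range at our corners rather than extending down to the
  ~1.5% seen for very large, low-rate fields;
* the convergence collapse at `w` of a few theta-periods requires fields
  broad enough that a window groups cells across the hole; with small
  fields the hole-crossing time is ~10 theta-periods and no collapse occurs
  inside the scanned `0.1–5` range;
* at small windows the learning time grows so steeply that `T_min(w)` near
  the opening width exceeds any desk-scale horizon, which biases the
  measured opening width upward (the scan reports the first width that
  converges before the horizon).

## Synthetic data: what it emulates, what it does not

The trajectory generator produces a correlated random walk (Ornstein–
Uhlenbeck heading, ±20% speed jitter) at 25 cm/s with `dt = 10 ms`,
reflecting off walls and holes; 30 minutes covers >99% of 5 cm occupancy
bins. It emulates steady exploratory coverage, not goal-directed behaviour,
thigmotaxis, immobility bouts or theta-speed coupling. Spike trains are
inhomogeneous Poisson via two-stage thinning (field rate, then modulation),
without refractoriness, bursting beyond the Poisson statistics, or
multi-field cells. Passing tests on these data show that the
coactivity-to-topology pipeline behaves as designed; they do not show that
real spike trains meet the model's independence assumptions.

## Time-developing place fields

With `dynamic_fields = TRUE`, both the amplitude and the width of each field
follow a logistic sigmoid in time with per-cell constant `tau` (log-normal
around `tau_mean = 240` s), placed so the amplitude at `t = 0` is below 2%
and the field is essentially formed after `tau` seconds — matching the
observation that fields form in about four minutes — plus a 0.1 Hz
background that fades as the field forms. In a monotone filtration the
background is hazardous: spatially random coincidences create edges that
never die. The dynamics experiment therefore runs the read-out burst-gated
(`min_spikes = 3` per cell per bin at `w = 4` theta-periods, for both the
static and the dynamic arm), which drops the expected number of background
coincidences over a session below one while keeping in-field detection
near certainty. The reported quantity is the median paired difference
`T_min(dynamic) - T_min(static)` in units of `tau_mean`.

## Numerical choices

* Persistence: Z/2 boundary-matrix column reduction with clearing
  (compiled); simplices capped at dimension 3, homology reported for
  dimensions 0–2; zero-persistence pairs are dropped; classes alive at the
  end of the filtration are open bars and count as persistent features.
* `T_min` detection scans the Betti trace at the filtration steps and takes
  the first time after the last disagreement with the true signature;
  ties in identifying "the" persistent loops are broken by earlier birth;
  open spurious bars are censored at the horizon and flagged.
* Horizon: the session end (capped at 60 min); non-convergence is declared
  beyond it.
* Coactivity: fixed consecutive bins (shifts and ≤50% edge jitter are
  exposed as robustness probes, since they leave `T_min` within the
  between-repeat spread); at least one spike per cell per bin by default,
  the threshold configurable as described above. Bin times are the bin
  start; simplices come from the coactive set of the bin directly rather
  than from a clique completion of the pairwise graph (a read-out neuron
  sees the group event), with a configurable alternative left out of scope.
* Window scan: log-spaced grid (24 widths over 0.1–5 theta-periods by
  default); plateau tolerance 10% on successive relative changes of
  `T_min(w)`; opening width is the first width with any convergence
  (`rho > 0`); the power-law exponent grid is `seq(1.05, 1.95, length 12)`
  and the fit minimises the coefficient of variation of `T_min * w^alpha`.
* GEV fitting is direct maximum likelihood (Nelder–Mead over location,
  log-scale and shape, three shape starts); modes are reported from the
  fitted density, never from histogram bins. Gamma and normal fits are
  MLE; KS comparison matrices are reported at a raw `alpha = 0.05`.
* Mayer–Vietoris subdivision cuts the arena with vertical lines that must
  miss all holes (so region intersections are contractible); each region is
  learned on its own occupancy clock, with restriction at the bin level to
  avoid splicing disjoint visits into false coactivity; regions much
  narrower than 2–3 field extents are flagged.
* Seeds: a master seed fans out to component child seeds by a fixed affine
  map (`child_seeds()`), so any component's stream can be changed in
  isolation.

## Reduced study conditions used by the checks

The full sweeps (1710 ensembles × 10 repeats × several theta conditions,
24-width scans) are cluster-scale. The packaged checks run: a 2×2×2 grid
(`N` in {250, 450} × `f` in {24, 28} Hz × `s` in {5, 5.5} cm) with 2–4
repeats and 15-minute sessions for the theta comparisons and connectivity
ranges; a 10-width scan at the reference-core ensemble (`N = 350`,
`f = 28`, `s = 5`); two ensemble sizes × 2 repeats × 30-minute sessions for
the formation experiment; and three repeats of the 2×2 two-hole subdivision
experiment. At this scale the robust theta reproductions are the shortening
of spurious-loop lifetimes, the lower peak loop count and the reduced
variability of the learning times; the typical-`T_min` and mean-loop-count
comparisons are strongly seed-dependent, because the theta benefit in this
field-size regime concentrates at the boundary of the learning region where
phase concentration protects the hole from being bridged. These sizes are the package's choices for a single-CPU
workflow; all of them are plain arguments, so any of the experiments scales
up by passing larger grids, longer sessions and more repeats.

## Known limitations

* The field-size regime is constrained by the hole geometry (see above);
  reproducing phenomena that depend on fields comparable to the arena
  requires either larger holes or the understanding that the hole becomes
  invisible.
* Homology is reported in dimensions 0–1 (2 available); no persistence
  landscapes or higher topology.
* The Poisson read-out has no synaptic or biophysical detail; the
  coactivity window is a single abstraction parameter.
* Learning times inherit heavy-tailed variability across centre draws;
  desk-scale repeats estimate typical values with wide error bars, which is
  why the robust summaries (medians, fitted modes) are used throughout.

## A worked example

```{r example}
library(topolearn)

arena <- make_arena(1, 1, holes = list(c(0.35, 0.35, 0.65, 0.65)))
trajectory <- generate_trajectory(arena, duration = 900, seed = 7)
theta <- make_theta("single", duration = 901)

spec <- ensemble_spec(N = 350, f_mean = 28, s_mean = 5)
ensemble <- sample_ensemble(spec, arena, seed = 5)

run <- run_learning(ensemble, arena, trajectory, theta,
                    window = coactivity_window(w = 0.25),
                    horizon = 900, seed = 9)
run$outcome          # converged? T_min?
betti_curve(run$barcode, c(60, 120, 300, 600))
f_vector(run$complex, run$outcome$t_min, N = 350)$eta
```
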