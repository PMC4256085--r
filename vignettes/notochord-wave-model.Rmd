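---
title: "Modelling the stochastic G1/S transition wave in the developing notochord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the stochastic G1/S transition wave in the developing notochord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notowave)
```

## The biological problem

During zebrafish axial development, newly formed notochordal cells are
arranged as two anterior-to-posterior columns (dorsal "upper" and ventral
"lower"). With the Fucci cell-cycle reporter their nuclei are red in G1 and
green from S phase onward, and live imaging at 2.5-min frames shows a mixed
red/green region — the *G1/S transition window* — travelling posteriorly as
the body axis elongates. The transition of each individual cell is
strikingly stochastic: cells do not enter S phase in spatial order. The
question this package addresses is what *regulatory mode* hides underneath
that noise: does the licensing signal travel continuously, or in discrete
periodic steps, and with what period relative to the neighbouring
segmentation clock?

## The model

Cells occupy a one-dimensional lattice `i = 1..n`. A signal-transmitting
wave licenses cells in steps of `z` cell diameters: step `k` fires at

```
t_k = k * L_c * z / (lambda * dt)     [frames]
```

where `L_c = 5` µm is the cell diameter, `lambda = 4/3` µm/min the
posterior elongation speed and `dt = 2.5` min the frame interval. After
step `k`, cells `1..k*z` are licensed. Once licensed, a G1 cell enters S
phase in each frame with probability `alpha_dt`, independently of every
other cell; the transition is irreversible. `z = 1` gives a continuous
wave; `z = 8` advances one somite width per 30-min segmentation-clock
cycle; `z = 16` and `z = 24` are the two- and three-fold periodic modes
(periods `z * L_c / lambda` = 60 and 90 min). The somite width in cells,
`T_som * lambda / L_c = 8`, ties the lattice to the embryo's geometry.

Two modelling choices are exposed rather than hard-coded:

* **Step origin.** No cell is licensed before `t_1` by default
  (`license_from_step_one = TRUE`); setting it `FALSE` licenses the first
  `z` cells from frame 0. Both readings are defensible from the observed
  wave pattern; the default starts the lattice fully unlicensed, which
  matches an all-G1 initial condition.
* **Step boundaries.** `t_k` values such as `3k/2` (for `z = 1`) are not
  representable exactly in floating point, so the licensing comparison
  uses `t_k <= t + 1e-9`; steps that land exactly on a frame behave as in
  exact arithmetic.

## Estimating the transition probability

Because upper and lower cells at the same position are licensed
simultaneously but transition independently, the signed difference of
their S-entry frames does not depend on the licensing schedule. For a
geometric waiting time with per-frame probability `p` the difference
`t = t1 - t2` of two independent cells has the closed form

```
g(t; p) = p * (1 - p)^|t| / (2 - p)
```

which the test suite validates against a brute-force truncated double sum
before it is used anywhere. `fit_transition_prob()` minimizes the residual
sum of squares between `g(t; p)` and the empirical difference pmf
(tabulated on every integer between the observed extremes, zeros
included) with a derivative-free simplex search on `logit(p)` started at
`p = 0.2`; the logit transform keeps the estimate in (0, 1) without
explicit constraints. Signed differences are the default; `fold = TRUE`
fits the folded `|t|` distribution instead and agrees closely. An
all-zero difference sample drives the estimate to the `p = 1` boundary
and is flagged as degenerate rather than silently reported.

On data simulated at the experimentally estimated probability
`p = 0.1101`, 500 pairs recover `p` to about ±0.01–0.02; the working
value used throughout the model analysis is `alpha_dt = 0.1` (about 10%
of licensed G1 cells transition per 2.5-min frame).

## Scoring and calling conventions

* **Transition calling.** A cell's entry frame is the earliest frame
  starting a run of `persistence = 5` consecutive frames with green
  strictly above red. "Strictly" means ties break the run, and a run
  truncated by the end of the recording never qualifies. The reported
  frame is the *first* frame of the run, i.e. the crossing frame.
* **Synthetic traces.** The generator draws logistic rise/fall curves
  whose continuous crossing sits half a frame before the true entry
  frame, so on the integer frame grid green first strictly exceeds red
  exactly at the entry frame and the noiseless round trip
  (truth → traces → calling) is exact. The imaging study does not report
  trace noise magnitudes; the defaults (peaks 100, `noise_sd = 5`,
  `rise_width = 8` frames) give a caller error distribution that is
  nontrivial but small, which is all the downstream tests require of
  them. Censored cells are rendered red-dominant throughout.
* **Landmarks.** The PGC (posterior-most green cell) is the largest
  S-phase index in a row, the ARC (anterior-most red cell) the smallest
  G1 index. PGC waiting times are the frames between successive strict
  increases of the PGC position; the first appearance starts the clock,
  and a multi-cell jump counts as one advance event. The transition
  window is the PGC plus the 7 cells anterior to it; when the PGC sits
  closer than 8 cells to the anterior boundary the count runs over the
  existing positions and the frame is flagged as clipped. Pair counts
  use the lower-row PGC as landmark by default.
* **Deterministic limit.** At `alpha_dt = 1` every licensed cell
  transitions immediately, the front is sharp, and the ARC sits exactly
  one cell behind the PGC — the transition window is empty, which is how
  the "coinciding" landmark trajectories of the deterministic model are
  checked. In that limit the PGC-anchored window is always fully green,
  so the window count is constant; the window-count oscillations only
  appear in stochastic runs.

## Linkage nulls

Whether S-phase entries of facing upper/lower cells are coupled is judged
against two Monte-Carlo nulls that keep each frame's observed green
counts fixed: a *random* null (both rows placed uniformly; expectation
`g_u * g_l / window`, which the implementation reproduces and the tests
verify by exhaustive enumeration) and a *biased* null in which a
uniformly chosen still-red lower site turns green with probability
`q = 0.9` when its upper partner is green and `1 - q` otherwise, until
the observed count is placed. The biased placement is simulated literally
(sequential proposals with rejection); an exact recursion over placement
orders on a 4-cell window serves as its oracle in the tests. At
`q = 0.5` the biased null collapses onto the random one, and it is
monotone in `q`. The defaults follow the published analysis
(`reps = 10000`, `q = 0.9`, `window = 8`); no formal hypothesis test is
attached — the comparison is by fit of the observed pair-count curve, and
independent simulated rows indeed track the random null.

## Model selection by KL distance

The experimental PGC waiting-time distribution `p(x)` is compared with
distributions `q(x)` simulated under each candidate `z` via the
Kullback-Leibler distance `D(p, q) = sum p(x) log(p(x)/q(x))` in nats
(the base only rescales all comparisons). Each candidate is simulated
repeatedly (300 replicates in the headline setting), each replicate
pooling the upper and lower PGC intervals of one paired lattice, and the
mean and SD of the replicate KL values rank the models; replicate KL
samples of different candidates are compared with two-sample KS tests.

Numerical choices:

* **Zero handling.** A finite simulation can leave `q(x) = 0` where the
  data have mass. Only in that case `q` is regularized with a
  pseudo-count `eps = 1/(N_q + S)` per union-support bin (`N_q` =
  simulated interval count, `S` = union support size) before
  renormalization. This keeps `D` finite, barely distorts well-populated
  bins, and leaves `D(p, p) = 0` exact.
* **Binning.** Intervals are binned at 1 frame (2.5 min); minute
  conversion happens only at reporting.
* **Replicate size.** The published analysis does not state the
  simulation size behind each of its 300 KL replicates; this package
  defaults to `n_cells = 100`, `t_max = 240` frames (600 min), which
  gives each replicate a pooled interval sample of the same order as one
  imaging session, and both are configurable.

Sensitivity sweeps rerun the selection over `alpha_dt` in 0.07–0.12 and
over a 7-cell somite-width assumption (candidates `z = 1, 7, 14, 21`;
two-fold period `14 * 5 / (4/3) = 52.5` min).

## What the synthetic generator does and does not emulate

The generator reproduces the statistical structure the analysis relies
on: geometric licensing-to-entry waits, a shared wave schedule with
independent rows, monotone states, censoring at the observation horizon,
and smooth noisy channel crossings. It does not emulate cell division,
rearrangement or movement along the axis, intensity bleaching or
background drift, segmentation errors, or embryo-to-embryo parameter
variability. Passing tests therefore demonstrate that the pipeline's
inference is correct *under the model's own assumptions*, not that those
assumptions hold in any particular imaging dataset.

## Problem sizes used in the tests

The packaged checks run the model-recovery experiment at
`n_cells = 100`, `t_max = 240`, 50 KL replicates per candidate and 20
seeds (the published analysis used 300 replicates; the ranking is stable
well below that), interval-shape checks on longer single runs
(`t_max = 500–700`), and linkage curves at 1000–2000 Monte-Carlo
repetitions per frame. These sizes keep every distributional check
comfortably inside its Monte-Carlo error while remaining quick to run.

## Known limitations

* The estimator assumes both members of a pair are licensed at the same
  frame; systematic upper/lower licensing offsets would bias `p_hat`.
* KL ranking is a relative criterion: it selects the best of the offered
  candidates and does not assess absolute goodness of fit (no AIC/BIC or
  Bayesian comparison is provided, matching the published approach).
* The ARC carries little wave information — selection based on ARC
  intervals recovers the truth less often, which the tests check
  directionally — so analyses should use PGC intervals.
* All spatial statistics assume a fixed lattice without cell
  rearrangement; applying them to tissues with significant cell mixing
  would require tracking-aware preprocessing upstream of this package.
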