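# notowave

Quantitative analysis of the stochastic G1/S transition in the developing
zebrafish notochord from Fucci live-imaging data.

In the embryonic notochord, two anterior-to-posterior columns of cells
(dorsal/"upper", ventral/"lower") switch their Fucci reporter from red
(G1) to green (S/G2/M) as a mixed-color *G1/S transition window* travels
posteriorly with body-axis elongation. Individual transitions are highly
stochastic, which hides the underlying regulatory mode. `notowave` is for
developmental biologists and modellers who want to infer that mode from
imaging-derived intensity traces or binarized state tables.

## The model

Cells sit on a 1-D lattice `i = 1..n`. A travelling wave licenses cells
in steps of `z` cell diameters at frames

    t_k = k · L_c · z / (λ · Δt),    k = 1, 2, ...

with cell diameter `L_c = 5` µm, elongation speed `λ = 4/3` µm/min and
frame interval `Δt = 2.5` min (one somite = `T·λ/L_c = 8` cells). A
licensed G1 cell enters S phase with probability `αΔt` per frame,
independently and irreversibly. `z = 1` is a continuous wave; `z = 8`
steps once per 30-min segmentation-clock cycle; `z = 16` and `z = 24`
have two- and three-fold that period.

Around this model the package provides:

* **Transition calling** — `call_transition()`, `binarize_traces()`:
  crossing-point rule with a 5-frame persistence requirement.
* **Window scoring** — `window_series()`, `landmark_intervals()`,
  `interval_distribution()`: PGC/ARC landmarks, window green counts,
  green-pair counts, and PGC waiting-time distributions.
* **Linkage nulls** — `null_pair_expectation()`, `linkage_curves()`:
  Monte-Carlo random and biased (q = 0.9) placement nulls for
  independence of S-entry between the two columns.
* **Probability estimation** — `fit_transition_prob()`: least-squares
  fit of the closed-form difference-of-geometrics distribution
  `g(t; p) = p(1−p)^|t|/(2−p)` to paired upper/lower entry-time
  differences, returning a `"gs_fit"` model object with the usual
  `coef`/`predict`/`plot`/`simulate` methods.
* **Model selection** — `select_wave_model()`, `sensitivity_sweep()`:
  Kullback-Leibler ranking of candidate `z` values against the PGC
  waiting-time distribution over repeated simulations, with pairwise KS
  tests.
* **Synthetic data** — `generate_lattice()`, `render_traces()`: model
  draws with known truth and noisy red/green traces with known crossing
  frames, so the whole pipeline is testable without raw images.
* **Pipeline** — `run_pipeline()`: synth → call → score → linkage →
  estimate → select, with TSV/JSON outputs and a reproducibility
  manifest.

## Worked example

Simulate a two-fold periodic "experiment", estimate the transition
probability from paired entry-time differences, and let the KL selection
recover the generating model:

```r
library(notowave)

cfg <- model_config(z = 16, t_max = 240, seed = 42)
lat <- generate_lattice(cfg)

fit <- fit_transition_prob(lat$entry)
fit
#> Per-frame G1/S transition probability (least-squares fit of the
#> two-sided geometric difference distribution)
#>
#>   p_hat = 0.1116 per frame   (n = 100 pairs, rss = 0.00813)

expd <- interval_distribution(lattice_intervals(lat))
sel <- select_wave_model(expd, c(1, 8, 16, 24), cfg, reps = 50, seed = 1)
sel
#> Wave-model selection by KL distance (pgc intervals, 50 reps)
#>
#>   z               label mean_kl  sd_kl
#>   1          continuous   1.639 0.1126
#>   8            periodic   1.450 0.2039
#>  16   two-fold periodic   1.101 0.3653
#>  24 three-fold periodic   1.470 0.2969
#>
#> Selected: z = 16 (two-fold periodic)
```

The fitted `p_hat ≈ 0.11` recovers the generating `αΔt = 0.1` (about 10%
of licensed G1 cells transition per 2.5-min frame), and the two-fold
periodic wave (60-min period) attains the lowest mean KL distance among
the four candidate regulatory modes.

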