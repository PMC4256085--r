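#' Wave step schedule of the signal-transmitting function
#'
#' The regulatory wave licenses cells in steps of `z` cells. Step `k`
#' fires at frame `t_k = k * L_c * z / (lam * dt)` (the time for the
#' elongating embryo to add `z` cell diameters, expressed in frame
#' units), and after it fires cells `1 .. k*z` satisfy the licensing
#' condition of the signal-transmitting function. The number of steps
#' `m` is chosen to exceed `m_c = lam * dt * t_max / (L_c * z)` so the
#' schedule covers the whole simulation.
#'
#' @param config A [model_config()].
#' @return An object of class `"wave_schedule"`: list with elements
#'   `t_k` (frame times of steps 1..m, possibly non-integer), `z`,
#'   `m`, `dt`, `period_min` (inter-step interval `z * L_c / lam` in
#'   minutes) and `base` (cells licensed before the first step: 0, or
#'   `z` when `license_from_step_one = FALSE`).
#' @examples
#' ws <- wave_schedule(model_config(z = 8))
#' ws$period_min        # 30 min: one somite per segmentation-clock cycle
#' diff(ws$t_k)[1] * 2.5
#' @export
wave_schedule <- function(config) {
  stopifnot(inherits(config, "model_config"))
  step_frames <- config$L_c * config$z / (config$lam * config$dt)
  m_c <- config$lam * config$dt * config$t_max / (config$L_c * config$z)
  m <- max(1L, as.integer(ceiling(m_c)) + 1L)
  structure(
    list(t_k = seq_len(m) * step_frames,
         z = config$z, m = m, dt = config$dt,
         period_min = config$z * config$L_c / config$lam,
         base = if (config$license_from_step_one) 0L else config$z,
         n_cells = config$n_cells),
    class = "wave_schedule"
  )
}

#' @export
print.wave_schedule <- function(x, ...) {
  cat(sprintf("Wave schedule: z = %d, %d steps, period %.4g min (%.4g frames)\n",
              x$z, x$m, x$period_min, x$period_min / x$dt))
  cat("  first steps at frames:",
      paste(signif(utils::head(x$t_k, 5), 4), collapse = ", "),
      if (x$m > 5) "..." else "", "\n")
  invisible(x)
}

#' Position of the licensing front at a frame
#'
#' @param t Frame index (0-based); may be a vector.
#' @param wave A [wave_schedule()].
#' @return Integer vector: the largest licensed cell index at each `t`
#'   (0 if no cell is licensed yet).
#' @export
front_position <- function(t, wave) {
  stopifnot(inherits(wave, "wave_schedule"), is.numeric(t), all(t >= 0))
  # tolerance absorbs floating-point error when t_k lands on a frame exactly
  vapply(t, function(tt) wave$base + wave$z * sum(wave$t_k <= tt + 1e-9),
         numeric(1))
}

#' Has the regulatory signal reached a cell?
#'
#' A cell is licensed for the G1/S transition once the travelling wave
#' front has passed its position, i.e. once `i <= z * #{k : t_k <= t}`.
#'
#' @param i Cell position(s), 1-based anterior-to-posterior.
#' @param t Frame index (0-based, scalar).
#' @param wave A [wave_schedule()].
#' @return Logical vector along `i`.
#' @examples
#' w <- wave_schedule(model_config(z = 8, t_max = 60))
#' signal_arrived(1:16, t = 12, wave = w)  # first somite width licensed
#' @export
signal_arrived <- function(i, t, wave) {
  stopifnot(inherits(wave, "wave_schedule"))
  if (!is.numeric(i) || any(i < 1) || any(i != as.integer(i))) {
    stop("'i' must be positive integer cell positions", call. = FALSE)
  }
  if (any(i > wave$n_cells)) {
    stop("'i' exceeds the lattice length", call. = FALSE)
  }
  stopifnot(length(t) == 1L, t >= 0)
  i <= front_position(t, wave)
}

#' Simulate one cell column of the stochastic G1/S lattice model
#'
#' All cells start in G1 at frame 0. At each frame step, every cell
#' that is licensed by the wave and still in G1 enters S phase with
#' probability `alpha_dt`, independently of all other cells; the
#' transition is irreversible.
#'
#' @param config A [model_config()]. Its `seed` (if non-NULL) fixes the
#'   RNG for this run.
#' @param wave Optional precomputed [wave_schedule()]; built from
#'   `config` when missing.
#' @return List with `states` (an `n_cells x t_max` 0/1 integer matrix,
#'   columns are frames 0 .. t_max-1, 1 = S) and `entry_frames`
#'   (integer vector; frame of S entry per cell, `NA` if the cell never
#'   transitions within `t_max`).
#' @examples
#' run <- simulate_row(model_config(alpha_dt = 1, z = 8, n_cells = 24,
#'                                  t_max = 60, seed = 1))
#' run$entry_frames[1:8]  # first somite width enters S at frame 12
#' @export
simulate_row <- function(config, wave = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(wave)) wave <- wave_schedule(config)
  with_seed(config$seed, simulate_row_impl(config, wave))
}

simulate_row_impl <- function(config, wave) {
  n <- config$n_cells
  t_max <- config$t_max
  entry <- rep(NA_integer_, n)
  in_g1 <- rep(TRUE, n)
  states <- matrix(0L, nrow = n, ncol = t_max)
  if (t_max >= 2L) {
    for (t in seq_len(t_max - 1L)) {  # frames 1 .. t_max-1
      front <- wave$base + wave$z * sum(wave$t_k <= t + 1e-9)
      if (front >= 1L) {
        idx <- which(in_g1[seq_len(min(front, n))])
        if (length(idx)) {
          flip <- idx[stats::runif(length(idx)) < config$alpha_dt]
          if (length(flip)) {
            in_g1[flip] <- FALSE
            entry[flip] <- t
          }
        }
      }
      states[!in_g1, t + 1L] <- 1L
    }
  }
  list(states = states, entry_frames = entry)
}

#' Simulate a two-column (upper/lower) notochord lattice
#'
#' The upper and lower cell columns are two independent realisations of
#' the stochastic model sharing one wave schedule: transitions in one
#' column do not influence the other (the experimentally supported
#' independence assumption).
#'
#' @param config A [model_config()]; `config$seed` (if non-NULL) makes
#'   the pair reproducible.
#' @return An object of class `"state_lattice"`: list with `states`
#'   (list of 0/1 matrices `upper`, `lower`), `entry` (data frame with
#'   columns `row`, `position`, `entry_frame`; `entry_frame` is `NA`
#'   for censored cells), `dt` and `config`.
#' @examples
#' lat <- simulate_lattice(model_config(z = 16, seed = 42))
#' head(lat$entry)
#' @export
simulate_lattice <- function(config) {
  stopifnot(inherits(config, "model_config"))
  wave <- wave_schedule(config)
  runs <- with_seed(config$seed, list(
    upper = simulate_row_impl(config, wave),
    lower = simulate_row_impl(config, wave)
  ))
  entry <- data.frame(
    row = rep(c("upper", "lower"), each = config$n_cells),
    position = rep(seq_len(config$n_cells), 2L),
    entry_frame = c(runs$upper$entry_frames, runs$lower$entry_frames),
    stringsAsFactors = FALSE
  )
  structure(
    list(states = list(upper = runs$upper$states, lower = runs$lower$states),
         entry = entry, dt = config$dt, config = config),
    class = "state_lattice"
  )
}

#' @export
print.state_lattice <- function(x, ...) {
  n <- nrow(x$states$upper)
  tm <- ncol(x$states$upper)
  n_s <- sum(x$states$upper[, tm]) + sum(x$states$lower[, tm])
  cat(sprintf("State lattice: 2 rows x %d cells x %d frames (dt = %.3g min)\n",
              n, tm, x$dt))
  cat(sprintf("  %d of %d cells in S at the final frame; %d censored\n",
              n_s, 2L * n, sum(is.na(x$entry$entry_frame))))
  invisible(x)
}

#' Plot a state lattice as a time-space map
#'
#' Draws the binarized G1 (red) / S (green) states of both cell columns
#' on the plane of time and anterior-posterior position.
#'
#' @param x A `"state_lattice"`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.state_lattice <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (rw in c("upper", "lower")) {
    st <- x$states[[rw]]
    graphics::image(x = (seq_len(ncol(st)) - 1L) * x$dt,
                    y = seq_len(nrow(st)), z = t(st),
                    col = c("#D7301F", "#31A354"), zlim = c(0, 1),
                    xlab = "time (min)", ylab = "position (cell)",
                    main = paste(rw, "row"), ...)
  }
  invisible(x)
}
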