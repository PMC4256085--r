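#' Model configuration for the travelling-wave G1/S lattice model
#'
#' Bundles the physical and model parameters of the stochastic G1/S
#' transition model: a one-dimensional anterior-to-posterior lattice of
#' notochordal cells is licensed by a travelling regulatory wave, and each
#' licensed G1 cell enters S phase independently with probability
#' `alpha_dt` per imaging frame.
#'
#' Defaults follow the imaging setup and measured embryo geometry: frames
#' every 2.5 min, cell diameter 5 um, posterior elongation speed 4/3
#' um/min, segmentation-clock period 30 min (so one somite spans
#' `T_som * lam / L_c = 8` cells), and per-frame transition probability
#' 0.1.
#'
#' @param alpha_dt Probability that a licensed G1 cell enters S phase
#'   within one frame; in (0, 1].
#' @param z Wave step size in cells (positive integer). `z = 1` is the
#'   continuous wave; `z = 8` advances one somite width per step (30-min
#'   period); `z = 16` and `z = 24` are the two- and three-fold periodic
#'   modes.
#' @param L_c Cell diameter in micrometres.
#' @param lam Posterior elongation speed in micrometres per minute.
#' @param dt Imaging frame interval in minutes.
#' @param T_som Segmentation-clock period in minutes.
#' @param n_cells Number of lattice positions (anterior to posterior).
#' @param t_max Number of frames simulated (frames are 0 .. t_max - 1).
#' @param seed Integer RNG seed, or `NULL` to use the session RNG state.
#' @param license_from_step_one Logical; if `TRUE` (default) no cell is
#'   licensed before the first wave step fires at `t_1`. If `FALSE` the
#'   first `z` cells are licensed from frame 0.
#'
#' @return An object of class `"model_config"`: a named list of the
#'   validated parameters.
#' @examples
#' cfg <- model_config(z = 16)
#' cfg$T_som * cfg$lam / cfg$L_c  # cells per somite width
#' @export
model_config <- function(alpha_dt = 0.1, z = 8L, L_c = 5, lam = 4 / 3,
                         dt = 2.5, T_som = 30, n_cells = 100L,
                         t_max = 120L, seed = NULL,
                         license_from_step_one = TRUE) {
  check_prob(alpha_dt, "alpha_dt")
  check_count(z, "z")
  for (nm in c("L_c", "lam", "dt", "T_som")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
    }
  }
  check_count(n_cells, "n_cells")
  check_count(t_max, "t_max")
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("'seed' must be a single integer or NULL", call. = FALSE)
    }
    seed <- as.integer(seed)
  }
  stopifnot(is.logical(license_from_step_one), length(license_from_step_one) == 1L)
  structure(
    list(alpha_dt = alpha_dt, z = as.integer(z), L_c = L_c, lam = lam,
         dt = dt, T_som = T_som, n_cells = as.integer(n_cells),
         t_max = as.integer(t_max), seed = seed,
         license_from_step_one = license_from_step_one),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("G1/S travelling-wave model configuration\n")
  cat(sprintf("  alpha_dt : %.4g per %.3g-min frame\n", x$alpha_dt, x$dt))
  cat(sprintf("  z        : %d cells per wave step (period %.4g min)\n",
              x$z, x$z * x$L_c / x$lam))
  cat(sprintf("  lattice  : %d cells x %d frames (%.4g min)\n",
              x$n_cells, x$t_max, x$t_max * x$dt))
  cat(sprintf("  geometry : L_c = %.3g um, lambda = %.4g um/min, T_som = %.3g min\n",
              x$L_c, x$lam, x$T_som))
  invisible(x)
}

# --- internal validation helpers -------------------------------------------

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1) {
    stop(sprintf("'%s' must be a single probability in (0, 1]", name),
         call. = FALSE)
  }
  invisible(p)
}

check_count <- function(n, name) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      n != as.integer(n)) {
    stop(sprintf("'%s' must be a single positive integer", name),
         call. = FALSE)
  }
  invisible(as.integer(n))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; a NULL seed just evaluates the expression.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
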