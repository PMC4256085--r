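#' Monte-Carlo null expectation of the green-pair count
#'
#' Expected number of upper/lower green-cell pairs in a window under
#' two in-silico nulls, keeping the observed number of green cells per
#' row fixed. In the random null both rows receive their green cells at
#' uniformly random distinct sites. In the biased null the upper row is
#' random and the lower row is filled one cell at a time: a uniformly
#' chosen still-red lower site turns green with probability `q` when
#' its upper partner is green and `1 - q` otherwise, until the observed
#' lower green count is reached — so `q > 0.5` couples the rows
#' positively.
#'
#' @param g_upper,g_lower Observed green-cell counts in the window, in
#'   `0 .. window`.
#' @param mode `"random"` or `"biased"`.
#' @param q Coupling probability of the biased null.
#' @param reps Number of Monte-Carlo repetitions.
#' @param window Window width in cells.
#' @param seed Optional RNG seed.
#' @return The Monte-Carlo mean pair count (numeric scalar), with the
#'   standard error of the mean attached as attribute `"se"`.
#' @examples
#' null_pair_expectation(4, 4, "random", reps = 2000, seed = 1)  # ~ 4*4/8 = 2
#' @export
null_pair_expectation <- function(g_upper, g_lower,
                                  mode = c("random", "biased"), q = 0.9,
                                  reps = 10000L, window = 8L, seed = NULL) {
  mode <- match.arg(mode)
  window <- check_count(window, "window")
  reps <- check_count(reps, "reps")
  for (g in list(g_upper = g_upper, g_lower = g_lower)) {
    if (!is.numeric(g) || length(g) != 1L || g < 0 || g > window ||
        g != as.integer(g)) {
      stop("green counts must be integers in [0, window]", call. = FALSE)
    }
  }
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1) {
    stop("'q' must be a probability in [0, 1]", call. = FALSE)
  }
  g_u <- as.integer(g_upper)
  g_l <- as.integer(g_lower)
  vals <- with_seed(seed, {
    if (mode == "random") {
      vapply(seq_len(reps), function(r) {
        up <- sample.int(window, g_u)
        lo <- sample.int(window, g_l)
        length(intersect(up, lo))
      }, numeric(1))
    } else {
      vapply(seq_len(reps), function(r) {
        upper <- logical(window)
        upper[sample.int(window, g_u)] <- TRUE
        lower <- logical(window)
        while (sum(lower) < g_l) {
          red <- which(!lower)
          p_red <- ifelse(upper[red], q, 1 - q)
          if (all(p_red == 0)) {
            stop("biased null cannot terminate: all remaining sites have ",
                 "acceptance probability 0 (q at a boundary)", call. = FALSE)
          }
          i <- red[sample.int(length(red), 1L)]
          p_i <- if (upper[i]) q else 1 - q
          if (stats::runif(1) < p_i) lower[i] <- TRUE
        }
        sum(upper & lower)
      }, numeric(1))
    }
  })
  est <- mean(vals)
  attr(est, "se") <- stats::sd(vals) / sqrt(reps)
  est
}

#' Observed and null green-pair-count curves over time
#'
#' For each frame of a window series (see [window_series()]), computes
#' the expected pair count under the random and/or biased null using
#' that frame's observed per-row window green counts, aligned with the
#' observed pair count. Frames where the landmark row has no PGC are
#' skipped and flagged.
#'
#' @param ws A window-series data frame from [window_series()].
#' @param mode `"random"`, `"biased"` or `"both"`.
#' @param q Coupling probability of the biased null.
#' @param reps Monte-Carlo repetitions per frame and null.
#' @param window Window width; defaults to the `"window"` attribute of
#'   `ws`.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `frame`, `observed`, `g_upper`,
#'   `g_lower`, `random`, `biased` (the null columns present as
#'   requested, `NA` on skipped frames) and `skipped`.
#' @export
linkage_curves <- function(ws, mode = c("both", "random", "biased"),
                           q = 0.9, reps = 10000L, window = NULL,
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(ws),
            all(c("frame", "row", "green_count", "pair_count") %in% names(ws)))
  if (is.null(window)) window <- attr(ws, "window") %||% 8L
  up <- ws[ws$row == "upper", ]
  lo <- ws[ws$row == "lower", ]
  stopifnot(identical(up$frame, lo$frame))
  out <- data.frame(frame = up$frame, observed = up$pair_count,
                    g_upper = up$green_count, g_lower = lo$green_count,
                    random = NA_real_, biased = NA_real_)
  out$skipped <- is.na(out$observed) | is.na(out$g_upper) | is.na(out$g_lower)
  with_seed(seed, {
    for (j in which(!out$skipped)) {
      if (mode %in% c("both", "random")) {
        out$random[j] <- as.numeric(null_pair_expectation(
          out$g_upper[j], out$g_lower[j], "random", q = q,
          reps = reps, window = window))
      }
      if (mode %in% c("both", "biased")) {
        out$biased[j] <- as.numeric(null_pair_expectation(
          out$g_upper[j], out$g_lower[j], "biased", q = q,
          reps = reps, window = window))
      }
    }
  })
  if (mode == "random") out$biased <- NULL
  if (mode == "biased") out$random <- NULL
  out
}
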