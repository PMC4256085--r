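#' Landmark cells of the G1/S transition window
#'
#' At each frame the transition window is demarcated by the
#' posterior-most green cell (PGC; the largest-index cell already in S)
#' and the anterior-most red cell (ARC; the smallest-index cell still
#' in G1).
#'
#' @param states_row 0/1 matrix (positions x frames) for one cell
#'   column, 1 = S.
#' @param t Frame index, 0-based.
#' @return The 1-based position, or `NA_integer_` if no such cell
#'   exists at `t` (no S cell yet for the PGC; every cell S for the
#'   ARC).
#' @examples
#' st <- matrix(c(1, 1, 0, 1, 0, 0), ncol = 1)  # one frame
#' find_pgc(st, 0)  # 4
#' find_arc(st, 0)  # 3
#' @export
find_pgc <- function(states_row, t) {
  v <- states_col(states_row, t)
  w <- which(v == 1L)
  if (length(w)) w[length(w)] else NA_integer_
}

#' @rdname find_pgc
#' @export
find_arc <- function(states_row, t) {
  v <- states_col(states_row, t)
  w <- which(v == 0L)
  if (length(w)) w[1L] else NA_integer_
}

states_col <- function(states_row, t) {
  stopifnot(is.matrix(states_row))
  if (length(t) != 1L || t < 0 || t > ncol(states_row) - 1L) {
    stop("frame 't' out of range", call. = FALSE)
  }
  states_row[, t + 1L]
}

#' Number of S cells in the stochastic transition window
#'
#' The stochastic G1/S transition window is the PGC together with the
#' `window - 1` cells anterior to it. At the anterior boundary (PGC
#' position smaller than `window`) the count runs over the existing
#' positions only.
#'
#' @inheritParams find_pgc
#' @param window Window width in cells (default 8, one somite width).
#' @return Number of S cells in the window, or `NA_integer_` when the
#'   row has no PGC at `t`.
#' @export
window_green_count <- function(states_row, t, window = 8L) {
  window <- check_count(window, "window")
  pgc <- find_pgc(states_row, t)
  if (is.na(pgc)) return(NA_integer_)
  lo <- max(1L, pgc - window + 1L)
  sum(states_row[lo:pgc, t + 1L])
}

#' Number of green cell pairs in the transition window
#'
#' Counts positions within the landmark-defined window where the upper
#' and lower cells are both in S phase. The window is anchored at the
#' PGC of the landmark row (lower by default).
#'
#' @param lattice A `"state_lattice"`.
#' @param t Frame index, 0-based.
#' @param window Window width in cells.
#' @param landmark Which row's PGC anchors the window: `"lower"`
#'   (default) or `"upper"`.
#' @return Pair count, or `NA_integer_` if the landmark row has no PGC
#'   at `t`.
#' @export
pair_count <- function(lattice, t, window = 8L, landmark = c("lower", "upper")) {
  stopifnot(inherits(lattice, "state_lattice"))
  landmark <- match.arg(landmark)
  window <- check_count(window, "window")
  pgc <- find_pgc(lattice$states[[landmark]], t)
  if (is.na(pgc)) return(NA_integer_)
  lo <- max(1L, pgc - window + 1L)
  sum(lattice$states$upper[lo:pgc, t + 1L] &
        lattice$states$lower[lo:pgc, t + 1L])
}

#' Total G1 and S cell counts per frame
#'
#' @param lattice A `"state_lattice"`.
#' @return Data frame with columns `frame`, `row`, `n_G1`, `n_S`; the
#'   two counts sum to the row length at every frame.
#' @export
state_totals <- function(lattice) {
  stopifnot(inherits(lattice, "state_lattice"))
  do.call(rbind, lapply(c("upper", "lower"), function(rw) {
    st <- lattice$states[[rw]]
    n_s <- colSums(st)
    data.frame(frame = seq_len(ncol(st)) - 1L, row = rw,
               n_G1 = nrow(st) - n_s, n_S = n_s,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Per-frame window series: landmarks, green counts and pair counts
#'
#' Scores every frame of a two-row lattice: PGC and ARC positions and
#' window green count per row, plus the green-pair count in the
#' landmark-anchored window. Frames where the window would be clipped
#' at the anterior boundary are flagged.
#'
#' @inheritParams pair_count
#' @return Data frame with columns `frame`, `row`, `pgc`, `arc`,
#'   `green_count`, `pair_count`, `clipped`. `pair_count` is the
#'   landmark-window value, repeated on both rows of a frame.
#' @export
window_series <- function(lattice, window = 8L, landmark = c("lower", "upper")) {
  stopifnot(inherits(lattice, "state_lattice"))
  landmark <- match.arg(landmark)
  window <- check_count(window, "window")
  t_max <- ncol(lattice$states$upper)
  out <- vector("list", t_max)
  for (t in seq_len(t_max) - 1L) {
    pc <- pair_count(lattice, t, window, landmark)
    lm_pgc <- find_pgc(lattice$states[[landmark]], t)
    rows <- lapply(c("upper", "lower"), function(rw) {
      st <- lattice$states[[rw]]
      pgc <- find_pgc(st, t)
      data.frame(frame = t, row = rw, pgc = pgc, arc = find_arc(st, t),
                 green_count = window_green_count(st, t, window),
                 pair_count = pc,
                 clipped = !is.na(lm_pgc) && lm_pgc < window,
                 stringsAsFactors = FALSE)
    })
    out[[t + 1L]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "window") <- window
  attr(res, "landmark") <- landmark
  res
}

#' Waiting times between successive landmark advances
#'
#' Follows the PGC (or ARC) of one cell column through time and
#' records, at each frame where its position strictly increases, the
#' number of frames elapsed since the previous advance. The landmark's
#' first appearance starts the clock and contributes no interval, and
#' an advance event yields one interval regardless of how many cells
#' the landmark jumped.
#'
#' @param states_row 0/1 matrix (positions x frames) for one column.
#' @param landmark `"pgc"` (default) or `"arc"`.
#' @return Integer vector of waiting times in frames (possibly empty).
#' @examples
#' # PGC appears at frame 1 and advances at frame 3: one interval of 2
#' st <- rbind(c(0, 1, 1, 1), c(0, 0, 0, 1))
#' landmark_intervals(st)
#' @export
landmark_intervals <- function(states_row, landmark = c("pgc", "arc")) {
  landmark <- match.arg(landmark)
  stopifnot(is.matrix(states_row), ncol(states_row) >= 2L)
  finder <- if (landmark == "pgc") find_pgc else find_arc
  pos <- vapply(seq_len(ncol(states_row)) - 1L,
                function(t) finder(states_row, t), integer(1))
  events <- integer(0)
  last <- NA_integer_
  for (t in seq_along(pos)) {
    p <- pos[t]
    if (is.na(p)) next
    if (is.na(last) || p > last) {
      events <- c(events, t - 1L)
      last <- p
    }
  }
  if (length(events) < 2L) integer(0) else diff(events)
}

#' Pooled landmark intervals of a two-row lattice
#'
#' Convenience wrapper: [landmark_intervals()] applied to the upper and
#' lower rows and concatenated.
#'
#' @param lattice A `"state_lattice"`.
#' @param landmark `"pgc"` or `"arc"`.
#' @return Integer vector of waiting times in frames.
#' @export
lattice_intervals <- function(lattice, landmark = c("pgc", "arc")) {
  stopifnot(inherits(lattice, "state_lattice"))
  landmark <- match.arg(landmark)
  c(landmark_intervals(lattice$states$upper, landmark),
    landmark_intervals(lattice$states$lower, landmark))
}

#' Empirical distribution of landmark waiting times
#'
#' Normalizes a list of integer waiting times (frames) into a
#' probability mass function on its observed support.
#'
#' @param intervals Non-empty integer vector of waiting times in
#'   frames; lists from several rows or replicates may be concatenated
#'   before calling.
#' @param dt Frame interval in minutes, kept for reporting.
#' @return Object of class `"interval_distribution"`: list with
#'   `support`, `counts`, `pmf`, `n` and `dt`.
#' @examples
#' interval_distribution(c(2, 2, 4))
#' @export
interval_distribution <- function(intervals, dt = 2.5) {
  if (length(intervals) == 0L) {
    stop("cannot build a distribution from an empty interval list",
         call. = FALSE)
  }
  if (!is.numeric(intervals) || anyNA(intervals) ||
      any(intervals != as.integer(intervals)) || any(intervals < 1)) {
    stop("'intervals' must be positive integers (frames)", call. = FALSE)
  }
  tab <- table(factor(as.integer(intervals)))
  support <- as.integer(names(tab))
  counts <- as.integer(tab)
  structure(
    list(support = support, counts = counts, pmf = counts / sum(counts),
         n = sum(counts), dt = dt),
    class = "interval_distribution"
  )
}

#' @export
print.interval_distribution <- function(x, ...) {
  cat(sprintf(
    "Waiting-time distribution: %d intervals on support %d..%d frames (dt = %.3g min)\n",
    x$n, min(x$support), max(x$support), x$dt))
  df <- data.frame(frames = x$support, minutes = x$support * x$dt,
                   count = x$counts, pmf = round(x$pmf, 4))
  print(utils::head(df, 12), row.names = FALSE)
  if (length(x$support) > 12) cat("  ...\n")
  invisible(x)
}

#' @export
plot.interval_distribution <- function(x, minutes = TRUE, ...) {
  xs <- if (minutes) x$support * x$dt else x$support
  graphics::plot(xs, x$pmf, type = "h", lwd = 3,
                 xlab = if (minutes) "waiting time (min)" else "waiting time (frames)",
                 ylab = "probability", ...)
  invisible(x)
}
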