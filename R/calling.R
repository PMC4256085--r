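#' Call the G1/S transition frame from one red/green intensity trace
#'
#' The transition is called at the crossing point of the two Fucci
#' channels: the earliest frame `t` such that the green intensity
#' strictly exceeds the red intensity at every one of `persistence`
#' consecutive frames starting at `t`. All `persistence` frames must
#' exist within the trace (a run truncated by the end of the recording
#' does not qualify), ties count as red-dominant and break the run, and
#' the reported frame is the first frame of the run — the crossing
#' frame itself.
#'
#' @param red,green Numeric intensity vectors of equal length (one
#'   value per frame, frame 0 first).
#' @param persistence Number of consecutive green-dominant frames
#'   required (default 5).
#' @return The 0-based entry frame, or `NA_integer_` if the cell never
#'   satisfies the rule (censored). A `persistence` longer than the
#'   trace yields `NA`, not an error.
#' @examples
#' call_transition(red = c(9, 9, 5, 1, 1, 1, 1), green = c(0, 1, 6, 8, 9, 9, 9),
#'                 persistence = 5)
#' @export
call_transition <- function(red, green, persistence = 5L) {
  if (!is.numeric(red) || !is.numeric(green) ||
      length(red) != length(green) || length(red) < 1L) {
    stop("'red' and 'green' must be numeric vectors of equal length >= 1",
         call. = FALSE)
  }
  if (anyNA(red) || anyNA(green) || any(red < 0) || any(green < 0)) {
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  }
  persistence <- check_count(persistence, "persistence")
  n <- length(red)
  if (persistence > n) return(NA_integer_)
  dominant <- green > red
  # running count of green-dominant frames in each length-`persistence` window
  run <- cumsum(dominant)
  window_sum <- run[persistence:n] - c(0, run)[1:(n - persistence + 1L)]
  hit <- which(window_sum == persistence)
  if (length(hit)) hit[1L] - 1L else NA_integer_
}

#' Binarize a set of intensity traces into a state lattice
#'
#' Applies [call_transition()] to every cell of a rectangular
#' (row x position x frame) trace table and assembles the binary G1/S
#' state lattice: a cell is in S phase at frame `t` iff
#' `t >= entry_frame`, so states are monotone by construction.
#'
#' @param traces Data frame in the trace format of [render_traces()]
#'   (columns `cell_id`, `row`, `position`, `frame`, `red`, `green`),
#'   covering both rows on a full rectangular grid.
#' @param persistence Passed to [call_transition()].
#' @param dt Frame interval in minutes (defaults to the `"dt"`
#'   attribute of `traces`, else 2.5).
#' @return List with `lattice` (a `"state_lattice"`) and `transitions`
#'   (data frame `row`, `position`, `entry_frame`, `NA` = censored).
#' @examples
#' cfg <- model_config(n_cells = 12, t_max = 50, seed = 3)
#' tr <- render_traces(generate_lattice(cfg)$entry,
#'                     trace_noise_spec(noise_sd = 0), cfg)
#' called <- binarize_traces(tr)
#' @export
binarize_traces <- function(traces, persistence = 5L, dt = NULL) {
  stopifnot(is.data.frame(traces))
  need <- c("row", "position", "frame", "red", "green")
  if (!all(need %in% names(traces))) {
    stop("trace table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(dt)) dt <- attr(traces, "dt") %||% 2.5
  rows <- c("upper", "lower")
  if (!all(traces$row %in% rows)) {
    stop("'row' must be \"upper\" or \"lower\"", call. = FALSE)
  }
  positions <- sort(unique(traces$position))
  frames <- sort(unique(traces$frame))
  if (!identical(positions, seq_along(positions)) ||
      !identical(as.integer(frames), seq_along(frames) - 1L)) {
    stop("traces must cover contiguous positions 1..n and frames 0..t_max-1",
         call. = FALSE)
  }
  n <- length(positions)
  t_max <- length(frames)
  counts <- table(traces$row, traces$position)
  if (any(counts > t_max)) {
    stop("duplicate (row, position, frame) entries in trace table",
         call. = FALSE)
  }
  if (any(counts < t_max)) {
    gaps <- which(counts < t_max, arr.ind = TRUE)
    stop("incomplete traces for cells: ",
         paste(rownames(counts)[gaps[, 1]], colnames(counts)[gaps[, 2]],
               sep = ":", collapse = ", "), call. = FALSE)
  }
  states <- list(upper = matrix(0L, n, t_max), lower = matrix(0L, n, t_max))
  entry <- expand.grid(position = seq_len(n), row = rows,
                       stringsAsFactors = FALSE)[, c("row", "position")]
  entry$entry_frame <- NA_integer_
  for (j in seq_len(nrow(entry))) {
    sub <- traces[traces$row == entry$row[j] &
                    traces$position == entry$position[j], ]
    sub <- sub[order(sub$frame), ]
    ef <- call_transition(sub$red, sub$green, persistence)
    entry$entry_frame[j] <- ef
    if (!is.na(ef)) {
      states[[entry$row[j]]][entry$position[j], (ef + 1L):t_max] <- 1L
    }
  }
  rownames(entry) <- NULL
  lattice <- structure(
    list(states = states, entry = entry, dt = dt, config = NULL),
    class = "state_lattice"
  )
  list(lattice = lattice, transitions = entry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
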