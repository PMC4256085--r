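#' Noise specification for synthetic Fucci intensity traces
#'
#' @param red_peak,green_peak Peak intensities (arbitrary units) of the
#'   G1 (red) and S/G2/M (green) reporter channels.
#' @param rise_width Width, in frames, over which the green channel
#'   rises and the red channel falls around the true crossing.
#' @param noise_sd Standard deviation of the additive Gaussian
#'   per-frame intensity noise; 0 gives noiseless traces.
#' @return An object of class `"trace_noise_spec"`.
#' @export
trace_noise_spec <- function(red_peak = 100, green_peak = 100,
                             rise_width = 8, noise_sd = 5) {
  if (!is.numeric(rise_width) || length(rise_width) != 1L || rise_width < 1) {
    stop("'rise_width' must be a single number >= 1", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("'noise_sd' must be a single non-negative number", call. = FALSE)
  }
  stopifnot(is.numeric(red_peak), red_peak > 0,
            is.numeric(green_peak), green_peak > 0)
  structure(list(red_peak = red_peak, green_peak = green_peak,
                 rise_width = rise_width, noise_sd = noise_sd),
            class = "trace_noise_spec")
}

#' Generate a synthetic two-column state lattice with known truth
#'
#' Draws upper and lower cell columns from the stochastic
#' travelling-wave model (see [simulate_lattice()]), returning both the
#' binary G1/S state lattice and the true S-entry frame of every cell,
#' so downstream transition calling and scoring can be validated
#' against known ground truth.
#'
#' @param config A [model_config()].
#' @return A `"state_lattice"`; `$entry` holds the true entry frames
#'   (`NA` = censored, i.e. still G1 at the last frame).
#' @examples
#' truth <- generate_lattice(model_config(seed = 7))
#' @export
generate_lattice <- function(config) {
  simulate_lattice(config)
}

#' Render synthetic Fucci red/green intensity traces
#'
#' Produces, for each cell, a smooth logistic color switch: the red
#' (G1) channel is high before the cell's S-entry frame and decays
#' after it, the green channel mirrors it, and optional Gaussian noise
#' is added per frame. On the noiseless curves the green signal first
#' strictly exceeds the red signal exactly at the entry frame (the
#' continuous crossing sits half a frame earlier, between the last
#' red-dominant and first green-dominant samples), so the
#' crossing-point caller recovers the truth exactly at zero noise.
#' Censored cells stay red-dominant throughout.
#'
#' @param entry Data frame with columns `row`, `position`,
#'   `entry_frame` (`NA` = censored), e.g. the `$entry` component of
#'   [generate_lattice()].
#' @param spec A [trace_noise_spec()].
#' @param config A [model_config()] supplying `t_max` and `dt`.
#' @param seed Optional RNG seed for the noise.
#' @return Data frame with columns `cell_id`, `row`, `position`,
#'   `frame`, `red`, `green`; intensities are clamped at 0. The frame
#'   interval is attached as attribute `"dt"`.
#' @examples
#' cfg <- model_config(n_cells = 10, t_max = 40, seed = 1)
#' tr <- render_traces(generate_lattice(cfg)$entry,
#'                     trace_noise_spec(noise_sd = 0), cfg)
#' @export
render_traces <- function(entry, spec = trace_noise_spec(), config,
                          seed = NULL) {
  stopifnot(is.data.frame(entry),
            all(c("row", "position", "entry_frame") %in% names(entry)),
            inherits(spec, "trace_noise_spec"),
            inherits(config, "model_config"))
  bad <- !is.na(entry$entry_frame) &
    (entry$entry_frame < 0 | entry$entry_frame >= config$t_max)
  if (any(bad)) {
    stop("entry frames must lie in [0, t_max) or be NA (censored)",
         call. = FALSE)
  }
  t_max <- config$t_max
  frames <- seq_len(t_max) - 1L
  s <- spec$rise_width / 8  # logistic scale: rise_width spans ~2%..98%
  n_cells <- nrow(entry)
  with_seed(seed, {
    out <- vector("list", n_cells)
    for (j in seq_len(n_cells)) {
      t0 <- entry$entry_frame[j]
      if (is.na(t0)) {
        m <- rep(0, t_max)
      } else {
        # centre chosen so the continuous crossing of gp*m and rp*(1-m)
        # falls at t0 - 1/2 for any peak ratio
        centre <- t0 - 0.5 - s * log(spec$red_peak / spec$green_peak)
        m <- stats::plogis((frames - centre) / s)
      }
      red <- spec$red_peak * (1 - m)
      green <- spec$green_peak * m
      if (spec$noise_sd > 0) {
        red <- red + stats::rnorm(t_max, sd = spec$noise_sd)
        green <- green + stats::rnorm(t_max, sd = spec$noise_sd)
      }
      out[[j]] <- data.frame(
        cell_id = sprintf("%s_%03d", entry$row[j], entry$position[j]),
        row = entry$row[j], position = entry$position[j],
        frame = frames, red = pmax(red, 0), green = pmax(green, 0),
        stringsAsFactors = FALSE
      )
    }
    traces <- do.call(rbind, out)
    rownames(traces) <- NULL
    attr(traces, "dt") <- config$dt
    traces
  })
}

# --- plain-text serialization ----------------------------------------------

#' Read and write pipeline tables as TSV
#'
#' All pipeline tables are tab-separated text with a header row:
#' traces (`cell_id`, `row`, `position`, `frame`, `red`, `green`),
#' lattices in long form (`row`, `position`, `frame`, `state`; state 0
#' = G1, 1 = S), and transition tables (`row`, `position`,
#' `entry_frame`, empty for censored cells).
#'
#' @param x Object to write (traces or transition data frame, or a
#'   `"state_lattice"`).
#' @param path File path.
#' @param dt Frame interval in minutes (used when reading a lattice).
#' @return The read functions return the corresponding object; write
#'   functions return `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_traces <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_traces <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "row", "position", "frame", "red", "green")
  if (!all(need %in% names(df))) {
    stop("trace table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname pipeline_io
#' @export
write_lattice <- function(x, path) {
  stopifnot(inherits(x, "state_lattice"))
  long <- do.call(rbind, lapply(c("upper", "lower"), function(rw) {
    st <- x$states[[rw]]
    data.frame(row = rw,
               position = rep(seq_len(nrow(st)), ncol(st)),
               frame = rep(seq_len(ncol(st)) - 1L, each = nrow(st)),
               state = as.integer(st),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_lattice <- function(path, dt = 2.5) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("row", "position", "frame", "state")
  if (!all(need %in% names(df))) {
    stop("lattice table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  states <- lapply(c(upper = "upper", lower = "lower"), function(rw) {
    sub <- df[df$row == rw, ]
    n <- max(sub$position)
    tm <- max(sub$frame) + 1L
    st <- matrix(0L, nrow = n, ncol = tm)
    st[cbind(sub$position, sub$frame + 1L)] <- as.integer(sub$state)
    st
  })
  entry <- entry_from_states(states)
  structure(list(states = states, entry = entry, dt = dt, config = NULL),
            class = "state_lattice")
}

#' @rdname pipeline_io
#' @export
write_transitions <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_transitions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = c(entry_frame = "integer"))
  need <- c("row", "position", "entry_frame")
  if (!all(need %in% names(df))) {
    stop("transition table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

# First S frame per cell from a list of state matrices (NA if never S).
entry_from_states <- function(states) {
  do.call(rbind, lapply(names(states), function(rw) {
    st <- states[[rw]]
    ef <- apply(st, 1L, function(v) {
      w <- which(v == 1L)
      if (length(w)) w[1L] - 1L else NA_integer_
    })
    data.frame(row = rw, position = seq_len(nrow(st)),
               entry_frame = as.integer(ef), stringsAsFactors = FALSE)
  }))
}
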