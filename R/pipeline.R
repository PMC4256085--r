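#' Run the end-to-end G1/S wave analysis
#'
#' Orchestrates the full pipeline — synthetic data generation (or
#' loading of user data), transition calling, window scoring, linkage
#' nulls, transition-probability estimation and KL model selection —
#' writing every stage's table as TSV and every result as JSON under
#' `out_dir`, together with a run manifest that records the
#' configuration, per-stage seeds and output paths so a rerun
#' reproduces all outputs exactly.
#'
#' @param config A [model_config()]; in synthetic mode it also defines
#'   the data-generating truth.
#' @param mode `"synthetic"` (generate traces from the model),
#'   `"from-traces"` (start from a trace TSV) or `"from-lattice"`
#'   (start from a binarized lattice TSV, skipping calling and
#'   trace-based estimation).
#' @param out_dir Output directory, created if missing.
#' @param seed Master RNG seed; per-stage seeds are derived from it and
#'   recorded in the manifest.
#' @param traces_file,lattice_file Input paths for the non-synthetic
#'   modes.
#' @param noise A [trace_noise_spec()] for synthetic trace rendering.
#' @param candidates Candidate wave step sizes for model selection.
#' @param selection_reps KL replicates per candidate.
#' @param linkage_reps Monte-Carlo repetitions per frame for the
#'   linkage nulls.
#' @param q Coupling probability of the biased linkage null.
#' @param window Transition-window width in cells.
#' @return The manifest (a list, also written as `manifest.json`),
#'   invisibly. Components `results` holds the in-memory stage results
#'   (`lattice`, `transitions`, `fit`, `selection`, `linkage`,
#'   `intervals`).
#' @examples
#' \donttest{
#' out <- tempfile("nw_run")
#' man <- run_pipeline(model_config(z = 16, t_max = 240), mode = "synthetic",
#'                     out_dir = out, seed = 11, selection_reps = 10,
#'                     linkage_reps = 200)
#' man$results$selection$selected
#' }
#' @export
run_pipeline <- function(config = model_config(),
                         mode = c("synthetic", "from-traces", "from-lattice"),
                         out_dir, seed = 1L,
                         traces_file = NULL, lattice_file = NULL,
                         noise = trace_noise_spec(),
                         candidates = c(1L, 8L, 16L, 24L),
                         selection_reps = 300L, linkage_reps = 10000L,
                         q = 0.9, window = 8L) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "model_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage_seeds <- with_seed(seed, as.list(sample.int(2147483646L, 5)))
  names(stage_seeds) <- c("synth", "traces", "linkage", "estimation",
                          "selection")
  paths <- list()
  results <- list()

  if (mode == "synthetic") {
    cfg <- config
    cfg$seed <- stage_seeds$synth
    truth <- generate_lattice(cfg)
    traces <- render_traces(truth$entry, noise, cfg,
                            seed = stage_seeds$traces)
    paths$truth_lattice <- file.path(out_dir, "truth_lattice.tsv")
    write_lattice(truth, paths$truth_lattice)
    paths$truth_transitions <- file.path(out_dir, "truth_transitions.tsv")
    write_transitions(truth$entry, paths$truth_transitions)
    paths$traces <- file.path(out_dir, "traces.tsv")
    write_traces(traces, paths$traces)
  } else if (mode == "from-traces") {
    if (is.null(traces_file) || !file.exists(traces_file)) {
      stop("stage 'input': traces_file missing or not found", call. = FALSE)
    }
    traces <- read_traces(traces_file)
    attr(traces, "dt") <- config$dt
    paths$traces <- traces_file
  }

  if (mode == "from-lattice") {
    if (is.null(lattice_file) || !file.exists(lattice_file)) {
      stop("stage 'input': lattice_file missing or not found", call. = FALSE)
    }
    lattice <- read_lattice(lattice_file, dt = config$dt)
    transitions <- lattice$entry
    paths$lattice <- lattice_file
  } else {
    called <- binarize_traces(traces, dt = config$dt)
    lattice <- called$lattice
    transitions <- called$transitions
    paths$lattice <- file.path(out_dir, "called_lattice.tsv")
    write_lattice(lattice, paths$lattice)
    paths$transitions <- file.path(out_dir, "called_transitions.tsv")
    write_transitions(transitions, paths$transitions)
  }
  results$lattice <- lattice
  results$transitions <- transitions

  # window scoring
  ws <- window_series(lattice, window = window)
  paths$window_series <- file.path(out_dir, "window_series.tsv")
  utils::write.table(ws, paths$window_series, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  intervals <- lattice_intervals(lattice, "pgc")
  if (length(intervals) == 0L) {
    stop("stage 'scoring': no PGC advances in the lattice", call. = FALSE)
  }
  exp_dist <- interval_distribution(intervals, dt = config$dt)
  paths$intervals <- file.path(out_dir, "pgc_intervals.tsv")
  utils::write.table(data.frame(interval_frames = intervals),
                     paths$intervals, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  results$intervals <- exp_dist

  # linkage nulls
  linkage <- linkage_curves(ws, mode = "both", q = q, reps = linkage_reps,
                            window = window, seed = stage_seeds$linkage)
  paths$linkage <- file.path(out_dir, "linkage_curves.tsv")
  utils::write.table(linkage, paths$linkage, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  results$linkage <- linkage

  # transition-probability estimation from paired differences
  diffs <- collect_differences(transitions)
  results$fit <- NULL
  if (length(diffs) > 0L) {
    fit <- fit_transition_prob(diffs)
    results$fit <- fit
    paths$fit <- file.path(out_dir, "fit.json")
    jsonlite::write_json(
      list(p_hat = fit$p_hat, rss = fit$rss, n_samples = fit$n_samples),
      paths$fit, auto_unbox = TRUE, digits = NA)
  }

  # model selection
  selection <- select_wave_model(exp_dist, candidates = candidates,
                                 config = config, reps = selection_reps,
                                 seed = stage_seeds$selection)
  results$selection <- selection
  paths$selection <- file.path(out_dir, "selection.json")
  jsonlite::write_json(
    list(selected_z = selection$selected,
         selected_label = model_label(selection$selected),
         models = lapply(seq_len(nrow(selection$table)), function(j) {
           list(z = selection$table$z[j],
                mean_kl = selection$table$mean_kl[j],
                sd_kl = selection$table$sd_kl[j])
         }),
         ks_p = selection$ks_p),
    paths$selection, auto_unbox = TRUE, digits = NA, na = "null")

  manifest <- list(
    package_version = as.character(utils::packageVersion("notowave")),
    mode = mode,
    seed = seed,
    stage_seeds = stage_seeds,
    config = unclass(config),
    parameters = list(candidates = candidates,
                      selection_reps = selection_reps,
                      linkage_reps = linkage_reps, q = q, window = window),
    paths = paths
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest$results <- results
  invisible(manifest)
}
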