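#' Kullback-Leibler distance between two waiting-time distributions
#'
#' Computes `D(p, q) = sum_x p(x) log(p(x) / q(x))` (natural log) over
#' the union of the two supports. Terms with `p(x) = 0` contribute
#' nothing. Because a finite simulation can miss support points that
#' the data occupy, `q` is regularized — only when it has zero mass on
#' a bin where `p` has mass — with a pseudo-count `eps = 1 / (N_q + S)`
#' added to every union-support bin (`N_q` = number of simulated
#' intervals behind `q`, `S` = union support size) before
#' renormalization; `p` is used as-is, so `D >= 0` with equality iff
#' the distributions agree on the union support.
#'
#' @param p The reference (experimental) [interval_distribution()].
#' @param q The candidate (simulated) [interval_distribution()].
#' @return Non-negative KL distance in nats.
#' @examples
#' p <- interval_distribution(c(1, 1, 2))
#' q <- interval_distribution(c(1, 2, 2, 3))
#' kl_distance(p, q)
#' kl_distance(p, p)  # 0 up to the pseudo-count
#' @export
kl_distance <- function(p, q) {
  stopifnot(inherits(p, "interval_distribution"),
            inherits(q, "interval_distribution"))
  for (d in list(p, q)) {
    if (abs(sum(d$pmf) - 1) > 1e-9 || any(d$pmf < 0)) {
      stop("inputs must be normalized probability mass functions",
           call. = FALSE)
    }
  }
  support <- sort(union(p$support, q$support))
  s <- length(support)
  p_mass <- numeric(s)
  p_mass[match(p$support, support)] <- p$pmf
  q_counts <- numeric(s)
  q_counts[match(q$support, support)] <- q$counts
  eps <- 1 / (q$n + s)
  q_mass <- (q_counts + eps) / (q$n + s * eps)
  pos <- p_mass > 0
  if (!any(q_counts[pos] == 0)) {
    # q covers the data's support: no regularization needed, so
    # D(p, p) is exactly 0
    q_mass <- numeric(s)
    q_mass[match(q$support, support)] <- q$pmf
  }
  sum(p_mass[pos] * log(p_mass[pos] / q_mass[pos]))
}

#' Repeated-simulation KL distance of one candidate wave model
#'
#' Simulates `reps` independent two-row lattices under the candidate
#' wave step size `z`, pools the upper and lower PGC waiting-time
#' intervals of each replicate into a simulated distribution `q`, and
#' scores `D(experimental, q)` for every replicate.
#'
#' @param experimental Reference [interval_distribution()] of PGC
#'   waiting times (frames).
#' @param z Candidate wave step size in cells.
#' @param config A [model_config()]; its `z` and `seed` are overridden
#'   per replicate.
#' @param reps Number of replicate simulations (the headline analysis
#'   uses 300).
#' @param seed Optional RNG seed for the replicate stream.
#' @param landmark Landmark whose intervals are scored, `"pgc"`
#'   (default) or `"arc"`.
#' @return Object of class `"kl_sample"`: list with `z`, `kl_values`
#'   (length `reps`), `mean`, `sd` and `landmark`. Replicates whose
#'   simulation produced no landmark advance are `NA` and excluded
#'   from the summaries.
#' @export
model_kl <- function(experimental, z, config, reps = 300L, seed = NULL,
                     landmark = c("pgc", "arc")) {
  stopifnot(inherits(experimental, "interval_distribution"),
            inherits(config, "model_config"))
  landmark <- match.arg(landmark)
  reps <- check_count(reps, "reps")
  z <- check_count(z, "z")
  rep_seeds <- with_seed(seed, sample.int(2147483646L, reps))
  cfg <- config
  cfg$z <- z
  kl <- vapply(seq_len(reps), function(r) {
    cfg$seed <- rep_seeds[r]
    lat <- simulate_lattice(cfg)
    iv <- lattice_intervals(lat, landmark)
    if (length(iv) == 0L) return(NA_real_)
    kl_distance(experimental, interval_distribution(iv, dt = cfg$dt))
  }, numeric(1))
  if (anyNA(kl)) {
    warning(sum(is.na(kl)), " replicate(s) produced no landmark advance",
            call. = FALSE)
  }
  structure(
    list(z = z, kl_values = kl, mean = mean(kl, na.rm = TRUE),
         sd = stats::sd(kl, na.rm = TRUE), reps = reps,
         landmark = landmark),
    class = "kl_sample"
  )
}

#' @export
print.kl_sample <- function(x, ...) {
  cat(sprintf("KL sample: z = %d (%s intervals), %d reps, mean = %.4f, sd = %.4f\n",
              x$z, x$landmark, x$reps, x$mean, x$sd))
  invisible(x)
}

#' Select the wave model best matching a waiting-time distribution
#'
#' Ranks candidate wave step sizes by the mean KL distance between the
#' experimental PGC waiting-time distribution and distributions
#' simulated under each candidate (see [model_kl()]), selects the
#' argmin, and compares the replicate KL samples of every candidate
#' pair with the two-sample Kolmogorov-Smirnov test.
#'
#' @inheritParams model_kl
#' @param candidates Integer vector of candidate step sizes; the named
#'   set of the analysis is `c(1, 8, 16, 24)` — continuous, periodic,
#'   two-fold and three-fold periodic.
#' @return Object of class `"wave_selection"`: list with `samples`
#'   (one [model_kl()] result per candidate), `table` (data frame `z`,
#'   `mean_kl`, `sd_kl`), `selected` (the winning `z`), `ks_stat` and
#'   `ks_p` (pairwise matrices), `landmark`, `reps`.
#' @examples
#' \donttest{
#' cfg <- model_config(z = 16, t_max = 240, seed = 5)
#' exp_dist <- interval_distribution(lattice_intervals(simulate_lattice(cfg)))
#' sel <- select_wave_model(exp_dist, c(1, 8, 16, 24), cfg, reps = 20, seed = 1)
#' sel$selected
#' }
#' @export
select_wave_model <- function(experimental, candidates = c(1L, 8L, 16L, 24L),
                              config = model_config(), reps = 300L,
                              seed = NULL, landmark = c("pgc", "arc")) {
  landmark <- match.arg(landmark)
  if (length(candidates) < 2L) {
    stop("need at least two candidate models", call. = FALSE)
  }
  cand_seeds <- with_seed(seed, sample.int(2147483646L, length(candidates)))
  samples <- lapply(seq_along(candidates), function(j) {
    model_kl(experimental, candidates[j], config, reps = reps,
             seed = cand_seeds[j], landmark = landmark)
  })
  names(samples) <- paste0("z", candidates)
  tab <- data.frame(z = as.integer(candidates),
                    mean_kl = vapply(samples, `[[`, numeric(1), "mean"),
                    sd_kl = vapply(samples, `[[`, numeric(1), "sd"),
                    row.names = NULL)
  k <- length(candidates)
  ks_stat <- ks_p <- matrix(NA_real_, k, k,
                            dimnames = list(names(samples), names(samples)))
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      kt <- suppressWarnings(stats::ks.test(
        stats::na.omit(samples[[a]]$kl_values),
        stats::na.omit(samples[[b]]$kl_values)))
      ks_stat[a, b] <- ks_stat[b, a] <- unname(kt$statistic)
      ks_p[a, b] <- ks_p[b, a] <- kt$p.value
    }
  }
  structure(
    list(samples = samples, table = tab,
         selected = tab$z[which.min(tab$mean_kl)],
         ks_stat = ks_stat, ks_p = ks_p,
         landmark = landmark, reps = reps),
    class = "wave_selection"
  )
}

#' @export
print.wave_selection <- function(x, ...) {
  cat(sprintf("Wave-model selection by KL distance (%s intervals, %d reps)\n\n",
              x$landmark, x$reps))
  tab <- x$table
  tab$label <- model_label(tab$z)
  print(tab[, c("z", "label", "mean_kl", "sd_kl")], row.names = FALSE,
        digits = 4)
  cat(sprintf("\nSelected: z = %d (%s)\n", x$selected,
              model_label(x$selected)))
  invisible(x)
}

#' @export
summary.wave_selection <- function(object, ...) {
  print(object)
  cat("\nPairwise KS p-values of the KL samples:\n")
  print(signif(object$ks_p, 3))
  invisible(object)
}

#' @export
plot.wave_selection <- function(x, ...) {
  tab <- x$table
  bp <- graphics::barplot(tab$mean_kl, names.arg = paste0("z=", tab$z),
                          ylab = "mean KL distance (nats)",
                          ylim = c(0, max(tab$mean_kl + tab$sd_kl) * 1.1),
                          ...)
  graphics::arrows(bp, tab$mean_kl - tab$sd_kl, bp, tab$mean_kl + tab$sd_kl,
                   angle = 90, code = 3, length = 0.05)
  invisible(x)
}

model_label <- function(z) {
  vapply(z, function(zz) {
    if (zz == 1) return("continuous")
    base <- if (zz %% 8 == 0) 8L else if (zz %% 7 == 0) 7L else NA_integer_
    ratio <- if (is.na(base)) NA_integer_ else zz %/% base
    if (is.na(ratio) || ratio > 3L) "periodic"
    else c("periodic", "two-fold periodic", "three-fold periodic")[ratio]
  }, character(1))
}

#' Sensitivity sweep of the model selection
#'
#' Reruns [select_wave_model()] over a grid of per-frame transition
#' probabilities and somite-width assumptions (8 cells: candidates
#' `z = 1, 8, 16, 24`; 7 cells: `z = 1, 7, 14, 21`) and summarizes
#' which model wins in each grid cell.
#'
#' @inheritParams select_wave_model
#' @param alphas Numeric vector of `alpha_dt` values to scan.
#' @param widths Named list of candidate sets keyed by somite width in
#'   cells.
#' @return Object of class `"sensitivity_sweep"`: list with `grid`
#'   (data frame `alpha_dt`, `width`, `selected`, `selected_label`,
#'   `min_mean_kl`) and `results` (the full selection objects).
#' @export
sensitivity_sweep <- function(experimental, config = model_config(),
                              alphas = seq(0.07, 0.12, by = 0.01),
                              widths = list(`8` = c(1L, 8L, 16L, 24L),
                                            `7` = c(1L, 7L, 14L, 21L)),
                              reps = 300L, seed = NULL) {
  stopifnot(is.numeric(alphas), length(alphas) >= 1L, is.list(widths))
  cells <- expand.grid(alpha_dt = alphas, width = names(widths),
                       stringsAsFactors = FALSE)
  cell_seeds <- with_seed(seed, sample.int(2147483646L, nrow(cells)))
  results <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    cfg <- config
    cfg$alpha_dt <- cells$alpha_dt[j]
    results[[j]] <- select_wave_model(
      experimental, candidates = widths[[cells$width[j]]], config = cfg,
      reps = reps, seed = cell_seeds[j])
  }
  cells$selected <- vapply(results, `[[`, numeric(1), "selected")
  cells$selected_label <- model_label(cells$selected)
  cells$min_mean_kl <- vapply(results, function(r) min(r$table$mean_kl),
                              numeric(1))
  structure(list(grid = cells, results = results),
            class = "sensitivity_sweep")
}

#' @export
print.sensitivity_sweep <- function(x, ...) {
  cat("Model-selection sensitivity sweep\n\n")
  print(x$grid, row.names = FALSE, digits = 4)
  win <- table(x$grid$selected_label)
  cat("\nWinner counts:", paste(names(win), win, sep = " = ",
                                collapse = ", "), "\n")
  invisible(x)
}

#' Window green-count oscillation and cross-row synchrony
#'
#' Tracks the number of S cells in the stochastic transition window of
#' each row over time and summarizes upper/lower synchrony as the
#' zero-lag Pearson correlation of the two series (over frames where
#' both rows have a PGC).
#'
#' @param lattice A `"state_lattice"`.
#' @param window Window width in cells.
#' @return List with `series` (data frame `frame`, `upper`, `lower`)
#'   and `correlation` (`NA` if fewer than 3 usable frames or either
#'   series is constant).
#' @export
window_oscillation_report <- function(lattice, window = 8L) {
  stopifnot(inherits(lattice, "state_lattice"))
  window <- check_count(window, "window")
  t_max <- ncol(lattice$states$upper)
  frames <- seq_len(t_max) - 1L
  upper <- vapply(frames, function(t)
    as.integer(window_green_count(lattice$states$upper, t, window)),
    integer(1))
  lower <- vapply(frames, function(t)
    as.integer(window_green_count(lattice$states$lower, t, window)),
    integer(1))
  ok <- !is.na(upper) & !is.na(lower)
  correlation <- if (sum(ok) >= 3L && stats::sd(upper[ok]) > 0 &&
                     stats::sd(lower[ok]) > 0) {
    stats::cor(upper[ok], lower[ok])
  } else if (sum(ok) >= 3L && identical(upper[ok], lower[ok])) {
    # e.g. the deterministic limit: both rows constant and identical --
    # perfectly synchronous by construction
    1
  } else {
    NA_real_
  }
  list(series = data.frame(frame = frames, upper = upper, lower = lower),
       correlation = correlation)
}
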