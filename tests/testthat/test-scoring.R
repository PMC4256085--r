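make_lattice <- function(upper, lower, dt = 2.5) {
  structure(list(states = list(upper = upper, lower = lower),
                 entry = NULL, dt = dt, config = NULL),
            class = "state_lattice")
}

test_that("PGC and ARC landmark definitions", {
  st <- matrix(c(1, 1, 0, 1, 0, 0), ncol = 1)  # [S,S,G1,S,G1,G1]
  expect_equal(find_pgc(st, 0), 4L)
  expect_equal(find_arc(st, 0), 3L)
  all_g1 <- matrix(0L, 6, 1)
  all_s <- matrix(1L, 6, 1)
  expect_true(is.na(find_pgc(all_g1, 0)))
  expect_equal(find_arc(all_g1, 0), 1L)
  expect_equal(find_pgc(all_s, 0), 6L)
  expect_true(is.na(find_arc(all_s, 0)))
  expect_error(find_pgc(st, 1), "out of range")
})

test_that("window green count over the PGC-anchored window", {
  # deterministic: positions 1..8 S, rest G1
  st <- matrix(c(rep(1, 8), rep(0, 4)), ncol = 1)
  expect_equal(window_green_count(st, 0, window = 8), 8L)
  # clipped window: PGC = 6 < 8, count over positions 1..6
  st2 <- matrix(c(1, 0, 1, 1, 0, 1, 0, 0, 0, 0), ncol = 1)
  expect_equal(window_green_count(st2, 0, window = 8), 4L)
  # no PGC
  expect_true(is.na(window_green_count(matrix(0L, 5, 1), 0)))
  # the PGC itself is S, so the count is always >= 1
  set.seed(5)
  lat <- simulate_lattice(model_config(z = 16, t_max = 150, seed = 5))
  for (t in seq(0, 149, by = 10)) {
    g <- window_green_count(lat$states$upper, t)
    if (!is.na(g)) expect_gte(g, 1L)
  }
})

test_that("pair count is the positional AND in the landmark window", {
  up <- matrix(c(1, 0, 1, 1, 1, 0, 1, 1), ncol = 1)
  lo <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1), ncol = 1)
  lat <- make_lattice(up, lo)
  # lower PGC = 8, window 1..8; pairs at positions 1, 4, 5, 8
  expect_equal(pair_count(lat, 0, window = 8), 4L)
  expect_equal(pair_count(lat, 0, window = 8, landmark = "upper"), 4L)
  # both rows all S in window -> 8; upper all G1 -> 0
  lat2 <- make_lattice(matrix(1L, 8, 1), matrix(1L, 8, 1))
  expect_equal(pair_count(lat2, 0), 8L)
  lat3 <- make_lattice(matrix(0L, 8, 1), matrix(1L, 8, 1))
  expect_equal(pair_count(lat3, 0), 0L)
  # landmark row with no PGC
  expect_true(is.na(pair_count(make_lattice(matrix(1L, 8, 1),
                                            matrix(0L, 8, 1)), 0)))
})

test_that("totals partition every row at every frame", {
  lat <- simulate_lattice(model_config(z = 8, n_cells = 40, t_max = 100,
                                       seed = 9))
  tot <- state_totals(lat)
  expect_true(all(tot$n_G1 + tot$n_S == 40))
  # n_S equals the number of transitions that have happened
  up <- tot[tot$row == "upper", ]
  ef <- lat$entry$entry_frame[lat$entry$row == "upper"]
  for (t in c(0, 30, 60, 99)) {
    expect_equal(up$n_S[up$frame == t], sum(!is.na(ef) & ef <= t))
  }
})

test_that("landmark positions are non-decreasing on every lattice", {
  for (seed in 1:5) {
    lat <- simulate_lattice(model_config(z = 16, t_max = 120, seed = seed))
    ws <- window_series(lat)
    for (rw in c("upper", "lower")) {
      sub <- ws[ws$row == rw, ]
      expect_true(all(diff(sub$pgc[!is.na(sub$pgc)]) >= 0))
      expect_true(all(diff(sub$arc[!is.na(sub$arc)]) >= 0))
    }
  }
})

test_that("landmark intervals are frame gaps between advance events", {
  # PGC appears at frame 1, advances at frame 3: one interval of 2
  st <- rbind(c(0, 1, 1, 1),
              c(0, 0, 0, 1))
  expect_equal(landmark_intervals(st), 2L)
  # a jump of several cells is one event
  st2 <- rbind(c(1, 1, 1),
               c(0, 1, 1),
               c(0, 1, 1),
               c(0, 0, 1))
  expect_equal(landmark_intervals(st2), c(1L, 1L))
  # never advances -> empty
  expect_equal(landmark_intervals(matrix(0L, 3, 4)), integer(0))
  expect_equal(landmark_intervals(matrix(1L, 3, 4)), integer(0))
  # sum of intervals spans first to last advance
  lat <- simulate_lattice(model_config(z = 8, t_max = 200, seed = 13))
  for (rw in c("upper", "lower")) {
    st <- lat$states[[rw]]
    iv <- landmark_intervals(st)
    pos <- vapply(seq_len(ncol(st)) - 1L, function(t) find_pgc(st, t),
                  integer(1))
    # advance events: first appearance, then every strict increase of the
    # running maximum
    events <- integer(0)
    last <- NA_integer_
    for (t in seq_along(pos)) {
      if (!is.na(pos[t]) && (is.na(last) || pos[t] > last)) {
        events <- c(events, t - 1L)
        last <- pos[t]
      }
    }
    expect_equal(sum(iv), max(events) - min(events))
  }
})

test_that("deterministic continuous front yields the alternating 1,2 cadence", {
  cfg <- model_config(alpha_dt = 1, z = 1, n_cells = 40, t_max = 80, seed = 1)
  run <- simulate_row(cfg)
  iv <- landmark_intervals(run$states)
  expect_gt(length(iv), 20)
  expect_setequal(unique(iv), c(1L, 2L))
  expect_true(all(iv[seq(1, length(iv) - 1, by = 2)] !=
                    iv[seq(2, length(iv), by = 2)]))
  # the front advances one cell per 1.5 frames on average
  expect_equal(mean(iv), 1.5, tolerance = 0.05)
})

test_that("interval distributions normalize and pool correctly", {
  d <- interval_distribution(c(2, 2, 4))
  expect_equal(d$support, c(2L, 4L))
  expect_equal(d$pmf, c(2 / 3, 1 / 3))
  expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
  # pooling two lists equals the distribution of the concatenation
  a <- c(1, 2, 2, 5)
  b <- c(2, 3)
  expect_equal(interval_distribution(c(a, b)),
               interval_distribution(c(b, a)))
  expect_error(interval_distribution(integer(0)), "empty")
  expect_error(interval_distribution(c(1.5, 2)), "integer")
})

test_that("continuous-model intervals concentrate at short waits", {
  cfg <- model_config(alpha_dt = 0.1, z = 1, n_cells = 300, t_max = 700,
                      seed = 31)
  lat <- simulate_lattice(cfg)
  d <- interval_distribution(lattice_intervals(lat))
  # most mass below 8 frames (20 min), with a decreasing trend
  expect_gt(sum(d$pmf[d$support < 8]), 0.8)
  expect_gt(sum(d$pmf[d$support <= 4]), sum(d$pmf[d$support > 4]))
})
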