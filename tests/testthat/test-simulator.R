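test_that("wave schedule follows t_k = k L_c z / (lambda dt)", {
  ws <- wave_schedule(model_config(z = 8, t_max = 120))
  expect_equal(ws$t_k[1], 12)                 # first step: 30 min
  expect_equal(diff(ws$t_k), rep(12, ws$m - 1))
  expect_equal(ws$period_min, 30)
  expect_gt(max(ws$t_k), 120)                 # schedule covers the run
  # inter-step interval in minutes equals z * L_c / lambda
  for (z in c(8L, 16L, 24L)) {
    expect_equal(wave_schedule(model_config(z = z))$period_min,
                 z * 5 / (4 / 3))
  }
})

test_that("licensing front matches the closed-form schedule", {
  cfg <- model_config(z = 8, n_cells = 40, t_max = 80)
  w <- wave_schedule(cfg)
  expect_false(any(signal_arrived(1:40, 0, w)))       # nothing before t_1
  expect_false(any(signal_arrived(1:40, 11, w)))
  expect_equal(which(signal_arrived(1:40, 12, w)), 1:8)
  expect_equal(which(signal_arrived(1:40, 24, w)), 1:16)
  expect_error(signal_arrived(0, 5, w), "positive integer")
  expect_error(signal_arrived(41, 5, w), "lattice length")

  # continuous wave: licensed count at frame t is floor(t / 1.5)
  w1 <- wave_schedule(model_config(z = 1, n_cells = 100, t_max = 120))
  for (t in c(0, 1, 2, 3, 10, 45, 119)) {
    expect_equal(front_position(t, w1), floor(t / 1.5), label = paste("t =", t))
    expect_equal(front_position(t, w1), front_oracle(t, z = 1))
  }
})

test_that("licensed front and per-cell states are monotone in time", {
  cfg <- model_config(z = 16, n_cells = 50, t_max = 150, seed = 11)
  w <- wave_schedule(cfg)
  fronts <- front_position(0:149, w)
  expect_true(all(diff(fronts) >= 0))
  run <- simulate_row(cfg)
  expect_true(all(apply(run$states, 1, function(v) all(diff(v) >= 0))))
  # entry frame is the first S frame
  for (i in which(!is.na(run$entry_frames))) {
    expect_equal(which(run$states[i, ] == 1L)[1] - 1L, run$entry_frames[i])
  }
})

test_that("deterministic limit equals the closed-form front for all (i, t)", {
  for (z in c(1L, 8L)) {
    cfg <- model_config(alpha_dt = 1, z = z, n_cells = 24, t_max = 40,
                        seed = 1)
    run <- simulate_row(cfg)
    w <- wave_schedule(cfg)
    for (t in 1:39) {
      expect_equal(which(run$states[, t + 1L] == 1L),
                   seq_len(min(front_position(t, w), 24L)),
                   label = sprintf("z = %d, t = %d", z, t))
    }
  }
})

test_that("stochastic transitions follow the per-frame binomial law", {
  # fraction of (licensed, still-G1) cells transitioning per frame ~ alpha_dt
  cfg <- model_config(alpha_dt = 0.1, z = 16, n_cells = 100, t_max = 120,
                      seed = 42)
  run <- simulate_row(cfg)
  w <- wave_schedule(cfg)
  n_eligible <- 0L
  n_flip <- 0L
  for (t in 1:119) {
    front <- min(front_position(t, w), 100L)
    if (front < 1L) next
    # eligible: licensed at t and still G1 entering frame t
    eligible <- sum(is.na(run$entry_frames[1:front]) |
                      run$entry_frames[1:front] >= t)
    flips <- sum(!is.na(run$entry_frames[1:front]) &
                   run$entry_frames[1:front] == t)
    n_eligible <- n_eligible + eligible
    n_flip <- n_flip + flips
  }
  p_hat <- n_flip / n_eligible
  se <- sqrt(0.1 * 0.9 / n_eligible)
  expect_lt(abs(p_hat - 0.1), 3 * se)
})

test_that("licensed waiting times are geometric with mean 1/alpha_dt", {
  cfg <- model_config(alpha_dt = 0.1, z = 8, n_cells = 500, t_max = 700,
                      seed = 3)
  run <- simulate_row(cfg)
  w <- wave_schedule(cfg)
  ok <- !is.na(run$entry_frames)
  license_frame <- ceiling(w$t_k[ceiling(seq_len(500) / 8)] - 1e-9)
  waits <- run$entry_frames[ok] - license_frame[ok] + 1L  # trials to success
  # keep cells with >= 100 frames of observation to make censoring negligible
  waits <- waits[license_frame[ok] + 100 <= 699]
  expect_gt(length(waits), 300)
  se <- sqrt((1 - 0.1) / 0.1^2 / length(waits))
  expect_lt(abs(mean(waits) - 10), 3 * se)
})

test_that("simulation is seed-deterministic and seeds differentiate runs", {
  cfg <- model_config(z = 16, seed = 99)
  a <- simulate_lattice(cfg)
  b <- simulate_lattice(cfg)
  expect_identical(a$states, b$states)
  expect_identical(a$entry, b$entry)
  cfg2 <- cfg
  cfg2$seed <- 100L
  expect_false(identical(simulate_lattice(cfg2)$states, a$states))
})

test_that("upper and lower rows are independent given licensing", {
  cfg <- model_config(alpha_dt = 0.3, z = 8, n_cells = 250, t_max = 400,
                      seed = 7)
  lat <- simulate_lattice(cfg)
  up <- lat$entry$entry_frame[lat$entry$row == "upper"]
  lo <- lat$entry$entry_frame[lat$entry$row == "lower"]
  ok <- !is.na(up) & !is.na(lo)
  expect_gt(sum(ok), 200)
  r <- cor(up[ok], lo[ok])
  # licensing frame is shared, so partial out the position effect
  w <- wave_schedule(cfg)
  lic <- ceiling(w$t_k[ceiling(seq_len(250) / 8)] - 1e-9)
  r_part <- cor(up[ok] - lic[ok], lo[ok] - lic[ok])
  expect_lt(abs(r_part), 3 / sqrt(sum(ok)))
  expect_gt(r, 0.5)  # shared wave induces the positional trend
})

test_that("deterministic pair has identical rows", {
  cfg <- model_config(alpha_dt = 1, z = 8, n_cells = 32, t_max = 60, seed = 1)
  lat <- simulate_lattice(cfg)
  expect_identical(lat$states$upper, lat$states$lower)
})
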