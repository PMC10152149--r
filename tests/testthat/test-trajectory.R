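test_that("instantaneous velocity: constant-speed and stationary tracks", {
  t <- seq(0, 100, by = 2)
  tr <- comet_track(time_min = t, x_um = 1.1 * t, y_um = rep(0, length(t)))
  v <- instantaneous_velocity(tr)
  expect_equal(v, rep(1.1, length(t)), tolerance = 1e-12)
  tr0 <- comet_track(time_min = t, x_um = rep(3, length(t)),
                     y_um = rep(4, length(t)))
  expect_equal(instantaneous_velocity(tr0), rep(0, length(t)))
  expect_error(instantaneous_velocity(comet_track(0, 1)), "2 frames")
  expect_error(instantaneous_velocity(tr, window = 4), "odd")
})

test_that("instantaneous velocity matches the analytic derivative of assembly growth", {
  V0 <- 1; l_max <- 120; sigma <- 1
  t <- seq(0, 240, by = 2)
  cf <- assembly_closed_form(t, V0, l_max, sigma)
  tr <- comet_track(time_min = t, comet_length_um = cf$l_um)
  v <- instantaneous_velocity(tr, window = 1)
  v_true <- V0 * exp(-(1 + sigma) * V0 * t / l_max)
  # central differences: discretization error only (O(dt^2) interior)
  expect_lt(max(abs(v - v_true)[2:(length(t) - 1)]), 2e-4)
})

test_that("motility half-life recovers constructed decay rates", {
  t_h <- seq(0, 10, by = 0.05)
  fit <- motility_half_life(exp(-0.3466 * t_h), t_h)
  expect_true(fit$ok)
  expect_equal(fit$half_life, log(2) / 0.3466, tolerance = 1e-6)
  expect_equal(fit$half_life, 2.0, tolerance = 1e-3)       # hours
  # slow flow-chamber-scale decay: 0.1/h -> half-life 6.93 h
  fit2 <- motility_half_life(2 * exp(-0.1 * t_h), t_h)
  expect_equal(fit2$half_life, log(2) / 0.1, tolerance = 1e-6)
  expect_equal(fit2$half_life, 6.93, tolerance = 1e-3)
  # constant velocity: no decay to fit
  flat <- motility_half_life(rep(1, 30), seq_len(30))
  expect_false(flat$ok)
  expect_match(flat$note, "not decaying")
  expect_false(motility_half_life(c(1, 2, 0, 0, 0), 1:5)$ok)
})

test_that("half-life fits tolerate multiplicative noise (fixed seeds)", {
  lambda <- 0.005 # per min
  t <- seq(0, 1000, by = 5) # > 200 points
  for (seed in 1:5) {
    noisy <- withr::with_seed(seed, {
      exp(-lambda * t) * rlnorm(length(t), 0, sqrt(log(1 + 0.1^2)))
    })
    fit <- motility_half_life(noisy, t)
    expect_rel_equal(fit$rate, lambda, 0.10, info = paste("seed", seed))
  }
  # noise-free recovery is tight
  expect_rel_equal(motility_half_life(exp(-lambda * t), t)$rate, lambda,
                   0.02)
})

test_that("half_life = ln2 * tau identity holds in every decay fit", {
  for (tau in c(5, 55, 200)) {
    f <- decay_time_constant(100 * exp(-seq(0, 120, 2) / tau),
                             seq(0, 120, 2))
    expect_equal(f$half_life, log(2) * f$tau)
    expect_equal(f$half_life, log(2) / f$rate)
  }
})

test_that("cumulative polymerized length integrates velocity", {
  t <- seq(0, 100, by = 1)
  cs <- cumulative_polymerized(rep(1.1, length(t)), t)
  expect_equal(max(cs$cumulative_length_um), 110)
  expect_true(all(diff(cs$cumulative_length_um) >= 0))
  expect_equal(max(cumulative_polymerized(rep(0, 11),
                                          0:10)$cumulative_length_um), 0)
  # closed-form integral of an exponentially decaying velocity
  t2 <- seq(0, 1000, by = 0.5)
  cs2 <- cumulative_polymerized(exp(-0.01 * t2), t2)
  expect_rel_equal(max(cs2$cumulative_length_um),
                   (1 - exp(-10)) / 0.01, 1e-3)
  # Richardson check: halving dt moves the integral < 0.1%
  t_coarse <- seq(0, 1000, by = 1)
  cs_coarse <- cumulative_polymerized(exp(-0.01 * t_coarse), t_coarse)
  expect_rel_equal(max(cs_coarse$cumulative_length_um),
                   max(cs2$cumulative_length_um), 1e-3)
  expect_error(cumulative_polymerized(c(1, -0.1, 1), 0:2), "clip_negative")
  expect_equal(
    max(cumulative_polymerized(c(1, -0.1, 1), 0:2,
                               clip_negative = TRUE)$cumulative_length_um),
    1) # 0.5 + 0 + 0.5
})

test_that("cycle counting and consumption rate conversions", {
  t <- seq(0, 100, by = 1)
  cs <- cycle_count(cumulative_polymerized(rep(1.1, length(t)), t), 110)
  expect_equal(attr(cs, "max_cycles"), 1.0)
  expect_equal(cs$cycles, cs$cumulative_length_um / 110)
  expect_equal(attr(cycle_count(
    data.frame(time_min = 0, cumulative_length_um = 660), 110),
    "max_cycles"), 6.0)
  expect_error(cycle_count(cs, 0), "positive")

  cr <- consumption_rate(cs, G_bar = 3, l_max = 110, window = 20)
  expect_equal(cr$consumption_rate_uM_per_h[50], 1.1 * 60 * 3 / 110)
  expect_equal(cr$consumption_rate_uM_per_h[50], 1.8)
  # linearity in G_bar
  cr2 <- consumption_rate(cs, G_bar = 6, l_max = 110, window = 20)
  expect_equal(cr2$consumption_rate_uM_per_h[50],
               2 * cr$consumption_rate_uM_per_h[50])
  expect_error(consumption_rate(cs, 3, 110, window = 1), "intervals")
})

test_that("tail fraction from background-corrected intensities", {
  expect_equal(tail_fraction(57, 100)$fraction, 0.57)
  expect_equal(tail_fraction(80, 80)$fraction, 1.0)
  expect_equal(tail_fraction(120, 200, background = 20)$fraction, 100 / 180)
  expect_error(tail_fraction(10, 20, background = 25), "positive")
  expect_warning(out <- tail_fraction(10, 100, background = c(20, 0)),
                 "outside")
  expect_false(out$in_range)
})

test_that("defect decay constants and disassembly speed", {
  t <- seq(0, 200, by = 2)
  f55 <- decay_time_constant(100 * exp(-t / 55), t)
  expect_equal(f55$tau, 55, tolerance = 1e-6)
  f22 <- decay_time_constant(100 * exp(-t / 22), t)
  expect_equal(f22$tau, 22, tolerance = 1e-6)
  expect_false(decay_time_constant(rep(7, 20), 1:20)$ok)

  expect_equal(disassembly_speed(60, 60), 1.0)
  expect_equal(disassembly_speed(66, 55), 1.2)
  expect_equal(disassembly_speed(26.4, 22), 1.2)
  expect_error(disassembly_speed(60, 0), "tau")
})

test_that("k+ estimation from filament elongation", {
  t_s <- seq(0, 100, by = 5)
  out <- estimate_kplus(0.5 + 0.0216 * t_s, t_s, G = 0.8)
  expect_equal(out$k_plus, 0.0216 / (0.0027 * 0.8), tolerance = 1e-9)
  expect_equal(out$k_plus, 10, tolerance = 1e-9)
  expect_false(out$depolymerizing)
  expect_equal(estimate_kplus(rep(2, 5), 1:5, G = 0.8)$k_plus, 0)
  # inverse proportionality in G
  expect_equal(estimate_kplus(0.5 + 0.0216 * t_s, t_s, G = 1.6)$k_plus, 5,
               tolerance = 1e-9)
  expect_warning(out2 <- estimate_kplus(10 - 0.01 * t_s, t_s, G = 0.8),
                 "depolymerizing")
  expect_true(out2$depolymerizing)
  expect_error(estimate_kplus(c(1, 2), c(1, 2), 0.8), "3 points")
})

test_that("track CSV round trip preserves the schema", {
  t <- seq(0, 20, by = 2)
  tr <- comet_track(time_min = t, comet_length_um = t * 0.5,
                    track_id = "roundtrip", x_um = t, y_um = t,
                    bead_velocity_um_per_min = rep(0.5, length(t)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  back <- read_tracks(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$comet_length_um, tr$comet_length_um)
  expect_equal(back[[1]]$time_min, tr$time_min)
  expect_error(read_tracks(withr::local_tempfile()), "not found")
})
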