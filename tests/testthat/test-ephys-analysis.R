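test_that("ramp slope recovers the frozen-gate conductance to machine tolerance", {
  rec <- simulate_recording(bsc_params(noise_sd_pA = 0), pulse_protocol(),
                            seed = 2)
  gv <- extract_gv_curve(rec)
  area <- surface_area(27.4)
  # ground truth: pulse-end open fraction from the generator's own gate
  p_end <- open_fraction(gv$e_m, e_half = 14.5, z = 1.46)
  g_true_nS <- (0.8 + (1.75 - 0.8) * p_end) * area * 1e6
  expect_equal(gv$g_nS, g_true_nS, tolerance = 1e-4)
})

test_that("ramp fitting handles constant traces, short windows, unit conversion", {
  t <- seq(0.5, 30, by = 0.5)
  v <- seq(70, -70, length.out = length(t))
  rc <- ramp_conductance(t, v, rep(5, length(t)))
  expect_equal(rc$g_nS, 0)
  expect_equal(rc$r2, 1) # a constant is fit exactly by a zero-slope line
  expect_error(ramp_conductance(t[1:8], v[1:8], rep(1, 8), trim_ms = 2),
               "fewer than 5")
  # nS -> mS cm^-2: 1 nS over 1 cm^2 is 1e-6 mS cm^-2 (hand conversion)
  expect_equal(specific_conductance(1, 1), 1e-6)
  expect_equal(specific_conductance(0, surface_area(27.4)), 0)
  expect_error(specific_conductance(1, 0), "positive")
})

test_that("low-linearity ramps are flagged and excluded from the fit", {
  rec <- simulate_recording(bsc_params(noise_sd_pA = 0), pulse_protocol(),
                            seed = 4)
  # wreck one sweep's ramp with heavy structured noise
  bad <- rec$data$sweep_index == 8 & rec$data$time_ms > 1000
  rec$data$current_pA[bad] <- rec$data$current_pA[bad] +
    2000 * sin(seq_len(sum(bad)))
  gv <- extract_gv_curve(rec, r2_gate = 0.99)
  expect_true(gv$flagged[gv$sweep == 8])
  expect_false(any(gv$flagged[gv$sweep != 8]))
  fit <- fit_boltzmann(gv)
  expect_true(fit$converged)
  expect_equal(fit$n_points, 14) # the flagged point is not used
  expect_equal(fit$e_half, 14.5, tolerance = 0.1)
})

test_that("strongly hyperpolarized pre-pulses drive G' to the G'_max asymptote", {
  prot <- pulse_protocol(pulse_levels_mV = seq(360, -360, by = -40))
  rec <- simulate_recording(bsc_params(noise_sd_pA = 0), prot, seed = 6)
  gv <- extract_gv_curve(rec)
  expect_equal(min(gv$g_specific), 0.8, tolerance = 1e-3)   # basal plateau
  expect_equal(max(gv$g_specific), 1.75, tolerance = 1e-3)  # maximal plateau
})

test_that("Boltzmann fit recovers noiseless curves to 1e-6 relative tolerance", {
  cases <- list(c(0.8, 1.75, 14.5, 1.46), c(0.43, 1.15, -6.5, 1.03),
                c(0, 2.5, -40, 3))
  for (th in cases) {
    fit <- fit_boltzmann(make_gv_curve(th[1], th[2], th[3], th[4]))
    expect_true(fit$converged)
    expect_equal(fit$g_b, th[1], tolerance = 1e-6)
    expect_equal(fit$g_max, th[2], tolerance = 1e-6)
    expect_equal(fit$e_half, th[3], tolerance = 1e-6)
    expect_equal(fit$z, th[4], tolerance = 1e-6)
    expect_identical(fit$g_max_net, fit$g_max - fit$g_b) # exact by construction
    # fitted curve bounded by its own asymptotes everywhere
    g_pred <- boltzmann_conductance(seq(-500, 500, 10), fit$g_b, fit$g_max,
                                    fit$e_half, fit$z)
    expect_true(all(g_pred >= fit$g_b - 1e-12 & g_pred <= fit$g_max + 1e-12))
  }
})

test_that("degenerate curves yield a flagged non-convergent fit, not a crash", {
  flat <- make_gv_curve(1, 1, 0, 1)
  expect_false(fit_boltzmann(flat)$converged)
  few <- make_gv_curve(0.5, 1.5, 0, 1, e_m = c(-100, -50, 0, 50, 100))
  expect_false(fit_boltzmann(few)$converged)
  expect_match(fit_boltzmann(few)$message, "fewer than 6")
})

test_that("crossover estimator: exact two-line and common-point constructions", {
  # two distinct lines crossing at -17 mV (plus a duplicate excluded by the
  # slope floor): the median intersection is exactly -17
  rec2 <- make_ramp_recording(slopes_nS = c(10, 10, 40), e_rev = -17)
  est <- estimate_reversal(rec2)
  expect_equal(est$e_rev, -17, tolerance = 1e-9)
  expect_equal(est$n_pairs, 2)
  # three noiseless lines through one point: zero dispersion
  rec3 <- make_ramp_recording(slopes_nS = c(5, 20, 45), e_rev = -31)
  est3 <- estimate_reversal(rec3)
  expect_equal(est3$e_rev, -31, tolerance = 1e-9)
  expect_equal(est3$dispersion, 0, tolerance = 1e-9)
  expect_true(est3$in_ramp_span)
  # all slopes equal: no crossover
  expect_error(estimate_reversal(make_ramp_recording(c(7, 7, 7))),
               "no crossover")
})

test_that("reversal potential of a simulated recording is recovered", {
  rec <- simulate_recording(bsc_params(), pulse_protocol(), seed = 21,
                            cell_type = "BSC")
  est <- estimate_reversal(rec)
  expect_equal(est$e_rev, -31, tolerance = 1)
  expect_true(est$in_ramp_span)
})

test_that("raising bath K+ moves the recovered reversal toward the new E_K", {
  rec_low <- simulate_recording(bsc_params(), pulse_protocol(ljp_mV = -23),
                                seed = 31)
  rec_hi <- simulate_recording(bsc_params(e_rev = -17),
                               pulse_protocol(ljp_mV = -14), seed = 32)
  shift <- estimate_reversal(rec_hi)$e_rev - estimate_reversal(rec_low)$e_rev
  expect_gt(shift, 0) # toward the less-negative E_K of the 30 mM bath
  expect_equal(shift, 14, tolerance = 1.5)
})

test_that("full pipeline identity: simulate -> extract -> fit recovers theta", {
  # noiseless: bias below 2% of each parameter's dynamic range
  for (seed in 1:3) {
    prm <- bsc_params(noise_sd_pA = 0)
    fit <- analyze_recording(simulate_recording(prm, pulse_protocol(),
                                                seed = seed))
    expect_equal(fit$g_b, prm$g_b, tolerance = 0.02)
    expect_equal(fit$g_max, prm$g_max, tolerance = 0.02)
    expect_lt(abs(fit$e_half - prm$e_half) / 280, 0.02) # 280 mV span
    expect_equal(fit$z, prm$z, tolerance = 0.02)
    rev <- estimate_reversal(simulate_recording(prm, pulse_protocol(),
                                                seed = seed))
    expect_equal(rev$e_rev, prm$e_rev, tolerance = 0.1)
  }
  # default noise, several seeds per type: parameters within stated tolerance
  for (seed in 1:6) {
    prm <- if (seed %% 2) bsc_params() else mc_params()
    fit <- analyze_recording(simulate_recording(prm, pulse_protocol(),
                                                seed = 100 + seed))
    expect_true(fit$converged)
    expect_equal(fit$e_half, prm$e_half, tolerance = 2)
    expect_equal(fit$z, prm$z, tolerance = 0.15)
    expect_equal(fit$g_max_net, prm$g_max - prm$g_b, tolerance = 0.1)
  }
})

test_that("group comparison averages fits per type and tests each parameter", {
  fits <- c(
    lapply(1:4, function(i) analyze_recording(
      simulate_recording(bsc_params(), pulse_protocol(), seed = 200 + i,
                         cell_type = "BSC"))),
    lapply(1:4, function(i) analyze_recording(
      simulate_recording(mc_params(), pulse_protocol(), seed = 300 + i,
                         cell_type = "MC"))))
  cmp <- compare_groups(fits)
  expect_setequal(cmp$parameter, c("g_b", "g_max", "g_max_net", "e_half", "z"))
  expect_equal(attr(cmp, "e_half_difference"), 21, tolerance = 1)
  expect_lt(cmp$p_value[cmp$parameter == "e_half"], 0.001)
  expect_equal(cmp$n_BSC, rep(4, 5))
  # identical groups: no parameter differs (P = 1)
  half <- fits[1:4]
  cmp0 <- compare_groups(c(half, half), group = rep(c("A", "B"), each = 4))
  expect_true(all(abs(cmp0$p_value - 1) < 1e-9))
  expect_error(compare_groups(fits[1:3], group = c("A", "A", "B")),
               ">= 2 converged fits")
})

test_that("non-convergent fits are dropped from group averaging with a message", {
  good <- lapply(1:4, function(i) analyze_recording(
    simulate_recording(bsc_params(), pulse_protocol(), seed = 400 + i)))
  bad <- fit_boltzmann(make_gv_curve(1, 1, 0, 1)) # degenerate
  fits <- c(good, list(bad))
  expect_message(
    cmp <- compare_groups(fits, group = c("BSC", "BSC", "MC", "MC", "MC")),
    "non-convergent")
  expect_equal(cmp$n_MC[1], 2)
})
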