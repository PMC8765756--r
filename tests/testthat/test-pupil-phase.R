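# noiseless sinusoid sampled at 1 kHz: landmarks fall at analytic times
sine_trace <- function(period = 1000, len = 3000, amp = 1, phase = 0) {
  t_ms <- 0:len
  tibble::tibble(t_ms = t_ms, value = amp * sin(2 * pi * t_ms / period + phase))
}

test_that("cycle detection finds analytic landmarks on a noiseless sinusoid", {
  cy <- detect_hippus_cycles(sine_trace(), smoothing_ms = 1)
  # sin minima at 750 and 2750 ms: two complete cycles
  expect_equal(nrow(cy), 2)
  expect_equal(cy$t_min_prev, c(750, 1750), tolerance = 2)
  expect_equal(cy$t_max_dil_rate, c(1000, 2000), tolerance = 2)
  expect_equal(cy$t_max, c(1250, 2250), tolerance = 2)
  expect_equal(cy$t_max_con_rate, c(1500, 2500), tolerance = 2)
  expect_equal(cy$t_min_next, c(1750, 2750), tolerance = 2)
  expect_true(all(cy$t_min_prev < cy$t_max_dil_rate &
                    cy$t_max_dil_rate < cy$t_max &
                    cy$t_max < cy$t_max_con_rate &
                    cy$t_max_con_rate < cy$t_min_next))
})

test_that("flat or amplitude-zero traces yield no cycles", {
  flat <- tibble::tibble(t_ms = 0:2000, value = 3)
  expect_equal(nrow(detect_hippus_cycles(flat)), 0)
  noise <- withr::with_seed(4, tibble::tibble(
    t_ms = 0:3000, value = rnorm(3001, 0, 0.1)
  ))
  expect_equal(nrow(detect_hippus_cycles(noise, smoothing_ms = 100)), 0)
})

test_that("landmarks survive noise within tolerance and ignore constant offsets", {
  tr <- sine_trace(period = 1000, len = 4000)
  noisy <- withr::with_seed(6, dplyr::mutate(tr, value = value + rnorm(dplyr::n(), 0, 0.1)))
  cy <- detect_hippus_cycles(noisy, smoothing_ms = 100)
  expect_gte(nrow(cy), 2)
  circ_err <- function(x, target, period = 1000) {
    d <- (x - target) %% period
    pmin(d, period - d)
  }
  expect_lt(max(circ_err(cy$t_max_dil_rate, 0)), 30 + 1)
  expect_lt(max(circ_err(cy$t_max, 250)), 30 + 1)

  shifted <- dplyr::mutate(noisy, value = value + 100)
  expect_equal(detect_hippus_cycles(shifted, smoothing_ms = 100), cy)
})

test_that("phase assignment anchors landmarks at 0/90/180/270 and interpolates", {
  tr <- sine_trace()
  cy <- detect_hippus_cycles(tr, smoothing_ms = 1)
  ph <- assign_phase(tr, cy)
  at <- function(t) ph$phase_deg[ph$t_ms == t]
  expect_equal(at(1000), 0, tolerance = 1)
  expect_equal(at(1250), 90, tolerance = 1)
  expect_equal(at(1500), 180, tolerance = 1)
  expect_equal(at(1750), 270, tolerance = 1)
  # linear between landmarks: midpoint of 0 and 90 maps to 45
  expect_equal(at(1125), 45, tolerance = 1)
  # undefined outside complete cycles
  expect_true(is.na(at(100)))
  # non-decreasing modulo 360 inside a cycle
  inside <- ph$phase_deg[ph$t_ms >= 750 & ph$t_ms < 1750]
  expect_true(all(diff(inside) %% 360 < 180, na.rm = TRUE))
})

test_that("asymmetric cycles still pin landmark phases exactly", {
  # asymmetric oscillation: fast rise, slow fall
  t_ms <- 0:4000
  v <- sin(2 * pi * t_ms / 1000) + 0.35 * sin(4 * pi * t_ms / 1000 + 1)
  tr <- tibble::tibble(t_ms = t_ms, value = v)
  cy <- detect_hippus_cycles(tr, smoothing_ms = 1)
  expect_gte(nrow(cy), 2)
  ph <- assign_phase(tr, cy)
  for (i in seq_len(nrow(cy))) {
    expect_equal(ph$phase_deg[ph$t_ms == cy$t_max_dil_rate[i]], 0, tolerance = 1e-9)
    expect_equal(ph$phase_deg[ph$t_ms == cy$t_max[i]], 90, tolerance = 1e-9)
    expect_equal(ph$phase_deg[ph$t_ms == cy$t_max_con_rate[i]], 180, tolerance = 1e-9)
  }
})

test_that("phase-triggered rate maps recover the imposed lead and slope", {
  sim <- simulate_session(sim_config(
    n_trials = 150, lc_pupil_coupling = 1, lc_pupil_lead_ms = 270,
    hippus = list(period_ms = 600), acc_pairs = list(), beep_fraction = 0,
    seed = 201
  ))
  m <- phase_triggered_map(sim$session, "rate", unit = "lc1")
  expect_s3_class(m, "lcacc_phase_map")
  expect_true(all(c("offset_ms", "phase_deg", "value", "n") %in% names(m)))
  f <- fit_phase_slope(m, "peaks")
  expect_true(f$reliable)
  expect_lt(f$slope, -0.54)
  expect_gt(f$slope, -0.66)
  expect_gt(f$zero_phase_time_ms, 270 - 60)
  expect_lt(f$zero_phase_time_ms, 270 + 60)
  g <- glance(f)
  expect_equal(g$slope, f$slope)
  expect_equal(tidy(f)$estimate[1], f$slope)
})

test_that("slope tracks -360/T across hippus periods", {
  for (T in c(800, 1000)) {
    sim <- simulate_session(sim_config(
      n_trials = 120, lc_pupil_coupling = 1, lc_pupil_lead_ms = 200,
      hippus = list(period_ms = T), acc_pairs = list(), beep_fraction = 0,
      trial_len_range_ms = c(4400, 5000), seed = 300 + T
    ))
    f <- fit_phase_slope(phase_triggered_map(sim$session, "rate", unit = "lc1"),
                         "peaks")
    expect_equal(f$slope, -360 / T, tolerance = 0.10 * 360 / T)
  }
})

test_that("uncoupled units give flat, unreliable maps", {
  sim <- simulate_session(sim_config(
    n_trials = 100, lc_pupil_coupling = 0, lc_rate_hz = 3, lc_rate_sdlog = 0,
    acc_pairs = list(), beep_fraction = 0, pupil_sample_rate_hz = 250,
    seed = 41
  ))
  m <- phase_triggered_map(sim$session, "rate", unit = "lc1",
                           offsets_ms = seq(-600, 600, 100))
  # z-scored flat map: modest cell-to-cell spread, no structure
  f <- fit_phase_slope(m, "peaks")
  expect_false(isTRUE(f$reliable) && abs(f$slope) > 0.3)
})

test_that("r_sc phase maps report the pair correlation across occurrences", {
  # pair with a synchronous shared Poisson train over the whole trial:
  # counts in any window correlate at shared / (shared + private) = 0.5
  s <- withr::with_seed(55, {
    n <- 100
    L <- 4000
    hip <- list(period_ms = 600, amplitude = 1, noise_sd = 0)
    phi0 <- runif(n, 0, 2 * pi)
    mk_train <- function(rate) sort(runif(rpois(1, rate * L / 1000), 0, L))
    spk <- purrr::map_dfr(seq_len(n), function(i) {
      shared <- mk_train(2)
      dplyr::bind_rows(
        tibble::tibble(trial_id = i, unit_id = "a1",
                       time_ms = sort(c(mk_train(2), shared))),
        tibble::tibble(trial_id = i, unit_id = "a2",
                       time_ms = sort(c(mk_train(2), shared)))
      )
    })
    pup <- purrr::map_dfr(seq_len(n), function(i) {
      tr <- simulate_pupil(L, hip, phi0 = phi0[i], sample_rate_hz = 250)
      tibble::tibble(trial_id = i, sample_index = seq_len(nrow(tr)),
                     value = tr$value)
    })
    session(
      session_id = "sync-pair",
      units = tibble::tibble(unit_id = c("a1", "a2"), region = "ACC"),
      trials = tibble::tibble(trial_id = seq_len(n), fix_on = 200,
                              stable_fix_on = 500, beep_time = NA_real_,
                              trial_end = L, gaze_ok = TRUE),
      spikes = spk,
      pupil = list(sample_rate = 250, t0 = 0, samples = pup)
    )
  })
  m <- phase_triggered_map(s, "rsc", pair = c("a1", "a2"),
                           offsets_ms = seq(-300, 300, 100))
  expect_s3_class(m, "lcacc_phase_map")
  expect_gt(median(m$value, na.rm = TRUE), 0.35)
  expect_lt(median(m$value, na.rm = TRUE), 0.65)
})

test_that("degenerate maps are flagged instead of fitted", {
  m <- tibble::tibble(
    offset_ms = rep(seq(-200, 200, 100), each = 3),
    phase_deg = rep(c(5, 15, 25), 5),
    value = rep(c(1, 2, 1), 5),
    n = 50L
  )
  class(m) <- c("lcacc_phase_map", class(m))
  attr(m, "quantity") <- "rate"
  f <- fit_phase_slope(m, "peaks")
  expect_false(f$reliable)
  expect_equal(f$slope, 0)
})
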