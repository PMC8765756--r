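test_that("PSTH recovers flat and single-spike structures", {
  # homogeneous Poisson at 2 sp/s: every bin within 3 sem of 2
  sim <- simulate_session(sim_config(
    n_trials = 500, lc_rate_hz = 2, lc_rate_sdlog = 0, lc_pupil_coupling = 0,
    beep_fraction = 1, responsive_fraction = 0, acc_pairs = list(),
    pupil_sample_rate_hz = 50, seed = 61
  ))
  p <- psth(sim$session, "lc1", align = "beep", bin_ms = 200,
            range_ms = c(-1000, 1000))
  expect_true(all(abs(p$rate - 2) <= 3 * p$sem))

  # one spike per trial at +100 ms in a 200 ms bin: rate 5 sp/s in that bin
  s <- session(
    session_id = "onespike",
    units = tibble::tibble(unit_id = "u", region = "LC"),
    trials = tibble::tibble(trial_id = 1:20, fix_on = 1, stable_fix_on = 2,
                            beep_time = 1000, trial_end = 3000, gaze_ok = TRUE),
    spikes = tibble::tibble(trial_id = 1:20, unit_id = "u", time_ms = 1100)
  )
  p2 <- psth(s, "u", bin_ms = 200, range_ms = c(-400, 400))
  expect_equal(p2$rate[p2$t_ms == 100], 5)
  expect_equal(sum(p2$rate), 5)
  expect_equal(p2$sem[p2$t_ms == 100], 0)

  # no spikes at all: all-zero PSTH
  s0 <- s
  s0$spikes <- s0$spikes[0, ]
  expect_true(all(psth(s0, "u", bin_ms = 200, range_ms = c(-400, 400))$rate == 0))
})

test_that("Fano time course shows gain quenching at the analytic level", {
  qs <- simulate_quench_trials(4000, rate_hz = 25, gain_sd = 0.4, seed = 71)
  ft <- fano_timecourse(qs, "u1", window_ms = 200, step_ms = 100,
                        range_ms = c(-800, 1000))
  pre <- mean(ft$fano[ft$t_ms < -100])
  post <- mean(ft$fano[ft$t_ms > 200])
  # Fano = 1 + lambda * sigma^2 = 1 + 5 * 0.16 = 1.8 before; 1 after
  expect_equal(pre, 1.8, tolerance = 0.1 * 1.8)
  expect_equal(post, 1.0, tolerance = 0.1)

  # deterministic spiking: Fano 0
  sdet <- session(
    session_id = "det",
    units = tibble::tibble(unit_id = "u", region = "LC"),
    trials = tibble::tibble(trial_id = 1:10, fix_on = 1, stable_fix_on = 2,
                            beep_time = 1000, trial_end = 2200, gaze_ok = TRUE),
    spikes = tibble::tibble(trial_id = rep(1:10, each = 2), unit_id = "u",
                            time_ms = rep(c(500, 1500), 10))
  )
  ftd <- fano_timecourse(sdet, "u", window_ms = 200, step_ms = 200,
                         range_ms = c(-800, 800))
  expect_true(all(ftd$fano[!is.na(ftd$fano)] == 0))
  expect_true(any(is.na(ftd$fano)))  # windows with zero mean are flagged
})

test_that("the burst-pause detector matches constructed cases and Poisson calibration", {
  s <- session(
    session_id = "bp",
    units = tibble::tibble(unit_id = "u", region = "LC"),
    trials = tibble::tibble(trial_id = 1:2, fix_on = 1, stable_fix_on = 2,
                            beep_time = 1000, trial_end = 3000, gaze_ok = TRUE),
    spikes = tibble::tibble(trial_id = c(1L, 1L), unit_id = "u",
                            time_ms = c(1050, 1120))
  )
  cl <- detect_lc_evoked_response(s, "u")
  expect_true(cl$responsive[1])    # burst of 2, silent pause window
  expect_false(cl$responsive[2])   # no spikes anywhere
  expect_equal(cl$burst_count, c(2L, 0L))

  # calibration on burst-free Poisson trials (rate 2 sp/s):
  # P(responsive) = P(Pois(0.6) >= 2) * P(Pois(1.0) = 0)
  sim <- simulate_session(sim_config(
    n_trials = 3000, lc_rate_hz = 2, lc_rate_sdlog = 0, lc_pupil_coupling = 0,
    beep_fraction = 1, responsive_fraction = 0, acc_pairs = list(),
    pupil_sample_rate_hz = 50, trial_len_range_ms = c(2400, 2600), seed = 81
  ))
  cl2 <- detect_lc_evoked_response(sim$session)
  p_cf <- (1 - ppois(1, 0.6)) * dpois(0, 1.0)
  expect_lt(abs(mean(cl2$responsive) - p_cf),
            3 * sqrt(p_cf * (1 - p_cf) / nrow(cl2)))

  # windows that do not fit in the trial error out
  s_short <- s
  s_short$trials$trial_end <- 1500
  s_short$spikes <- s_short$spikes[s_short$spikes$time_ms < 1500, ]
  expect_error(detect_lc_evoked_response(s_short, "u"), regexp = "window")
})

test_that("fake-beep classification is seeded and hits inserted bursts", {
  sim <- simulate_session(sim_config(
    n_trials = 400, beep_fraction = 0.25, acc_pairs = list(),
    pupil_sample_rate_hz = 50, seed = 91
  ))
  f1 <- detect_fake_beep(sim$session, seed = 5)
  f2 <- detect_fake_beep(sim$session, seed = 5)
  expect_identical(f1, f2)
  expect_true(all(f1$trial_id %in%
                    sim$session$trials$trial_id[is.na(sim$session$trials$beep_time)]))
  # virtual times follow the real beep schedule
  offs <- f1$event_ms - 500
  expect_true(all(offs >= 1000 & offs <= 1500))

  # spontaneous bursts inserted at known virtual times are detected
  base <- sim$session
  fb <- detect_fake_beep(base, seed = 6)
  hot <- fb$trial_id[seq_len(100)]
  extra <- tibble::tibble(
    trial_id = rep(hot, each = 3), unit_id = "lc1",
    time_ms = rep(fb$event_ms[seq_len(100)], each = 3) + c(20, 60, 120)
  )
  # silence the pause window on those trials
  ev <- fb$event_ms[seq_len(100)][match(base$spikes$trial_id, hot)]
  drop <- !is.na(ev) & base$spikes$unit_id == "lc1" &
    base$spikes$time_ms >= ev + 300 & base$spikes$time_ms < ev + 800
  base$spikes <- dplyr::arrange(
    dplyr::bind_rows(base$spikes[!drop, ], extra),
    trial_id, unit_id, time_ms
  )
  fb2 <- detect_fake_beep(base, seed = 6)
  expect_gte(mean(fb2$responsive[fb2$trial_id %in% hot]), 0.95)
})

test_that("pre/post r_sc differences recover an event-locked gate shift", {
  sim <- simulate_session(sim_config(
    n_trials = 900, acc_pairs = replicate(30, beep_gate_spec(), simplify = FALSE),
    pupil_sample_rate_hz = 50, seed = 101
  ))
  s <- sim$session
  cl <- detect_lc_evoked_response(s)
  pp <- pre_post_rsc_difference(s, truth_pairs(sim), cl, bin_sizes_ms = 1000)
  dr <- pp$differences
  ci_r <- bootstrap_median_ci(dr$delta_rsc[dr$group == "responsive"], seed = 1)
  expect_lt(abs(ci_r$estimate - 0.25), 0.08)
  ci_n <- bootstrap_median_ci(dr$delta_rsc[dr$group == "non_responsive"], seed = 1)
  expect_lte(ci_n$lower, 0.05)
  expect_gte(ci_n$upper, -0.05)
  # invariant: used + removed = condition trials
  expect_true(all(pp$records$n_trials_used + pp$records$n_outliers_removed %in%
                    table(cl$responsive)))
})

test_that("fake-beep contrast is null when nothing changes at the virtual event", {
  sim <- simulate_session(sim_config(
    n_trials = 700, acc_pairs = replicate(25, beep_gate_spec(), simplify = FALSE),
    pupil_sample_rate_hz = 50, seed = 111
  ))
  fb <- detect_fake_beep(sim$session, seed = 7)
  pp <- pre_post_rsc_difference(sim$session, truth_pairs(sim), fb,
                                bin_sizes_ms = 1000)
  ci <- bootstrap_median_ci(pp$contrast$contrast, seed = 1)
  expect_lte(ci$lower, 0)
  expect_gte(ci$upper, 0)
})

test_that("pupil responses split by median and track LC burst size", {
  sim <- simulate_session(sim_config(n_trials = 500, acc_pairs = list(),
                                     pupil_sample_rate_hz = 250, seed = 121))
  pr <- pupil_response(sim$session)
  expect_true(all(c("baseline", "evoked_amp", "evoked_group",
                    "baseline_group") %in% names(pr)))
  # median splits are balanced within 1
  expect_lte(abs(diff(table(pr$evoked_group))), 1)
  expect_lte(abs(diff(table(pr$baseline_group))), 1)
  # evoked amplitude correlates with the LC burst count by construction
  cl <- detect_lc_evoked_response(sim$session)
  j <- dplyr::inner_join(pr, cl, by = "trial_id")
  ct <- suppressWarnings(cor.test(j$burst_count, j$evoked_amp,
                                  method = "spearman"))
  expect_gt(unname(ct$estimate), 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("r_sc time courses flag an imposed post-event shared-input step", {
  sim <- simulate_session(sim_config(
    n_trials = 900, acc_pairs = replicate(25, beep_gate_spec(), simplify = FALSE),
    pupil_sample_rate_hz = 50, seed = 131
  ))
  s <- sim$session
  cl <- detect_lc_evoked_response(s)
  grp <- tibble::tibble(
    trial_id = cl$trial_id,
    group = ifelse(cl$responsive, "evoked", "no_evoked")
  )
  tc <- timecourse_rsc(s, truth_pairs(sim), grp, align = "beep",
                       window_ms = 500, step_ms = 250,
                       range_ms = c(-1000, 1000), slope_epoch_ms = c(0, 800))
  expect_setequal(unique(tc$series$group), c("evoked", "no_evoked"))
  med <- tc$series |>
    dplyr::group_by(group, t_ms) |>
    dplyr::summarise(r = median(r, na.rm = TRUE), .groups = "drop")
  post_ev <- med$r[med$group == "evoked" & med$t_ms > 250]
  pre_ev <- med$r[med$group == "evoked" & med$t_ms < -250]
  expect_gt(mean(post_ev), mean(pre_ev))
  # the no-evoked group stays near its pre-event level
  post_ne <- med$r[med$group == "no_evoked" & med$t_ms > 250]
  pre_ne <- med$r[med$group == "no_evoked" & med$t_ms < -250]
  expect_lt(abs(mean(post_ne) - mean(pre_ne)), 0.1)
})
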