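#' Correlated spike counts from the common-input Poisson model
#'
#' Draws per-trial counts `N1 = B1 + C`, `N2 = B2 + C` with independent
#' private components `B1, B2 ~ Poisson(lambda_private)` and a shared
#' component `C ~ Poisson(lambda_shared)`. The implied Pearson correlation
#' is exactly `lambda_shared / (lambda_private + lambda_shared)`, which is
#' the analytic ground truth used throughout the test battery.
#'
#' @param n_trials Number of trials (at least 1).
#' @param lambda_private,lambda_shared Non-negative expected counts per
#'   window.
#' @param seed Optional integer seed.
#' @return Tibble with columns `count_a`, `count_b`.
#' @export
simulate_correlated_counts <- function(n_trials, lambda_private, lambda_shared,
                                       seed = NULL) {
  stopifnot(n_trials >= 1)
  if (lambda_private < 0 || lambda_shared < 0) rlang::abort("rates must be >= 0")
  run <- function() {
    shared <- stats::rpois(n_trials, lambda_shared)
    tibble::tibble(
      count_a = stats::rpois(n_trials, lambda_private) + shared,
      count_b = stats::rpois(n_trials, lambda_private) + shared
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' ACC pair specification for the session generator
#'
#' A pair is defined by its private and shared Poisson intensities at the
#' reference window, optionally gated by the simulated LC state:
#'
#' * `gate_on = "none"`: fixed intensities, expected counts per 1.1 s
#'   stable-fixation reference window, stationary over the trial.
#' * `gate_on = "lc"`: `gate` is `list(zero = c(private=, shared=),
#'   nonzero = ...)`, expected counts per 1.1 s reference window; which
#'   element applies on a trial is decided by the simulated LC unit's spike
#'   count in that trial's reference window.
#' * `gate_on = "beep"`: `gate` is `list(pre = ..., post = ...)`, expected
#'   counts per 1 s window; `pre` applies in the second before the beep and
#'   on every trial without an evoked LC response, `post` in the second
#'   after the beep on trials with an evoked response.
#'
#' @param lambda_private,lambda_shared Baseline intensities (used directly
#'   for `gate_on = "none"`; for gated pairs they are ignored in favour of
#'   `gate`).
#' @param gate_on One of `"none"`, `"lc"`, `"beep"`.
#' @param gate Named list as described above; each element is a numeric
#'   vector with entries `private` and `shared`.
#' @return A `pair_spec` list.
#' @export
pair_spec <- function(lambda_private = 4, lambda_shared = 1,
                      gate_on = c("none", "lc", "beep"), gate = NULL) {
  gate_on <- match.arg(gate_on)
  if (lambda_private < 0 || lambda_shared < 0) rlang::abort("rates must be >= 0")
  if (gate_on == "lc" && !all(c("zero", "nonzero") %in% names(gate))) {
    rlang::abort("lc gate needs elements 'zero' and 'nonzero'")
  }
  if (gate_on == "beep" && !all(c("pre", "post") %in% names(gate))) {
    rlang::abort("beep gate needs elements 'pre' and 'post'")
  }
  if (!is.null(gate)) {
    for (g in gate) {
      if (!all(c("private", "shared") %in% names(g)) || any(g < 0)) {
        rlang::abort("each gate element needs non-negative 'private' and 'shared'")
      }
    }
  }
  structure(list(lambda_private = lambda_private, lambda_shared = lambda_shared,
                 gate_on = gate_on, gate = gate),
            class = "lcacc_pair_spec")
}

#' Session generator configuration
#'
#' Bundles every parameter of [simulate_session()] with defaults that match
#' the recorded study conditions: beeps on ~25% of fixation trials, an LC
#' unit whose per-trial rate is lognormal (median 1.2 sp/s, sdlog 1) so that
#' roughly a third of trials carry no LC spike and the nonzero trials have a
#' median [IQR] rate of 1.8 [0.9-3.6] sp/s in the 1.1 s reference window, a
#' quasi-periodic hippus with a ~600 ms period that the LC modulation leads,
#' and a beep-evoked LC burst-pause kernel with a coupled pupil dilation.
#'
#' @param n_trials Number of trials.
#' @param trial_len_range_ms Range (min, max) of the stable-fixation span;
#'   each trial's length is drawn uniformly from it. The default keeps every
#'   trial long enough for the 2.1 s stable-fixation analysis span and the
#'   1 s pre/post beep windows.
#' @param beep_fraction Fraction of trials with a beep (default 0.25).
#' @param responsive_fraction Fraction of beep trials on which the LC emits
#'   the evoked burst-pause response (default 0.5, between the two monkeys'
#'   54% and 43%).
#' @param lc_rate_hz Median LC rate in sp/s (default 1.2).
#' @param lc_rate_sdlog Lognormal spread of the per-trial LC rate (default 1).
#' @param lc_pupil_coupling Modulation depth m of the LC rate by pupil
#'   phase, `rate ~ 1 + m cos(...)` (default 0.5).
#' @param lc_pupil_lead_ms Temporal offset d between the hippus 0-degree
#'   landmark (maximum dilation rate) and the LC modulation peak (default
#'   270 ms); with a periodic signal a lag of d is indistinguishable from a
#'   lead of T - d, and the phase-map analysis reports this same d as its
#'   0-degree crossing.
#' @param hippus List: `period_ms` (default 600), `amplitude` (default 1,
#'   arbitrary units), `noise_sd` (default 0.1, smoothed Gaussian).
#' @param evoked List: `burst_rate_hz` (50), `burst_dur_ms` (200),
#'   `pause_dur_ms` (600), `pupil_dilation_amp` (0.5), `dilation_latency_ms`
#'   (500).
#' @param acc_pairs List of [pair_spec()]s (default: ten ungated
#'   common-input pairs with private 4, shared 1).
#' @param fix_on_ms,stable_fix_on_ms Event times, ms from trial start.
#' @param beep_after_range_ms Beep onset window after stable fixation
#'   (default 1000-1500 ms).
#' @param pupil_sample_rate_hz Pupil sampling rate (default 1000).
#' @param gaze_pass_prob Probability a trial passes the gaze criterion
#'   (default 1; the recorded data are gaze-screened upstream).
#' @param seed Optional integer seed; the whole session is reproducible
#'   from it.
#' @return A `lcacc_sim_config` list.
#' @export
sim_config <- function(n_trials = 200,
                       trial_len_range_ms = c(3600, 5000),
                       beep_fraction = 0.25,
                       responsive_fraction = 0.5,
                       lc_rate_hz = 1.2,
                       lc_rate_sdlog = 1,
                       lc_pupil_coupling = 0.5,
                       lc_pupil_lead_ms = 270,
                       hippus = list(),
                       evoked = list(),
                       acc_pairs = NULL,
                       fix_on_ms = 200,
                       stable_fix_on_ms = 500,
                       beep_after_range_ms = c(1000, 1500),
                       pupil_sample_rate_hz = 1000,
                       gaze_pass_prob = 1,
                       seed = NULL) {
  hippus <- utils::modifyList(
    list(period_ms = 600, amplitude = 1, noise_sd = 0.1), hippus
  )
  evoked <- utils::modifyList(
    list(burst_rate_hz = 50, burst_dur_ms = 200, pause_dur_ms = 600,
         pupil_dilation_amp = 0.5, dilation_latency_ms = 500), evoked
  )
  if (is.null(acc_pairs)) acc_pairs <- replicate(10, pair_spec(), simplify = FALSE)
  cfg <- list(n_trials = n_trials, trial_len_range_ms = trial_len_range_ms,
              beep_fraction = beep_fraction,
              responsive_fraction = responsive_fraction,
              lc_rate_hz = lc_rate_hz, lc_rate_sdlog = lc_rate_sdlog,
              lc_pupil_coupling = lc_pupil_coupling,
              lc_pupil_lead_ms = lc_pupil_lead_ms,
              hippus = hippus, evoked = evoked, acc_pairs = acc_pairs,
              fix_on_ms = fix_on_ms, stable_fix_on_ms = stable_fix_on_ms,
              beep_after_range_ms = beep_after_range_ms,
              pupil_sample_rate_hz = pupil_sample_rate_hz,
              gaze_pass_prob = gaze_pass_prob, seed = seed)
  if (beep_fraction < 0 || beep_fraction > 1) rlang::abort("beep_fraction in [0,1]")
  if (hippus$period_ms <= 0) rlang::abort("hippus period must be > 0")
  if (lc_rate_hz < 0 || evoked$burst_rate_hz < 0) rlang::abort("rates must be >= 0")
  if (stable_fix_on_ms + beep_after_range_ms[2] +
      evoked$burst_dur_ms + evoked$pause_dur_ms > trial_len_range_ms[1] + stable_fix_on_ms) {
    rlang::abort("evoked kernel does not fit inside the shortest trial")
  }
  structure(cfg, class = "lcacc_sim_config")
}

#' Simulate a pupil trace for one trial
#'
#' Quasi-periodic hippus `A sin(2 pi t / T + phi0)` plus smoothed Gaussian
#' noise; on beep trials an additive dilation kernel (alpha function rising
#' to `amp` at `dilation_latency_ms` after the beep, then decaying).
#'
#' @param trial_len_ms Trial length.
#' @param hippus List with `period_ms`, `amplitude`, `noise_sd`.
#' @param phi0 Phase offset in radians.
#' @param sample_rate_hz Sampling rate.
#' @param beep_ms Beep time or `NA`.
#' @param dilation_amp Peak amplitude of the evoked dilation.
#' @param dilation_latency_ms Time to the dilation peak.
#' @param seed Optional integer seed (noise only).
#' @return Tibble `t_ms`, `value`.
#' @export
simulate_pupil <- function(trial_len_ms, hippus, phi0 = 0,
                           sample_rate_hz = 1000, beep_ms = NA,
                           dilation_amp = 0, dilation_latency_ms = 500,
                           seed = NULL) {
  run <- function() {
    t_ms <- seq(0, trial_len_ms, by = 1000 / sample_rate_hz)
    v <- hippus$amplitude * sin(2 * pi * t_ms / hippus$period_ms + phi0)
    if (hippus$noise_sd > 0) {
      k <- max(1, round(sample_rate_hz * 0.05))
      v <- v + moving_average(stats::rnorm(length(t_ms), 0, hippus$noise_sd), k)
    }
    if (!is.na(beep_ms) && dilation_amp != 0) {
      tau <- (t_ms - beep_ms) / dilation_latency_ms
      kern <- ifelse(tau > 0, dilation_amp * tau * exp(1 - tau), 0)
      v <- v + kern
    }
    tibble::tibble(t_ms = t_ms, value = v)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate LC spikes for one trial
#'
#' Inhomogeneous Poisson process with rate
#' `base * (1 + m cos(2 pi (t - d) / T + phi0))`, phase-locked to the same
#' hippus oscillator as the trial's pupil trace so the LC modulation peak
#' falls `d` ms after the pupil's maximum-dilation-rate landmark. On evoked
#' trials an additive burst of `burst_rate_hz` for `burst_dur_ms` after the
#' beep is followed by a hard pause (rate 0) of `pause_dur_ms`.
#'
#' @param trial_len_ms Trial length.
#' @param base_rate_hz Baseline rate.
#' @param coupling Modulation depth m in `[0, 1]`.
#' @param period_ms,lead_ms,phi0 Hippus period T, temporal offset d, and the
#'   trial's phase offset (radians).
#' @param beep_ms Beep time or `NA`.
#' @param evoked `NULL`, or the evoked kernel list (see [sim_config()]);
#'   applied only when `beep_ms` is given.
#' @param seed Optional integer seed.
#' @return Sorted numeric spike times in ms.
#' @export
simulate_lc_spikes <- function(trial_len_ms, base_rate_hz, coupling = 0,
                               period_ms = 600, lead_ms = 270, phi0 = 0,
                               beep_ms = NA, evoked = NULL, seed = NULL) {
  stopifnot(base_rate_hz >= 0, coupling >= 0, coupling <= 1)
  rate_fn <- function(t) {
    r <- base_rate_hz *
      (1 + coupling * cos(2 * pi * (t - lead_ms) / period_ms + phi0))
    if (!is.na(beep_ms) && !is.null(evoked)) {
      in_burst <- t >= beep_ms & t < beep_ms + evoked$burst_dur_ms
      in_pause <- t >= beep_ms + evoked$burst_dur_ms &
        t < beep_ms + evoked$burst_dur_ms + evoked$pause_dur_ms
      r <- r + ifelse(in_burst, evoked$burst_rate_hz, 0)
      r[in_pause] <- 0
    }
    r
  }
  rmax <- base_rate_hz * (1 + coupling) +
    if (!is.na(beep_ms) && !is.null(evoked)) evoked$burst_rate_hz else 0
  run <- function() {
    if (rmax <= 0) return(numeric(0))
    n <- stats::rpois(1, rmax * trial_len_ms / 1000)
    if (n == 0) return(numeric(0))
    cand <- stats::runif(n, 0, trial_len_ms)
    keep <- stats::runif(n) < rate_fn(cand) / rmax
    sort(cand[keep])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# spikes for one unit of a common-input pair inside one window: total count
# n placed i.i.d. uniform, so a sub-bin of fraction q holds an independent
# Binomial(n, q) thinning and pairwise r_sc grows linearly with bin size
# toward the reference-window value
uniform_window_spikes <- function(n, lo, hi) {
  if (n == 0) return(numeric(0))
  stats::runif(n, lo, hi)
}

#' Simulate a full session with analytic ground truth
#'
#' Assembles trials, a hippus-coupled LC unit with beep-evoked burst-pause
#' responses, a pupil trace whose evoked dilation amplitude is proportional
#' to the realized LC burst size, and ACC unit pairs built from the
#' common-input Poisson model, optionally gated by the LC state (see
#' [pair_spec()]). Pair counts are constructed at a reference window (the
#' 1.1 s stable-fixation window, or the 1 s pre/post beep windows for
#' beep-gated pairs) with the shared count placed at independent uniform
#' times in each unit; outside the reference windows the units fire
#' independent Poisson background at the matched marginal rate.
#'
#' @param config A [sim_config()].
#' @return List with `session` (an `lcacc_session`) and `truth`, a list
#'   holding the generative targets: per-pair r_sc by condition, the hippus
#'   period and LC temporal offset, the evoked kernel, the expected Fano
#'   factor (1, Poisson), and the per-trial beep/responsive flags.
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "lcacc_sim_config"))
  run <- function() with(config, {
    trial_id <- seq_len(n_trials)
    len <- stats::runif(n_trials, trial_len_range_ms[1], trial_len_range_ms[2])
    trial_end <- stable_fix_on_ms + len
    gaze_ok <- stats::runif(n_trials) < gaze_pass_prob
    is_beep <- stats::runif(n_trials) < beep_fraction
    beep_time <- ifelse(
      is_beep,
      stable_fix_on_ms + stats::runif(n_trials, beep_after_range_ms[1],
                                      beep_after_range_ms[2]),
      NA_real_
    )
    responsive <- is_beep & stats::runif(n_trials) < responsive_fraction
    phi0 <- stats::runif(n_trials, 0, 2 * pi)
    lc_base <- stats::rlnorm(n_trials, log(lc_rate_hz), lc_rate_sdlog)

    # LC unit
    lc_spk <- purrr::map(trial_id, function(i) {
      simulate_lc_spikes(
        trial_len_ms = trial_end[i], base_rate_hz = lc_base[i],
        coupling = lc_pupil_coupling, period_ms = hippus$period_ms,
        lead_ms = lc_pupil_lead_ms, phi0 = phi0[i],
        beep_ms = if (responsive[i]) beep_time[i] else NA,
        evoked = evoked
      )
    })
    burst_count <- vapply(trial_id, function(i) {
      if (!is_beep[i]) return(NA_integer_)
      as.integer(sum(lc_spk[[i]] >= beep_time[i] &
                       lc_spk[[i]] < beep_time[i] + evoked$burst_dur_ms))
    }, integer(1))

    # pupil; evoked dilation amplitude proportional to the realized burst
    expected_burst <- max(evoked$burst_rate_hz * evoked$burst_dur_ms / 1000, 1)
    pupil_samples <- purrr::map_dfr(trial_id, function(i) {
      amp <- if (is_beep[i]) {
        evoked$pupil_dilation_amp * burst_count[i] / expected_burst
      } else {
        0
      }
      tr <- simulate_pupil(
        trial_len_ms = trial_end[i], hippus = hippus, phi0 = phi0[i],
        sample_rate_hz = pupil_sample_rate_hz, beep_ms = beep_time[i],
        dilation_amp = amp, dilation_latency_ms = evoked$dilation_latency_ms
      )
      tibble::tibble(trial_id = i, sample_index = seq_len(nrow(tr)),
                     value = tr$value)
    })

    # LC reference-window counts decide the lc-gated pair condition
    ref_lo <- stable_fix_on_ms + 1000
    ref_hi <- ref_lo + 1100
    lc_ref <- vapply(lc_spk, function(sp) sum(sp >= ref_lo & sp < ref_hi),
                     numeric(1))
    lc_nonzero <- lc_ref > 0

    pair_tabs <- purrr::imap(acc_pairs, function(ps, j) {
      ua <- sprintf("acc%03da", j)
      ub <- sprintf("acc%03db", j)
      sim_pair_trials(ps, trial_id, trial_end, lc_nonzero, responsive,
                      beep_time, ref_lo, ref_hi, ua, ub)
    })

    units <- dplyr::bind_rows(
      tibble::tibble(unit_id = "lc1", region = "LC"),
      purrr::imap_dfr(acc_pairs, function(ps, j) {
        tibble::tibble(unit_id = sprintf("acc%03d%s", j, c("a", "b")),
                       region = "ACC")
      })
    )
    spikes <- dplyr::bind_rows(
      tibble::tibble(
        trial_id = rep(trial_id, lengths(lc_spk)),
        unit_id = "lc1",
        time_ms = unlist(lc_spk)
      ),
      dplyr::bind_rows(pair_tabs)
    )
    trials <- tibble::tibble(
      trial_id = as.integer(trial_id), fix_on = fix_on_ms,
      stable_fix_on = stable_fix_on_ms, beep_time = beep_time,
      trial_end = trial_end, gaze_ok = gaze_ok
    )
    s <- session(
      session_id = "sim",
      units = units, trials = trials,
      spikes = dplyr::arrange(spikes, .data$trial_id, .data$unit_id, .data$time_ms),
      pupil = list(sample_rate = pupil_sample_rate_hz, t0 = 0,
                   samples = pupil_samples),
      meta = list(generator = "lcacc::simulate_session")
    )
    truth <- list(
      pairs = purrr::imap_dfr(acc_pairs, function(ps, j) {
        tgt <- pair_targets(ps)
        tibble::tibble(
          pair_id = sprintf("acc%03da:acc%03db", j, j),
          unit_a = sprintf("acc%03da", j), unit_b = sprintf("acc%03db", j),
          gate_on = ps$gate_on,
          r_all = tgt[["all"]], r_zero = tgt[["zero"]],
          r_nonzero = tgt[["nonzero"]],
          r_pre = tgt[["pre"]], r_post = tgt[["post"]],
          delta_rsc = tgt[["delta"]]
        )
      }),
      hippus_period_ms = hippus$period_ms,
      lc_lead_ms = lc_pupil_lead_ms,
      lc_coupling = lc_pupil_coupling,
      evoked = evoked,
      expected_fano = 1,
      trials = tibble::tibble(
        trial_id = as.integer(trial_id), beep = is_beep,
        responsive = responsive, lc_base_rate_hz = lc_base,
        lc_ref_count = as.integer(lc_ref), burst_count = burst_count,
        phi0 = phi0
      )
    )
    list(session = s, truth = truth)
  })
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

# analytic r_sc targets implied by a pair spec
pair_targets <- function(ps) {
  rr <- function(g) unname(g["shared"] / (g["shared"] + g["private"]))
  out <- c(all = NA_real_, zero = NA_real_, nonzero = NA_real_,
           pre = NA_real_, post = NA_real_, delta = NA_real_)
  if (ps$gate_on == "none") {
    out["all"] <- ps$lambda_shared / (ps$lambda_shared + ps$lambda_private)
  } else if (ps$gate_on == "lc") {
    out["zero"] <- rr(ps$gate$zero)
    out["nonzero"] <- rr(ps$gate$nonzero)
    out["delta"] <- out["nonzero"] - out["zero"]
  } else {
    out["pre"] <- rr(ps$gate$pre)
    out["post"] <- rr(ps$gate$post)
    out["delta"] <- out["post"] - out["pre"]
  }
  out
}

# spike tables for one ACC pair over all trials
sim_pair_trials <- function(ps, trial_id, trial_end, lc_nonzero, responsive,
                            beep_time, ref_lo, ref_hi, ua, ub) {
  n <- length(trial_id)
  emit <- function(unit, trial, times) {
    tibble::tibble(trial_id = rep(trial, lengths(times)),
                   unit_id = unit, time_ms = unlist(times))
  }
  if (ps$gate_on %in% c("none", "lc")) {
    lam <- matrix(c(ps$lambda_private, ps$lambda_shared), n, 2, byrow = TRUE)
    if (ps$gate_on == "lc") {
      lam[!lc_nonzero, ] <- matrix(ps$gate$zero[c("private", "shared")],
                                   sum(!lc_nonzero), 2, byrow = TRUE)
      lam[lc_nonzero, ] <- matrix(ps$gate$nonzero[c("private", "shared")],
                                  sum(lc_nonzero), 2, byrow = TRUE)
    }
    shared <- stats::rpois(n, lam[, 2])
    b1 <- stats::rpois(n, lam[, 1])
    b2 <- stats::rpois(n, lam[, 1])
    # background outside the reference window at the matched marginal rate
    bg_rate <- rowSums(lam) / 1.1 / 1000   # spikes per ms
    bg_pre <- ref_lo * bg_rate
    bg_post <- pmax(trial_end - ref_hi, 0) * bg_rate
    mk <- function(counts) {
      lapply(seq_len(n), function(i) {
        c(uniform_window_spikes(counts[i], ref_lo, ref_hi),
          uniform_window_spikes(stats::rpois(1, bg_pre[i]), 0, ref_lo),
          uniform_window_spikes(stats::rpois(1, bg_post[i]), ref_hi, trial_end[i]))
      })
    }
    dplyr::bind_rows(emit(ua, trial_id, mk(b1 + shared)),
                     emit(ub, trial_id, mk(b2 + shared)))
  } else {
    # beep gate: exact common-input structure in the 1 s windows around the
    # beep; stationary whole-trial structure at the pre intensities on
    # no-beep trials (any 1 s sub-window then has equal pre/post statistics)
    pre <- ps$gate$pre
    post <- ps$gate$post
    out_a <- vector("list", n)
    out_b <- vector("list", n)
    for (i in seq_len(n)) {
      if (!is.na(beep_time[i])) {
        bt <- beep_time[i]
        lam_post <- if (responsive[i]) post else pre
        sh1 <- stats::rpois(1, pre["shared"])
        sh2 <- stats::rpois(1, lam_post["shared"])
        w1 <- c(bt - 1000, bt)
        w2 <- c(bt, bt + 1000)
        bg <- sum(pre) / 1000  # spikes per ms outside the two windows
        spk <- function() {
          c(uniform_window_spikes(stats::rpois(1, pre["private"]) + sh1, w1[1], w1[2]),
            uniform_window_spikes(stats::rpois(1, lam_post["private"]) + sh2, w2[1], w2[2]),
            uniform_window_spikes(stats::rpois(1, bg * w1[1]), 0, w1[1]),
            uniform_window_spikes(stats::rpois(1, bg * (trial_end[i] - w2[2])),
                                  w2[2], trial_end[i]))
        }
        out_a[[i]] <- spk()
        out_b[[i]] <- spk()
      } else {
        L <- trial_end[i]
        sh <- stats::rpois(1, pre["shared"] * L / 1000)
        out_a[[i]] <- uniform_window_spikes(
          stats::rpois(1, pre["private"] * L / 1000) + sh, 0, L)
        out_b[[i]] <- uniform_window_spikes(
          stats::rpois(1, pre["private"] * L / 1000) + sh, 0, L)
      }
    }
    dplyr::bind_rows(emit(ua, trial_id, out_a), emit(ub, trial_id, out_b))
  }
}

#' Simulate trials with multiplicative gain for variability quenching
#'
#' Generates one unit firing Poisson spikes whose rate before the event is
#' scaled by a per-trial Gaussian gain (`g ~ N(1, gain_sd)`, truncated at 0)
#' and is fixed at the base rate afterwards. Counts in a pre-event window
#' holding `lambda` expected spikes then have Fano factor
#' `1 + lambda * gain_sd^2`, dropping to 1 after the event: the
#' doubly stochastic analogue of stimulus-driven variability quenching.
#'
#' @param n_trials Number of trials.
#' @param rate_hz Base firing rate (default 25 sp/s, i.e. 5 expected spikes
#'   per 200 ms window).
#' @param gain_sd SD of the pre-event gain (default 0.4).
#' @param event_ms Event (beep) time (default 1000 ms).
#' @param trial_len_ms Trial length (default 2200 ms).
#' @param seed Optional integer seed.
#' @return An `lcacc_session` with one LC unit and every trial a beep trial
#'   at `event_ms`; the realized gains are in `meta$gains`.
#' @export
simulate_quench_trials <- function(n_trials, rate_hz = 25, gain_sd = 0.4,
                                   event_ms = 1000, trial_len_ms = 2200,
                                   seed = NULL) {
  run <- function() {
    gains <- pmax(stats::rnorm(n_trials, 1, gain_sd), 0)
    spk <- lapply(seq_len(n_trials), function(i) {
      pre_n <- stats::rpois(1, rate_hz * gains[i] * event_ms / 1000)
      post_n <- stats::rpois(1, rate_hz * (trial_len_ms - event_ms) / 1000)
      sort(c(stats::runif(pre_n, 0, event_ms),
             stats::runif(post_n, event_ms, trial_len_ms)))
    })
    trials <- tibble::tibble(
      trial_id = seq_len(n_trials), fix_on = 1, stable_fix_on = 2,
      beep_time = event_ms, trial_end = trial_len_ms, gaze_ok = TRUE
    )
    session(
      session_id = "sim-quench",
      units = tibble::tibble(unit_id = "u1", region = "LC"),
      trials = trials,
      spikes = tibble::tibble(
        trial_id = rep(seq_len(n_trials), lengths(spk)),
        unit_id = "u1", time_ms = unlist(spk)
      ),
      meta = list(gains = NULL)
    ) -> s
    s$meta$gains <- gains
    s
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
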