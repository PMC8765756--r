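#' Event-aligned trial table
#'
#' @param s An `lcacc_session`.
#' @param align `"beep"` (beep trials, aligned to beep onset) or
#'   `"stable_fix"` (all trials, aligned to stable-fixation onset).
#' @return Tibble `trial_id`, `event_ms`, `trial_end`.
#' @export
align_events <- function(s, align = c("beep", "stable_fix")) {
  align <- match.arg(align)
  tr <- s$trials
  if (align == "beep") {
    tr <- tr[!is.na(tr$beep_time), ]
    tibble::tibble(trial_id = tr$trial_id, event_ms = tr$beep_time,
                   trial_end = tr$trial_end)
  } else {
    tibble::tibble(trial_id = tr$trial_id, event_ms = tr$stable_fix_on,
                   trial_end = tr$trial_end)
  }
}

# event-aligned count matrix: trials x windows, windows given by lo/hi (ms
# relative to event); trials whose windows would leave [0, trial_end] dropped
aligned_counts <- function(s, unit, events, lo, hi) {
  keep <- events$event_ms + min(lo) >= 0 & events$event_ms + max(hi) <= events$trial_end
  events <- events[keep, ]
  by_trial <- spikes_by_trial(s, unit, events$trial_id)
  m <- t(vapply(seq_len(nrow(events)), function(i) {
    count_in_windows(by_trial[[i]], events$event_ms[i] + lo,
                     events$event_ms[i] + hi)
  }, numeric(length(lo))))
  list(counts = m, trial_id = events$trial_id)
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate in fixed bins around an alignment event, with
#' the standard error of the mean across trials.
#'
#' @param s An `lcacc_session`.
#' @param unit Unit id.
#' @param align Passed to [align_events()].
#' @param bin_ms Bin width (default 50 ms).
#' @param range_ms Two-element window around the event (default
#'   `c(-1000, 1500)`). Trials that cannot cover it are dropped.
#' @return Tibble of class `lcacc_psth`: `t_ms` (bin center), `rate`
#'   (sp/s), `sem`, `n_trials`.
#' @export
psth <- function(s, unit, align = "beep", bin_ms = 50, range_ms = c(-1000, 1500)) {
  events <- align_events(s, align)
  if (nrow(events) == 0) rlang::abort("no alignment events")
  edges <- seq(range_ms[1], range_ms[2], by = bin_ms)
  ac <- aligned_counts(s, unit, events, edges[-length(edges)], edges[-1])
  rates <- ac$counts / (bin_ms / 1000)
  n <- nrow(rates)
  out <- tibble::tibble(
    t_ms = (edges[-length(edges)] + edges[-1]) / 2,
    rate = colMeans(rates),
    sem = apply(rates, 2, stats::sd) / sqrt(n),
    n_trials = n
  )
  structure(out, class = c("lcacc_psth", class(out)), unit = unit, bin_ms = bin_ms)
}

#' Fano-factor time course around an event
#'
#' Trial-to-trial Fano factor (variance/mean of spike counts) in sliding
#' windows relative to the alignment event; the drop after a stimulus is the
#' variability-quenching signature.
#'
#' @inheritParams psth
#' @param window_ms Counting window (default 200 ms).
#' @param step_ms Step between window centers (default 50 ms).
#' @return Tibble of class `lcacc_fano_timecourse`: `t_ms` (window center),
#'   `fano` (`NA` where the mean count is zero), `mean_count`, `n_trials`.
#' @export
fano_timecourse <- function(s, unit, align = "beep", window_ms = 200,
                            step_ms = 50, range_ms = c(-1000, 1500)) {
  events <- align_events(s, align)
  if (nrow(events) < 2) rlang::abort("need at least 2 trials")
  centers <- seq(range_ms[1] + window_ms / 2, range_ms[2] - window_ms / 2,
                 by = step_ms)
  ac <- aligned_counts(s, unit, events, centers - window_ms / 2,
                       centers + window_ms / 2)
  m <- colMeans(ac$counts)
  v <- apply(ac$counts, 2, stats::var)
  out <- tibble::tibble(
    t_ms = centers,
    fano = ifelse(m > 0, v / m, NA_real_),
    mean_count = m,
    n_trials = nrow(ac$counts)
  )
  structure(out, class = c("lcacc_fano_timecourse", class(out)),
            unit = unit, window_ms = window_ms)
}

#' Classify beep-evoked LC responses
#'
#' A trial is classified as having the characteristic evoked response when
#' the unit fires at least `burst_min` spikes in the burst window
#' `[event, event + burst_window_ms)` and at most `pause_max` spikes in the
#' following pause window of `pause_window_ms`. The burst-then-pause
#' criterion is a declared, parameterized contract; the defaults (300 ms /
#' at least 2 spikes, then 500 ms / 0 spikes) encode the transient
#' increase-then-decrease morphology of evoked LC responses.
#'
#' @param s An `lcacc_session`.
#' @param unit LC unit id (default: first LC unit).
#' @param burst_window_ms,burst_min Burst window and minimum spike count.
#' @param pause_window_ms,pause_max Pause window (starting at the end of the
#'   burst window) and maximum spike count.
#' @param events Optional tibble `trial_id`, `event_ms`, `trial_end`
#'   (default: beep trials). Windows must fit inside every trial.
#' @return Tibble: `trial_id`, `event_ms`, `burst_count`, `pause_count`,
#'   `responsive`.
#' @export
detect_lc_evoked_response <- function(s, unit = region_units(s, "LC")[1],
                                      burst_window_ms = 300, burst_min = 2,
                                      pause_window_ms = 500, pause_max = 0,
                                      events = align_events(s, "beep")) {
  if (nrow(events) == 0) rlang::abort("no events to classify")
  span <- burst_window_ms + pause_window_ms
  if (any(events$event_ms + span > events$trial_end)) {
    rlang::abort("burst + pause window exceeds a trial")
  }
  by_trial <- spikes_by_trial(s, unit, events$trial_id)
  burst <- purrr::map2_dbl(by_trial, events$event_ms,
                           ~ count_in_windows(.x, .y, .y + burst_window_ms))
  pause <- purrr::map2_dbl(by_trial, events$event_ms,
                           ~ count_in_windows(.x, .y + burst_window_ms, .y + span))
  tibble::tibble(
    trial_id = events$trial_id, event_ms = events$event_ms,
    burst_count = as.integer(burst), pause_count = as.integer(pause),
    responsive = burst >= burst_min & pause <= pause_max
  )
}

#' Fake-beep classification on no-beep trials
#'
#' Control analysis: assigns each no-beep trial a virtual event time drawn
#' from the real beep schedule (uniform 1000-1500 ms after stable fixation)
#' and applies the same burst-pause detector, so "responsive" flags mark
#' spontaneous LC transients comparable to the beep-evoked ones.
#'
#' @inheritParams detect_lc_evoked_response
#' @param seed Optional integer seed for the virtual times.
#' @param min_after_ms,max_after_ms Virtual-event offsets after stable
#'   fixation (defaults 1000 and 1500 ms).
#' @return As [detect_lc_evoked_response()], on no-beep trials, with
#'   `event_ms` holding the virtual times.
#' @export
detect_fake_beep <- function(s, unit = region_units(s, "LC")[1],
                             burst_window_ms = 300, burst_min = 2,
                             pause_window_ms = 500, pause_max = 0,
                             min_after_ms = 1000, max_after_ms = 1500,
                             seed = NULL) {
  tr <- s$trials[is.na(s$trials$beep_time), ]
  if (nrow(tr) == 0) rlang::abort("no no-beep trials")
  span <- burst_window_ms + pause_window_ms
  draw <- function() stats::runif(nrow(tr), min_after_ms, max_after_ms)
  offs <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  events <- tibble::tibble(trial_id = tr$trial_id,
                           event_ms = tr$stable_fix_on + offs,
                           trial_end = tr$trial_end)
  short <- events$event_ms + span > events$trial_end
  if (any(short)) {
    rlang::abort(paste0("trial ", events$trial_id[short][1],
                        " too short for the detector windows"))
  }
  detect_lc_evoked_response(s, unit, burst_window_ms, burst_min,
                            pause_window_ms, pause_max, events = events)
}

#' Pre/post event r_sc differences by trial group
#'
#' For each pair, bin size and trial group, computes r_sc (full
#' preprocessing chain) from counts in the window of `bin` ms immediately
#' preceding the event and the window immediately following it, and returns
#' the post - pre difference per group plus the between-group contrast
#' (first group minus second).
#'
#' @param s An `lcacc_session`.
#' @param pairs Tibble `unit_a`, `unit_b` (optionally `pair_id`).
#' @param classification Tibble `trial_id`, `event_ms`, `responsive` (from
#'   [detect_lc_evoked_response()] or [detect_fake_beep()]).
#' @param bin_sizes_ms Counting windows (default 1000 ms, the 1 s windows).
#' @param outlier_sd,min_trials As in [conditioned_rsc()].
#' @return List: `records` (r per pair x bin x group x phase), `differences`
#'   (post - pre per pair x bin x group), `contrast` (responsive minus
#'   non-responsive difference per pair x bin).
#' @export
pre_post_rsc_difference <- function(s, pairs, classification,
                                    bin_sizes_ms = 1000,
                                    outlier_sd = 3, min_trials = 5) {
  if (!"pair_id" %in% names(pairs)) {
    pairs$pair_id <- paste(pairs$unit_a, pairs$unit_b, sep = ":")
  }
  cl <- dplyr::inner_join(classification,
                          s$trials[, c("trial_id", "trial_end")], by = "trial_id")
  records <- purrr::map_dfr(bin_sizes_ms, function(b) {
    ok <- cl$event_ms - b >= 0 & cl$event_ms + b <= cl$trial_end
    cc <- cl[ok, ]
    units <- unique(c(pairs$unit_a, pairs$unit_b))
    cnt <- lapply(stats::setNames(units, units), function(u) {
      by_trial <- spikes_by_trial(s, u, cc$trial_id)
      pre <- purrr::map2_dbl(by_trial, cc$event_ms,
                             ~ count_in_windows(.x, .y - b, .y))
      post <- purrr::map2_dbl(by_trial, cc$event_ms,
                              ~ count_in_windows(.x, .y, .y + b))
      cbind(pre = pre, post = post)
    })
    purrr::pmap_dfr(pairs[, c("pair_id", "unit_a", "unit_b")],
                    function(pair_id, unit_a, unit_b) {
      purrr::map_dfr(c(TRUE, FALSE), function(grp) {
        idx <- which(cc$responsive == grp)
        purrr::map_dfr(c("pre", "post"), function(ph) {
          rec <- if (length(idx) >= 2) {
            rsc_pair(cnt[[unit_a]][idx, ph], cnt[[unit_b]][idx, ph],
                     outlier_sd, min_trials)
          } else {
            tibble::tibble(r = NA_real_, n_trials_used = length(idx),
                           n_outliers_removed = 0L)
          }
          dplyr::bind_cols(
            tibble::tibble(pair_id = pair_id, bin_size_ms = b,
                           group = ifelse(grp, "responsive", "non_responsive"),
                           phase = ph),
            rec
          )
        })
      })
    })
  })
  differences <- records |>
    dplyr::select("pair_id", "bin_size_ms", "group", "phase", "r") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "r",
                       names_prefix = "r_") |>
    dplyr::mutate(delta_rsc = .data$r_post - .data$r_pre)
  contrast <- differences |>
    dplyr::select("pair_id", "bin_size_ms", "group", "delta_rsc") |>
    tidyr::pivot_wider(names_from = "group", values_from = "delta_rsc") |>
    dplyr::mutate(contrast = .data$responsive - .data$non_responsive)
  list(records = records, differences = differences, contrast = contrast)
}

#' Evoked and baseline pupil response per trial
#'
#' Baseline is the mean pupil over the second before the event; the evoked
#' amplitude is the post-event maximum (search window `post_ms`, default
#' 2 s) minus baseline. Median splits of both measures, computed within the
#' session, label each trial `large`/`small` for grouping.
#'
#' @param s An `lcacc_session` with pupil data.
#' @param events Tibble `trial_id`, `event_ms` (default: beep trials).
#' @param pre_ms,post_ms Baseline and search windows (defaults 1000, 2000).
#' @return Tibble: `trial_id`, `baseline`, `evoked_amp`, `evoked_group`,
#'   `baseline_group`.
#' @export
pupil_response <- function(s, events = align_events(s, "beep"),
                           pre_ms = 1000, post_ms = 2000) {
  if (nrow(events) == 0) rlang::abort("no events")
  res <- purrr::pmap_dfr(events[, c("trial_id", "event_ms")],
                         function(trial_id, event_ms) {
    tr <- pupil_trial_trace(s, trial_id)
    pre <- tr$value[tr$t_ms >= event_ms - pre_ms & tr$t_ms < event_ms]
    post <- tr$value[tr$t_ms > event_ms & tr$t_ms <= event_ms + post_ms]
    if (length(pre) == 0 || length(post) == 0) {
      rlang::abort(paste0("trial ", trial_id, ": insufficient pupil trace"))
    }
    tibble::tibble(trial_id = trial_id, baseline = mean(pre),
                   evoked_amp = max(post) - mean(pre))
  })
  res |>
    dplyr::mutate(
      evoked_group = ifelse(.data$evoked_amp > stats::median(.data$evoked_amp),
                            "large", "small"),
      baseline_group = ifelse(.data$baseline > stats::median(.data$baseline),
                              "large", "small")
    )
}

#' r_sc time course around an event, by trial group
#'
#' Computes r_sc per pair in sliding windows aligned to the event,
#' separately for each trial group; tests each post-event window's per-pair
#' values against the pooled pre-event baseline windows (rank-sum); and
#' compares between groups the per-pair linear slope of r_sc over a
#' post-event epoch.
#'
#' @param s An `lcacc_session`.
#' @param pairs Tibble `unit_a`, `unit_b` (optionally `pair_id`).
#' @param groups Tibble `trial_id`, `group` (character); trials absent from
#'   it are ignored.
#' @param align Passed to [align_events()].
#' @param window_ms,step_ms Sliding window width and step (defaults 500,
#'   100 ms).
#' @param range_ms Window-center range around the event.
#' @param slope_epoch_ms Post-event epoch over which per-pair slopes are
#'   fit (default `c(100, 600)`).
#' @param outlier_sd,min_trials As in [conditioned_rsc()].
#' @return List: `series` (r per pair x window x group), `bin_tests`
#'   (per-window rank-sum vs pre-event baseline, per group), `slopes`
#'   (per-pair epoch slope per group), `slope_test` (between-group rank-sum
#'   on the slopes, when there are exactly 2 groups).
#' @export
timecourse_rsc <- function(s, pairs, groups, align = "stable_fix",
                           window_ms = 500, step_ms = 100,
                           range_ms = c(-1000, 1500),
                           slope_epoch_ms = c(100, 600),
                           outlier_sd = 3, min_trials = 5) {
  if (!"pair_id" %in% names(pairs)) {
    pairs$pair_id <- paste(pairs$unit_a, pairs$unit_b, sep = ":")
  }
  events <- align_events(s, align)
  events <- dplyr::inner_join(events, groups, by = "trial_id")
  centers <- seq(range_ms[1] + window_ms / 2, range_ms[2] - window_ms / 2,
                 by = step_ms)
  lo <- centers - window_ms / 2
  hi <- centers + window_ms / 2
  keep <- events$event_ms + min(lo) >= 0 & events$event_ms + max(hi) <= events$trial_end
  events <- events[keep, ]
  units <- unique(c(pairs$unit_a, pairs$unit_b))
  cnt <- lapply(stats::setNames(units, units), function(u) {
    aligned_counts(s, u, events, lo, hi)$counts
  })
  series <- purrr::pmap_dfr(pairs[, c("pair_id", "unit_a", "unit_b")],
                            function(pair_id, unit_a, unit_b) {
    purrr::map_dfr(unique(events$group), function(g) {
      idx <- which(events$group == g)
      purrr::map_dfr(seq_along(centers), function(j) {
        rec <- if (length(idx) >= 2) {
          rsc_pair(cnt[[unit_a]][idx, j], cnt[[unit_b]][idx, j],
                   outlier_sd, min_trials)
        } else {
          tibble::tibble(r = NA_real_, n_trials_used = length(idx),
                         n_outliers_removed = 0L)
        }
        dplyr::bind_cols(
          tibble::tibble(pair_id = pair_id, group = g, t_ms = centers[j]),
          rec
        )
      })
    })
  })
  baseline <- series[series$t_ms < 0, ]
  bin_tests <- series |>
    dplyr::filter(.data$t_ms >= 0) |>
    dplyr::group_by(.data$group, .data$t_ms) |>
    dplyr::group_modify(function(d, key) {
      base <- baseline$r[baseline$group == key$group]
      base <- base[!is.na(base)]
      r <- d$r[!is.na(d$r)]
      if (length(r) < 3 || length(base) < 3) {
        return(tibble::tibble(p_value = NA_real_, n = length(r)))
      }
      ht <- ranksum_test(r, base)
      tibble::tibble(p_value = ht$p_value, n = length(r))
    }) |>
    dplyr::ungroup()
  slopes <- series |>
    dplyr::filter(.data$t_ms >= slope_epoch_ms[1], .data$t_ms < slope_epoch_ms[2],
                  !is.na(.data$r)) |>
    dplyr::group_by(.data$pair_id, .data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) return(tibble::tibble(slope = NA_real_))
      tibble::tibble(slope = unname(stats::coef(stats::lm(r ~ t_ms, data = d))[2]))
    }) |>
    dplyr::ungroup()
  gl <- unique(events$group)
  slope_test <- if (length(gl) == 2) {
    a <- slopes$slope[slopes$group == gl[1] & !is.na(slopes$slope)]
    b <- slopes$slope[slopes$group == gl[2] & !is.na(slopes$slope)]
    if (length(a) >= 3 && length(b) >= 3) ranksum_test(a, b) else NULL
  } else {
    NULL
  }
  list(series = series, bin_tests = bin_tests, slopes = slopes,
       slope_test = slope_test)
}
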