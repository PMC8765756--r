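#' Pupil trace of one trial
#'
#' @param s An `lcacc_session`.
#' @param trial_id Trial to extract.
#' @return Tibble with `t_ms` (relative to trial start) and `value`.
#' @export
pupil_trial_trace <- function(s, trial_id) {
  ps <- s$pupil$samples
  ps <- ps[ps$trial_id == trial_id, ]
  tibble::tibble(
    t_ms = s$pupil$t0 + (ps$sample_index - 1) / s$pupil$sample_rate * 1000,
    value = ps$value
  )
}

# centered moving average; width in samples forced odd; edges use the
# shrinking window so the output has no NA and no phase lag
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  if (k == 1L || length(x) < 3) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  h <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect hippus cycles in a pupil trace
#'
#' Smooths the trace with a centered moving average and delimits cycles by
#' successive local minima. Shallow wiggles are pruned: whenever the
#' excursion between two adjacent minima fails to reach `min_amplitude`, the
#' higher minimum is discarded and the neighbouring cycles merged, so noise
#' on a flat trace yields no cycles at all. Within each surviving cycle the
#' five landmarks are located: the bounding minima, the maximum, and the
#' extrema of the smoothed derivative on the rising (maximum dilation rate)
#' and falling (maximum constriction rate) limbs. Incomplete cycles at the
#' trace boundaries are dropped. Adding a constant to the trace changes
#' nothing.
#'
#' @param trace Tibble with `t_ms` and `value` ([pupil_trial_trace()]), or a
#'   numeric vector with `sample_rate_hz` given.
#' @param smoothing_ms Moving-average width (default 50 ms).
#' @param min_amplitude Minimum peak-to-trough excursion for a real cycle,
#'   in trace units (default 0.1; tune to the hippus amplitude scale).
#' @param sample_rate_hz Needed only when `trace` is a bare vector.
#' @return Tibble, one row per complete cycle: `t_min_prev`,
#'   `t_max_dil_rate`, `t_max`, `t_max_con_rate`, `t_min_next` (ms).
#' @export
detect_hippus_cycles <- function(trace, smoothing_ms = 50, min_amplitude = 0.1,
                                 sample_rate_hz = NULL) {
  if (is.numeric(trace)) {
    stopifnot(!is.null(sample_rate_hz))
    trace <- tibble::tibble(t_ms = (seq_along(trace) - 1) / sample_rate_hz * 1000,
                            value = trace)
  }
  empty <- tibble::tibble(t_min_prev = double(), t_max_dil_rate = double(),
                          t_max = double(), t_max_con_rate = double(),
                          t_min_next = double())
  n <- nrow(trace)
  if (n < 5) return(empty)
  dt <- stats::median(diff(trace$t_ms))
  k <- round(smoothing_ms / dt)
  sm <- moving_average(trace$value, k)
  d <- diff(sm)
  # strict local minima of the smoothed trace (plateaus collapse leftward)
  sgn <- sign(d)
  nz <- sgn != 0
  if (!any(nz)) return(empty)
  run <- rle(sgn[nz])
  if (length(run$lengths) < 2) return(empty)
  idx_nz <- which(nz)
  ends <- cumsum(run$lengths)
  mins <- integer(0)
  for (i in seq_len(length(run$lengths) - 1)) {
    if (run$values[i] < 0 && run$values[i + 1] > 0) {
      mins <- c(mins, idx_nz[ends[i]] + 1L)
    }
  }
  if (length(mins) < 2) return(empty)
  # prune shallow oscillations: drop the higher of two adjacent minima when
  # the intervening peak is not at least min_amplitude above both
  repeat {
    if (length(mins) < 2) return(empty)
    depth <- vapply(seq_len(length(mins) - 1), function(i) {
      seg <- sm[mins[i]:mins[i + 1]]
      max(seg) - max(sm[mins[i]], sm[mins[i + 1]])
    }, numeric(1))
    if (all(depth >= min_amplitude)) break
    i <- which.min(depth)
    drop <- if (sm[mins[i]] > sm[mins[i + 1]]) i else i + 1L
    mins <- mins[-drop]
  }
  # derivative is re-smoothed with the same window: the raw central
  # difference amplifies whatever noise the first smoothing pass left
  deriv <- moving_average(c(NA, (sm[-(1:2)] - sm[1:(n - 2)]) / 2, NA)[-c(1, n)], k)
  deriv <- c(NA, deriv, NA)
  purrr::map_dfr(seq_len(length(mins) - 1), function(i) {
    a <- mins[i]; b <- mins[i + 1]
    pk <- a + which.max(sm[a:b]) - 1L
    if (pk <= a + 1 || pk >= b - 1) return(empty)
    rise <- a:pk
    fall <- pk:b
    tibble::tibble(
      t_min_prev = trace$t_ms[a],
      t_max_dil_rate = trace$t_ms[rise[which.max(deriv[rise])]],
      t_max = trace$t_ms[pk],
      t_max_con_rate = trace$t_ms[fall[which.min(deriv[fall])]],
      t_min_next = trace$t_ms[b]
    )
  })
}

# landmark phases in degrees: minima bracket the cycle at -90 and 270, with
# 0 = max dilation rate, 90 = max size, 180 = max constriction rate
.landmark_phases <- c(-90, 0, 90, 180, 270)

#' Assign pupil phase to trace samples
#'
#' Maps each cycle's landmarks to 0 degrees (maximum dilation rate), 90
#' (maximum size), 180 (maximum constriction rate) and 270 (minimum size),
#' interpolating linearly in time between consecutive landmarks (bounding
#' minima sit at 270 of the previous and current cycle). Samples outside
#' complete cycles get `NA`.
#'
#' @param trace Tibble with `t_ms`, `value`.
#' @param cycles Output of [detect_hippus_cycles()].
#' @return `trace` with an added `phase_deg` column in `[0, 360)`.
#' @export
assign_phase <- function(trace, cycles) {
  phase <- rep(NA_real_, nrow(trace))
  for (i in seq_len(nrow(cycles))) {
    cy <- cycles[i, ]
    knots_t <- c(cy$t_min_prev, cy$t_max_dil_rate, cy$t_max,
                 cy$t_max_con_rate, cy$t_min_next)
    if (any(diff(knots_t) <= 0)) next
    inside <- trace$t_ms >= cy$t_min_prev & trace$t_ms < cy$t_min_next
    phase[inside] <- stats::approx(knots_t, .landmark_phases,
                                   xout = trace$t_ms[inside])$y %% 360
  }
  dplyr::mutate(trace, phase_deg = phase)
}

# one occurrence time per cycle per phase-bin center, by inverting the
# piecewise-linear landmark map
phase_occurrences <- function(cycles, phase_bin_deg = 10) {
  centers <- seq(phase_bin_deg / 2, 360 - phase_bin_deg / 2, by = phase_bin_deg)
  # map [0,360) labels onto the cycle's native [-90, 270) span
  native <- ((centers + 90) %% 360) - 90
  purrr::map_dfr(seq_len(nrow(cycles)), function(i) {
    cy <- cycles[i, ]
    knots_t <- c(cy$t_min_prev, cy$t_max_dil_rate, cy$t_max,
                 cy$t_max_con_rate, cy$t_min_next)
    if (any(diff(knots_t) <= 0)) return(NULL)
    tibble::tibble(
      cycle = i,
      phase_deg = centers,
      t_ms = stats::approx(.landmark_phases, knots_t, xout = native)$y
    )
  })
}

#' Phase-triggered map of LC rate or ACC r_sc
#'
#' For every complete hippus cycle in every trial, each pupil phase has one
#' occurrence time. A cell of the map is (temporal offset, phase bin); its
#' value summarizes the signal in a `window_ms`-wide window centered
#' `offset` ms from each occurrence of that phase, pooled over all
#' occurrences in the session. For `"rate"` the value is the mean firing
#' rate of `unit`, z-scored across cells; for `"rsc"` it is the Pearson
#' spike-count correlation of the `pair` across occurrences. Windows that
#' would leave the trial are dropped; cells with fewer than `min_n`
#' occurrences are `NA`.
#'
#' @param s An `lcacc_session` with pupil data.
#' @param signal `"rate"` or `"rsc"`.
#' @param unit Unit id for `signal = "rate"` (default: first LC unit).
#' @param pair Character vector of two unit ids for `signal = "rsc"`.
#' @param offsets_ms Temporal offsets of the window center (default
#'   -1000 to 1000 ms in 100 ms steps).
#' @param window_ms Window width (default 500 ms).
#' @param phase_bin_deg Phase bin width (default 10 degrees, 36 bins).
#' @param smoothing_ms,min_amplitude Passed to [detect_hippus_cycles()].
#' @param min_n Minimum occurrences per cell (default 10).
#' @param zscore For `"rate"`: z-score the cell means per unit (default
#'   `TRUE`, matching how the maps are displayed).
#' @return Tibble of class `lcacc_phase_map`: `offset_ms`, `phase_deg`,
#'   `value`, `n`, plus attributes `quantity` and `window_ms`.
#' @export
phase_triggered_map <- function(s, signal = c("rate", "rsc"),
                                unit = region_units(s, "LC")[1], pair = NULL,
                                offsets_ms = seq(-1000, 1000, by = 100),
                                window_ms = 500, phase_bin_deg = 10,
                                smoothing_ms = 50, min_amplitude = 0.1,
                                min_n = 10, zscore = TRUE) {
  signal <- match.arg(signal)
  units <- if (signal == "rate") unit else pair
  stopifnot(length(units) == ifelse(signal == "rate", 1, 2), !anyNA(units))

  trial_ids <- s$trials$trial_id
  end_of <- stats::setNames(s$trials$trial_end, trial_ids)
  occ <- purrr::map_dfr(trial_ids, function(tr) {
    cycles <- detect_hippus_cycles(pupil_trial_trace(s, tr),
                                   smoothing_ms = smoothing_ms,
                                   min_amplitude = min_amplitude)
    if (nrow(cycles) == 0) return(NULL)
    dplyr::mutate(phase_occurrences(cycles, phase_bin_deg), trial_id = tr)
  })
  if (nrow(occ) == 0) {
    out <- tibble::tibble(offset_ms = double(), phase_deg = double(),
                          value = double(), n = integer())
    return(structure(out, class = c("lcacc_phase_map", class(out)),
                     quantity = signal, window_ms = window_ms))
  }

  half <- window_ms / 2
  grid <- tidyr::crossing(occ, offset_ms = offsets_ms) |>
    dplyr::mutate(lo = .data$t_ms + .data$offset_ms - half,
                  hi = .data$t_ms + .data$offset_ms + half) |>
    dplyr::filter(.data$lo >= 0, .data$hi <= end_of[as.character(.data$trial_id)])

  for (u in units) {
    by_trial <- spikes_by_trial(s, u)
    counts <- numeric(nrow(grid))
    for (tr in unique(grid$trial_id)) {
      sel <- grid$trial_id == tr
      counts[sel] <- count_in_windows(by_trial[[as.character(tr)]],
                                      grid$lo[sel], grid$hi[sel])
    }
    grid[[paste0("count_", match(u, units))]] <- counts
  }

  if (signal == "rate") {
    cells <- grid |>
      dplyr::group_by(.data$offset_ms, .data$phase_deg) |>
      dplyr::summarise(value = mean(.data$count_1) / (window_ms / 1000),
                       n = dplyr::n(), .groups = "drop")
    cells$value[cells$n < min_n] <- NA_real_
    if (zscore) {
      mu <- mean(cells$value, na.rm = TRUE)
      sdv <- stats::sd(cells$value, na.rm = TRUE)
      if (!is.na(sdv) && sdv > 0) cells$value <- (cells$value - mu) / sdv
    }
  } else {
    cells <- grid |>
      dplyr::group_by(.data$offset_ms, .data$phase_deg) |>
      dplyr::summarise(
        value = if (dplyr::n() >= min_n) {
          spike_count_correlation(.data$count_1, .data$count_2)
        } else {
          NA_real_
        },
        n = dplyr::n(), .groups = "drop"
      )
  }
  structure(cells, class = c("lcacc_phase_map", class(cells)),
            quantity = signal, window_ms = window_ms)
}

#' Fit a line to the extremum phase of a phase-triggered map
#'
#' Per temporal offset, finds the phase bin holding the map's extremum
#' (`mode = "peaks"` for rate maps, `"minima"` for r_sc maps), unwraps the
#' resulting phase sequence along offsets (adding multiples of 360 degrees
#' to minimize successive jumps), and fits ordinary least squares
#' `phase = slope * offset + intercept`. A diagonal with slope -360/T
#' degrees/ms is the signature of a fixed temporal relationship to a hippus
#' of period T; the delay is reported as the fitted line's 0-degree crossing
#' reduced into `[0, T)`. Fits whose slope is not reliably nonzero
#' (p >= 0.05) are flagged unreliable.
#'
#' @param map An `lcacc_phase_map`.
#' @param mode `"peaks"` or `"minima"`.
#' @param min_n Minimum occurrences a cell needs to enter the fit.
#' @return Object of class `lcacc_phase_fit` with elements `slope`
#'   (deg/ms), `intercept`, `zero_phase_time_ms`, `period_ms`, `p_value`,
#'   `reliable`, `n_offsets`, `mode`, and the underlying `points`.
#' @export
fit_phase_slope <- function(map, mode = c("peaks", "minima"), min_n = 10) {
  mode <- match.arg(mode)
  df <- map[!is.na(map$value) & map$n >= min_n, ]
  pts <- df |>
    dplyr::group_by(.data$offset_ms) |>
    dplyr::summarise(
      phase_deg = .data$phase_deg[if (mode == "peaks") which.max(.data$value)
                                  else which.min(.data$value)],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$offset_ms)
  if (nrow(pts) < 3) rlang::abort("need at least 3 offsets with a defined extremum")
  ph <- pts$phase_deg
  for (i in 2:length(ph)) {
    k <- round((ph[i - 1] - ph[i]) / 360)
    ph[i] <- ph[i] + 360 * k
  }
  pts$phase_unwrapped <- ph
  if (stats::sd(ph) == 0) {
    fit <- list(slope = 0, intercept = ph[1], zero_phase_time_ms = NA_real_,
                period_ms = NA_real_, p_value = NA_real_, reliable = FALSE,
                n_offsets = nrow(pts), mode = mode, points = pts)
    return(structure(fit, class = "lcacc_phase_fit"))
  }
  m <- stats::lm(phase_unwrapped ~ offset_ms, data = pts)
  # a noiseless map has bin-quantized phases exactly on a line; the
  # perfect-fit warning from summary.lm is expected there
  co <- suppressWarnings(summary(m))$coefficients
  slope <- co["offset_ms", "Estimate"]
  p <- co["offset_ms", "Pr(>|t|)"]
  period <- if (slope != 0) 360 / abs(slope) else NA_real_
  t0 <- if (slope != 0) (-co["(Intercept)", "Estimate"] / slope) %% period else NA_real_
  fit <- list(slope = slope, intercept = co["(Intercept)", "Estimate"],
              zero_phase_time_ms = t0, period_ms = period, p_value = p,
              reliable = is.finite(p) && p < 0.05,
              n_offsets = nrow(pts), mode = mode, points = pts, model = m)
  structure(fit, class = "lcacc_phase_fit")
}

#' @export
print.lcacc_phase_fit <- function(x, ...) {
  cat("<lcacc_phase_fit> mode =", x$mode, "\n")
  cat(sprintf("  slope: %.3f deg/ms (p = %.3g)%s\n", x$slope, x$p_value,
              if (x$reliable) "" else "  [unreliable]"))
  cat(sprintf("  implied period: %.0f ms; 0-degree crossing: %.0f ms\n",
              x$period_ms, x$zero_phase_time_ms))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_phase_slope
#' @param x An `lcacc_phase_fit`.
#' @param ... Unused.
#' @export
tidy.lcacc_phase_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    p.value = c(x$p_value, NA_real_)
  )
}

#' @rdname fit_phase_slope
#' @export
glance.lcacc_phase_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, zero_phase_time_ms = x$zero_phase_time_ms,
    period_ms = x$period_ms, p_value = x$p_value,
    reliable = x$reliable, n_offsets = x$n_offsets, mode = x$mode
  )
}
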