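#' Count spikes in a window anchored at an epoch start
#'
#' The counting interval is half-open, `[start, start + bin_ms)`: a spike
#' exactly at the right edge is excluded. The bin must fit inside the epoch.
#'
#' @param times Numeric spike times, ms relative to trial start.
#' @param epoch One epoch: a list or one-row tibble with `start` and
#'   `duration` (see [extract_stable_fixation_epochs()]).
#' @param bin_ms Window length, ms; must not exceed `epoch$duration`.
#' @return Integer count.
#' @export
count_spikes <- function(times, epoch, bin_ms) {
  if (bin_ms > epoch$duration[[1]]) {
    rlang::abort("bin_ms exceeds the epoch duration")
  }
  lo <- epoch$start[[1]]
  sum(times >= lo & times < lo + bin_ms)
}

# vectorized half-open window counts over one sorted spike vector
count_in_windows <- function(sorted_times, lo, hi) {
  findInterval(hi, sorted_times, left.open = TRUE) -
    findInterval(lo, sorted_times, left.open = TRUE)
}

#' Per-trial spike-count table
#'
#' Counts spikes for every unit in each trial's analysis window
#' `[epoch start, epoch start + bin)`, one window per trial per bin size.
#' Returns the counts in long form, one row per trial x unit x bin size,
#' including explicit zeros, so tables for several bin sizes can simply be
#' row-bound.
#'
#' @param s An `lcacc_session`.
#' @param epochs Tibble from [extract_stable_fixation_epochs()], or any tibble
#'   with `trial_id`, `start`, `duration`.
#' @param bin_sizes_ms Numeric vector of window lengths, each no longer than
#'   the epoch duration.
#' @param units Character vector of unit ids (default: all units).
#' @return Tibble with columns `trial_id`, `unit_id`, `bin_size_ms`, `count`.
#' @export
spike_count_table <- function(s, epochs, bin_sizes_ms, units = s$units$unit_id) {
  stopifnot(nrow(epochs) > 0)
  if (max(bin_sizes_ms) > min(epochs$duration)) {
    rlang::abort("bin size exceeds the epoch duration")
  }
  purrr::map_dfr(units, function(u) {
    by_trial <- spikes_by_trial(s, u, epochs$trial_id)
    purrr::map_dfr(bin_sizes_ms, function(b) {
      n <- purrr::map2_int(by_trial, epochs$start,
                           ~ count_in_windows(.x, .y, .y + b))
      tibble::tibble(trial_id = epochs$trial_id, unit_id = u,
                     bin_size_ms = b, count = n)
    })
  })
}

#' Mean, variance and Fano factor of a spike-count vector
#'
#' Sample variance (n - 1 denominator). The Fano factor, variance over mean,
#' is `NA` (undefined) when the mean is zero.
#'
#' @param counts Integer vector of per-trial counts, length at least 2.
#' @return One-row tibble: `n`, `mean`, `variance`, `fano`.
#' @export
count_stats <- function(counts) {
  if (length(counts) < 2) rlang::abort("need at least 2 trials")
  m <- mean(counts)
  v <- stats::var(counts)
  tibble::tibble(n = length(counts), mean = m, variance = v,
                 fano = if (m > 0) v / m else NA_real_)
}

#' Partition trials by the partner region's spike count
#'
#' Groups trials by the conditioning neuron's spike count in the 1.1 s
#' reference window: 0, 1, 2, 3, or 4+ spikes, plus the derived binary split
#' into zero versus nonzero trials. Counts (not rates) are used because the
#' zero group is literally "no spikes in the window".
#'
#' @param counts Integer vector of the partner unit's reference-window counts.
#' @param trial_ids Optional trial ids (defaults to `seq_along(counts)`).
#' @return Tibble with `trial_id`, `count`, `group` (factor `0,1,2,3,4+`)
#'   and `nonzero` (logical).
#' @export
partition_trials_by_partner <- function(counts, trial_ids = seq_along(counts)) {
  stopifnot(length(counts) == length(trial_ids), all(counts >= 0))
  grp <- ifelse(counts >= 4, "4+", as.character(counts))
  tibble::tibble(
    trial_id = trial_ids,
    count = as.integer(counts),
    group = factor(grp, levels = c("0", "1", "2", "3", "4+")),
    nonzero = counts > 0
  )
}

#' Reference-window counts of the conditioning unit
#'
#' Convenience wrapper: counts the given unit's spikes in each trial's full
#' stable-fixation reference window and partitions the trials with
#' [partition_trials_by_partner()].
#'
#' @param s An `lcacc_session`.
#' @param unit Conditioning unit id; default: the session's first LC unit.
#' @param epochs Reference epochs (default: stable-fixation epochs).
#' @return See [partition_trials_by_partner()].
#' @export
partner_trial_groups <- function(s, unit = region_units(s, "LC")[1],
                                 epochs = extract_stable_fixation_epochs(s)) {
  stopifnot(!is.na(unit))
  by_trial <- spikes_by_trial(s, unit, epochs$trial_id)
  n <- purrr::pmap_int(list(by_trial, epochs$start, epochs$duration),
                       function(sp, st, du) count_in_windows(sp, st, st + du))
  partition_trials_by_partner(n, epochs$trial_id)
}

#' Partner-conditioned count statistics and their differences
#'
#' For every target unit, bin size and statistic (mean, variance, Fano),
#' computes the value on zero-partner and nonzero-partner trials and their
#' difference (nonzero - zero). Units with fewer than `min_trials` trials in
#' either condition are flagged missing rather than dropped. The direction of
#' conditioning is set entirely by `labels`, so the same function serves
#' LC-conditioned ACC statistics and the region-swapped analysis.
#'
#' @param count_table Long count table from [spike_count_table()] for the
#'   target units (any number of bin sizes).
#' @param labels Trial labels from [partition_trials_by_partner()] /
#'   [partner_trial_groups()].
#' @param min_trials Minimum trials per condition (default 5).
#' @return Tibble with one row per unit x bin size x statistic: `zero`,
#'   `nonzero`, `difference`, `n_zero`, `n_nonzero`, `missing`.
#' @export
conditioned_stat_difference <- function(count_table, labels, min_trials = 5) {
  df <- dplyr::inner_join(count_table,
                          labels[, c("trial_id", "nonzero")], by = "trial_id")
  df |>
    dplyr::group_by(.data$unit_id, .data$bin_size_ms) |>
    dplyr::group_modify(function(d, key) {
      z <- d$count[!d$nonzero]
      nz <- d$count[d$nonzero]
      miss <- length(z) < min_trials || length(nz) < min_trials
      stat_pair <- function(f) {
        if (miss) c(NA_real_, NA_real_) else c(f(z), f(nz))
      }
      fano <- function(x) {
        m <- mean(x)
        if (m > 0) stats::var(x) / m else NA_real_
      }
      vals <- rbind(mean = stat_pair(mean),
                    variance = stat_pair(stats::var),
                    fano = stat_pair(fano))
      tibble::tibble(
        statistic = rownames(vals),
        zero = vals[, 1], nonzero = vals[, 2],
        difference = vals[, 2] - vals[, 1],
        n_zero = length(z), n_nonzero = length(nz),
        missing = miss
      )
    }) |>
    dplyr::ungroup()
}

#' Across-unit relations among conditioned-statistic differences
#'
#' Spearman correlations, per bin size, between the per-unit differences of
#' each pair of statistics (delta mean vs delta variance, etc.), mirroring
#' the across-unit difference-relation analysis.
#'
#' @param diffs Output of [conditioned_stat_difference()].
#' @return Tibble: `bin_size_ms`, `stat_a`, `stat_b`, `rho`, `p_value`, `n`.
#' @export
stat_difference_relations <- function(diffs) {
  wide <- diffs |>
    dplyr::filter(!.data$missing) |>
    dplyr::select("unit_id", "bin_size_ms", "statistic", "difference") |>
    tidyr::pivot_wider(names_from = "statistic", values_from = "difference")
  combos <- utils::combn(c("mean", "variance", "fano"), 2)
  wide |>
    dplyr::group_by(.data$bin_size_ms) |>
    dplyr::group_modify(function(d, key) {
      purrr::map_dfr(seq_len(ncol(combos)), function(i) {
        a <- combos[1, i]; b <- combos[2, i]
        keep <- stats::complete.cases(d[[a]], d[[b]])
        ct <- suppressWarnings(
          stats::cor.test(d[[a]][keep], d[[b]][keep], method = "spearman")
        )
        tibble::tibble(stat_a = a, stat_b = b,
                       rho = unname(ct$estimate), p_value = ct$p.value,
                       n = sum(keep))
      })
    }) |>
    dplyr::ungroup()
}
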