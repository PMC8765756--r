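#' Z-score a spike-count vector
#'
#' Centers to mean 0 and scales to sample SD 1. A constant vector has no
#' defined z-score; all `NA` is returned (the caller treats this as "no
#' trial exceeds any threshold"). Applying the function twice returns the
#' same values.
#'
#' @param counts Numeric vector, length at least 2.
#' @return Numeric vector of z-scores, or all-`NA` if the input is constant.
#' @export
zscore_counts <- function(counts) {
  if (length(counts) < 2) rlang::abort("need at least 2 trials")
  s <- stats::sd(counts)
  if (s == 0) return(rep(NA_real_, length(counts)))
  (counts - mean(counts)) / s
}

#' Outlier-trial mask for a pair
#'
#' One-pass rule: a trial is kept iff neither neuron's response is more than
#' `threshold` standard deviations from its mean, with z-scores computed once
#' from the full trial set being correlated (no iteration). The comparison is
#' strict, so `|z|` exactly at the threshold is kept; an undefined z-score
#' (constant counts) removes nothing.
#'
#' @param za,zb Z-scored counts of the two neurons (equal length).
#' @param threshold SD cutoff (default 3).
#' @return Logical keep-mask.
#' @export
remove_outlier_trials <- function(za, zb, threshold = 3) {
  stopifnot(length(za) == length(zb))
  za <- ifelse(is.na(za), 0, za)
  zb <- ifelse(is.na(zb), 0, zb)
  !(abs(za) > threshold | abs(zb) > threshold)
}

#' Pearson spike-count correlation
#'
#' @param a,b Numeric count vectors of equal length.
#' @return Pearson r, or `NA` if either vector is constant.
#' @export
spike_count_correlation <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("count vectors differ in length")
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# full r_sc preprocessing for one pair on one trial set:
# z-score, one-pass >threshold-SD removal, Pearson on the kept trials
rsc_pair <- function(a, b, outlier_sd = 3, min_trials = 5) {
  n <- length(a)
  if (n < 2) {
    return(tibble::tibble(r = NA_real_, n_trials_used = n, n_outliers_removed = 0L))
  }
  keep <- remove_outlier_trials(zscore_counts(a), zscore_counts(b), outlier_sd)
  a <- a[keep]; b <- b[keep]
  r <- if (length(a) >= min_trials) spike_count_correlation(a, b) else NA_real_
  tibble::tibble(r = r, n_trials_used = length(a),
                 n_outliers_removed = n - length(a))
}

#' Shuffle null distribution of r_sc
#'
#' Correlations of spike-count vectors built from independently permuted
#' trials for each neuron, destroying the trial pairing while preserving each
#' neuron's count distribution.
#'
#' @param a,b Numeric count vectors of equal length.
#' @param n_shuffles Number of permutations.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_shuffles` correlations.
#' @export
shuffled_null <- function(a, b, n_shuffles, seed = NULL) {
  stopifnot(length(a) == length(b))
  run <- function() {
    vapply(seq_len(n_shuffles), function(i) {
      stats::cor(sample(a), sample(b))
    }, numeric(1))
  }
  if (n_shuffles == 0) return(numeric(0))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Tercile partition of pair values
#'
#' Rank-based split into three groups whose sizes differ by at most one;
#' when the size is not divisible by three the extra members go to the lower
#' terciles. Ties are broken by stable input order. `NA` values keep an `NA`
#' label and do not count toward the split.
#'
#' @param values Numeric vector with at least 3 defined values (e.g.,
#'   condition-independent r_sc per pair at one bin size).
#' @return Integer vector of tercile labels 1 (lowest) to 3 (highest).
#' @export
tercile_partition <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) rlang::abort("need at least 3 defined values")
  if (length(unique(values[ok])) == 1) {
    rlang::warn("all values equal; terciles follow input order")
  }
  k <- n %/% 3
  sizes <- k + (seq_len(3) <= n %% 3)
  lab <- rep(NA_integer_, length(values))
  lab[ok] <- rep.int(1:3, sizes)[rank(values[ok], ties.method = "first")]
  lab
}

#' Partner-conditioned pairwise spike-count correlations
#'
#' For every pair, bin size and condition, computes r_sc with the full
#' preprocessing chain: z-score the trial counts of the condition's trial
#' set, remove trials where either neuron is more than `outlier_sd` SDs from
#' its mean (one pass), then Pearson-correlate the kept counts. Conditions
#' are: `all` (condition-independent, the basis for tercile partitions),
#' `zero`/`nonzero` (partner fired no spike / at least one spike), and the
#' five partner count groups `0,1,2,3,4+`. Records with fewer than
#' `min_trials` usable trials carry `r = NA` rather than a noisy estimate.
#'
#' The conditioning direction is set by `labels`, so LC-conditioned ACC
#' correlations and the region-swapped (ACC-conditioned LC) analysis use the
#' same code path.
#'
#' @param count_table Long table from [spike_count_table()] covering the
#'   paired units (one or more bin sizes).
#' @param labels Trial partition from [partner_trial_groups()].
#' @param pairs Tibble with columns `unit_a`, `unit_b` (and optionally
#'   `pair_id`). Default: all unordered unit pairs in `count_table`.
#' @param outlier_sd Outlier threshold in SDs (default 3).
#' @param min_trials Minimum usable trials per condition (default 5).
#' @param zscore_scope `"condition"` (default) z-scores within the trial set
#'   actually being correlated; `"all"` z-scores once across all labeled
#'   trials before conditioning.
#' @return Tibble of r_sc records: `pair_id`, `unit_a`, `unit_b`,
#'   `bin_size_ms`, `condition`, `r`, `n_trials_used`, `n_outliers_removed`.
#' @export
conditioned_rsc <- function(count_table, labels, pairs = NULL,
                            outlier_sd = 3, min_trials = 5,
                            zscore_scope = c("condition", "all")) {
  zscore_scope <- match.arg(zscore_scope)
  units <- unique(count_table$unit_id)
  if (is.null(pairs)) {
    cmb <- utils::combn(units, 2)
    pairs <- tibble::tibble(unit_a = cmb[1, ], unit_b = cmb[2, ])
  }
  if (!"pair_id" %in% names(pairs)) {
    pairs$pair_id <- paste(pairs$unit_a, pairs$unit_b, sep = ":")
  }
  labels <- labels[labels$trial_id %in% unique(count_table$trial_id), ]
  cond_trials <- c(
    list(all = labels$trial_id,
         zero = labels$trial_id[!labels$nonzero],
         nonzero = labels$trial_id[labels$nonzero]),
    lapply(split(labels$trial_id, labels$group), identity)
  )

  purrr::map_dfr(unique(count_table$bin_size_ms), function(b) {
    tab <- count_table[count_table$bin_size_ms == b, ]
    wide <- tidyr::pivot_wider(tab[, c("trial_id", "unit_id", "count")],
                               names_from = "unit_id", values_from = "count")
    wide <- wide[match(labels$trial_id, wide$trial_id), ]
    purrr::pmap_dfr(pairs, function(unit_a, unit_b, pair_id, ...) {
      a_all <- wide[[unit_a]]
      b_all <- wide[[unit_b]]
      keep_glob <- rep(TRUE, nrow(wide))
      if (zscore_scope == "all") {
        keep_glob <- remove_outlier_trials(zscore_counts(a_all),
                                           zscore_counts(b_all), outlier_sd)
      }
      purrr::imap_dfr(cond_trials, function(ids, cond) {
        idx <- which(labels$trial_id %in% ids & keep_glob)
        if (length(idx) < 2) {
          rec <- tibble::tibble(r = NA_real_,
                                n_trials_used = length(idx),
                                n_outliers_removed = 0L)
        } else if (zscore_scope == "condition") {
          rec <- rsc_pair(a_all[idx], b_all[idx], outlier_sd, min_trials)
        } else {
          a <- a_all[idx]; b <- b_all[idx]
          rec <- tibble::tibble(
            r = if (length(a) >= min_trials) spike_count_correlation(a, b) else NA_real_,
            n_trials_used = length(a), n_outliers_removed = 0L
          )
        }
        dplyr::bind_cols(
          tibble::tibble(pair_id = pair_id, unit_a = unit_a, unit_b = unit_b,
                         bin_size_ms = b, condition = cond),
          rec
        )
      })
    })
  })
}

#' Per-pair conditioned r_sc differences
#'
#' Difference in r_sc between the partner-nonzero and partner-zero
#' conditions, per pair and bin size, with the pair's condition-independent
#' r_sc and its tercile attached (terciles computed per bin size from the
#' `all` condition, exactly as the tercile figure panels are built).
#'
#' @param records Output of [conditioned_rsc()].
#' @return Tibble: `pair_id`, `bin_size_ms`, `r_all`, `tercile`, `r_zero`,
#'   `r_nonzero`, `delta_rsc` (nonzero - zero).
#' @export
rsc_difference <- function(records) {
  wide <- records |>
    dplyr::filter(.data$condition %in% c("all", "zero", "nonzero")) |>
    dplyr::select("pair_id", "bin_size_ms", "condition", "r") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "r",
                       names_prefix = "r_")
  wide |>
    dplyr::group_by(.data$bin_size_ms) |>
    dplyr::mutate(tercile = if (sum(!is.na(.data$r_all)) >= 3) {
      tercile_partition(.data$r_all)
    } else {
      NA_integer_
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(delta_rsc = .data$r_nonzero - .data$r_zero) |>
    dplyr::select("pair_id", "bin_size_ms", "r_all", "tercile",
                  "r_zero", "r_nonzero", "delta_rsc")
}

#' Relate r_sc differences to rate and Fano differences
#'
#' Joins each pair's conditioned r_sc difference with its two units'
#' conditioned mean-count and Fano differences, and reports the across-pair
#' Spearman correlation of delta r_sc with delta rate and with delta Fano,
#' per bin size (the pair value is the mean of its two units' differences).
#'
#' @param rsc_diffs Output of [rsc_difference()].
#' @param stat_diffs Output of [conditioned_stat_difference()] for the same
#'   units and bin sizes.
#' @param pairs Tibble `pair_id`, `unit_a`, `unit_b`.
#' @return List with `pairs` (per-pair table of `delta_rsc`, `delta_mean`,
#'   `delta_fano`) and `relations` (Spearman rho and p per bin and measure).
#' @export
rsc_rate_fano_relation <- function(rsc_diffs, stat_diffs, pairs) {
  unit_diffs <- stat_diffs |>
    dplyr::filter(.data$statistic %in% c("mean", "fano"), !.data$missing) |>
    dplyr::select("unit_id", "bin_size_ms", "statistic", "difference")
  per_pair <- rsc_diffs |>
    dplyr::inner_join(pairs, by = "pair_id") |>
    dplyr::left_join(unit_diffs, by = c(unit_a = "unit_id", "bin_size_ms"),
                     relationship = "many-to-many") |>
    dplyr::left_join(unit_diffs,
                     by = c(unit_b = "unit_id", "bin_size_ms", "statistic"),
                     suffix = c("_a", "_b")) |>
    dplyr::mutate(pair_difference = (.data$difference_a + .data$difference_b) / 2) |>
    dplyr::select("pair_id", "bin_size_ms", "delta_rsc", "statistic",
                  "pair_difference") |>
    tidyr::pivot_wider(names_from = "statistic", values_from = "pair_difference",
                       names_prefix = "delta_")
  relations <- per_pair |>
    tidyr::pivot_longer(dplyr::any_of(c("delta_mean", "delta_fano")),
                        names_to = "measure", values_to = "delta_stat") |>
    dplyr::group_by(.data$bin_size_ms, .data$measure) |>
    dplyr::group_modify(function(d, key) {
      keep <- stats::complete.cases(d$delta_rsc, d$delta_stat)
      if (sum(keep) < 3) {
        return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = sum(keep)))
      }
      ct <- suppressWarnings(stats::cor.test(d$delta_rsc[keep],
                                             d$delta_stat[keep],
                                             method = "spearman"))
      tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
    }) |>
    dplyr::ungroup()
  list(pairs = per_pair, relations = relations)
}

#' Shuffle a count table across trials
#'
#' Independently permutes each unit's counts across trials (within each bin
#' size), destroying all trial-by-trial pairing between units and with any
#' conditioning labels while leaving every marginal count distribution
#' intact. Running the conditioned analyses on the shuffled table is the
#' negative control.
#'
#' @param count_table Long table from [spike_count_table()].
#' @param seed Optional integer seed.
#' @return A count table of the same shape with permuted counts.
#' @export
shuffle_count_table <- function(count_table, seed = NULL) {
  run <- function() {
    count_table |>
      dplyr::group_by(.data$unit_id, .data$bin_size_ms) |>
      dplyr::mutate(count = sample(.data$count)) |>
      dplyr::ungroup()
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
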