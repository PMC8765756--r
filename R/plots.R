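#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a peri-stimulus time histogram
#'
#' @param object An `lcacc_psth`.
#' @param ... Unused.
#' @return A ggplot: mean rate with a +/- 1 sem ribbon.
#' @export
autoplot.lcacc_psth <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms, y = .data$rate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rate - .data$sem,
                                      ymax = .data$rate + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event (ms)", y = "rate (sp/s)",
                  title = attr(object, "unit"))
}

#' Plot a Fano-factor time course
#'
#' @param object An `lcacc_fano_timecourse`.
#' @param ... Unused.
#' @return A ggplot with the Poisson reference level at 1.
#' @export
autoplot.lcacc_fano_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms, y = .data$fano)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from event (ms)", y = "Fano factor")
}

#' Plot a phase-triggered map
#'
#' @param object An `lcacc_phase_map`.
#' @param ... Unused.
#' @return A ggplot raster of value over (offset, phase).
#' @export
autoplot.lcacc_phase_map <- function(object, ...) {
  lab <- if (attr(object, "quantity") == "rate") "z-scored rate" else "r_sc"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset_ms, y = .data$phase_deg,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab, na.value = "grey90") +
    ggplot2::labs(x = "time from phase occurrence (ms)", y = "pupil phase (deg)")
}

#' Plot conditioned r_sc differences against bin size
#'
#' Median and bootstrapped 95% CI of the per-pair difference (partner
#' nonzero minus zero), per bin size and, when present, per tercile.
#'
#' @param diffs Output of [rsc_difference()].
#' @param seed Seed for the bootstrap intervals.
#' @return A ggplot.
#' @export
plot_rsc_difference <- function(diffs, seed = 1) {
  grp <- if (all(is.na(diffs$tercile))) NULL else "tercile"
  summ <- diffs |>
    dplyr::filter(!is.na(.data$delta_rsc)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("bin_size_ms", grp)))) |>
    dplyr::group_modify(~ bootstrap_median_ci(.x$delta_rsc, seed = seed)) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$bin_size_ms,
                                          y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "bin size (ms)", y = "delta r_sc (nonzero - zero)")
  if (!is.null(grp)) p <- p + ggplot2::facet_wrap(~tercile, labeller = "label_both")
  p
}
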