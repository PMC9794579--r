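#' Plot a dose-inhibition table with fitted Hill curves
#'
#' Measured block fractions on a log-dose axis, overlaid with the posterior
#' median Hill curve and a spaghetti sample of posterior curves when
#' `samples` is given.
#'
#' @param records Dose-response tibble (one drug x channel).
#' @param samples Optional `hill_samples` for the same drug x channel.
#' @param n_curves Number of posterior curves to overlay.
#' @return A ggplot.
#' @export
plot_dose_response <- function(records, samples = NULL, n_curves = 100) {
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$conc_nM, y = .data$block)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (nM)", y = "fractional block",
                  title = paste(records$drug[1], "x", records$channel[1])) +
    ggplot2::theme_minimal()
  if (!is.null(samples)) {
    dgrid <- 10^seq(log10(min(records$conc_nM)) - 1,
                    log10(max(records$conc_nM)) + 1, length.out = 80)
    take <- samples[seq_len(min(n_curves, nrow(samples))), ]
    curves <- purrr::map_dfr(seq_len(nrow(take)), function(i) {
      tibble::tibble(sample_id = take$sample_id[i], conc_nM = dgrid,
                     block = hill_block(take$ic50[i], take$h[i], dgrid))
    })
    med <- tibble::tibble(
      conc_nM = dgrid,
      block = hill_block(median(samples$ic50), median(samples$h), dgrid)
    )
    p <- p +
      ggplot2::geom_line(data = curves,
                         ggplot2::aes(group = .data$sample_id),
                         alpha = 0.05, colour = "steelblue") +
      ggplot2::geom_line(data = med, colour = "firebrick", linewidth = 1)
  }
  p
}

#' Plot beat traces from a paced run
#'
#' @param traces Output of [run_paced()].
#' @param beats Beat indices to show (default: the last available beat).
#' @param vars Trace columns to facet (default Vm, Cai, ICaL, IKr).
#' @return A ggplot.
#' @export
plot_beat <- function(traces, beats = NULL,
                      vars = c("vm", "cai", "ICaL", "IKr")) {
  beats <- beats %||% max(traces$beat)
  sub <- traces[traces$beat %in% beats, c("beat", "time", vars)]
  long <- tidyr::pivot_longer(sub, cols = dplyr::all_of(vars),
                              names_to = "trace", values_to = "value")
  long$trace <- factor(long$trace, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = factor(.data$beat))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trace, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time in beat (ms)", y = NULL, colour = "beat") +
    ggplot2::theme_minimal()
}

#' Plot beat-to-beat variability series
#'
#' @param series Long variability tibble from [variability_series()] or
#'   [as_tibble()] on a `variability_pool`.
#' @param feature Optional feature to filter on.
#' @return A ggplot.
#' @export
plot_variability <- function(series, feature = NULL) {
  if (!is.null(feature)) series <- series[series$feature == feature, ]
  aes <- ggplot2::aes(x = .data$beat, y = .data$value)
  if ("risk" %in% names(series)) {
    aes <- ggplot2::aes(x = .data$beat, y = .data$value,
                        colour = .data$risk)
  }
  ggplot2::ggplot(series, aes) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "beat", y = "biomarker value") +
    ggplot2::theme_minimal()
}

#' Plot the metric distributions of a repeated-test evaluation
#'
#' Histograms of the per-iteration one-vs-rest AUC per risk class.
#'
#' @param object A `tdp_test_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tdp_test_summary <- function(object, ...) {
  it <- object$iterations
  long <- tidyr::pivot_longer(
    it[, paste0("auc_", TDP_RISKS)],
    cols = dplyr::everything(),
    names_to = "class", values_to = "auc", names_prefix = "auc_"
  )
  long$class <- factor(long$class, levels = TDP_RISKS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "one-vs-rest AUC", y = "iterations") +
    ggplot2::theme_minimal()
}
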