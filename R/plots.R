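# Simple renderings of the standard cost-effectiveness figures; the
# underlying data are returned by run_psa(), ceac() and run_dsa().

#' Cost-effectiveness plane of PSA draws
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness-to-pay line to draw (euro/QALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = psa$wtp) {
  d <- psa$draws
  ggplot2::ggplot(d, ggplot2::aes(x = delta_qaly,
                                  y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs (apixaban - VKA)",
                  y = "Incremental cost (EUR)",
                  title = "Cost-effectiveness plane")
}

#' Cost-effectiveness acceptability curve
#'
#' @param ceac_df Output of [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  ggplot2::ggplot(ceac_df, ggplot2::aes(x = wtp,
                                        y = probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (EUR/QALY)",
                  y = "P(apixaban cost-effective)",
                  title = "Cost-effectiveness acceptability curve")
}

#' Tornado diagram of one-way sensitivity results
#'
#' @param dsa A [run_dsa()] result.
#' @param top Number of parameters to show (default 10).
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa, top = 10) {
  d <- utils::head(dsa[order(-dsa$swing), ], top)
  base <- (d$inmb_low + d$inmb_high)[which.min(d$swing)] / 2
  d$id <- factor(d$id, levels = rev(d$id))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = inmb_low,
                                       xend = inmb_high,
                                       y = id, yend = id),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "INMB (EUR) at lower/upper bound", y = NULL,
                  title = "One-way sensitivity (tornado)")
}
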