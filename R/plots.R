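#' Physiologic trend panels
#'
#' Renders the standard stacked trend display for a run: MAP (with the
#' target line and shaded hemorrhage/resuscitation phases), norepinephrine
#' rate, bolus event marks from the command ledger, HR, SvO2 and lactate.
#' Monitoring dropouts appear as gaps in the MAP panel, since invalid
#' snapshots carry `NA` features.
#'
#' @param run a `refit_run` from [run_scenario()], or a trend data.frame
#'   (then `ledger` and `times` may be given separately)
#' @param ledger optional command ledger data.frame
#' @param times optional list with `injury`, `resus_start`, `end` (s)
#' @param map_target MAP target line (mmHg)
#' @return a patchwork object of stacked ggplots
#' @export
render_trends <- function(run, ledger = NULL, times = NULL, map_target = 60) {
  if (inherits(run, "refit_run")) {
    ledger <- ledger %||% run$ledger
    times <- times %||% run$times
    map_target <- run$config$controller$map_target
    trend <- run$trend
  } else {
    trend <- run
  }
  if (is.null(trend) || nrow(trend) == 0) stop("empty trend log")
  trend$t_min <- trend$t_s / 60

  shade <- NULL
  if (!is.null(times)) {
    has_resus <- !is.na(times$resus_start %||% NA_real_)
    xmin <- c(times$injury, if (has_resus) times$resus_start)
    xmax <- c(if (has_resus) times$resus_start else times$end,
              if (has_resus) times$end)
    shade <- data.frame(xmin = xmin / 60, xmax = xmax / 60,
                        phase = c("hemorrhage",
                                  if (has_resus) "resuscitation"))
  }

  base_panel <- function(y, lab) {
    g <- ggplot2::ggplot(trend, ggplot2::aes(x = .data$t_min,
                                             y = .data[[y]]))
    if (!is.null(shade)) {
      g <- g + ggplot2::geom_rect(
        data = shade, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf, fill = .data$phase),
        alpha = 0.12)
    }
    g + ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
      ggplot2::labs(x = NULL, y = lab) +
      ggplot2::theme_minimal(base_size = 9) +
      ggplot2::theme(legend.position = "none")
  }

  p_map <- base_panel("map", "MAP (mmHg)") +
    ggplot2::geom_hline(yintercept = map_target, linetype = 2,
                        linewidth = 0.3, colour = "grey40")
  p_ne <- base_panel("ne_rate", "NE (µg/kg/min)")
  p_hr <- base_panel("hr", "HR (min⁻¹)")
  p_svo2 <- base_panel("svo2", "SvO2 (%)")
  p_lact <- base_panel("lactate", "Lactate (mmol/l)") +
    ggplot2::labs(x = "time (min)")

  p_bolus <- ggplot2::ggplot() +
    ggplot2::labs(x = NULL, y = "boluses") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(legend.position = "none",
                   axis.text.y = ggplot2::element_blank()) +
    ggplot2::xlim(range(trend$t_min))
  if (!is.null(ledger) && nrow(ledger) > 0) {
    bol <- ledger[ledger$kind == "bolus", , drop = FALSE]
    if (nrow(bol) > 0) {
      bol$t_min <- bol$t_issued / 60
      p_bolus <- p_bolus +
        ggplot2::geom_segment(
          data = bol,
          ggplot2::aes(x = .data$t_min, xend = .data$t_min, y = 0, yend = 1,
                       colour = .data$channel),
          linewidth = 0.8)
    }
  }

  patchwork::wrap_plots(p_ne, p_bolus, p_map, p_svo2, p_hr, p_lact,
                        ncol = 1, heights = c(1, 0.5, 1.5, 1, 1, 1))
}
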