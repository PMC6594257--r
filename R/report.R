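# Figure-equivalent rendering of a cohort result.  Plotting is isolated
# here so the numeric pipeline carries no plotting dependency; ggplot2
# is required only when these functions are called.

star_label <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' Render figure-equivalent panels from a cohort result
#'
#' Produces the standard panels: group-mean comodulogram heat maps
#' (phase 2-12 Hz x amplitude 10-200 Hz), bar charts of mean PAC,
#' coherence / partial coherence and Eglob with 95% CIs, and band-mean
#' PDC bars, annotated `*` for p < 0.05 and `**` for p < 0.01.  Panels
#' whose metric table is empty are skipped with a notice.
#'
#' @param res a [run_study()] result.
#' @param out_dir optional directory; panels are saved as PNG when set.
#' @return Named list of ggplot objects, invisibly.
#' @export
render_report <- function(res, out_dir = NULL) {
  stopifnot(inherits(res, "cohort_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("render_report requires the 'ggplot2' package")
  g2 <- ggplot2::ggplot
  aes <- ggplot2::aes
  panels <- list()

  cm <- res$tables$comodulogram
  if (!is.null(cm) && nrow(cm) > 0L) {
    agg <- stats::aggregate(mi ~ group + week + phase_channel + f_phase + f_amp,
                            data = cm, FUN = mean)
    panels$comodulogram <- g2(agg, aes(x = .data$f_phase, y = .data$f_amp,
                                       fill = .data$mi)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(option = "inferno") +
      ggplot2::facet_grid(phase_channel + week ~ group) +
      ggplot2::labs(x = "phase frequency (Hz)",
                    y = "amplitude frequency (Hz)", fill = "MI")
  } else message("comodulogram table empty; panel skipped")

  bar_panel <- function(metric, keycols, ylab) {
    df <- res$tables[[metric]]
    gs <- res$group_stats
    if (is.null(df) || nrow(df) == 0L) {
      message(metric, " table empty; panel skipped")
      return(NULL)
    }
    df$key <- if (length(keycols))
      apply(df[keycols], 1L, paste, collapse = ">") else metric
    agg <- do.call(rbind, lapply(split(df, interaction(df$group, df$week,
                                                       df$key, drop = TRUE)),
      function(s) {
        ci <- summarize_ci(s$value)
        data.frame(group = s$group[1L], week = s$week[1L], key = s$key[1L],
                   mean = ci$mean, lo = ci$ci_lo, hi = ci$ci_hi)
      }))
    stars <- NULL
    if (!is.null(gs)) {
      sub <- gs[gs$metric == metric & gs$p < 0.05, , drop = FALSE]
      if (nrow(sub) > 0L)
        stars <- data.frame(week = sub$week, key = sub$key,
                            label = star_label(sub$p),
                            y = apply(sub[c("ci_buffer_hi", "ci_k18_hi")],
                                      1L, max))
    }
    p <- g2(agg, aes(x = .data$key, y = .data$mean, fill = .data$group)) +
      ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
      ggplot2::geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi),
                             position = ggplot2::position_dodge(0.9),
                             width = 0.25) +
      ggplot2::facet_wrap(~week, labeller = ggplot2::label_both) +
      ggplot2::scale_fill_manual(values = c(buffer = "grey20",
                                            k18 = "forestgreen")) +
      ggplot2::labs(x = NULL, y = ylab)
    if (!is.null(stars))
      p <- p + ggplot2::geom_text(data = stars,
                                  aes(x = .data$key, y = .data$y * 1.05,
                                      label = .data$label),
                                  inherit.aes = FALSE, size = 6)
    p
  }

  panels$pac_intra <- bar_panel("pac_intra", "channel", "mean theta-gamma PAC")
  panels$pac_inter <- bar_panel("pac_inter", c("phase_channel", "amp_channel"),
                                "mean intersite PAC")
  panels$coherence <- bar_panel("coherence", c("a", "b"),
                                "band-mean coherence")
  panels$partial_coherence <- bar_panel("partial_coherence", c("a", "b"),
                                        "band-mean partial coherence")
  panels$eglob <- bar_panel("eglob", character(0), "global efficiency")
  panels$pdc <- bar_panel("pdc", c("source", "sink", "band"),
                          "band-mean extended PDC")
  panels <- Filter(Negate(is.null), panels)

  if (!is.null(out_dir) && length(panels)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(panels))
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), panels[[nm]],
                      width = 9, height = 6, dpi = 150)
  }
  invisible(panels)
}
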