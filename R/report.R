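#' Render figures and summary tables from decode results
#'
#' Reads the CSV results written by [run_decode()] and produces, per
#' condition and viewing-angle difference, a time-course figure with the
#' mean and standard error of the real d' values (solid line, dark band),
#' the random-labeling null (dashed line, light band) and thick horizontal
#' bars over the significant intervals; plus, when subsampling results are
#' present, mean +/- SE d' against roster size.  Every figure's plotted
#' values are also written as CSV, and all significant intervals are
#' collected in `summary_intervals.csv`.
#'
#' @param outdir Directory holding the decode results; figures are written
#'   to `file.path(outdir, "figures")`.
#' @param min_run,bin_alpha Consecutive-bin rule used to recompute the
#'   significance bars from the stored per-bin p-values.
#' @return Tibble of significant intervals, invisibly.
#' @export
run_report <- function(outdir, bin_alpha = 0.001, min_run = 5L) {
  dp_files <- list.files(outdir, "^dprime_.*\\.csv$", full.names = TRUE)
  if (length(dp_files) == 0L) {
    stop_user("no decode results found in ", outdir)
  }
  figdir <- file.path(outdir, "figures")
  if (!dir.exists(figdir)) dir.create(figdir, recursive = TRUE)
  all_intervals <- list()
  for (f in dp_files) {
    tag <- sub("^dprime_(.*)\\.csv$", "\\1", basename(f))
    dp <- read.csv(f, check.names = FALSE)
    sig_path <- file.path(outdir, paste0("significance_", tag, ".csv"))
    pv <- if (file.exists(sig_path)) read.csv(sig_path) else NULL
    if (is.null(pv)) {
      warning("missing significance track for ", tag, "; reporting d' only")
    }

    agg <- stats::aggregate(dprime ~ bin_center_ms + is_null, dp,
                            function(v) c(mean = mean(v),
                                          se = sd(v) / sqrt(length(v))))
    plotted <- data.frame(bin_center_ms = agg$bin_center_ms,
                          is_null = agg$is_null,
                          mean_dprime = agg$dprime[, "mean"],
                          se_dprime = agg$dprime[, "se"])
    write.csv(plotted, file.path(figdir, paste0("timecourse_", tag, ".csv")),
              row.names = FALSE)

    intervals <- if (!is.null(pv)) {
      significant_runs(pv$p_value, pv$bin_center_ms, bin_alpha, min_run)
    } else {
      tibble(start_ms = numeric(), end_ms = numeric(), n_bins = integer())
    }
    if (nrow(intervals)) {
      all_intervals[[tag]] <- cbind(condition = tag,
                                    as.data.frame(intervals))
    }

    plotted$curve <- ifelse(plotted$is_null, "random labeling", "observed")
    bar_y <- max(plotted$mean_dprime + plotted$se_dprime) * 1.05
    p <- ggplot2::ggplot(plotted,
                         ggplot2::aes(x = bin_center_ms,
                                      y = mean_dprime,
                                      linetype = curve)) +
      ggplot2::geom_ribbon(ggplot2::aes(
        ymin = mean_dprime - se_dprime,
        ymax = mean_dprime + se_dprime,
        group = curve, alpha = curve), fill = "grey40",
        colour = NA) +
      ggplot2::scale_alpha_manual(values = c("observed" = 0.45,
                                             "random labeling" = 0.2)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time from stimulus onset (ms)", y = "d'",
                    title = tag) +
      ggplot2::theme_classic()
    if (nrow(intervals)) {
      p <- p + ggplot2::annotate("segment",
                                 x = intervals$start_ms,
                                 xend = intervals$end_ms,
                                 y = bar_y, yend = bar_y, linewidth = 2)
    }
    grDevices::pdf(file.path(figdir, paste0("timecourse_", tag, ".pdf")),
                   width = 6, height = 4)
    print(p)
    grDevices::dev.off()
  }

  ss_files <- list.files(outdir, "^subsample_.*\\.csv$", full.names = TRUE)
  for (f in ss_files) {
    tag <- sub("^subsample_(.*)\\.csv$", "\\1", basename(f))
    sc <- read.csv(f)
    p <- ggplot2::ggplot(sc, ggplot2::aes(x = n_cells,
                                          y = mean_dprime)) +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = mean_dprime - se_dprime,
        ymax = mean_dprime + se_dprime), width = 1.5) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "number of cells", y = "d'", title = tag) +
      ggplot2::theme_classic()
    grDevices::pdf(file.path(figdir, paste0("subsample_", tag, ".pdf")),
                   width = 5, height = 4)
    print(p)
    grDevices::dev.off()
  }

  summary <- if (length(all_intervals)) {
    do.call(rbind, all_intervals)
  } else {
    data.frame(condition = character(), start_ms = numeric(),
               end_ms = numeric(), n_bins = integer())
  }
  write.csv(summary, file.path(outdir, "summary_intervals.csv"),
            row.names = FALSE)
  invisible(as_tibble(summary))
}
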