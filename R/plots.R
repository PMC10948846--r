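## Figure output for the analysis surface: correlation scatter with fit
## line, and grid-study bars.  Base graphics to PNG; no plotting
## dependencies.

#' Save a correlation scatter plot with a least-squares fit line
#'
#' @param x,y the correlated variables (e.g. ICC and stiffness).
#' @param report optional \code{correlation_report} whose coefficients are
#'   annotated in the title.
#' @param path PNG output path.
#' @param xlab,ylab axis labels.
#' @return \code{path}, invisibly.
#' @export
save_correlation_plot <- function(x, y, report = NULL, path,
                                  xlab = "ICC (ml/cmH2O)",
                                  ylab = "FSI-based stiffness (N/m)") {
  grDevices::png(path, width = 900, height = 700, res = 120)
  on.exit(grDevices::dev.off())
  graphics::plot(x, y, pch = 19, col = "#00000088", xlab = xlab,
                 ylab = ylab,
                 main = if (is.null(report)) "" else
                   sprintf("Pearson r = %.3f (p = %.3g), Spearman rho = %.3f (p = %.3g)",
                           report$pearson_r, report$pearson_p,
                           report$spearman_rho, report$spearman_p))
  graphics::abline(stats::lm(y ~ x), col = "firebrick", lwd = 2)
  invisible(path)
}

#' Save a grid-independence bar plot
#'
#' One bar per refinement level (final-cycle mean ICP, cmH2O) with the
#' successive relative differences printed above.
#'
#' @param report a \code{grid_study_report}.
#' @param path PNG output path.
#' @return \code{path}, invisibly.
#' @export
save_grid_study_plot <- function(report, path) {
  grDevices::png(path, width = 900, height = 700, res = 120)
  on.exit(grDevices::dev.off())
  lv <- report$levels
  bp <- graphics::barplot(lv$icp_cmH2O, names.arg = lv$level,
                          ylab = "cycle-mean ventricular ICP (cmH2O)",
                          col = "steelblue")
  if (length(report$successive_diff_pct))
    graphics::text(bp[-1], lv$icp_cmH2O[-1],
                   labels = sprintf("%.3g%%", report$successive_diff_pct),
                   pos = 3, cex = 0.9)
  invisible(path)
}
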