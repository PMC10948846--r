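## Statistical surface: Shapiro-Wilk normality, dual Pearson/Spearman
## correlation with a fixed significance threshold, mesh grid-independence
## reporting, and calculated-vs-measured ICP validation.

#' Dual correlation analysis with normality screening
#'
#' Pearson (t-transform p-value) and Spearman (exact permutation p for
#' n <= 9 without ties, t-approximation otherwise) correlations between two
#' variables, with per-variable Shapiro-Wilk statistics reported alongside
#' and verdicts at the given significance threshold.
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @param alpha significance threshold (default 0.05).
#' @param var_names length-2 character names used in reports.
#' @return Object of class \code{correlation_report}.
#' @examples
#' r <- correlation_analysis(1:10, (1:10)^2)
#' r$spearman_rho   # 1: perfect monotone
#' @export
correlation_analysis <- function(x, y, alpha = 0.05,
                                 var_names = c("x", "y")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  flag <- NULL
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    flag <- "constant input: correlation undefined"
    rep <- list(n = length(x), pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                shapiro = NULL, alpha = alpha, verdicts = NULL, flag = flag,
                var_names = var_names)
    return(structure(rep, class = "correlation_report"))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) <= 9 && !has_ties))
  sw <- lapply(list(x, y), stats::shapiro.test)
  verdict <- function(p) if (p < alpha) "significant" else "not_significant"
  structure(list(
    n = length(x),
    pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    shapiro = list(
      stats::setNames(c(sw[[1]]$statistic, sw[[1]]$p.value), c("W", "p")),
      stats::setNames(c(sw[[2]]$statistic, sw[[2]]$p.value), c("W", "p"))),
    alpha = alpha,
    verdicts = c(pearson = verdict(pe$p.value),
                 spearman = verdict(sp$p.value)),
    flag = flag, var_names = var_names), class = "correlation_report")
}

#' @exportS3Method base::print
print.correlation_report <- function(x, ...) {
  cat(sprintf("Correlation report (%s vs %s), n = %d\n",
              x$var_names[1], x$var_names[2], x$n))
  if (!is.null(x$flag)) {
    cat("  flagged:", x$flag, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Pearson  r   = %+.4f (p = %.4g) -> %s\n",
              x$pearson_r, x$pearson_p, x$verdicts["pearson"]))
  cat(sprintf("  Spearman rho = %+.4f (p = %.4g) -> %s\n",
              x$spearman_rho, x$spearman_p, x$verdicts["spearman"]))
  cat(sprintf("  Shapiro-Wilk: %s W = %.4f (p = %.3g); %s W = %.4f (p = %.3g)\n",
              x$var_names[1], x$shapiro[[1]]["W"], x$shapiro[[1]]["p"],
              x$var_names[2], x$shapiro[[2]]["W"], x$shapiro[[2]]["p"]))
  cat(sprintf("  alpha = %g\n", x$alpha))
  invisible(x)
}

#' Serialize a correlation report to a plain list (for JSON output)
#'
#' @param report a \code{correlation_report}.
#' @return A named list of plain vectors.
#' @export
correlation_report_list <- function(report) {
  list(n = report$n, pearson_r = report$pearson_r,
       pearson_p = report$pearson_p, spearman_rho = report$spearman_rho,
       spearman_p = report$spearman_p,
       shapiro = report$shapiro, alpha = report$alpha,
       verdicts = as.list(report$verdicts), flag = report$flag)
}

#' Grid-independence study of the coupled ICP computation
#'
#' Runs the coupled FSI simulation at successive mesh refinement levels and
#' reports the final-cycle mean ventricular ICP per level plus successive
#' relative differences in percent.  Non-converged levels are flagged and
#' excluded with a warning.
#'
#' @param geometry a \code{\link{head_geometry}} or built region.
#' @param waveform_triplet waveforms passed to \code{\link{run_fsi}}.
#' @param levels refinement levels (>= 2), by name or numeric factor.
#' @param coupling a \code{\link{coupling_config}}.
#' @param base_h coarse-level target cell size, mm.
#' @param fluid_props,material physical parameters.
#' @param runner optional override \code{function(level) ->
#'   list(icp = , converged = )} used for testing the reporting logic
#'   without running simulations.
#' @param ... forwarded to \code{\link{run_fsi}}.
#' @return Object of class \code{grid_study_report}: data.frame
#'   \code{levels} (level, icp_cmH2O, converged, max_diameter_mm) and
#'   \code{successive_diff_pct}.
#' @export
grid_independence <- function(geometry = head_geometry(),
                              waveform_triplet = NULL,
                              levels = c("coarse", "medium", "fine",
                                         "very_fine"),
                              coupling = coupling_config(),
                              base_h = 16,
                              fluid_props = fluid_properties(),
                              material = poro_viscoelastic_material(),
                              runner = NULL, ...) {
  if (length(levels) < 2) stop("need at least 2 refinement levels")
  icp <- numeric(length(levels)); ok <- logical(length(levels))
  hmax <- rep(NA_real_, length(levels))
  for (i in seq_along(levels)) {
    if (!is.null(runner)) {
      r <- runner(levels[i])
      icp[i] <- r$icp; ok[i] <- isTRUE(r$converged)
    } else {
      mesh <- generate_mesh(geometry, levels[i], base_h = base_h)
      hmax[i] <- max_cell_diameter(mesh)
      res <- run_fsi(mesh, fluid_props, material, waveform_triplet,
                     coupling, ...)
      ok[i] <- all(res$converged[final_cycle_index(res)])
      icp[i] <- if (ok[i]) extract_icp(res, "cycle_mean") else NA_real_
    }
  }
  if (any(!ok))
    warning("non-converged levels excluded: ",
            paste(levels[!ok], collapse = ", "))
  lv <- data.frame(level = as.character(levels), icp_cmH2O = icp,
                   converged = ok, max_diameter_mm = hmax,
                   stringsAsFactors = FALSE)
  use <- which(ok)
  diffs <- if (length(use) >= 2)
    abs(diff(icp[use])) / abs(icp[use][-1]) * 100 else numeric(0)
  structure(list(levels = lv, successive_diff_pct = diffs),
            class = "grid_study_report")
}

#' @exportS3Method base::print
print.grid_study_report <- function(x, ...) {
  cat("Grid-independence study (final-cycle mean ventricular ICP):\n")
  print(x$levels, row.names = FALSE)
  if (length(x$successive_diff_pct))
    cat("  successive differences (%):",
        paste(signif(x$successive_diff_pct, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Calculated-versus-measured ICP comparison
#'
#' Per-patient absolute percent differences plus the dual correlation
#' report between the two series.  Pairs with a zero measured value are
#' flagged and excluded from the percentage summary.
#'
#' @param calculated,measured paired ICP values, cmH2O.
#' @param alpha significance threshold for the correlation report.
#' @return Object of class \code{validation_report}: \code{diff_pct}
#'   (per pair, NA where flagged), \code{max_diff_pct},
#'   \code{correlation} (a \code{correlation_report}, or a flag string when
#'   fewer than 3 valid pairs).
#' @export
validation_compare <- function(calculated, measured, alpha = 0.05) {
  if (length(calculated) != length(measured))
    stop("calculated and measured must be paired")
  flagged <- measured == 0
  diff_pct <- ifelse(flagged, NA_real_,
                     abs(calculated - measured) / abs(measured) * 100)
  corr <- if (sum(!flagged) >= 3)
    correlation_analysis(calculated[!flagged], measured[!flagged], alpha,
                         var_names = c("calculated", "measured"))
  else "insufficient-n"
  structure(list(diff_pct = diff_pct,
                 max_diff_pct = if (all(is.na(diff_pct))) NA_real_
                 else max(diff_pct, na.rm = TRUE),
                 n_flagged = sum(flagged), correlation = corr),
            class = "validation_report")
}

#' @exportS3Method base::print
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Calculated vs measured ICP: n = %d, max |diff| = %.3g%%\n",
    length(x$diff_pct), x$max_diff_pct))
  if (inherits(x$correlation, "correlation_report")) print(x$correlation)
  else cat("  correlation:", x$correlation, "\n")
  invisible(x)
}
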