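# Table and figure outputs for a full analysis run: a summary-table CSV per
# result object, a forest plot of the GEE estimates, learning-curve panels
# and the cohort start/end panel, plus a JSON run manifest stamped with the
# seed and a config hash.

#' Render analysis results to tables and figures
#'
#' @param results Named list holding any of `univariate` (from
#'   [compare_groups()]), `gee` (from [fit_gee()]), `curves` (from
#'   [fit_learning_curves()]), `cohorts` (from [compare_cohorts()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Seed to stamp into the run manifest.
#' @return Invisibly, the manifest list (paths written, config hash, seed).
#' @export
render_report <- function(results, out_dir, seed = NA_integer_) {
  if (length(results) == 0) vpdx_abort("render_report: empty results list")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) vpdx_abort(paste0("cannot create output directory ", out_dir))
  }
  written <- character()
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  emit_fig <- function(plot, name, width = 7, height = 5) {
    path <- file.path(out_dir, name)
    ggplot2::ggsave(path, plot, width = width, height = height)
    written <<- c(written, path)
  }

  if (!is.null(results$univariate)) {
    emit_csv(results$univariate, "table_univariate.csv")
  }
  if (!is.null(results$gee)) {
    tab <- results$gee$table
    emit_csv(tab, "table_gee.csv")
    fp <- ggplot2::ggplot(tab, ggplot2::aes(
      x = .data$estimate, y = stats::reorder(.data$term, .data$estimate))) +
      ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::geom_pointrange(ggplot2::aes(
        xmin = .data$estimate - 1.96 * .data$se,
        xmax = .data$estimate + 1.96 * .data$se)) +
      ggplot2::labs(x = "GEE estimate (log odds of correct diagnosis)",
                    y = NULL,
                    title = "Reasoning components predicting correct diagnosis") +
      ggplot2::theme_minimal()
    emit_fig(fp, "fig_gee_forest.pdf")
  }
  if (!is.null(results$curves)) {
    trend <- dplyr::bind_rows(lapply(results$curves, function(m) {
      dplyr::mutate(m$trend, metric = m$metric)
    }))
    emit_csv(trend, "table_learning_curves.csv")
    pct <- trend[grepl("_pct$", trend$metric), ]
    if (nrow(pct)) {
      p1 <- ggplot2::ggplot(pct, ggplot2::aes(.data$sequence_index, .data$fit,
                                              colour = .data$metric,
                                              fill = .data$metric)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                             alpha = 0.2, colour = NA) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "Case sequence", y = "Score (%)",
                      title = "Learning curves: reasoning component scores") +
        ggplot2::theme_minimal()
      emit_fig(p1, "fig_learning_scores.pdf")
    }
    rates <- trend[trend$metric %in% c("error_count", "correct"), ]
    if (nrow(rates)) {
      rates$fit <- ifelse(rates$metric == "correct", 1 - rates$fit, rates$fit)
      tmp <- rates$lwr
      rates$lwr <- ifelse(rates$metric == "correct", 1 - rates$upr, rates$lwr)
      rates$upr <- ifelse(rates$metric == "correct", 1 - tmp, rates$upr)
      rates$metric <- ifelse(rates$metric == "correct", "misdiagnosis_rate",
                             rates$metric)
      p2 <- ggplot2::ggplot(rates, ggplot2::aes(.data$sequence_index, .data$fit)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                             alpha = 0.2) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~metric, scales = "free_y") +
        ggplot2::labs(x = "Case sequence", y = NULL,
                      title = "Cognitive errors and misdiagnoses across practice") +
        ggplot2::theme_minimal()
      emit_fig(p2, "fig_errors_misdx.pdf")
    }
  }
  if (!is.null(results$cohorts)) {
    emit_csv(results$cohorts, "table_cohorts.csv")
    cc <- tidyr::pivot_longer(results$cohorts, c("mean_M1", "mean_M2"),
                              names_to = "cohort", values_to = "mean")
    cc$cohort <- sub("mean_", "", cc$cohort)
    p3 <- ggplot2::ggplot(cc, ggplot2::aes(.data$period, .data$mean,
                                           fill = .data$cohort)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(~metric, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "Mean",
                    title = "M1 vs M2 at curriculum start and end of pre-clerkship") +
      ggplot2::theme_minimal()
    emit_fig(p3, "fig_cohorts.pdf")
  }

  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(results),
    files = basename(written)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
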