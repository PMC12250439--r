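#' @title Result writers and plots
#' @description CSV is the canonical, byte-reproducible output surface; a
#'   JSON summary sits alongside for audit, and plots (tornado diagram,
#'   cost-effectiveness plane) are best-effort artifacts rendered only when
#'   ggplot2 is available.
#' @name reporting
NULL

write_manifest <- function(out_dir, config_path = NULL, seed = NULL,
                           files = character(0)) {
  manifest <- list(
    tool = "waitcea",
    version = as.character(utils::packageVersion("waitcea")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_checksum = if (!is.null(config_path)) {
      unname(tools::md5sum(config_path))
    } else {
      NULL
    },
    seed = seed,
    files = as.list(basename(files)))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

write_results_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

#' Tornado diagram for a DSA result
#'
#' @param dsa a [run_dsa()] result.
#' @param top number of widest bars to show.
#' @return A ggplot object, or `NULL` when ggplot2 is unavailable.
#' @export
plot_tornado <- function(dsa, top = 12L) {
  stopifnot(inherits(dsa, "dsa_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(NULL)
  df <- utils::head(dsa$entries[!dsa$entries$infeasible, , drop = FALSE],
                    top)
  df$parameter_path <- factor(df$parameter_path,
                              levels = rev(df$parameter_path))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = icer_low, xend = icer_high,
      y = parameter_path, yend = parameter_path),
      linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = dsa$base_icer, linetype = 2) +
    ggplot2::labs(x = "Composite societal ICER", y = NULL,
                  title = sprintf("One-way sensitivity (+/- %.0f%%)",
                                  100 * dsa$relative_delta))
}

#' Cost-effectiveness plane scatter for a PSA result
#'
#' Incremental QALYs on the x axis against incremental societal cost on
#' the y axis, one point per draw, with the WTP threshold as a line
#' through the origin.
#'
#' @param psa a [run_psa()] result.
#' @return A ggplot object, or `NULL` when ggplot2 is unavailable.
#' @export
plot_ce_plane <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(NULL)
  ggplot2::ggplot(psa$draws) +
    ggplot2::geom_point(ggplot2::aes(x = delta_qalys,
                                     y = delta_cost_societal),
                        alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = psa$wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental societal cost",
                  title = sprintf("PSA (%d draws)", psa$n_draws))
}

save_plot_quietly <- function(p, path) {
  if (is.null(p)) return(invisible(NULL))
  ok <- try(suppressMessages(ggplot2::ggsave(path, p, width = 7,
                                             height = 5, dpi = 120)),
            silent = TRUE)
  if (inherits(ok, "try-error")) return(invisible(NULL))
  invisible(path)
}

utils::globalVariables(c("icer_low", "icer_high", "parameter_path",
                         "delta_qalys", "delta_cost_societal"))
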