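#' Plot group-specific and cumulative estimate trajectories
#'
#' Two-panel figure (group-specific on the left, cumulative on the right):
#' point estimates against the coreness group index `k` with 95% confidence
#' error bars, one series per method. Missing estimates (small groups)
#' appear as gaps. A drift of the cumulative trajectory away from the
#' group-1 estimate as weaker instruments accumulate is the visual
#' signature of pleiotropy among peripheral instruments.
#'
#' @param trajectory A [trajectory_table()] data.frame (or an
#'   `mr_core_result`).
#' @param path Optional output path; the device is chosen from the
#'   extension (`.pdf`, `.svg`, `.png`, ...).
#' @param width,height,dpi Passed to [ggplot2::ggsave()] when `path` is
#'   given.
#' @return The ggplot object, invisibly.
#' @export
plot_trajectory <- function(trajectory, path = NULL, width = 9, height = 4.5,
                            dpi = 300) {
  if (inherits(trajectory, "mr_core_result"))
    trajectory <- trajectory_table(trajectory)
  if (!is.data.frame(trajectory) || nrow(trajectory) == 0)
    data_error("empty trajectory table")
  d <- trajectory[!is.na(trajectory$beta), , drop = FALSE]
  if (nrow(d) == 0) data_error("trajectory table contains no estimates")
  d$scope <- factor(d$scope, levels = c("group", "cumulative"),
                    labels = c("group-specific", "cumulative"))
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = k, y = beta, colour = method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = ci_low, ymax = ci_high),
      position = ggplot2::position_dodge(width = 0.5), size = 0.3) +
    ggplot2::facet_wrap(~scope) +
    ggplot2::scale_x_continuous(breaks = function(lim)
      unique(round(pretty(lim)))) +
    ggplot2::labs(x = "instrument group k (1 = putative core)",
                  y = "causal effect estimate (95% CI)",
                  colour = "method") +
    ggplot2::theme_bw()
  if (!is.null(path))
    ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(p)
}

utils::globalVariables(c("k", "beta", "method", "ci_low", "ci_high"))
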