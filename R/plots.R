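#' Plot the health equity impact plane
#'
#' Interventions are scattered with inequality impact (DALYs gained or lost
#' through the change in inequality, dEDE - dNHB) on the x axis and
#' population net health benefit on the y axis; the four quadrants separate
#' win-win interventions (upper right) from trade-offs.
#'
#' @param object A `dcea_equity_plane` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcea_equity_plane <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$inequality_impact, y = .data$dnhb))
  if (!is.null(object$in_ehp)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$in_ehp), alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Inequality impact (DALYs, dEDE - dNHB)",
                  y = "Population net health benefit (DALYs)",
                  colour = "In current package",
                  title = "Health equity impact plane")
}

#' Plot a per-subgroup HALE distribution
#'
#' @param object A `dcea_hale` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of HALE by subgroup.
#' @export
autoplot.dcea_hale <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$subgroup, y = .data$hale)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Health-adjusted life expectancy (years)",
                  title = "Baseline HALE by subgroup")
}

#' Plot a distributional impact table
#'
#' Direct benefit, opportunity cost and net health benefit by subgroup,
#' summed over the interventions in the table.
#'
#' @param object A `dcea_impact` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcea_impact <- function(object, ...) {
  by_sub <- dplyr::summarise(
    dplyr::group_by(object, .data$subgroup),
    `Direct benefit` = sum(.data$direct_benefit),
    `Opportunity cost` = -sum(.data$opportunity_cost),
    `Net health benefit` = sum(.data$net_benefit),
    .groups = "drop"
  )
  long <- tidyr::pivot_longer(by_sub, -"subgroup", names_to = "component",
                              values_to = "dalys")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subgroup, y = .data$dalys,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "DALYs (averted > 0, forgone < 0)",
                  fill = NULL, title = "Distributional impact by subgroup")
}
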