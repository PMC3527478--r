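#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time-lag regression
#'
#' Scatter of community distance against the square root of the time lag
#' with the fitted regression line.
#'
#' @param object A `tla_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tla_fit
#' @export
autoplot.tla_fit <- function(object, ...) {
  df <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sqrt_lag, y = .data$distance)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope,
      colour = "steelblue", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = expression(sqrt("time lag")),
      y = "community distance",
      title = sprintf(
        "%s: slope %.3f, R² %.3f", object$group,
        object$slope, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}

#' Biplot of a CCA fit
#'
#' Sites as points, environmental variables as arrows from the origin
#' (type-2 scaling: species scores scaled by eigenvalues; arrows scaled to
#' the site cloud).
#'
#' @param object A `cca_fit` with at least 2 constrained axes.
#' @param arrow_scale Multiplier applied to the arrow coordinates.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cca_fit
#' @export
autoplot.cca_fit <- function(object, arrow_scale = NULL, ...) {
  if (ncol(object$site_scores) < 2) {
    rlang::abort("biplot needs at least 2 constrained axes")
  }
  sites <- tibble::as_tibble(object$site_scores[, 1:2],
    .name_repair = ~ c("a1", "a2")
  )
  sites$label <- rownames(object$site_scores)
  arrows <- tibble::as_tibble(object$biplot_arrows[, 1:2],
    .name_repair = ~ c("a1", "a2")
  )
  arrows$variable <- rownames(object$biplot_arrows)
  if (is.null(arrow_scale)) {
    arrow_scale <- 0.8 * max(abs(c(sites$a1, sites$a2))) /
      max(abs(c(arrows$a1, arrows$a2)), 1e-12)
  }
  pct <- 100 * object$eigenvalues[1:2] / object$total_inertia
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$a1, y = .data$a2)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(colour = "grey30", alpha = 0.7) +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(
        x = 0, y = 0,
        xend = .data$a1 * arrow_scale, yend = .data$a2 * arrow_scale
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "black"
    ) +
    ggplot2::geom_text(
      data = arrows,
      ggplot2::aes(
        x = .data$a1 * arrow_scale * 1.08,
        y = .data$a2 * arrow_scale * 1.08,
        label = .data$variable
      ),
      size = 3
    ) +
    ggplot2::labs(
      x = sprintf("CCA1 (%.1f%%)", pct[1]),
      y = sprintf("CCA2 (%.1f%%)", pct[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot alpha diversity over time by texture class
#'
#' @param alpha Output of [alpha_diversity()].
#' @param metadata Sample metadata.
#' @param statistic `"shannon"` or `"richness"`.
#' @return A ggplot of per-date texture means with standard-error bars.
#' @export
plot_alpha_diversity <- function(alpha, metadata, statistic = c("shannon", "richness")) {
  statistic <- match.arg(statistic)
  df <- dplyr::inner_join(alpha, metadata, by = "sample_id") |>
    dplyr::group_by(.data$texture, .data$date) |>
    dplyr::summarise(
      mean = mean(.data[[statistic]]),
      se = stats::sd(.data[[statistic]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$date, y = .data$mean,
    colour = .data$texture, group = .data$texture
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$se,
      ymax = .data$mean + .data$se
    )) +
    ggplot2::labs(x = NULL, y = statistic, colour = "texture") +
    ggplot2::theme_minimal()
}

#' Plot temporal beta diversity per site
#'
#' @param beta Output of [temporal_beta()].
#' @param metadata Sample metadata (for the texture class of each site).
#' @return A ggplot bar chart of per-site temporal beta diversity.
#' @export
plot_temporal_beta <- function(beta, metadata) {
  tex <- dplyr::distinct(metadata, .data$site_id, .data$texture)
  df <- dplyr::inner_join(beta, tex, by = "site_id")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$site_id, y = .data$beta, fill = .data$texture
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "site", y = "temporal β (mean Bray-Curtis)") +
    ggplot2::theme_minimal()
}
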