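#' Tidy an agreement report
#'
#' @param x A `lordist_agreement`.
#' @param ... Unused.
#' @return One row per statistic with `estimate`, `std_error`, `conf_low`,
#'   `conf_high`.
#' @export
tidy.lordist_agreement <- function(x, ...) {
  tibble::tibble(
    statistic = c("agreement_percent", "kappa", paste0("weighted_kappa_", x$weights)),
    estimate = c(x$agreement_percent, x$kappa, x$weighted_kappa),
    std_error = c(NA, x$kappa_se, NA),
    conf_low = c(NA, x$kappa_ci[1], NA),
    conf_high = c(NA, x$kappa_ci[2], NA)
  )
}

#' @rdname tidy.lordist_agreement
#' @export
glance.lordist_agreement <- function(x, ...) {
  tibble::tibble(
    agreement_percent = x$agreement_percent,
    kappa = x$kappa, kappa_se = x$kappa_se,
    kappa_conf_low = x$kappa_ci[1], kappa_conf_high = x$kappa_ci[2],
    weighted_kappa = x$weighted_kappa, weights = x$weights,
    n = x$n, label = x$label
  )
}

#' Tidy a kappa fit
#'
#' @param x A `lordist_kappa`.
#' @param ... Unused.
#' @export
tidy.lordist_kappa <- function(x, ...) {
  tibble::tibble(
    estimate = x$kappa, std_error = x$se,
    conf_low = x$ci[1], conf_high = x$ci[2],
    p_observed = x$po, p_expected = x$pe, n = x$n, label = x$label
  )
}

#' Tidy an ICC fit
#'
#' @param x A `lordist_icc`.
#' @param ... Unused.
#' @export
tidy.lordist_icc <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, conf_low = x$ci[1], conf_high = x$ci[2], label = x$label,
    msr = x$msr, msc = x$msc, mse = x$mse,
    n_subjects = x$n, n_ratings = x$k
  )
}

#' Tidy a lordosis curve: its nodes
#'
#' @param x A `lordosis_curve`.
#' @param ... Unused.
#' @return A tibble of node index, abscissa and ordinate.
#' @export
tidy.lordosis_curve <- function(x, ...) {
  nodes_x <- x$x
  nodes_y <- x$y
  tibble::tibble(node = seq_along(nodes_x) - 1, x = nodes_x, y = nodes_y)
}

#' Plot the lordosis curve with its apex and segment shares
#'
#' @param object A `lordosis_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lordosis_curve <- function(object, ...) {
  grid <- seq(object$x[1], object$x[length(object$x)], length.out = 400)
  seg <- findInterval(grid, object$x, rightmost.closed = TRUE)
  df <- tibble::tibble(x = grid, y = eval_curve(object, grid), segment = factor(seg))
  apex <- find_apex(object)
  nodes <- tidy.lordosis_curve(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_area(ggplot2::aes(fill = .data$segment), alpha = 0.35, position = "identity") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = nodes, size = 2) +
    ggplot2::annotate("point", x = apex$x, y = apex$y, shape = 17, size = 3, colour = "red") +
    ggplot2::labs(
      x = "distance along T12-sacrum axis (px)", y = "deflection (px)",
      fill = "segment",
      title = "Lordosis curve",
      subtitle = sprintf("apex at K = %.1f%%", 100 * (apex$x - object$a) / object$s)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a long correlation table
#'
#' @param corr Output of [correlation_matrix()].
#' @return A ggplot tile plot of the lower triangle, starred at significance.
#' @export
plot_correlation <- function(corr) {
  vars <- unique(c(corr$var1, corr$var2))
  df <- dplyr::mutate(
    corr,
    var1 = factor(.data$var1, levels = vars),
    var2 = factor(.data$var2, levels = vars),
    lab = ifelse(
      is.na(.data$r), "",
      paste0(sprintf("%.2f", .data$r), ifelse(!is.na(.data$significant) & .data$significant, "*", ""))
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var2, y = .data$var1, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$lab), size = 3) +
    ggplot2::scale_fill_gradient2(low = "indianred", mid = "white", high = "steelblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Correlation matrix (lower triangle)") +
    ggplot2::theme_minimal()
}
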