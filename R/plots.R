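#' Plot the per-position CA variance profile of a superposed ensemble
#'
#' Variance against residue number, with the retention cut at a chosen
#' truncation level marked: positions below the cut would be retained in
#' the derived ensemble at that level.
#'
#' @param object a `superposed_ensemble`
#' @param percent optional truncation level to highlight
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.superposed_ensemble <- function(object, percent = NULL, ...) {
  df <- object$variance
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$variance)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue (target numbering)",
                  y = expression("C" * alpha * " variance (" * ring(A)^2 * ")"),
                  title = sprintf("Ensemble variance profile (%d members, %d core positions)",
                                  length(object$members), length(object$core)))
  if (!is.null(percent)) {
    retained <- retained_at(object, percent)
    p <- p + ggplot2::geom_point(
      data = df[df$resno %in% retained, , drop = FALSE],
      colour = "#2166ac", size = 1.2) +
      ggplot2::labs(subtitle = sprintf("%d%% level retains %d positions",
                                       percent, length(retained)))
  }
  p
}

#' Plot per-member r.m.s.d. across truncation levels
#'
#' One line per ensemble member: r.m.s.d. from the centroid over the
#' retained positions, against the truncation level. Truncating away the
#' most variable positions should drive the r.m.s.d. down.
#'
#' @param object an `ensemble_set` from [build_ensembles()]
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.ensemble_set <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$percent), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percent, y = .data$rmsd,
                                   group = .data$member,
                                   colour = .data$member)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "truncation level (% of core retained)",
                  y = "member r.m.s.d. from centroid (Å)",
                  colour = "member")
}

#' Plot a ranked solution summary
#'
#' Refined R-free per search model, coloured by triage category, in rank
#' order.
#'
#' @param object a ranked tibble from [rank_solutions()]
#' @param ... unused
#' @return a ggplot object
#' @export
plot_solutions <- function(object, ...) {
  df <- object[!is.na(object$r_free), , drop = FALSE]
  df$model_id <- factor(df$model_id, levels = rev(df$model_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_free, y = .data$model_id,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(0.35, 0.5), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(GOOD = "#1b7837", MARGINAL = "#fdb863",
                                          POOR = "#b2182b", UNKNOWN = "grey70")) +
    ggplot2::labs(x = expression(R[free]), y = NULL, fill = "category")
}
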