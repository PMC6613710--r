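#' Plot a per-gene pause profile
#'
#' Line plot of mean pause score per codon with a standard-deviation ribbon;
#' motif codons (when annotated by [gene_profile()]) are marked on the axis.
#'
#' @param object A `pause_profile` tibble from [gene_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pause_profile
#' @export
autoplot.pause_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$codon, y = .data$mean_score)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$mean_score - .data$sd_score, 0),
                   ymax = .data$mean_score + .data$sd_score),
      fill = "grey80"
    ) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Codon", y = "Pause score",
                  title = unique(object$gene_id)) +
    ggplot2::theme_classic()
  if ("motif_hit" %in% names(object) && any(object$motif_hit)) {
    p <- p + ggplot2::geom_point(
      data = object[object$motif_hit, ],
      ggplot2::aes(y = -max(object$mean_score) * 0.03),
      shape = 8, colour = "red", size = 2
    )
  }
  p
}

#' @rdname autoplot.pause_profile
#' @param x A `pause_profile`.
#' @param y Unused.
#' @export
plot.pause_profile <- function(x, y, ...) print(autoplot.pause_profile(x, ...))

#' Plot a weighted sequence-logo matrix
#'
#' Stacked-letter rendering of a position weight matrix: at each position,
#' residue letters are stacked by weight (tallest on top), analogous to a
#' frequency-scaled sequence logo.
#'
#' @param object A `logo_matrix` from [weighted_logo()].
#' @param min_weight Residues below this weight are omitted from the stack
#'   for legibility.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot logo_matrix
#' @export
autoplot.logo_matrix <- function(object, min_weight = 0.02, ...) {
  df <- as_tibble(as.table(unclass(object)), .name_repair = ~ c("aa", "site", "weight")) |>
    mutate(site = factor(.data$site, levels = colnames(object))) |>
    filter(.data$weight >= min_weight) |>
    group_by(.data$site) |>
    arrange(.data$weight, .by_group = TRUE) |>
    mutate(ymax = cumsum(.data$weight),
           ymin = .data$ymax - .data$weight,
           ymid = (.data$ymin + .data$ymax) / 2) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site)) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = as.integer(.data$site) - 0.45,
                   xmax = as.integer(.data$site) + 0.45,
                   ymin = .data$ymin, ymax = .data$ymax, fill = .data$aa),
      colour = "white", linewidth = 0.2, show.legend = FALSE
    ) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$ymid, label = .data$aa, size = .data$weight),
      fontface = "bold", show.legend = FALSE
    ) +
    ggplot2::scale_size(range = c(2, 8)) +
    ggplot2::labs(x = "Ribosome site", y = "Weight") +
    ggplot2::theme_classic()
}

#' @rdname autoplot.logo_matrix
#' @param x A `logo_matrix`.
#' @param y Unused.
#' @export
plot.logo_matrix <- function(x, y, ...) print(autoplot.logo_matrix(x, ...))

#' Compare tripeptide pause scores between two conditions
#'
#' Scatter plot of per-tripeptide mean P-site pause scores (one condition per
#' axis) with the identity line; the strongest off-diagonal tripeptides are
#' labelled.
#'
#' @param tp_a,tp_b [tripeptide_scores()] tibbles for the two conditions
#'   (same framing).
#' @param label_a,label_b Axis labels.
#' @param n_label Number of top condition-B tripeptides to label.
#' @return A ggplot object.
#' @export
plot_tripeptide_comparison <- function(tp_a, tp_b,
                                       label_a = "condition A",
                                       label_b = "condition B",
                                       n_label = 10) {
  df <- inner_join(
    tp_a |> select("tripeptide", score_a = "mean_score"),
    tp_b |> select("tripeptide", score_b = "mean_score"),
    by = "tripeptide"
  ) |>
    filter(!is.na(.data$score_a), !is.na(.data$score_b))
  top <- df |> arrange(dplyr::desc(.data$score_b)) |> head(n_label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score_a, y = .data$score_b)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$tripeptide),
                       size = 2.5, vjust = -0.6) +
    ggplot2::labs(x = paste("Mean pause score,", label_a),
                  y = paste("Mean pause score,", label_b)) +
    ggplot2::theme_classic()
}
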