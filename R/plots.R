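#' Fitness plot: query vs control background
#'
#' The standard QFA fitness plot: each point is one gene deletion's mean
#' fitness in the control background (x) and the query background (y), with
#' the dashed line of equal fitness (`y = x`) and the solid independence
#' line (`y = m x`, the fitness predicted under genetic independence).
#' Points above the independence line suppress the query defect; points
#' below enhance it. Optional highlight sets color chosen gene groups.
#'
#' @param interactions An `interaction_table` from [compute_interactions()].
#' @param highlights Optional `data.frame` with columns `orf` and `group`;
#'   highlighted genes are drawn colored by group on top of the gray cloud.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_fitness_comparison <- function(interactions, highlights = NULL,
                                    title = NULL) {
  m <- attr(interactions, "m")
  df <- as.data.frame(interactions)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$F_control, y = .data$F_query)) +
    ggplot2::geom_point(color = "grey60", size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", color = "grey40") +
    ggplot2::geom_abline(slope = m, intercept = 0, color = "grey25") +
    ggplot2::labs(x = "Control background fitness (doublings²/day)",
                  y = "Query background fitness (doublings²/day)",
                  title = title,
                  subtitle = sprintf("independence slope m = %.3g", m)) +
    ggplot2::theme_classic()
  if (!is.null(highlights) && nrow(highlights)) {
    hi <- merge(df, highlights, by = "orf")
    p <- p + ggplot2::geom_point(data = hi,
                                 ggplot2::aes(color = .data$group), size = 2) +
      ggplot2::labs(color = "gene set")
  }
  p
}

#' Multi-screen fitness profiles for selected genes
#'
#' Draws each selected gene's value across every screen condition of a
#' profile matrix as a connected line (profile), the batch equivalent of an
#' interactive profile browser.
#'
#' @param matrix A `profile_matrix`.
#' @param genes ORFs to draw (others are omitted).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_fitness_profiles <- function(matrix, genes, title = NULL) {
  stopifnot(inherits(matrix, "profile_matrix"))
  genes <- intersect(genes, matrix$genes)
  if (!length(genes)) stop("none of the requested genes are in the matrix",
                           call. = FALSE)
  v <- matrix$values[genes, , drop = FALSE]
  df <- data.frame(orf = rep(genes, times = ncol(v)),
                   screen = factor(rep(colnames(v), each = nrow(v)),
                                   levels = matrix$screens),
                   value = as.vector(v))
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$screen, y = .data$value,
                                   color = .data$orf, group = .data$orf)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "screen condition",
                  y = if (matrix$value_kind == "gis")
                    "genetic interaction strength (doublings²/day)"
                  else "fitness (doublings²/day)",
                  title = title, color = "gene") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
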