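# Thin ggplot2 layer over the exported tables; every plot can be rebuilt
# from the TSVs written by run_all().

#' Workflow plots
#'
#' Convenience visualizations of the core results: rarefaction curves per
#' sample, a diversity barplot across rounds, a similarity heatmap, length
#' distributions, and a stacked positional-composition bar chart (the
#' tabular form of a sequence logo; use [logo_heights()] for
#' information-scaled heights).
#'
#' @param curves A tibble of rarefaction points with a `sample_name`
#'   column (e.g. the `rarefaction.tsv` written by [run_all()], or a
#'   single [rarefaction_curve()]).
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(curves) {
  if (inherits(curves, "rarefaction_curve")) {
    curves <- dplyr::bind_cols(
      tibble::tibble(sample_name = attr(curves, "sample_name")),
      tibble::as_tibble(curves))
  }
  ggplot2::ggplot(curves, ggplot2::aes(.data$depth, .data$unique,
                                       colour = .data$sample_name)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reads sampled", y = "unique sequences",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rarefaction
#' @param div A tibble (`sample_name`, `diversity`) from
#'   [diversity_table()].
#' @export
plot_diversity <- function(div) {
  ggplot2::ggplot(div, ggplot2::aes(.data$sample_name, .data$diversity)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "diversity") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rarefaction
#' @param mat A `similarity_matrix` from [pairwise_matrix()].
#' @export
plot_similarity <- function(mat) {
  stopifnot(inherits(mat, "similarity_matrix"))
  long <- tidyr::expand_grid(sample_a = rownames(mat),
                             sample_b = colnames(mat))
  long$value <- as.vector(t(unclass(mat)))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_a, .data$sample_b,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = attr(mat, "method")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_rarefaction
#' @param dist A `length_distribution` from [length_distribution()].
#' @export
plot_length_distribution <- function(dist) {
  ggplot2::ggplot(tibble::as_tibble(dist),
                  ggplot2::aes(.data$length, .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = paste0("length (", attr(dist, "unit"), ")"),
                  y = attr(dist, "weighting")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_rarefaction
#' @param aa_mat A `positional_aa_matrix` from [positional_aa_matrix()].
#' @export
plot_aa_composition <- function(aa_mat) {
  stopifnot(inherits(aa_mat, "positional_aa_matrix"))
  long <- tibble::tibble(
    position = rep(seq_len(ncol(aa_mat)), each = nrow(aa_mat)),
    aa = rep(rownames(aa_mat), times = ncol(aa_mat)),
    fraction = as.vector(unclass(aa_mat)))
  long <- long[long$fraction > 0, ]
  ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$fraction,
                                     fill = .data$aa)) +
    ggplot2::geom_col(position = "stack", width = 0.9) +
    ggplot2::labs(x = "position", y = "fraction", fill = "AA") +
    ggplot2::theme_minimal()
}
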