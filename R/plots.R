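#' Stacked-bar plot of frequency-bin composition
#'
#' Mirrors the standard depth-comparison figure: one stacked bar per
#' dataset, segments colored by frequency bin, heights the percentage of
#' cleaned reads in each bin (the bottom segment is the singleton
#' population).
#'
#' @param ... Named `pd_bins` objects (or a single named list of them).
#' @return A ggplot object.
#' @export
plot_bin_composition <- function(...) {
  bins <- list(...)
  if (length(bins) == 1 && is.list(bins[[1]]) &&
      !inherits(bins[[1]], "pd_bins")) {
    bins <- bins[[1]]
  }
  nm <- names(bins) %||% paste0("dataset", seq_along(bins))
  df <- purrr::imap(bins, function(b, name) {
    tibble(dataset = if (nzchar(name)) name else
             attr(b, "label") %||% "dataset",
           bin = b$bin, read_percentage = b$read_percentage)
  }) |> bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(
    x = dataset, y = read_percentage,
    fill = factor(bin, levels = rev(levels(df$bin)))
  )) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::scale_fill_viridis_d(name = "absolute\nfrequency",
                                  direction = -1) +
    ggplot2::labs(x = NULL, y = "% of cleaned reads") +
    ggplot2::theme_minimal()
}

#' @method autoplot pd_bins
#' @export
autoplot.pd_bins <- function(object, ...) {
  plot_bin_composition(object)
}

#' @method autoplot pd_spectrum
#' @export
autoplot.pd_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = frequency, y = n_peptides)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "absolute frequency",
                  y = "number of peptides",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

posfreq_long <- function(object) {
  tidyr::pivot_longer(as_tibble(object), -residue,
                      names_to = "position", values_to = "value") |>
    mutate(position = as.integer(position))
}

#' @method autoplot pd_posfreq
#' @export
autoplot.pd_posfreq <- function(object, ...) {
  ggplot2::ggplot(posfreq_long(object),
                  ggplot2::aes(x = position, y = residue, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% of\nsequences") +
    ggplot2::scale_x_continuous(breaks = seq_len(
      sum(names(object) != "residue"))) +
    ggplot2::labs(x = "peptide position", y = NULL,
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Heatmap of positional-frequency differences
#'
#' Red marks residues overrepresented in the test dataset relative to the
#' reference, blue underrepresented, in percentage points.
#'
#' @param object A `pd_posdiff` from [positional_difference()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pd_posdiff
#' @export
autoplot.pd_posdiff <- function(object, ...) {
  labs <- attr(object, "labels")
  ggplot2::ggplot(posfreq_long(object),
                  ggplot2::aes(x = position, y = residue, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", name = "pp diff") +
    ggplot2::scale_x_continuous(breaks = seq_len(
      sum(names(object) != "residue"))) +
    ggplot2::labs(x = "peptide position", y = NULL,
                  title = paste(labs[1], "vs", labs[2])) +
    ggplot2::theme_minimal()
}
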