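#' Percentage of distinct sequences
#'
#' Relative diversity normalized to the dataset: unique cleaned reads
#' divided by absolute cleaned reads, times 100. A library-quality
#' indicator that shrinks with sequencing depth for a fixed pool.
#'
#' @param stats Cleaning statistics (one or more rows, see
#'   [cleaning_stats()]), or a `pd_dataset`.
#' @return Tibble with columns `dataset` and `percent_distinct`.
#' @export
#' @examples
#' percent_distinct(cleaning_stats(unique_cleaned = 68, absolute_cleaned = 100))
percent_distinct <- function(stats) {
  stats <- as_stats(stats)
  if (any(stats$absolute_cleaned <= 0)) {
    abort("percent_distinct is undefined with zero cleaned reads",
          class = "pepdepth_undefined")
  }
  tibble(
    dataset = stats$dataset,
    percent_distinct = 100 * stats$unique_cleaned / stats$absolute_cleaned
  )
}

as_stats <- function(x) {
  if (inherits(x, "pd_dataset")) return(x$stats)
  stopifnot(is.data.frame(x))
  x
}

#' Fold difference in unique cleaned reads between two datasets
#'
#' @param stats_a,stats_b One-row cleaning statistics (numerator,
#'   denominator) or `pd_dataset` objects.
#' @return The fold difference `unique_cleaned(a) / unique_cleaned(b)` as
#'   a double (full precision; round at the reporting layer).
#' @export
#' @examples
#' unique_read_ratio(cleaning_stats(unique_cleaned = 3.70e6),
#'                   cleaning_stats(unique_cleaned = 5.21e5))
unique_read_ratio <- function(stats_a, stats_b) {
  a <- as_stats(stats_a)$unique_cleaned
  b <- as_stats(stats_b)$unique_cleaned
  stopifnot(length(a) == 1, length(b) == 1)
  if (a <= 0 || b <= 0) {
    abort("unique_read_ratio requires nonzero unique cleaned reads",
          class = "pepdepth_undefined")
  }
  a / b
}

#' Frequency-bin composition of a dataset
#'
#' Groups peptides into bins by absolute frequency (1, 2, ..., `max_bin`,
#' and `> max_bin`). Per bin, `unique_count` is the number of distinct
#' peptides (stacked-bar width) and `read_percentage` the percentage of
#' cleaned reads those peptides account for (stacked-bar height). The
#' singleton percentage of a dataset is the bin-1 `read_percentage`.
#'
#' @param x A `pd_freq_matrix`.
#' @param max_bin Highest individually resolved frequency (default 10).
#' @param weighting `"abundance"` (default; heights are percent of reads)
#'   or `"unique"` (heights are percent of unique sequences), the latter
#'   provided for cross-checks.
#' @return A `pd_bins` tibble with columns `bin` (factor), `unique_count`,
#'   `read_percentage`.
#' @export
#' @examples
#' fm <- freq_matrix(c("A", "B", "C"), c(1, 1, 2))
#' bin_composition(fm)
bin_composition <- function(x, max_bin = 10,
                            weighting = c("abundance", "unique")) {
  stopifnot(inherits(x, "pd_freq_matrix"), nrow(x) > 0)
  weighting <- arg_match(weighting)
  f <- x$absolute_frequency
  lev <- c(as.character(seq_len(max_bin)), paste0(">", max_bin))
  bin <- ifelse(f > max_bin, paste0(">", max_bin), as.character(f))
  bin <- factor(bin, levels = lev)
  total_reads <- sum(f)
  df <- tibble(bin = bin, f = f) |>
    group_by(bin, .drop = FALSE) |>
    summarise(unique_count = n(), reads = sum(f), .groups = "drop")
  denom <- if (weighting == "abundance") total_reads else nrow(x)
  num <- if (weighting == "abundance") df$reads else df$unique_count
  out <- tibble(
    bin = df$bin,
    unique_count = df$unique_count,
    read_percentage = 100 * num / denom
  )
  structure(out, class = c("pd_bins", class(tibble())),
            label = attr(x, "label"), weighting = weighting)
}

#' @rdname bin_composition
#' @export
singleton_percentage <- function(x, weighting = c("abundance", "unique")) {
  b <- bin_composition(x, weighting = weighting)
  b$read_percentage[b$bin == "1"]
}

#' Absolute-frequency spectrum and distinct frequency values
#'
#' Maps each absolute frequency f to the number of peptides observed
#' exactly f times. The number of rows is the count of distinct frequency
#' values (DFV), a measure of how heterogeneous the detected abundance
#' distribution is; deeper sequencing of the same pool resolves more DFVs.
#'
#' @param x A `pd_freq_matrix`.
#' @return A `pd_spectrum` tibble with columns `frequency` and
#'   `n_peptides`, sorted by frequency.
#' @export
#' @examples
#' frequency_spectrum(freq_matrix(c("A", "B", "C"), c(1, 1, 2)))
frequency_spectrum <- function(x) {
  stopifnot(inherits(x, "pd_freq_matrix"))
  out <- tibble(frequency = x$absolute_frequency) |>
    dplyr::count(frequency, name = "n_peptides") |>
    arrange(frequency)
  structure(out, class = c("pd_spectrum", class(tibble())),
            label = attr(x, "label"))
}

#' @rdname frequency_spectrum
#' @export
dfv_count <- function(x) {
  if (inherits(x, "pd_spectrum")) return(nrow(x))
  if (inherits(x, "pd_freq_matrix")) {
    return(length(unique(x$absolute_frequency)))
  }
  abort("dfv_count expects a pd_spectrum or pd_freq_matrix",
        class = "pepdepth_invalid_input")
}

#' Chi-square test with Yates continuity correction for a 2x2 table
#'
#' Statistic `N * (max(0, |ad - bc| - N/2))^2 /
#' ((a+b)(c+d)(a+c)(b+d))` with `N = a+b+c+d`, compared against the
#' chi-square distribution with 1 degree of freedom. Used to contrast
#' singleton vs non-singleton read counts between two datasets.
#'
#' @param a,b,c,d Cell counts (row-wise 2x2).
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_yates(40, 10, 10, 40)
chi_square_yates <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || anyNA(cells)) {
    abort("cell counts must be nonnegative", class = "pepdepth_invalid_input")
  }
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    abort("all margins of the 2x2 table must be positive",
          class = "pepdepth_invalid_input")
  }
  stat <- n * max(0, abs(a * d - b * c) - n / 2)^2 / prod(margins)
  tibble(statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}
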