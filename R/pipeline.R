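#' Configuration for an end-to-end pipeline run
#'
#' Bundles input FASTQ paths, the extraction configuration and the
#' analysis options for [run_pipeline()].
#'
#' @param datasets Named character vector of FASTQ paths (name = dataset
#'   label). At least one; cross-dataset analyses need two or more.
#' @param out_dir Output directory (created if missing).
#' @param extraction A [extraction_config()].
#' @param compare_pair Length-2 character vector naming the datasets for
#'   the distinguishing / positional-difference analyses, in the order
#'   (test/shallower, reference/deeper). Defaults to the first two
#'   datasets.
#' @param frequencies Group-defining absolute frequencies for
#'   [distinguishing_analysis()].
#' @param alpha Family-wise level for confidence intervals.
#' @param z,m_tests CI quantile controls, see [wald_poisson_ci()].
#' @param weighting Positional-frequency weighting, `"unique"` or
#'   `"abundance"`.
#' @param max_bin Highest individually resolved frequency bin.
#' @param seed Seed applied at the start of the run.
#' @return A `pd_run_config` list.
#' @export
run_config <- function(datasets, out_dir,
                       extraction = extraction_config(),
                       compare_pair = NULL,
                       frequencies = seq(20, 50, by = 5),
                       alpha = 0.05, z = NULL, m_tests = NULL,
                       weighting = c("unique", "abundance"),
                       max_bin = 10, seed = 1L) {
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    abort("datasets must be a named character vector of FASTQ paths",
          class = "pepdepth_invalid_config")
  }
  missing <- datasets[!file.exists(datasets)]
  if (length(missing) > 0) {
    abort(paste0("input FASTQ not found: ",
                 paste(missing, collapse = ", ")),
          class = "pepdepth_missing_file")
  }
  compare_pair <- compare_pair %||%
    if (length(datasets) >= 2) names(datasets)[1:2] else NULL
  if (!is.null(compare_pair) &&
      !all(compare_pair %in% names(datasets))) {
    abort("compare_pair must name configured datasets",
          class = "pepdepth_invalid_config")
  }
  structure(list(
    datasets = datasets,
    out_dir = out_dir,
    extraction = as_extraction_config(extraction),
    compare_pair = compare_pair,
    frequencies = frequencies,
    alpha = alpha,
    z = z,
    m_tests = m_tests,
    weighting = arg_match(weighting),
    max_bin = max_bin,
    seed = as.integer(seed)
  ), class = "pd_run_config")
}

#' Run the full characterization pipeline
#'
#' Processes every configured FASTQ into a frequency matrix and cleaning
#' statistics, computes the single-dataset metrics (percent distinct,
#' bin composition, frequency spectrum and DFV), and, when two or more
#' datasets are configured, the cross-dataset analyses (peptide overlap,
#' distinguishing capacity, positional frequency difference). All tables
#' are written as CSV under `out_dir` alongside a human-readable
#' `summary.txt`; every number in the summary comes from a written table.
#' Identical config + seed reproduces byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return A `pd_run` list (datasets, summary, bins, spectra, overlap,
#'   distinguishing, positional results, output paths), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pd_run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  t0 <- Sys.time()
  paths <- character(0)
  note <- function(fmt, ...) message(sprintf(fmt, ...))

  datasets <- list()
  for (nm in names(config$datasets)) {
    t1 <- Sys.time()
    ds <- process_dataset(config$datasets[[nm]], config$extraction,
                          label = nm)
    datasets[[nm]] <- ds
    p <- out(paste0("matrix_", nm, ".csv"))
    write_frequency_matrix(ds$freq_matrix, p)
    paths <- c(paths, p)
    note("processed %s: %d reads (%d cleaned) [%.1fs]", nm,
         ds$stats$total_absolute, ds$stats$absolute_cleaned,
         as.numeric(difftime(Sys.time(), t1, units = "secs")))
  }

  bins <- map(datasets, function(ds) {
    bin_composition(ds$freq_matrix, max_bin = config$max_bin)
  })
  spectra <- map(datasets, function(ds) frequency_spectrum(ds$freq_matrix))

  summary_tbl <- purrr::imap(datasets, function(ds, nm) {
    s <- ds$stats
    dplyr::bind_cols(
      s,
      tibble(
        percent_distinct = percent_distinct(s)$percent_distinct,
        singleton_percentage =
          if (nrow(ds$freq_matrix) > 0)
            singleton_percentage(ds$freq_matrix) else NA_real_,
        dfv = dfv_count(ds$freq_matrix)
      )
    )
  }) |> bind_rows()
  readr::write_csv(summary_tbl, out("summary.csv"))

  bins_tbl <- purrr::imap(bins, function(b, nm) {
    dplyr::bind_cols(tibble(dataset = nm), as_tibble(b))
  }) |> bind_rows()
  readr::write_csv(bins_tbl, out("bins.csv"))

  spectrum_tbl <- purrr::imap(spectra, function(s, nm) {
    dplyr::bind_cols(tibble(dataset = nm), as_tibble(s))
  }) |> bind_rows()
  readr::write_csv(spectrum_tbl, out("spectrum.csv"))
  paths <- c(paths, out(c("summary.csv", "bins.csv", "spectrum.csv")))

  overlap <- NULL
  dist <- NULL
  posdiff <- NULL
  if (length(datasets) >= 2) {
    mats <- map(datasets, "freq_matrix")
    overlap <- peptide_overlap(mats[seq_len(min(4, length(mats)))])
    readr::write_csv(overlap, out("overlap.csv"))

    a <- config$compare_pair[1]
    b <- config$compare_pair[2]
    dist <- distinguishing_analysis(
      mats[[a]], mats[[b]],
      frequencies = config$frequencies,
      alpha = config$alpha, m_tests = config$m_tests, z = config$z
    )
    readr::write_csv(dist$members, out("ci_table.csv"))
    readr::write_csv(dist$groups, out("ci_groups.csv"))

    pf <- map(mats[c(a, b)], positional_frequency,
              weighting = config$weighting)
    for (nm in names(pf)) {
      p <- out(paste0("posfreq_", nm, ".csv"))
      readr::write_csv(as_tibble(pf[[nm]]), p)
      paths <- c(paths, p)
    }
    posdiff <- positional_difference(pf[[a]], pf[[b]])
    readr::write_csv(as_tibble(posdiff), out("posdiff.csv"))
    paths <- c(paths, out(c("overlap.csv", "ci_table.csv",
                            "ci_groups.csv", "posdiff.csv")))
  }

  writeLines(render_summary(summary_tbl, bins_tbl, overlap, dist, config),
             out("summary.txt"))
  paths <- c(paths, out("summary.txt"))
  note("pipeline finished in %.1fs, outputs in %s",
       as.numeric(difftime(Sys.time(), t0, units = "secs")),
       config$out_dir)

  invisible(structure(list(
    datasets = datasets,
    summary = summary_tbl,
    bins = bins,
    spectra = spectra,
    overlap = overlap,
    distinguishing = dist,
    posdiff = posdiff,
    paths = paths,
    config = config
  ), class = "pd_run"))
}

# Report layer: all formatting (1 d.p. folds, 3 s.f. scientific relative
# frequencies, "<0.0001" p-values) lives here; the CSVs keep full
# precision.
render_summary <- function(summary_tbl, bins_tbl, overlap, dist, config) {
  fmt_sci <- function(x) formatC(x, format = "e", digits = 2)
  lines <- c("pepdepth pipeline summary", "")
  for (i in seq_len(nrow(summary_tbl))) {
    s <- summary_tbl[i, ]
    lines <- c(lines, sprintf(
      "%s: %s cleaned reads (%s unique, %.1f%% distinct), %s removed (%.2f%%), singleton %.1f%%, DFV %d",
      s$dataset, format(s$absolute_cleaned, big.mark = ","),
      format(s$unique_cleaned, big.mark = ","), s$percent_distinct,
      format(s$absolute_removed, big.mark = ","),
      s$pct_absolute_removed, s$singleton_percentage, s$dfv
    ))
  }
  if (nrow(summary_tbl) >= 2) {
    folds <- utils::combn(seq_len(nrow(summary_tbl)), 2, simplify = FALSE)
    lines <- c(lines, "", "unique-cleaned-read fold differences:")
    for (p in folds) {
      r <- summary_tbl$unique_cleaned[p[1]] /
        summary_tbl$unique_cleaned[p[2]]
      lines <- c(lines, sprintf("  %s / %s = %.1f",
                                summary_tbl$dataset[p[1]],
                                summary_tbl$dataset[p[2]], r))
    }
  }
  if (!is.null(overlap)) {
    lines <- c(lines, "", "identical peptides between datasets:")
    off <- overlap[overlap$set_a != overlap$set_b, ]
    lines <- c(lines, sprintf("  %s & %s: %s", off$set_a, off$set_b,
                              format(off$n_common, big.mark = ",")))
  }
  if (!is.null(dist)) {
    lines <- c(lines, "", sprintf(
      "distinguishing capacity (%s groups vs %s, z = %.4f):",
      dist$labels[1], dist$labels[2], dist$z
    ))
    g <- dist$groups
    lines <- c(lines, sprintf(
      "  frequency %d: %d shared peptides, %s",
      as.integer(g$frequency_a), g$n_members,
      ifelse(g$significant, "resolved (disjoint CIs)", "not resolved")
    ))
  }
  lines
}

#' @export
print.pd_run <- function(x, ...) {
  cat(paste(render_summary(x$summary,
                           NULL, x$overlap, x$distinguishing, x$config),
            collapse = "\n"), "\n")
  invisible(x)
}
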