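#' Extraction configuration
#'
#' Parameters of the read-cleaning procedure: anchored location of the
#' peptide-encoding region, expected peptide length, required amino-acid
#' linker, and strand policy. Anchor matching is exact (no mismatches) with
#' first-occurrence semantics, which keeps the accounting auditable; reads
#' are scanned on the forward strand only unless `reverse_complement` is
#' set, matching single-end amplicon sequencing with fixed primer
#' orientation.
#'
#' @param upstream_anchor,downstream_anchor Exact nucleotide flanks
#'   bounding the insert+linker coding region. Defaults match
#'   [synthetic_library_config()].
#' @param peptide_length Displayed peptide length in residues.
#' @param linker_aa Amino-acid linker required immediately after the
#'   peptide in the translated region.
#' @param reverse_complement If `TRUE`, reads whose forward strand lacks
#'   the anchors are re-scanned on the reverse complement.
#' @return A `pd_extraction_config` list.
#' @export
extraction_config <- function(upstream_anchor = "ACGTTCGAGGTCAGCTCATA",
                              downstream_anchor = "TGACCTGTAGCCTTAGGACT",
                              peptide_length = 12,
                              linker_aa = "GGGS",
                              reverse_complement = FALSE) {
  cfg <- list(
    upstream_anchor = toupper(upstream_anchor),
    downstream_anchor = toupper(downstream_anchor),
    peptide_length = as.integer(peptide_length),
    linker_aa = toupper(linker_aa),
    reverse_complement = isTRUE(reverse_complement)
  )
  if (nchar(cfg$upstream_anchor) < 1 || nchar(cfg$downstream_anchor) < 1) {
    abort("anchors must be nonempty", class = "pepdepth_invalid_config")
  }
  if (cfg$peptide_length < 1 || nchar(cfg$linker_aa) < 1) {
    abort("peptide_length must be >= 1 and linker_aa nonempty",
          class = "pepdepth_invalid_config")
  }
  structure(cfg, class = "pd_extraction_config")
}

# Derive an extraction config from a synthetic library config.
as_extraction_config <- function(x) {
  if (inherits(x, "pd_extraction_config")) return(x)
  if (inherits(x, "pd_library_config")) {
    return(extraction_config(
      upstream_anchor = x$upstream_anchor,
      downstream_anchor = x$downstream_anchor,
      peptide_length = x$peptide_length,
      linker_aa = x$linker_aa
    ))
  }
  abort("expected a pd_extraction_config or pd_library_config",
        class = "pepdepth_invalid_config")
}

# Chunked FASTQ reader. Applies `fun(tibble(read_id, sequence))` to
# successive blocks of records so memory stays proportional to the chunk,
# not the file. Validates the 4-line layout and the sequence alphabet,
# reporting 1-based file line numbers on failure.
fastq_chunk_apply <- function(path, fun, chunk_records = 100000L) {
  if (!file.exists(path)) {
    abort(paste0("FASTQ file not found: ", path),
          class = "pepdepth_missing_file")
  }
  con <- file(path, open = "r")
  on.exit(close(con))
  line0 <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_records)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L) {
      abort(sprintf("truncated FASTQ record at line %d",
                    line0 + 4L * (length(lines) %/% 4L) + 1L),
            class = "pepdepth_malformed_fastq")
    }
    nrec <- length(lines) %/% 4L
    hdr <- lines[seq(1L, length(lines), by = 4L)]
    seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
    plus <- lines[seq(3L, length(lines), by = 4L)]
    bad_hdr <- which(substr(hdr, 1L, 1L) != "@")
    if (length(bad_hdr) > 0) {
      abort(sprintf("expected '@' header at line %d",
                    line0 + 4L * (bad_hdr[1] - 1L) + 1L),
            class = "pepdepth_malformed_fastq")
    }
    bad_plus <- which(substr(plus, 1L, 1L) != "+")
    if (length(bad_plus) > 0) {
      abort(sprintf("expected '+' separator at line %d",
                    line0 + 4L * (bad_plus[1] - 1L) + 3L),
            class = "pepdepth_malformed_fastq")
    }
    bad_seq <- which(grepl("[^ACGTN]", seqs))
    if (length(bad_seq) > 0) {
      abort(sprintf("non-ACGTN character in sequence at line %d",
                    line0 + 4L * (bad_seq[1] - 1L) + 2L),
            class = "pepdepth_malformed_fastq")
    }
    ids <- sub("^@", "", sub("\\s.*$", "", hdr))
    fun(tibble(read_id = ids, sequence = seqs))
    line0 <- line0 + length(lines)
    if (nrec < chunk_records) break
  }
  invisible(line0 %/% 4L)
}

#' Read a 4-line FASTQ file
#'
#' @param path FASTQ path.
#' @param chunk_records Records per internally processed chunk.
#' @return Tibble with columns `read_id` and `sequence`, in file order.
#'   Malformed records raise an error naming the offending line number.
#' @export
parse_fastq <- function(path, chunk_records = 100000L) {
  chunks <- list()
  fastq_chunk_apply(path, function(df) {
    chunks[[length(chunks) + 1L]] <<- df
  }, chunk_records = chunk_records)
  if (length(chunks) == 0L) {
    return(tibble(read_id = character(0), sequence = character(0)))
  }
  bind_rows(chunks)
}

#' Locate the peptide-encoding region between vector anchors
#'
#' Returns the subsequence strictly between the first exact occurrence of
#' the upstream anchor and the first subsequent exact occurrence of the
#' downstream anchor, checking that its length equals
#' `3 * (peptide_length + nchar(linker_aa))`.
#'
#' @param reads Character vector of read sequences.
#' @param config A [extraction_config()].
#' @return Tibble with columns `region` (nucleotides, `NA` on failure) and
#'   `reason` (`NA`, `"no_anchor"` or `"wrong_insert_length"`).
#' @export
extract_insert <- function(reads, config = extraction_config()) {
  config <- as_extraction_config(config)
  n <- length(reads)
  up <- config$upstream_anchor
  down <- config$downstream_anchor
  expected <- 3L * (config$peptide_length + nchar(config$linker_aa))

  region <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  if (n == 0) return(tibble(region = region, reason = reason))

  pos_up <- regexpr(up, reads, fixed = TRUE)
  has_up <- pos_up > 0
  rest_start <- pos_up + nchar(up)
  rest <- ifelse(has_up, substr(reads, rest_start, nchar(reads)), "")
  pos_down <- regexpr(down, rest, fixed = TRUE)
  ok <- has_up & pos_down > 0
  reason[!ok] <- "no_anchor"
  region[ok] <- substr(rest[ok], 1L, pos_down[ok] - 1L)
  wrong <- ok & nchar(region) != expected
  reason[wrong] <- "wrong_insert_length"
  region[wrong] <- NA_character_
  tibble(region = region, reason = reason)
}

#' Classify reads into cleaned peptides and removal reasons
#'
#' Applies the cleaning rule: locate the region between the anchors,
#' translate it, require the configured amino-acid linker immediately after
#' the peptide, and require no `*` (stop) or `X` (ambiguous) anywhere in
#' peptide+linker. The first failing rule sets the removal reason, in the
#' fixed order `no_anchor`, `wrong_insert_length`, `contains_stop_or_X`,
#' `missing_linker`, so every removed read has exactly one reason.
#'
#' @param reads Tibble with `read_id` and `sequence` (as from
#'   [parse_fastq()]), or a character vector of sequences.
#' @param config A [extraction_config()].
#' @return Tibble with columns `read_id`, `status` (`"cleaned"` /
#'   `"removed"`), `peptide` (cleaned reads only), `reason` (removed reads
#'   only) and `removed_key` (identity used for unique-removed accounting:
#'   the raw extracted region when extractable, else the full read).
#' @export
classify_reads <- function(reads, config = extraction_config()) {
  config <- as_extraction_config(config)
  if (is.character(reads)) {
    reads <- tibble(
      read_id = sprintf("read_%d", seq_along(reads)),
      sequence = toupper(reads)
    )
  }
  seqs <- reads$sequence
  ext <- extract_insert(seqs, config)

  if (config$reverse_complement) {
    retry <- which(ext$reason == "no_anchor")
    if (length(retry) > 0) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[retry])
      ))
      ext2 <- extract_insert(rc, config)
      ext[retry, ] <- ext2
      seqs[retry] <- rc
    }
  }

  n <- nrow(reads)
  L <- config$peptide_length
  nl <- nchar(config$linker_aa)
  status <- rep("removed", n)
  peptide <- rep(NA_character_, n)
  reason <- ext$reason

  ok <- is.na(reason)
  if (any(ok)) {
    aa <- translate_nt(ext$region[ok])
    pep <- substr(aa, 1L, L)
    linker_obs <- substr(aa, L + 1L, L + nl)
    bad_char <- grepl("[*X]", aa)
    bad_linker <- !bad_char & linker_obs != config$linker_aa
    idx <- which(ok)
    reason[idx[bad_char]] <- "contains_stop_or_X"
    reason[idx[bad_linker]] <- "missing_linker"
    clean <- idx[!bad_char & !bad_linker]
    status[clean] <- "cleaned"
    peptide[clean] <- pep[!bad_char & !bad_linker]
  }

  tibble(
    read_id = reads$read_id,
    status = status,
    peptide = peptide,
    reason = reason,
    removed_key = ifelse(status == "cleaned", NA_character_,
                         ifelse(is.na(ext$region), seqs, ext$region))
  )
}

#' @rdname classify_reads
#' @param read A single read sequence.
#' @export
classify_read <- function(read, config = extraction_config()) {
  classify_reads(read, config)[1, ]
}

removal_reasons <- c("no_anchor", "wrong_insert_length",
                     "contains_stop_or_X", "missing_linker")

#' Build a frequency-sorted peptide matrix
#'
#' The frequency matrix is the central table every downstream statistic
#' consumes: one row per distinct peptide with its absolute frequency
#' (count) and relative frequency in percent of cleaned reads, sorted by
#' descending count with lexicographic tie-break.
#'
#' @param peptide Character vector of distinct peptides.
#' @param count Absolute frequencies (positive integers).
#' @param total Total cleaned reads the relative frequencies are computed
#'   against; defaults to `sum(count)`. Supplying it explicitly supports
#'   partial tables quoted against a full dataset.
#' @param label Optional dataset label.
#' @return A `pd_freq_matrix` tibble with columns `peptide`,
#'   `absolute_frequency`, `relative_frequency` (percent), and attributes
#'   `total_cleaned` and `label`.
#' @export
#' @examples
#' freq_matrix(c("AAAA", "CCCC"), c(3, 1))
freq_matrix <- function(peptide, count, total = sum(count), label = NULL) {
  stopifnot(length(peptide) == length(count))
  if (anyDuplicated(peptide)) {
    abort("peptides must be distinct", class = "pepdepth_invalid_matrix")
  }
  count <- as.integer(count)
  if (length(count) > 0 && any(count < 1)) {
    abort("absolute frequencies must be >= 1",
          class = "pepdepth_invalid_matrix")
  }
  ord <- order(-count, peptide, method = "radix")
  out <- tibble(
    peptide = peptide[ord],
    absolute_frequency = count[ord],
    relative_frequency = if (total > 0) 100 * count[ord] / total else numeric(length(count))
  )
  structure(out,
            class = c("pd_freq_matrix", class(tibble())),
            total_cleaned = as.double(total),
            label = label)
}

#' @rdname freq_matrix
#' @param x A `pd_freq_matrix`.
#' @export
total_cleaned <- function(x) attr(x, "total_cleaned")

#' Table-1-style cleaning statistics
#'
#' One-row accounting of a dataset's cleaning outcome: unique and absolute
#' cleaned/removed read counts, their totals and removal percentages, and
#' per-reason removed counts. Constructable by hand (e.g. from a published
#' table) or produced by [process_dataset()].
#'
#' @param unique_cleaned,unique_removed,absolute_cleaned,absolute_removed
#'   Read counts.
#' @param reason_counts Named numeric of per-reason removed read counts
#'   (absolute), over `no_anchor`, `wrong_insert_length`,
#'   `contains_stop_or_X`, `missing_linker`.
#' @param dataset Dataset label.
#' @return A one-row tibble with derived totals and percentages.
#' @export
#' @examples
#' cleaning_stats(unique_cleaned = 5.21e5, absolute_cleaned = 6.23e5,
#'                unique_removed = 7.89e4, absolute_removed = 1.60e5)
cleaning_stats <- function(unique_cleaned, unique_removed = 0,
                           absolute_cleaned = unique_cleaned,
                           absolute_removed = 0,
                           reason_counts = NULL, dataset = NA_character_) {
  rc <- setNames(rep(0, length(removal_reasons)), removal_reasons)
  if (!is.null(reason_counts)) rc[names(reason_counts)] <- reason_counts
  tibble(
    dataset = dataset,
    unique_cleaned = unique_cleaned,
    unique_removed = unique_removed,
    total_unique = unique_cleaned + unique_removed,
    absolute_cleaned = absolute_cleaned,
    absolute_removed = absolute_removed,
    total_absolute = absolute_cleaned + absolute_removed,
    pct_unique_removed =
      if (unique_cleaned + unique_removed > 0)
        100 * unique_removed / (unique_cleaned + unique_removed) else 0,
    pct_absolute_removed =
      if (absolute_cleaned + absolute_removed > 0)
        100 * absolute_removed / (absolute_cleaned + absolute_removed) else 0,
    n_no_anchor = unname(rc["no_anchor"]),
    n_wrong_insert_length = unname(rc["wrong_insert_length"]),
    n_contains_stop_or_x = unname(rc["contains_stop_or_X"]),
    n_missing_linker = unname(rc["missing_linker"])
  )
}

#' Process a dataset into a frequency matrix and cleaning statistics
#'
#' Streams a FASTQ file through [classify_reads()] in chunks, accumulating
#' peptide counts for cleaned reads and raw-region counts for removed
#' reads, and returns the frequency-sorted matrix together with the
#' cleaning accounting. A removed read's "unique" identity is its raw
#' extracted nucleotide region when the anchors were found, else the full
#' read sequence.
#'
#' @param path FASTQ path.
#' @param config A [extraction_config()].
#' @param label Dataset label; defaults to the file name.
#' @param chunk_records Records per streamed chunk.
#' @return A `pd_dataset` list with elements `freq_matrix`
#'   (`pd_freq_matrix`) and `stats` (one-row tibble, see
#'   [cleaning_stats()]). `tidy()` returns the matrix, `glance()` the
#'   stats.
#' @export
process_dataset <- function(path, config = extraction_config(),
                            label = NULL,
                            chunk_records = 100000L) {
  label <- label %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  clean_chunks <- list()
  removed_chunks <- list()
  reason_tot <- setNames(rep(0, length(removal_reasons)), removal_reasons)
  n_total <- 0L

  fastq_chunk_apply(path, function(df) {
    out <- classify_reads(df, config)
    n_total <<- n_total + nrow(out)
    cleaned <- out$peptide[out$status == "cleaned"]
    if (length(cleaned) > 0) {
      clean_chunks[[length(clean_chunks) + 1L]] <<-
        dplyr::count(tibble(peptide = cleaned), peptide, name = "n")
    }
    rem <- out[out$status == "removed", c("removed_key", "reason")]
    if (nrow(rem) > 0) {
      removed_chunks[[length(removed_chunks) + 1L]] <<-
        dplyr::count(rem, removed_key, name = "n")
      rtab <- table(rem$reason)
      reason_tot[names(rtab)] <<- reason_tot[names(rtab)] + as.numeric(rtab)
    }
  }, chunk_records = chunk_records)

  clean_counts <- if (length(clean_chunks) > 0) {
    bind_rows(clean_chunks) |>
      group_by(peptide) |>
      summarise(n = sum(n), .groups = "drop")
  } else {
    tibble(peptide = character(0), n = integer(0))
  }
  removed_counts <- if (length(removed_chunks) > 0) {
    bind_rows(removed_chunks) |>
      group_by(removed_key) |>
      summarise(n = sum(n), .groups = "drop")
  } else {
    tibble(removed_key = character(0), n = integer(0))
  }

  fm <- freq_matrix(clean_counts$peptide, clean_counts$n, label = label)
  stats <- cleaning_stats(
    unique_cleaned = nrow(clean_counts),
    unique_removed = nrow(removed_counts),
    absolute_cleaned = sum(clean_counts$n),
    absolute_removed = sum(removed_counts$n),
    reason_counts = reason_tot,
    dataset = label
  )
  structure(list(freq_matrix = fm, stats = stats),
            class = "pd_dataset")
}

#' @rdname process_dataset
#' @param reads Tibble with `read_id` and `sequence`.
#' @export
process_reads <- function(reads, config = extraction_config(),
                          label = "dataset") {
  out <- classify_reads(reads, config)
  cleaned <- dplyr::count(
    tibble(peptide = out$peptide[out$status == "cleaned"]), peptide,
    name = "n"
  )
  rem <- out[out$status == "removed", ]
  reason_tot <- table(factor(rem$reason, levels = removal_reasons))
  fm <- freq_matrix(cleaned$peptide, cleaned$n, label = label)
  stats <- cleaning_stats(
    unique_cleaned = nrow(cleaned),
    unique_removed = length(unique(rem$removed_key)),
    absolute_cleaned = sum(cleaned$n),
    absolute_removed = nrow(rem),
    reason_counts = as.numeric(reason_tot) |> setNames(removal_reasons),
    dataset = label
  )
  structure(list(freq_matrix = fm, stats = stats), class = "pd_dataset")
}

#' Read/write a frequency matrix CSV
#'
#' CSV layout: `peptide,absolute_frequency,relative_frequency_percent`.
#'
#' @param x A `pd_freq_matrix`.
#' @param path CSV path.
#' @return `write_frequency_matrix()` returns `path` invisibly;
#'   `read_frequency_matrix()` returns a `pd_freq_matrix`.
#' @export
write_frequency_matrix <- function(x, path) {
  stopifnot(inherits(x, "pd_freq_matrix"))
  out <- tibble(
    peptide = x$peptide,
    absolute_frequency = x$absolute_frequency,
    relative_frequency_percent = x$relative_frequency
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_frequency_matrix
#' @param total,label Passed to [freq_matrix()]; by default the total is
#'   the column sum.
#' @export
read_frequency_matrix <- function(path, total = NULL, label = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("peptide", "absolute_frequency") %in% names(df)))
  freq_matrix(df$peptide, df$absolute_frequency,
              total = total %||% sum(df$absolute_frequency),
              label = label %||% sub("\\.csv$", "", basename(path)))
}

#' Subsample reads from a frequency matrix
#'
#' Draws a fixed number of cleaned reads without replacement from the
#' dataset the matrix summarizes (hypergeometric subsampling), emulating a
#' shallower sequencing run of the same pool.
#'
#' @param x A `pd_freq_matrix`.
#' @param n_reads Number of reads to keep; alternatively `fraction`.
#' @param fraction Fraction of reads to keep (ignored if `n_reads` given).
#' @param label Label for the subsampled matrix.
#' @return A `pd_freq_matrix`.
#' @export
subsample_matrix <- function(x, n_reads = NULL, fraction = NULL,
                             label = NULL) {
  stopifnot(inherits(x, "pd_freq_matrix"))
  total <- sum(x$absolute_frequency)
  if (is.null(n_reads)) {
    stopifnot(!is.null(fraction), fraction >= 0, fraction <= 1)
    n_reads <- round(fraction * total)
  }
  stopifnot(n_reads <= total)
  picks <- sample.int(total, n_reads)
  owner <- findInterval(picks - 1L, cumsum(c(0L, x$absolute_frequency)),
                        left.open = FALSE)
  cnt <- tabulate(owner, nbins = nrow(x))
  keep <- cnt > 0
  freq_matrix(x$peptide[keep], cnt[keep],
              label = label %||% attr(x, "label"))
}

#' @export
print.pd_dataset <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<pd_dataset '%s'>\n  cleaned: %s reads, %s unique; removed: %s reads (%.2f%%)\n",
    s$dataset, format(s$absolute_cleaned, big.mark = ","),
    format(s$unique_cleaned, big.mark = ","),
    format(s$absolute_removed, big.mark = ","), s$pct_absolute_removed
  ))
  print(head(x$freq_matrix, 5))
  invisible(x)
}
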