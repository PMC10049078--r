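cfg <- tiny_config()
ecfg <- manual_extraction_config(cfg)

test_that("FASTQ parsing preserves order and validates records", {
  f <- withr::local_tempfile(fileext = ".fastq")

  file.create(f)
  expect_equal(nrow(parse_fastq(f)), 0)

  write_fastq_lines(c("ACGT", "GGTTAA"), f, ids = c("a", "b"))
  rec <- parse_fastq(f)
  expect_equal(rec$read_id, c("a", "b"))
  expect_equal(rec$sequence, c("ACGT", "GGTTAA"))

  write_fastq_lines(c("ACGT", "ACQT"), f)
  expect_error(parse_fastq(f), "line 6", class = "pepdepth_malformed_fastq")

  writeLines(c("@x", "ACGT", "+"), f)
  expect_error(parse_fastq(f), class = "pepdepth_malformed_fastq")

  writeLines(c("no_at_sign", "ACGT", "+", "IIII"), f)
  expect_error(parse_fastq(f), "line 1", class = "pepdepth_malformed_fastq")

  expect_error(parse_fastq(file.path(tempdir(), "absent.fastq")),
               class = "pepdepth_missing_file")
})

test_that("chunked parsing matches whole-file parsing", {
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_lines(replicate(25, manual_read(random_peptides(1), cfg)), f)
  expect_equal(parse_fastq(f, chunk_records = 4), parse_fastq(f))
})

test_that("insert extraction works between first anchor occurrences", {
  pep <- "TLHFKPPNVTML"
  read <- manual_read(pep, cfg)
  ext <- extract_insert(read, ecfg)
  expect_equal(ext$region, paste0(fixed_encode(pep), fixed_encode("GGGS")))
  expect_true(is.na(ext$reason))

  # missing downstream anchor
  no_down <- paste0(cfg$upstream_anchor, fixed_encode(pep))
  expect_equal(extract_insert(no_down, ecfg)$reason, "no_anchor")
  expect_equal(extract_insert("ACGTACGT", ecfg)$reason, "no_anchor")

  # single-nucleotide deletion in the insert shifts the region length
  shifted <- paste0(cfg$upstream_anchor,
                    substr(fixed_encode(pep), 2, 36),
                    fixed_encode("GGGS"), cfg$downstream_anchor)
  expect_equal(extract_insert(shifted, ecfg)$reason, "wrong_insert_length")
})

test_that("reads are classified with one reason in fixed precedence order", {
  pep <- "ACDEFGHIKLMN"
  expect_equal(classify_read(manual_read(pep, cfg), ecfg)$peptide, pep)

  # stop codon inside the insert
  stop_insert <- paste0("TAG", substr(fixed_encode(pep), 4, 36))
  r <- classify_read(manual_read(pep, cfg, insert_nt = stop_insert), ecfg)
  expect_equal(r$status, "removed")
  expect_equal(r$reason, "contains_stop_or_X")

  # ambiguous base inside the insert
  amb <- paste0("AAN", substr(fixed_encode(pep), 4, 36))
  expect_equal(classify_read(manual_read(pep, cfg, insert_nt = amb),
                             ecfg)$reason, "contains_stop_or_X")

  # linker mutated to another sense peptide
  r <- classify_read(manual_read(pep, cfg, linker_nt = fixed_encode("GAGS")),
                     ecfg)
  expect_equal(r$reason, "missing_linker")

  # stop in a read whose anchors are broken reports no_anchor first
  broken <- paste0("TTTT", substr(cfg$upstream_anchor, 5, 20), "TAG")
  expect_equal(classify_read(broken, ecfg)$reason, "no_anchor")

  # stop beats missing linker: both defects present
  r <- classify_read(
    manual_read(pep, cfg, insert_nt = stop_insert,
                linker_nt = fixed_encode("GAGS")), ecfg)
  expect_equal(r$reason, "contains_stop_or_X")
})

test_that("reverse-complement rescue is off by default and config-switchable", {
  pep <- "MWYVACDEFGHI"
  fwd <- manual_read(pep, cfg)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  expect_equal(classify_read(rc, ecfg)$reason, "no_anchor")
  ecfg_rc <- extraction_config(cfg$upstream_anchor, cfg$downstream_anchor,
                               reverse_complement = TRUE)
  expect_equal(classify_read(rc, ecfg_rc)$peptide, pep)
})

test_that("processing accounts for every read exactly once", {
  peps <- c("AAAAAAAAAAAC", "CCCCCCCCCCCD", "DDDDDDDDDDDE")
  good <- manual_read(peps[c(1, 1, 1, 2, 2, 3, 3)], cfg)
  bad <- c(
    manual_read(peps[1], cfg,
                insert_nt = paste0("TAA", substr(fixed_encode(peps[1]), 4, 36))),
    manual_read(peps[2], cfg, linker_nt = fixed_encode("SSSS")),
    "ACGTACGTACGT"
  )
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_lines(c(good, bad), f)
  ds <- suppressMessages(process_dataset(f, ecfg, label = "fixture"))

  s <- ds$stats
  expect_equal(s$absolute_cleaned, 7)
  expect_equal(s$absolute_removed, 3)
  expect_equal(s$total_absolute, 10)
  expect_equal(s$unique_cleaned, 3)
  expect_equal(s$unique_removed, 3)
  expect_equal(s$n_contains_stop_or_x, 1)
  expect_equal(s$n_missing_linker, 1)
  expect_equal(s$n_no_anchor, 1)

  fm <- ds$freq_matrix
  expect_equal(fm$peptide, peps)          # sorted desc, lexicographic ties
  expect_equal(fm$absolute_frequency, c(3, 2, 2))
  expect_equal(sum(fm$absolute_frequency), s$absolute_cleaned)
  expect_equal(fm$relative_frequency, 100 * c(3, 2, 2) / 7)
  expect_equal(sum(fm$relative_frequency), 100)

  # re-processing the same file is identical
  ds2 <- suppressMessages(process_dataset(f, ecfg, label = "fixture"))
  expect_identical(ds$freq_matrix, ds2$freq_matrix)
  expect_identical(ds$stats, ds2$stats)
})

test_that("empty input yields empty matrix and all-zero stats", {
  f <- withr::local_tempfile(fileext = ".fastq")
  file.create(f)
  ds <- suppressMessages(process_dataset(f, ecfg))
  expect_equal(nrow(ds$freq_matrix), 0)
  expect_equal(ds$stats$total_absolute, 0)
  expect_equal(ds$stats$total_unique, 0)
})

test_that("per-reason removals match generator class totals on synthetic data", {
  scfg <- synthetic_library_config(
    true_diversity = 100, seed = 303,
    defect_rates = list(stop_codon_insert = 0.1, ambiguous_base = 0.05,
                        frameshift_indel = 0.08, missing_linker = 0.06,
                        substitution_per_base = 0)
  )
  pool <- sample_true_library(scfg)
  sim <- simulate_reads(pool, 4000, scfg)
  ds <- process_reads(sim$reads, manual_extraction_config(scfg))

  totals <- setNames(sim$class_totals$n, sim$class_totals$class)
  zero <- function(x) if (is.na(x)) 0 else x
  expect_equal(ds$stats$n_contains_stop_or_x,
               sum(totals[c("stop_codon_insert", "ambiguous_base")]))
  expect_equal(ds$stats$n_wrong_insert_length,
               zero(totals["frameshift_indel"]) |> unname())
  expect_equal(ds$stats$n_missing_linker,
               zero(totals["missing_linker"]) |> unname())
  expect_equal(ds$stats$absolute_cleaned, zero(totals["none"]) |> unname())

  # conservation
  expect_equal(ds$stats$absolute_cleaned + ds$stats$absolute_removed, 4000)
  # cleaned multiset equals the generator log for non-defective reads
  truth_clean <- sort(sim$truth$peptide[sim$truth$class == "none"])
  got <- rep(ds$freq_matrix$peptide, ds$freq_matrix$absolute_frequency)
  expect_equal(sort(got), truth_clean)
})

test_that("subsampling a matrix conserves totals and is seed-stable", {
  set.seed(11)
  fm <- freq_matrix(random_peptides(200), sample(1:20, 200, replace = TRUE))
  set.seed(5)
  sub <- subsample_matrix(fm, fraction = 0.3)
  expect_equal(sum(sub$absolute_frequency),
               round(0.3 * sum(fm$absolute_frequency)))
  expect_true(all(sub$peptide %in% fm$peptide))
  set.seed(5)
  expect_identical(sub, subsample_matrix(fm, fraction = 0.3))
  expect_error(subsample_matrix(fm, n_reads = sum(fm$absolute_frequency) + 1))
})
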