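#' Configuration for a synthetic NNK phage display library
#'
#' Describes the simulated library and read structure: a pool of
#' `true_diversity` distinct displayed peptides, reads laid out as
#' `upstream_anchor | NNK insert | linker codons | downstream_anchor`, and
#' per-read defect classes that make reads fail the cleaning filters the
#' way defective library clones and sequencing artifacts do.
#'
#' Defect classes and their downstream removal reasons:
#' \describe{
#'   \item{stop_codon_insert}{one insert codon replaced by TAA/TAG/TGA;
#'     removed as `contains_stop_or_X`.}
#'   \item{ambiguous_base}{one insert base replaced by `N`; removed as
#'     `contains_stop_or_X` (translates to `X`).}
#'   \item{frameshift_indel}{one nucleotide deleted or inserted inside the
#'     insert; removed as `wrong_insert_length`.}
#'   \item{missing_linker}{linker codons resampled from sense codons so the
#'     translated linker differs from `linker_aa`; removed as
#'     `missing_linker`.}
#'   \item{substitution_per_base}{independent per-base substitutions over
#'     the whole read (default 0); substitutions may hit anchors and cause
#'     `no_anchor` removals, or silently change the observed peptide.}
#' }
#' `stop_codon_insert`, `frameshift_indel` and `missing_linker` are drawn
#' mutually exclusively per read; `ambiguous_base` is applied only to reads
#' left intact by that draw, so generator class counts map one-to-one onto
#' removal reasons when `substitution_per_base = 0`.
#'
#' @param true_diversity Number of distinct peptides in the true pool.
#' @param abundance_model List with `family` (`"lognormal"` or `"uniform"`)
#'   and, for log-normal, `sigma` (sd of log weights; 0 gives equal
#'   weights). Default log-normal with `sigma = 1`, reflecting the skewed
#'   clone abundances of amplified libraries.
#' @param peptide_length Displayed peptide length in residues.
#' @param linker_aa Amino-acid linker displayed after the peptide.
#' @param upstream_anchor,downstream_anchor Fixed vector flanks (A/C/G/T)
#'   bounding the peptide+linker coding region. Defaults are arbitrary
#'   20-nt synthetic constants; supply the real vector flanks when
#'   simulating a specific construct.
#' @param defect_rates Named list of per-read probabilities, see Details.
#' @param seed Optional RNG seed applied by [sample_true_library()] and
#'   [simulate_reads()].
#' @return A `pd_library_config` list.
#' @export
#' @examples
#' cfg <- synthetic_library_config(true_diversity = 50, seed = 1)
#' cfg$defect_rates$stop_codon_insert
synthetic_library_config <- function(true_diversity = 10000,
                                     abundance_model = list(family = "lognormal", sigma = 1),
                                     peptide_length = 12,
                                     linker_aa = "GGGS",
                                     upstream_anchor = "ACGTTCGAGGTCAGCTCATA",
                                     downstream_anchor = "TGACCTGTAGCCTTAGGACT",
                                     defect_rates = list(),
                                     seed = NULL) {
  rates <- list(
    stop_codon_insert = 0.10,
    ambiguous_base = 0.02,
    frameshift_indel = 0.06,
    missing_linker = 0.04,
    substitution_per_base = 0
  )
  unknown <- setdiff(names(defect_rates), names(rates))
  if (length(unknown) > 0) {
    abort(paste0("unknown defect rate(s): ", paste(unknown, collapse = ", ")),
          class = "pepdepth_invalid_config")
  }
  rates[names(defect_rates)] <- defect_rates
  cfg <- structure(list(
    true_diversity = as.integer(true_diversity),
    abundance_model = abundance_model,
    peptide_length = as.integer(peptide_length),
    insert_nt_length = 3L * as.integer(peptide_length),
    linker_aa = toupper(linker_aa),
    upstream_anchor = toupper(upstream_anchor),
    downstream_anchor = toupper(downstream_anchor),
    defect_rates = rates,
    seed = seed
  ), class = "pd_library_config")
  validate_library_config(cfg)
}

validate_library_config <- function(cfg) {
  r <- cfg$defect_rates
  probs <- unlist(r)
  if (is.na(cfg$true_diversity) || cfg$true_diversity < 1) {
    abort("true_diversity must be >= 1", class = "pepdepth_invalid_config")
  }
  if (any(probs < 0 | probs > 1)) {
    abort("defect rates must be probabilities in [0, 1]",
          class = "pepdepth_invalid_config")
  }
  if (r$stop_codon_insert + r$frameshift_indel + r$missing_linker > 1) {
    abort("stop + frameshift + missing_linker rates must sum to <= 1",
          class = "pepdepth_invalid_config")
  }
  if (cfg$peptide_length < 1) {
    abort("peptide_length must be >= 1", class = "pepdepth_invalid_config")
  }
  if (cfg$insert_nt_length != 3L * cfg$peptide_length) {
    abort("insert length must be 3 x peptide_length",
          class = "pepdepth_invalid_config")
  }
  if (nchar(cfg$linker_aa) < 1) {
    abort("linker_aa must be nonempty", class = "pepdepth_invalid_config")
  }
  for (a in c(cfg$upstream_anchor, cfg$downstream_anchor)) {
    if (nchar(a) < 1 || grepl("[^ACGT]", a)) {
      abort("anchors must be nonempty A/C/G/T sequences",
            class = "pepdepth_invalid_config")
    }
  }
  fam <- cfg$abundance_model$family
  if (!fam %in% c("lognormal", "uniform")) {
    abort("abundance_model$family must be 'lognormal' or 'uniform'",
          class = "pepdepth_invalid_config")
  }
  cfg
}

#' Sample the true peptide pool of a synthetic library
#'
#' Draws `true_diversity` distinct peptides codon-wise uniformly over the
#' 31 coding NNK codons (so residue probabilities follow NNK codon
#' multiplicity, as in a real NNK-synthesized library; no peptide contains
#' a stop) and assigns normalized abundance weights from the configured
#' abundance model.
#'
#' @param config A [synthetic_library_config()].
#' @return A `pd_pool` tibble with columns `peptide` and `weight`
#'   (weights sum to 1), carrying the config as attribute `config`.
#' @export
#' @examples
#' pool <- sample_true_library(synthetic_library_config(5, seed = 42))
#' sum(pool$weight)
sample_true_library <- function(config) {
  stopifnot(inherits(config, "pd_library_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$peptide_length
  space <- 20 ^ L
  if (config$true_diversity > space) {
    abort(sprintf(
      "true_diversity (%d) exceeds the %d-mer peptide space (20^%d)",
      config$true_diversity, L, L
    ), class = "pepdepth_invalid_config")
  }
  nt <- nnk_tables()
  peptides <- character(0)
  need <- config$true_diversity
  while (need > 0) {
    batch <- max(need, 32L)
    res <- sample(nt$coding_aa, batch * L, replace = TRUE)
    new <- do.call(paste0, as.data.frame(
      matrix(res, nrow = batch, ncol = L), stringsAsFactors = FALSE
    ))
    peptides <- unique(c(peptides, new))
    need <- config$true_diversity - length(peptides)
  }
  peptides <- peptides[seq_len(config$true_diversity)]

  n <- length(peptides)
  am <- config$abundance_model
  w <- switch(am$family,
    lognormal = rlnorm(n, meanlog = 0, sdlog = am$sigma %||% 1),
    uniform = runif(n)
  )
  if (n == 1L) w <- 1
  w <- w / sum(w)
  structure(
    tibble(peptide = peptides, weight = w),
    class = c("pd_pool", class(tibble())),
    config = config
  )
}

#' Simulate sequencing reads from a synthetic library pool
#'
#' Draws `n_reads` reads from the pool by abundance weight, NNK-encodes
#' peptide and linker, assembles
#' `upstream_anchor | insert | linker | downstream_anchor` with constant
#' placeholder qualities (the cleaning procedure uses no quality
#' filtering), and applies the configured defect classes. The returned
#' truth log records, per read, the defect class and the sampled peptide.
#'
#' @param pool A `pd_pool` from [sample_true_library()].
#' @param n_reads Number of reads to simulate.
#' @param config The library config; defaults to the pool's own.
#' @return A `pd_sim` list with `reads` (tibble: `read_id`, `sequence`,
#'   `quality`), `truth` (tibble: `read_id`, `class`, `peptide`) and
#'   `class_totals` (tibble: `class`, `n`).
#' @export
simulate_reads <- function(pool, n_reads, config = attr(pool, "config")) {
  stopifnot(inherits(pool, "pd_pool"), n_reads >= 0)
  config <- validate_library_config(config)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n <- as.integer(n_reads)
  if (n == 0L) {
    empty <- tibble(read_id = character(0), sequence = character(0),
                    quality = character(0))
    return(structure(list(
      reads = empty,
      truth = tibble(read_id = character(0), class = character(0),
                     peptide = character(0)),
      class_totals = tibble(class = character(0), n = integer(0))
    ), class = "pd_sim"))
  }

  L <- config$peptide_length
  linker <- strsplit(config$linker_aa, "", fixed = TRUE)[[1]]
  r <- config$defect_rates

  idx <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$weight)
  peptides <- pool$peptide[idx]

  # mutually exclusive structural defect draw, then ambiguous-base overlay
  # on reads left intact so class counts match removal reasons exactly
  u <- runif(n)
  p1 <- r$stop_codon_insert
  p2 <- p1 + r$frameshift_indel
  p3 <- p2 + r$missing_linker
  class <- rep("none", n)
  class[u < p1] <- "stop_codon_insert"
  class[u >= p1 & u < p2] <- "frameshift_indel"
  class[u >= p2 & u < p3] <- "missing_linker"
  amb <- class == "none" & runif(n) < r$ambiguous_base
  class[amb] <- "ambiguous_base"

  res_mat <- matrix(unlist(strsplit(peptides, "", fixed = TRUE)),
                    nrow = n, ncol = L, byrow = TRUE)
  codon_mat <- encode_residue_matrix(res_mat)

  is_stop <- class == "stop_codon_insert"
  if (any(is_stop)) {
    k <- sum(is_stop)
    pos <- sample.int(L, k, replace = TRUE)
    codon_mat[cbind(which(is_stop), pos)] <-
      sample(c("TAA", "TAG", "TGA"), k, replace = TRUE)
  }

  insert_nt <- do.call(paste0, as.data.frame(codon_mat,
                                             stringsAsFactors = FALSE))

  if (any(amb)) {
    k <- sum(amb)
    pos <- sample.int(3L * L, k, replace = TRUE)
    tgt <- which(amb)
    insert_nt[tgt] <- paste0(
      substr(insert_nt[tgt], 1L, pos - 1L), "N",
      substr(insert_nt[tgt], pos + 1L, 3L * L)
    )
  }

  is_fs <- class == "frameshift_indel"
  if (any(is_fs)) {
    tgt <- which(is_fs)
    k <- length(tgt)
    del <- runif(k) < 0.5
    pos <- sample.int(3L * L, k, replace = TRUE)
    s <- insert_nt[tgt]
    ins_base <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    insert_nt[tgt] <- ifelse(
      del,
      paste0(substr(s, 1L, pos - 1L), substr(s, pos + 1L, 3L * L)),
      paste0(substr(s, 1L, pos), ins_base, substr(s, pos + 1L, 3L * L))
    )
  }

  linker_mat <- encode_residue_matrix(
    matrix(linker, nrow = n, ncol = length(linker), byrow = TRUE)
  )
  linker_nt <- do.call(paste0, as.data.frame(linker_mat,
                                             stringsAsFactors = FALSE))
  is_ml <- class == "missing_linker"
  if (any(is_ml)) {
    linker_nt[is_ml] <- broken_linkers(sum(is_ml), config$linker_aa)
  }

  seqs <- paste0(config$upstream_anchor, insert_nt, linker_nt,
                 config$downstream_anchor)

  s_rate <- r$substitution_per_base
  if (s_rate > 0) {
    seqs <- substitute_bases(seqs, s_rate)
  }

  ids <- sprintf("read_%07d", seq_len(n))
  reads <- tibble(read_id = ids, sequence = seqs,
                  quality = strrep("I", nchar(seqs)))
  truth <- tibble(read_id = ids, class = class, peptide = peptides)
  structure(list(
    reads = reads,
    truth = truth,
    class_totals = dplyr::count(truth, class, name = "n")
  ), class = "pd_sim")
}

# Random sense-codon linkers guaranteed to translate to something other
# than linker_aa and to contain no stop or ambiguity, so the read fails
# only the linker filter.
broken_linkers <- function(k, linker_aa) {
  nl <- nchar(linker_aa)
  cods <- sense_codons()
  out <- character(k)
  todo <- seq_len(k)
  while (length(todo) > 0) {
    cand <- do.call(paste0, as.data.frame(
      matrix(sample(cods, length(todo) * nl, replace = TRUE),
             nrow = length(todo), ncol = nl),
      stringsAsFactors = FALSE
    ))
    ok <- translate_nt(cand) != linker_aa
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  out
}

# Independent per-base substitutions at rate `rate` over each sequence.
substitute_bases <- function(seqs, rate) {
  lens <- nchar(seqs)
  nsub <- rbinom(length(seqs), lens, rate)
  hit <- which(nsub > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(lens[i], nsub[i])
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Write simulated reads as a 4-line FASTQ file
#'
#' @param sim A `pd_sim` from [simulate_reads()], or a tibble with columns
#'   `read_id`, `sequence` and optionally `quality`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  reads <- if (inherits(sim, "pd_sim")) sim$reads else sim
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  qual <- reads$quality %||% strrep("I", nchar(reads$sequence))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual),
               con)
  }
  invisible(path)
}

#' Simulate a library and write FASTQ plus ground-truth tables
#'
#' Convenience wrapper: samples a pool, simulates reads, and writes the
#' FASTQ together with a truth log CSV (`read_id`, `class`, `peptide`) and
#' a pool CSV (`peptide`, `weight`).
#'
#' @inheritParams simulate_reads
#' @param config A [synthetic_library_config()].
#' @param out_fastq FASTQ output path.
#' @param out_truth,out_pool Optional CSV output paths.
#' @return The `pd_sim` object, invisibly, with the pool attached as
#'   attribute `pool`.
#' @export
simulate_dataset <- function(config, n_reads, out_fastq,
                             out_truth = NULL, out_pool = NULL) {
  pool <- sample_true_library(config)
  sim <- simulate_reads(pool, n_reads, config)
  write_fastq(sim, out_fastq)
  if (!is.null(out_truth)) readr::write_csv(sim$truth, out_truth)
  if (!is.null(out_pool)) {
    readr::write_csv(as_tibble(pool), out_pool)
  }
  attr(sim, "pool") <- pool
  invisible(sim)
}
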