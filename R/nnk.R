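#' NNK degenerate-codon tables
#'
#' NNK codons have the pattern N-N-K (N = A/C/G/T, K = G/T): 32 codons
#' covering all 20 standard amino acids with a single stop (TAG). This is the
#' degenerate scheme used to synthesize random-peptide phage display
#' libraries such as the commercial 12-mer libraries this package targets.
#'
#' @return `nnk_codon_table()` returns a tibble with one row per NNK codon
#'   (columns `codon`, `aa`); `nnk_residue_weights()` returns the expected
#'   per-position residue probabilities of an NNK library (codon multiplicity
#'   over the 31 coding NNK codons), a named numeric vector over the 20
#'   residues.
#' @export
#' @examples
#' nnk_codon_table()
#' nnk_residue_weights()[c("L", "M")] # 3 codons for Leu vs 1 for Met
nnk_codon_table <- function() {
  nnk_tables()$table
}

#' @rdname nnk_codon_table
#' @export
nnk_residue_weights <- function() {
  nnk_tables()$weights
}

# Build NNK lookup tables once from the standard genetic code.
nnk_tables <- function() {
  if (is.null(the$nnk)) {
    bases <- c("A", "C", "G", "T")
    codons <- as.vector(outer(
      as.vector(outer(bases, bases, paste0)), c("G", "T"), paste0
    ))
    aa <- unname(GENETIC_CODE[codons])
    tab <- tibble(codon = codons, aa = aa)
    coding <- tab[tab$aa != "*", ]
    by_aa <- split(coding$codon, coding$aa)
    w <- vapply(by_aa, length, integer(1)) / nrow(coding)
    the$nnk <- list(
      table = tab,
      by_aa = by_aa,
      coding_codons = coding$codon,
      coding_aa = coding$aa,
      weights = w[order(names(w))]
    )
  }
  the$nnk
}

sense_codons <- function() {
  if (is.null(the$sense)) {
    the$sense <- names(GENETIC_CODE)[GENETIC_CODE != "*"]
  }
  the$sense
}

#' Encode a peptide as an NNK-compatible nucleotide insert
#'
#' Reverse-translates an amino-acid sequence using codons drawn uniformly at
#' random among the NNK codons encoding each residue, emulating
#' degenerate-oligo synthesis. Uses the session RNG; call [set.seed()] for
#' reproducibility.
#'
#' @param peptide Character scalar of standard one-letter residue codes.
#' @return Nucleotide string of length `3 * nchar(peptide)`; every codon
#'   matches N-N-\[G/T\] and translates back to the input.
#' @export
#' @examples
#' encode_peptide_nnk("MW") # "ATGTGG": Met and Trp have unique NNK codons
encode_peptide_nnk <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L, !is.na(peptide))
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  by_aa <- nnk_tables()$by_aa
  bad <- setdiff(res, names(by_aa))
  if (length(bad) > 0) {
    abort(paste0(
      "peptide contains residues with no NNK codon: ",
      paste(unique(bad), collapse = ", ")
    ), class = "pepdepth_invalid_residue")
  }
  paste(vapply(
    res,
    function(r) {
      cs <- by_aa[[r]]
      cs[sample.int(length(cs), 1L)]
    },
    character(1)
  ), collapse = "")
}

# Vectorized NNK encoding of a residue matrix (reads x positions).
# Returns a codon matrix of the same shape. One sample() call per
# (position, residue) pair, so cost is ~20 * ncol draws regardless of n.
encode_residue_matrix <- function(res_mat) {
  by_aa <- nnk_tables()$by_aa
  codon_mat <- matrix("", nrow = nrow(res_mat), ncol = ncol(res_mat))
  for (j in seq_len(ncol(res_mat))) {
    col <- res_mat[, j]
    for (r in unique(col)) {
      rows <- which(col == r)
      cs <- by_aa[[r]]
      if (is.null(cs)) {
        abort(paste0("no NNK codon for residue '", r, "'"),
              class = "pepdepth_invalid_residue")
      }
      codon_mat[rows, j] <- cs[sample.int(length(cs), length(rows),
                                          replace = TRUE)]
    }
  }
  codon_mat
}

#' Translate nucleotide sequences
#'
#' Standard-code translation used by the read-cleaning pipeline: stop codons
#' (TAA, TAG, TGA) become `*` and any codon containing a character other
#' than A/C/G/T (e.g. an ambiguous `N` base call) becomes `X`. Downstream
#' filtering removes reads whose translated insert or linker contains `*`
#' or `X`.
#'
#' @param nt Character vector of nucleotide sequences, each with length
#'   divisible by 3.
#' @return Character vector of amino-acid sequences.
#' @export
#' @examples
#' translate_nt(c("ATGTGG", "TAA", "ATN"))
translate_nt <- function(nt) {
  stopifnot(is.character(nt))
  if (length(nt) == 0) return(character(0))
  lens <- nchar(nt)
  if (anyNA(nt) || any(lens %% 3 != 0)) {
    abort("sequence length not divisible by 3",
          class = "pepdepth_bad_length")
  }
  out <- character(length(nt))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (L == 0) {
      out[idx] <- ""
      next
    }
    x <- nt[idx]
    starts <- seq(1L, L, by = 3L)
    aa_mat <- matrix("", nrow = length(idx), ncol = length(starts))
    for (k in seq_along(starts)) {
      codon <- substr(x, starts[k], starts[k] + 2L)
      aa <- unname(GENETIC_CODE[codon])
      aa[is.na(aa)] <- "X"
      aa_mat[, k] <- aa
    }
    out[idx] <- do.call(paste0, as.data.frame(aa_mat,
                                              stringsAsFactors = FALSE))
  }
  out
}
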