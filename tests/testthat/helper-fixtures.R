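# Shared fixtures: a small synthetic library config with all defects off,
# and hand-built reads assembled from an independently chosen codon table
# (first NNK codon in alphabetical order per residue) so extraction tests
# do not depend on the package's own encoder.

zero_defects <- list(stop_codon_insert = 0, ambiguous_base = 0,
                     frameshift_indel = 0, missing_linker = 0,
                     substitution_per_base = 0)

tiny_config <- function(true_diversity = 20, seed = 101, ...) {
  synthetic_library_config(true_diversity = true_diversity, seed = seed, ...)
}

# fixed reverse-translation independent of encode_peptide_nnk()
fixed_codon <- local({
  map <- c(A = "GCG", C = "TGT", D = "GAT", E = "GAG", F = "TTT",
           G = "GGG", H = "CAT", I = "ATT", K = "AAG", L = "CTG",
           M = "ATG", N = "AAT", P = "CCG", Q = "CAG", R = "AGG",
           S = "AGT", T = "ACG", V = "GTG", W = "TGG", Y = "TAT")
  function(res) unname(map[res])
})

fixed_encode <- function(peptide) {
  vapply(peptide, function(p) {
    paste(fixed_codon(strsplit(p, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# read = upstream | insert nt | linker nt | downstream
manual_read <- function(peptide, cfg = tiny_config(),
                        insert_nt = fixed_encode(peptide),
                        linker_nt = fixed_encode(cfg$linker_aa)) {
  paste0(cfg$upstream_anchor, insert_nt, linker_nt, cfg$downstream_anchor)
}

manual_extraction_config <- function(cfg = tiny_config()) {
  extraction_config(cfg$upstream_anchor, cfg$downstream_anchor,
                    cfg$peptide_length, cfg$linker_aa)
}

write_fastq_lines <- function(seqs, path, ids = sprintf("r%d", seq_along(seqs))) {
  writeLines(
    as.vector(rbind(paste0("@", ids), seqs, "+", strrep("I", nchar(seqs)))),
    path
  )
  path
}

random_peptides <- function(n, len = 12) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, character(1))
}
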