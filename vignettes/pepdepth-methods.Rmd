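---
title: "Methods: depth-aware characterization of phage display peptide libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-aware characterization of phage display peptide libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Random-peptide phage display libraries (the package's defaults target an
M13-type 12-mer library displaying the peptide plus a GGGS linker on pIII)
are characterized by amplicon sequencing of the insert. The quantities
practitioners read off such data — observed diversity (unique peptides),
singleton percentage, percent distinct sequences, frequency spectra — all
depend jointly on the library *and* on the number of reads sequenced.
`pepdepth` implements the analysis chain from raw FASTQ to depth-aware
comparison statistics, plus a ground-truthed simulator, so the depth
dependence itself can be studied and the pipeline tested end to end
without any raw sequencing data.

## Read cleaning

A read is cleaned in four ordered steps; the first failure is recorded as
the single removal reason:

1. **Anchor location** (`no_anchor`). The region strictly between the
   first exact occurrence of the upstream anchor and the first subsequent
   exact occurrence of the downstream anchor is extracted. Matching is
   exact (no mismatch tolerance) and forward-strand only by default;
   both choices keep the accounting auditable and match single-end
   amplicons with fixed primer orientation. A reverse-complement rescue
   scan is available via `extraction_config(reverse_complement = TRUE)`.
2. **Length** (`wrong_insert_length`). The region must be exactly
   `3 * (peptide_length + nchar(linker_aa))` nucleotides; one-base indels
   (frameshifts) fail here.
3. **Translation** (`contains_stop_or_X`). Standard genetic code; stop
   codons give `*`, any codon containing a non-ACGT character gives `X`.
   TAG is translated as a stop, not as amber-suppressed Gln, because the
   cleaning rule removes all `*`-containing reads. Any `*` or `X` in
   peptide+linker removes the read.
4. **Linker** (`missing_linker`). The translated region must end in the
   configured amino-acid linker (default `GGGS`) immediately after the
   peptide.

No quality filtering is applied anywhere: the cleaning rule is purely
sequence-based, and the simulator writes constant placeholder qualities
accordingly.

Removed reads enter the "unique removed" tally keyed by their raw
extracted nucleotide region when the anchors were found, else by the full
read sequence. Uniqueness of unparseable reads has no canonical
definition; this keying is the package's choice and is applied
consistently.

`process_dataset()` streams the FASTQ in chunks (default 100,000 records),
so memory scales with the chunk and the accumulating count tables, not
the file; malformed records abort with the offending line number.

## The frequency matrix and single-dataset statistics

The frequency matrix holds one row per distinct peptide with absolute
frequency $n_i$ and relative frequency $100\,n_i/N$ (percent of the $N$
cleaned reads), sorted by descending count with lexicographic
tie-breaking so output is reproducible.

* **Percent distinct** $= 100\,U/N$ with $U$ the unique cleaned count.
* **Bin composition**: peptides are grouped by absolute frequency into
  bins $1, 2, \dots, 10, >10$; per bin the unique count (stacked-bar
  width) and the percentage of reads (height) are reported. Heights are
  abundance-weighted by default, because the published stacked bars show
  the *sum of abundances* per bin; a unique-sequence-weighted variant is
  available for cross-checks (`weighting = "unique"`). The singleton
  percentage is the bin-1 height.
* **Frequency spectrum**: the map $f \mapsto$ number of peptides with
  absolute frequency $f$, with the conservation identities
  $\sum_f f\,c(f) = N$ and $\sum_f c(f) = U$; the number of keys is the
  distinct-frequency-value (DFV) count. Display binning of the x axis
  (e.g. collapsing frequencies above 1000) is left to plotting; the
  module reports the raw spectrum.
* **Yates-corrected chi-square** for 2×2 contrasts (singleton vs
  non-singleton reads across two datasets):
  $\chi^2 = N(\max(0, |ad-bc| - N/2))^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$,
  1 df. The closed form is implemented directly and cross-checked in the
  test suite against `stats::chisq.test(correct = TRUE)` on random
  tables.

Full precision is kept everywhere; rounding (1 d.p. folds, 3 s.f.
scientific relative frequencies, `p < 0.0001` formatting) happens only in
the human-readable report layer of `run_pipeline()`.

## Confidence intervals and distinguishing capacity

For an absolute frequency $n$ the package uses the Poisson–Wald interval

$$ [\,\mathrm{round}(n - z\sqrt{n}),\ \mathrm{round}(n + z\sqrt{n})\,] $$

with round-half-to-even to integers, the lower bound clipped at 0, and a
single quantile $z$ shared by all intervals of an analysis. The
Bonferroni correction for $m$ simultaneous intervals at family-wise level
$\alpha$ gives $z = \Phi^{-1}(1 - \alpha/2m)$ (`bonferroni_z()`).

The default $z = 3.3246$ was calibrated once against the 19 published
example intervals this functional form reproduces: those intervals pin
$z$ to the band $[3.3204, 3.3288]$ (a nominal $z = 3.32$ fails one row,
count 90, whose lower bound 58.504 would round to 59), and the default is
the band midpoint. Bonferroni divisors $m = 56$ and $m = 57$ at
$\alpha = 0.05$ both fall inside the band; the published analysis did not
state its divisor, so the calibrated quantile is exposed as a plain
config parameter (`z`, or `m_tests` to derive it) rather than asserted as
the original computation.

`distinguishing_analysis()` takes the peptides with absolute frequency
exactly $f$ in dataset A (for each requested $f$) that are also present
in dataset B and computes both datasets' intervals. A group is
*significant* — B resolves abundances that A sees as tied — when at least
one pair of member intervals in B is disjoint. Disjointness is strict:
intervals sharing a single integer are not disjoint. Pairwise
disjointness is the minimal reading consistent with reporting only
confidence intervals; no additional test statistic is imposed.

## Composition comparisons

* **Overlap**: pairwise identical-peptide counts over unique peptide
  strings (2–4 datasets); the self-overlap equals the unique cleaned
  count. The computed artifact is the intersection-size table; Venn
  rendering is deliberately left to the user.
* **Positional frequencies**: peptides are one-hot encoded; cell
  $(r, j)$ is the percentage of sequences (default) or reads
  (`weighting = "abundance"`) with residue $r$ at position $j$, so each
  position column sums to 100. Whether published heatmaps of this kind
  are read- or sequence-weighted is generally not stated; unique
  weighting is the default because it is insensitive to a handful of
  dominant clones, and both modes are provided.
  `positional_difference(A, B)` is the signed elementwise difference in
  percentage points with B as reference; its columns sum to 0.

## The synthetic library generator

The generator defines the study conditions for every property test. It
emulates:

* a **true pool** of `true_diversity` distinct 12-mers drawn codon-wise
  uniformly over the 31 coding NNK codons (N-N-G/T), so residue
  probabilities follow NNK codon multiplicity (Leu, Arg, Ser 3/31 each;
  Met, Trp 1/31) exactly as in degenerate-oligo synthesis, and no sampled
  peptide contains a stop;
* **abundance weights** from a log-normal model, $\sigma = 1$ by default.
  Amplified libraries have strongly skewed clone abundances; the true
  distribution of any given naive library is unknown, so the family and
  $\sigma$ are plain config (`abundance_model`), with a uniform
  alternative, and $\sigma = 0$ degenerates to equal weights;
* **reads** assembled as `upstream_anchor | NNK insert | linker codons |
  downstream_anchor` with constant qualities. Anchors default to
  arbitrary 20-nt synthetic constants: real vector flank sequences differ
  by construct and should be supplied by the user rather than hard-coded;
* **defect classes** at per-read rates: a stop codon substituted into the
  insert, an ambiguous `N` base, a one-base frameshift indel, linker
  codons resampled to a different sense peptide, and optional per-base
  substitutions. Stop/frameshift/linker defects are a mutually exclusive
  per-read draw and the ambiguous-base defect is applied only to reads
  left intact, so generator class totals map one-to-one onto removal
  reasons — the property the extraction tests assert. Per-base
  substitutions (default 0) break that exactness by design: they can
  destroy anchors or silently mutate the observed peptide.

Default defect rates — stop 0.10, frameshift 0.06, missing linker 0.04,
ambiguous 0.02 — give an expected removed fraction of
$0.20 + 0.80 \times 0.02 \approx 21.6\%$, in the ~20–22% range reported
for naive-library sequencing, and were fixed once as the simulation's
study conditions.

What the simulator does **not** model: PCR amplification bias, chimeric
reads, realistic quality-score error profiles, paired-end reads. Passing
tests therefore demonstrate correctness of the analysis chain and the
depth effects under idealized defect structure, not robustness to
platform-specific error modes.

## Numerical and design choices

* Anchor matching is exact; a mismatch tolerance is a possible config
  extension, not a default, to keep removal accounting deterministic.
* Frequency-matrix ordering (count desc, then lexicographic) and the
  fixed removal-reason precedence make every output byte-reproducible;
  `run_pipeline()` with identical config+seed rewrites identical CSVs.
* CI bounds use R's `round()` (half-to-even), which the published
  intervals are consistent with; floor/ceiling rounding is not (it fails
  the count-256 lower bound).
* Degenerate inputs: empty FASTQ gives an empty matrix and all-zero
  stats; a count of 0 gives the interval [0; 0]; groups with no members
  are empty, not errors; `percent_distinct` and fold ratios error on
  zero denominators.
* Problem sizes used by the shipped tests were chosen for a laptop-class
  run: the exactness check simulates and re-extracts $10^6$ reads
  (~1 min), the removal-rate calibration uses 20 seeds × 10,000 reads,
  and the depth-dependence check subsamples a 50,000-read dataset from a
  20,000-peptide pool at 10% depth 20 times.

## Known limitations

* Observed unique peptides is the working definition of diversity;
  richness extrapolation (Chao1, rarefaction asymptotics) is out of
  scope.
* The Poisson–Wald interval is a normal approximation; for very small
  counts exact (Garwood-type) intervals would differ, but the calibrated
  form is the one consistent with the published tables this package's
  comparisons are modeled on.
* Cleaning has no sequencing-error correction or clustering: a one-base
  miscall inside the insert yields a different (valid) peptide and
  inflates observed diversity, at any depth.
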