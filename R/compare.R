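# Default normal quantile for Bonferroni-corrected 95% CIs on absolute
# frequencies. Midpoint of the band [3.3204, 3.3288] of z values that
# reproduce, with a single shared quantile and round-half-to-even, all 19
# published example intervals this form was calibrated against; Bonferroni
# divisors m = 56 and m = 57 at family-wise alpha = 0.05 both fall inside
# the band. Override via `z` or `m_tests`.
PD_DEFAULT_Z <- 3.3246

#' Normal quantile for a Bonferroni-corrected two-sided interval
#'
#' @param alpha Family-wise two-sided level (default 0.05).
#' @param m_tests Bonferroni divisor (number of intervals computed).
#' @return `qnorm(1 - alpha / (2 * m_tests))`.
#' @export
#' @examples
#' bonferroni_z(0.05, 1)  # plain 95% quantile, 1.96
#' bonferroni_z(0.05, 56)
bonferroni_z <- function(alpha = 0.05, m_tests = 1) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)", class = "pepdepth_invalid_input")
  }
  if (!is.numeric(m_tests) || m_tests < 1) {
    abort("m_tests must be >= 1", class = "pepdepth_invalid_input")
  }
  qnorm(1 - alpha / (2 * m_tests))
}

#' Bonferroni-corrected Poisson-Wald confidence interval for read counts
#'
#' Interval `count +/- z * sqrt(count)` with bounds rounded half-to-even
#' to integers and the lower bound clipped at 0 - the Wald normal
#' approximation to a Poisson count, with the quantile inflated by a
#' Bonferroni correction for the family of intervals computed in an
#' analysis. A count of 0 yields the degenerate interval \[0; 0\].
#'
#' @param count Absolute frequencies (vectorized, nonnegative).
#' @param alpha Family-wise two-sided level.
#' @param m_tests Bonferroni divisor; used to derive `z` when `z` is not
#'   supplied.
#' @param z Normal quantile to use directly. Default 3.3246
#'   (see [bonferroni_z()] for deriving one from `alpha` and `m_tests`).
#' @return Tibble with columns `count`, `lower`, `upper`, `alpha`,
#'   `m_tests`, `z`.
#' @export
#' @examples
#' wald_poisson_ci(c(20, 256))  # [5; 35] and [203; 309]
wald_poisson_ci <- function(count, alpha = 0.05, m_tests = NULL, z = NULL) {
  if (any(count < 0) || anyNA(count)) {
    abort("counts must be nonnegative", class = "pepdepth_invalid_input")
  }
  if (is.null(z)) {
    z <- if (is.null(m_tests)) PD_DEFAULT_Z else bonferroni_z(alpha, m_tests)
  }
  half <- z * sqrt(count)
  tibble(
    count = as.integer(count),
    lower = pmax(0L, as.integer(round(count - half))),
    upper = as.integer(round(count + half)),
    alpha = alpha,
    m_tests = m_tests %||% NA_integer_,
    z = z
  )
}

ci_disjoint_pair_exists <- function(lower, upper) {
  # some pair (i, j) has upper_i < lower_j; intervals sharing an integer
  # endpoint are not disjoint
  length(lower) >= 2 && min(upper) < max(lower)
}

#' Distinguishing-capacity analysis between two sequencing depths
#'
#' For each requested absolute frequency f, collects the peptides observed
#' exactly f times in dataset A (typically the shallower run) that are
#' also present in dataset B, and computes Bonferroni-corrected Poisson
#' confidence intervals for their frequencies in both datasets. A group is
#' flagged significant when at least one pair of member intervals in B is
#' disjoint: peptides tied at frequency f in A that B resolves as having
#' different abundances.
#'
#' @param matrix_a,matrix_b `pd_freq_matrix` objects (A = reference for
#'   group membership, B = deeper comparison set).
#' @param frequencies Absolute frequencies in A defining the groups.
#' @param alpha Family-wise level for the intervals.
#' @param m_tests Optional Bonferroni divisor, e.g. the total number of
#'   intervals computed across the analysis (one per member in each
#'   dataset); used to derive the quantile when `z` is not supplied.
#' @param z Normal quantile used for every interval; when neither `z` nor
#'   `m_tests` is given, the calibrated default 3.3246 is used.
#' @return A `pd_distinguish` list: `members` (per-peptide tibble with
#'   counts, relative frequencies and CI bounds in both datasets),
#'   `groups` (per-frequency tibble with `n_members` and `significant`),
#'   and the shared `z`, `alpha`, `m_tests`. `tidy()` returns `members`,
#'   `glance()` a one-row summary.
#' @export
distinguishing_analysis <- function(matrix_a, matrix_b,
                                    frequencies = seq(20, 50, by = 5),
                                    alpha = 0.05, m_tests = NULL, z = NULL) {
  stopifnot(inherits(matrix_a, "pd_freq_matrix"),
            inherits(matrix_b, "pd_freq_matrix"))
  b_idx <- setNames(seq_len(nrow(matrix_b)), matrix_b$peptide)

  groups <- map(frequencies, function(f) {
    sel <- matrix_a$absolute_frequency == f
    peps <- matrix_a$peptide[sel]
    peps <- sort(peps[peps %in% names(b_idx)])
    tibble(
      frequency_a = f,
      peptide = peps,
      count_a = rep(as.integer(f), length(peps)),
      rel_a = matrix_a$relative_frequency[match(peps, matrix_a$peptide)],
      count_b = matrix_b$absolute_frequency[b_idx[peps]],
      rel_b = matrix_b$relative_frequency[b_idx[peps]]
    )
  })
  members <- bind_rows(groups)

  if (is.null(z) && !is.null(m_tests)) {
    z <- bonferroni_z(alpha, m_tests)
  } else if (is.null(z)) {
    z <- PD_DEFAULT_Z
  }
  if (nrow(members) > 0) {
    ci_a <- wald_poisson_ci(members$count_a, alpha = alpha, z = z)
    ci_b <- wald_poisson_ci(members$count_b, alpha = alpha, z = z)
    members$lower_a <- ci_a$lower
    members$upper_a <- ci_a$upper
    members$lower_b <- ci_b$lower
    members$upper_b <- ci_b$upper
  } else {
    members[c("lower_a", "upper_a", "lower_b", "upper_b")] <-
      rep(list(integer(0)), 4)
  }

  group_summary <- map(frequencies, function(f) {
    m <- members[members$frequency_a == f, ]
    tibble(
      frequency_a = f,
      n_members = nrow(m),
      significant = ci_disjoint_pair_exists(m$lower_b, m$upper_b)
    )
  }) |> bind_rows()

  structure(list(
    members = members,
    groups = group_summary,
    z = z,
    alpha = alpha,
    m_tests = m_tests,
    labels = c(attr(matrix_a, "label") %||% "A",
               attr(matrix_b, "label") %||% "B")
  ), class = "pd_distinguish")
}

#' @export
print.pd_distinguish <- function(x, ...) {
  cat(sprintf("<pd_distinguish %s vs %s> z = %.4f, alpha = %g\n",
              x$labels[1], x$labels[2], x$z, x$alpha))
  print(x$groups)
  invisible(x)
}

#' Identical-peptide overlap between datasets
#'
#' Counts peptide sequences common to each pair of datasets (set
#' intersection over unique peptides). The self-overlap of a dataset is
#' its unique cleaned read count.
#'
#' @param ... Two to four `pd_freq_matrix` objects, optionally named;
#'   unnamed arguments fall back to their matrix labels.
#' @return Tibble with columns `set_a`, `set_b`, `n_common` covering all
#'   unordered pairs including self-pairs.
#' @export
peptide_overlap <- function(...) {
  mats <- list(...)
  if (length(mats) == 1 && is.list(mats[[1]]) &&
      !inherits(mats[[1]], "pd_freq_matrix")) {
    mats <- mats[[1]]
  }
  if (length(mats) < 2 || length(mats) > 4) {
    abort("peptide_overlap expects 2 to 4 frequency matrices",
          class = "pepdepth_invalid_input")
  }
  nm <- names(mats)
  if (is.null(nm)) nm <- rep("", length(mats))
  for (i in seq_along(mats)) {
    stopifnot(inherits(mats[[i]], "pd_freq_matrix"))
    if (nm[i] == "") {
      nm[i] <- attr(mats[[i]], "label") %||% paste0("set", i)
    }
  }
  sets <- map(mats, "peptide")
  pairs <- list()
  for (i in seq_along(sets)) {
    for (j in i:length(sets)) {
      pairs[[length(pairs) + 1L]] <- tibble(
        set_a = nm[i], set_b = nm[j],
        n_common = if (i == j) length(sets[[i]])
                   else length(intersect(sets[[i]], sets[[j]]))
      )
    }
  }
  bind_rows(pairs)
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Position-specific amino-acid frequency matrix
#'
#' One-hot encodes the peptides of a dataset and reports, for each of the
#' 20 standard residues and each peptide position, the percentage of
#' sequences (or of reads, when abundance-weighted) carrying that residue
#' at that position. Every position column sums to 100.
#'
#' @param x A `pd_freq_matrix` whose peptides all share one length.
#' @param weighting `"unique"` (default; each distinct peptide counts
#'   once) or `"abundance"` (peptides weighted by absolute frequency).
#' @return A `pd_posfreq` tibble: column `residue` plus one numeric column
#'   per position (`"1"` ... `"L"`), values in percent.
#' @export
#' @examples
#' positional_frequency(freq_matrix("AAAA", 3))
positional_frequency <- function(x, weighting = c("unique", "abundance")) {
  stopifnot(inherits(x, "pd_freq_matrix"), nrow(x) > 0)
  weighting <- arg_match(weighting)
  lens <- unique(nchar(x$peptide))
  if (length(lens) != 1) {
    abort("peptides must all have the same length",
          class = "pepdepth_ragged_peptides")
  }
  L <- lens
  w <- if (weighting == "abundance") x$absolute_frequency else
    rep(1, nrow(x))
  res_mat <- matrix(unlist(strsplit(x$peptide, "", fixed = TRUE)),
                    nrow = nrow(x), ncol = L, byrow = TRUE)
  out <- matrix(0, nrow = length(AA_ALPHABET), ncol = L,
                dimnames = list(AA_ALPHABET, as.character(seq_len(L))))
  if (any(!res_mat %in% AA_ALPHABET)) {
    abort("peptides contain non-standard residues",
          class = "pepdepth_invalid_residue")
  }
  for (j in seq_len(L)) {
    s <- vapply(split(w, factor(res_mat[, j], levels = AA_ALPHABET)),
                sum, numeric(1))
    out[, j] <- 100 * s / sum(w)
  }
  structure(
    dplyr::bind_cols(tibble(residue = AA_ALPHABET), as_tibble(out)),
    class = c("pd_posfreq", class(tibble())),
    weighting = weighting,
    label = attr(x, "label")
  )
}

#' Positional-frequency difference between two datasets
#'
#' Elementwise difference (percentage points) of two positional frequency
#' matrices: `a - b`, with `b` the reference, so positive cells mark
#' residues overrepresented in `a`. Column sums are 0 up to rounding
#' because each input column sums to 100.
#'
#' @param a,b `pd_posfreq` matrices of identical dimensions (a = test
#'   set, b = reference).
#' @return A `pd_posdiff` tibble of the same shape.
#' @export
positional_difference <- function(a, b) {
  stopifnot(inherits(a, "pd_posfreq"), inherits(b, "pd_posfreq"))
  if (!identical(dim(a), dim(b)) || !identical(a$residue, b$residue)) {
    abort("positional frequency matrices have mismatched dimensions",
          class = "pepdepth_dim_mismatch")
  }
  num <- setdiff(names(a), "residue")
  out <- a
  out[num] <- as_tibble(as.data.frame(a[num] - b[num]))
  structure(out, class = c("pd_posdiff", class(tibble())),
            labels = c(attr(a, "label") %||% "A",
                       attr(b, "label") %||% "B"))
}
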