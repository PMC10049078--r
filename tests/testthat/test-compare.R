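test_that("Poisson-Wald intervals match published examples and degenerate cases", {
  ci <- wald_poisson_ci(c(20, 256, 0))
  expect_equal(ci$lower, c(5, 203, 0))
  expect_equal(ci$upper, c(35, 309, 0))
  expect_true(all(ci$lower <= ci$count & ci$count <= ci$upper))

  expect_error(wald_poisson_ci(-1), class = "pepdepth_invalid_input")
  expect_error(bonferroni_z(alpha = 0), class = "pepdepth_invalid_input")
  expect_error(bonferroni_z(m_tests = 0), class = "pepdepth_invalid_input")
  expect_equal(bonferroni_z(0.05, 1), qnorm(0.975))
})

test_that("interval width grows with count and with the Bonferroni divisor", {
  counts <- c(1, 5, 20, 100, 400)
  w1 <- with(wald_poisson_ci(counts, m_tests = 1), upper - lower)
  expect_true(all(diff(w1) >= 0))
  for (cnt in counts) {
    wm <- vapply(c(1, 5, 50, 500), function(m) {
      with(wald_poisson_ci(cnt, m_tests = m), upper - lower)
    }, numeric(1))
    expect_true(all(diff(wm) >= 0))
  }
})

make_pair <- function(counts_b, f = 20, n_filler = 5) {
  peps <- sprintf("PEP%02d", seq_along(counts_b))
  filler <- sprintf("FIL%02d", seq_len(n_filler))
  a <- freq_matrix(c(peps, filler),
                   c(rep(f, length(peps)), seq_len(n_filler) + 100),
                   label = "shallow")
  b <- freq_matrix(c(peps, "ONLYB"), c(counts_b, 7), label = "deep")
  list(a = a, b = b)
}

test_that("tied shallow frequencies are resolved when deep CIs are disjoint", {
  m <- make_pair(c(87, 90, 189, 85, 170, 161))
  res <- distinguishing_analysis(m$a, m$b, frequencies = 20)
  expect_equal(res$groups$n_members, 6)
  expect_true(res$groups$significant)
  # the witnessing pair: CIs of 189 and 85
  mem <- tidy(res)
  expect_equal(mem$lower_b[mem$count_b == 189], 143)
  expect_equal(mem$upper_b[mem$count_b == 189], 235)
  expect_equal(mem$lower_b[mem$count_b == 85], 54)
  expect_equal(mem$upper_b[mem$count_b == 85], 116)
  expect_gt(mem$lower_b[mem$count_b == 189], mem$upper_b[mem$count_b == 85])

  g <- glance(res)
  expect_equal(g$n_significant, 1)
  expect_equal(g$n_members, 6)
})

test_that("identical or touching deep intervals are not called significant", {
  same <- distinguishing_analysis(make_pair(rep(120, 4))$a,
                                  make_pair(rep(120, 4))$b,
                                  frequencies = 20)
  expect_false(same$groups$significant)

  # boundary case from the CI formula: two counts whose intervals share
  # exactly one integer
  z <- 3.3246
  c1 <- 100
  upper1 <- round(c1 + z * sqrt(c1))
  c2 <- Position(function(c) round(c - z * sqrt(c)) == upper1, 1:1000)
  expect_false(is.na(c2))
  m <- make_pair(c(c1, c2))
  res <- distinguishing_analysis(m$a, m$b, frequencies = 20)
  mem <- tidy(res)
  expect_equal(mem$upper_b[mem$count_b == c1], mem$lower_b[mem$count_b == c2])
  expect_false(res$groups$significant)

  # one step further apart they disjoin
  m2 <- make_pair(c(c1, c2 + 5))
  expect_true(distinguishing_analysis(m2$a, m2$b,
                                      frequencies = 20)$groups$significant)
})

test_that("distinguishing analysis ignores input order and missing groups", {
  m <- make_pair(c(87, 90, 189, 85, 170, 161))
  set.seed(3)
  shuf <- function(fm) {
    idx <- sample(nrow(fm))
    freq_matrix(fm$peptide[idx], fm$absolute_frequency[idx],
                label = attr(fm, "label"))
  }
  r1 <- distinguishing_analysis(m$a, m$b, frequencies = c(20, 25))
  r2 <- distinguishing_analysis(shuf(m$a), shuf(m$b), frequencies = c(20, 25))
  expect_equal(r1$members, r2$members)
  expect_equal(r1$groups, r2$groups)
  # no peptide has frequency 25 in A: empty group, no error
  expect_equal(r1$groups$n_members[r1$groups$frequency_a == 25], 0)
  expect_false(r1$groups$significant[r1$groups$frequency_a == 25])
})

test_that("peptide overlap counts identical sequences pairwise", {
  a <- freq_matrix(c("AAA", "CCC", "DDD"), c(5, 2, 1), label = "a")
  b <- freq_matrix(c("CCC", "DDD", "EEE", "FFF"), c(1, 1, 1, 9), label = "b")
  c3 <- freq_matrix(c("GGG"), 4, label = "c")
  ov <- peptide_overlap(a, b, c3)
  pick <- function(x, y) {
    ov$n_common[(ov$set_a == x & ov$set_b == y) |
                  (ov$set_a == y & ov$set_b == x)]
  }
  expect_equal(pick("a", "a"), 3)
  expect_equal(pick("b", "b"), 4)
  expect_equal(pick("a", "b"), 2)
  expect_equal(pick("a", "c"), 0)
  expect_error(peptide_overlap(a), class = "pepdepth_invalid_input")
})

test_that("overlap of two shallow samples matches a multinomial oracle", {
  set.seed(202)
  n_pep <- 400
  w <- rlnorm(n_pep); w <- w / sum(w)
  peps <- random_peptides(n_pep)
  depth <- 600
  draw <- function() {
    cnt <- as.vector(rmultinom(1, depth, w))
    freq_matrix(peps[cnt > 0], cnt[cnt > 0])
  }
  # empirical oracle: mean intersection over independent replicate pairs
  oracle <- replicate(30, {
    c1 <- rmultinom(1, depth, w) > 0
    c2 <- rmultinom(1, depth, w) > 0
    sum(c1 & c2)
  })
  got <- peptide_overlap(s1 = draw(), s2 = draw())
  n_common <- got$n_common[got$set_a == "s1" & got$set_b == "s2"]
  expect_lt(abs(n_common - mean(oracle)), 4 * sd(oracle))
  expect_lt(n_common, n_pep)  # equal-depth samples overlap incompletely
})

test_that("positional frequencies one-hot encode residues by position", {
  single <- positional_frequency(freq_matrix("AAAAAAAAAAAA", 3))
  expect_equal(unlist(single[single$residue == "A", -1], use.names = FALSE),
               rep(100, 12))
  expect_equal(sum(single[, -1]), 1200)

  two <- positional_frequency(freq_matrix(c("ACDE", "CADE"), c(2, 2)))
  expect_equal(two[["1"]][two$residue %in% c("A", "C")], c(50, 50))

  # abundance weighting follows counts
  wtd <- positional_frequency(freq_matrix(c("AAAA", "CCCC"), c(3, 1)),
                              weighting = "abundance")
  expect_equal(wtd[["1"]][wtd$residue == "A"], 75)

  expect_error(positional_frequency(freq_matrix(c("AA", "AAA"), c(1, 1))),
               class = "pepdepth_ragged_peptides")
})

test_that("an NNK-sampled pool approaches NNK codon-table residue frequencies", {
  cfg <- synthetic_library_config(true_diversity = 8000, seed = 55)
  pool <- sample_true_library(cfg)
  fm <- freq_matrix(pool$peptide, rep(1, nrow(pool)))
  pf <- positional_frequency(fm, weighting = "unique")
  expected <- 100 * nnk_residue_weights()
  for (j in as.character(1:12)) {
    expect_equal(sum(pf[[j]]), 100)
    # binomial sampling band around each expected residue percentage
    se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / 8000)
    expect_true(all(abs(pf[[j]] - expected[pf$residue]) < 4 * se[pf$residue]))
  }
  expect_gt(sum(pf$residue == "L"), 0)
  l_vs_m <- mean(unlist(pf[pf$residue == "L", -1])) /
    mean(unlist(pf[pf$residue == "M", -1]))
  expect_lt(abs(l_vs_m - 3), 0.5)
})

test_that("positional differences are signed, antisymmetric and balanced", {
  set.seed(8)
  a <- positional_frequency(freq_matrix(random_peptides(200),
                                        sample(1:9, 200, TRUE)))
  b <- positional_frequency(freq_matrix(random_peptides(150),
                                        sample(1:9, 150, TRUE)))
  zero <- positional_difference(a, a)
  expect_true(all(abs(as.matrix(zero[, -1])) < 1e-12))

  d_ab <- positional_difference(a, b)
  d_ba <- positional_difference(b, a)
  expect_equal(as.matrix(d_ab[, -1]), -as.matrix(d_ba[, -1]))
  expect_true(all(abs(colSums(as.matrix(d_ab[, -1]))) < 1e-9))

  short <- positional_frequency(freq_matrix("ACD", 1))
  expect_error(positional_difference(a, short),
               class = "pepdepth_dim_mismatch")
})
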