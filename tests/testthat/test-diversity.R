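test_that("Chao1 follows the classical and bias-corrected branches", {
  expect_equal(chao1(counts_repertoire(c(1L, 1L, 1L, 2L, 2L, 5L))), 8.25)
  expect_equal(chao1(counts_repertoire(c(1L, 1L, 3L))), 4)       # f2 = 0
  r_no_singletons <- counts_repertoire(c(3L, 4L, 5L))
  expect_equal(chao1(r_no_singletons), richness(r_no_singletons))
})

test_that("inverse Simpson matches closed forms and bounds", {
  for (n in c(1L, 2L, 10L)) {
    expect_equal(inverse_simpson(counts_repertoire(rep(5L, n))), n,
                 tolerance = 1e-12)
  }
  expect_equal(inverse_simpson(counts_repertoire(c(10L, 5L, 5L))), 1 / 0.375,
               tolerance = 1e-12)
  set.seed(101)
  for (i in 1:20) {
    r <- random_repertoire(richness = sample(2:50, 1))
    expect_lte(inverse_simpson(r), richness(r) + 1e-9)
    expect_gte(inverse_simpson(r), 1 - 1e-9)
    scaled <- counts_repertoire(r$clonotypes$count * 7L)
    expect_equal(inverse_simpson(scaled), inverse_simpson(r),
                 tolerance = 1e-12)
  }
})

test_that("diversity statistics agree with brute-force oracles", {
  set.seed(102)
  for (i in 1:200) {
    counts <- sample.int(30, sample(2:50, 1), replace = TRUE)
    r <- counts_repertoire(counts)
    expect_equal(chao1(r), oracle_chao1(counts), tolerance = 1e-12)
    expect_equal(inverse_simpson(r), oracle_isi(counts), tolerance = 1e-12)
    expect_equal(rank_band_mass(r), oracle_rank_band(counts),
                 tolerance = 1e-12)
  }
})

test_that("z-score expansion counting uses strict thresholds and sample sd", {
  expect_equal(expanded_count_z2(counts_repertoire(c(rep(1L, 9), 11L))), 1)
  expect_equal(expanded_count_z2(counts_repertoire(c(1L, 1L, 1L, 1L, 6L))), 0)
  expect_warning(z <- expanded_count_z2(counts_repertoire(rep(4L, 10))),
                 "constant")
  expect_equal(z, 0)
  expect_warning(z1 <- expanded_count_z2(counts_repertoire(5L)), "richness")
  expect_equal(z1, 0)
  # population-sd flag changes the denominator
  r <- counts_repertoire(c(rep(1L, 9), 11L))
  expect_equal(expanded_count_z2(r, population_sd = TRUE), 1)
})

test_that("expansion count is invariant to clonotype order", {
  set.seed(103)
  counts <- sample.int(100, 40, replace = TRUE)
  r1 <- counts_repertoire(counts)
  r2 <- counts_repertoire(sample(counts))
  expect_equal(expanded_count_z2(r1), expanded_count_z2(r2))
})

test_that("low-frequency counting uses a strict upper bound", {
  expect_equal(low_freq_count(counts_repertoire(c(50L, 99L, 100L, 150L))), 2)
  expect_equal(low_freq_count(counts_repertoire(c(100L, 200L))), 0)
  set.seed(104)
  counts <- sample.int(300, 50, replace = TRUE)
  expect_equal(low_freq_count(counts_repertoire(counts)),
               sum(counts < 100))
})

test_that("rank bands partition read mass with the documented boundaries", {
  expect_equal(rank_band_mass(counts_repertoire(c(9L, 7L, 5L, 3L, 1L))),
               c(top1_10 = 1, top11_100 = 0, top101_1000 = 0, rest = 0))
  uniform_1000 <- counts_repertoire(rep(2L, 1000))
  expect_equal(rank_band_mass(uniform_1000),
               c(top1_10 = 0.01, top11_100 = 0.09, top101_1000 = 0.9,
                 rest = 0))
  set.seed(105)
  r <- random_repertoire(30)
  expect_equal(sum(rank_band_mass(r)), 1, tolerance = 1e-12)
})

test_that("frequency bands use a closed upper boundary at 0.1%", {
  at_boundary <- counts_repertoire(1000L, total_pad = 1000000L)
  fb <- freq_band_richness(at_boundary)
  expect_equal(fb[["low"]], 1)  # exactly 0.1% goes low; pad clone is high
  above <- counts_repertoire(1001L, total_pad = 1000000L)
  expect_equal(freq_band_richness(above)[["low"]], 0)
  set.seed(106)
  r <- random_repertoire(25)
  expect_equal(sum(freq_band_richness(r)), richness(r))
})

test_that("length distributions support read and clonotype weighting", {
  r <- new_repertoire(
    data.frame(cdr3_aa = c("CASSLGQYLEQYF", "CASSLGQYLSEQPQF"),  # 13, 15
               v_gene = "TRBV15", j_gene = "TRBJ2-1",
               count = c(90L, 10L)), "S")
  expect_equal(cdr3_length_distribution(r),
               c("13" = 0.9, "15" = 0.1))
  expect_equal(cdr3_length_distribution(r, "clonotypes"),
               c("13" = 0.5, "15" = 0.5))
  set.seed(107)
  expect_equal(sum(cdr3_length_distribution(random_repertoire(30))), 1,
               tolerance = 1e-12)
})

test_that("gene usage is read-weighted by default and sums to one", {
  r <- new_repertoire(
    data.frame(cdr3_aa = c("CASSAF", "CASSDF"),
               v_gene = c("TRBV15", "TRBV27"), j_gene = "TRBJ2-1",
               count = c(30L, 70L)), "S")
  expect_equal(gene_usage(r, "V"), c(TRBV15 = 0.3, TRBV27 = 0.7))
  expect_equal(gene_usage(r, "J"), c("TRBJ2-1" = 1))
  expect_equal(gene_usage(r, "V", "clonotypes"),
               c(TRBV15 = 0.5, TRBV27 = 0.5))
})

test_that("group comparison delegates to the standard tests", {
  ks_same <- compare_groups(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)),
                            "ks_two_sample")
  expect_equal(ks_same$p, 1)
  f <- compare_groups(matrix(c(5, 5, 5, 5), 2), "fisher_exact")
  expect_equal(f$statistic, 1, tolerance = 0.05)
  expect_equal(f$p, 1)
  set.seed(108)
  shifted <- compare_groups(list(a = rnorm(10), b = rnorm(10) + 10),
                            "wilcoxon_rank_sum")
  expect_lt(shifted$p, 0.001)
  paired <- compare_groups(list(a = c(1, 2, 3), b = c(2, 3, 4)),
                           "wilcoxon_signed_rank")
  expect_true(is.finite(paired$p))
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "at least 2")
  expect_error(compare_groups(list(a = c(1, 2), b = c(1, 2, 3)),
                              "wilcoxon_signed_rank"), "paired")
})

test_that("diversity summaries collect every per-sample statistic coherently", {
  set.seed(109)
  r <- random_repertoire(40)
  s <- diversity_summary(r)
  expect_equal(s$richness, richness(r))
  expect_equal(s$chao1, chao1(r))
  expect_equal(s$inverse_simpson, inverse_simpson(r))
  expect_equal(s$top1_10 + s$top11_100 + s$top101_1000 + s$rest, 1,
               tolerance = 1e-12)
  expect_equal(s$richness_low_band + s$richness_high_band, s$richness)
})
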