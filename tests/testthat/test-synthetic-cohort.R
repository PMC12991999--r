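test_that("sampled CDR3s keep the conserved frame and length floor", {
  set.seed(11)
  s <- sample_cdr3(10000, 9, 2)  # mean near the floor to stress resampling
  expect_true(all(startsWith(s, "C")))
  expect_true(all(endsWith(s, "F")))
  expect_true(all(nchar(s) >= 8))
  expect_true(all(valid_cdr3(s)))
})

test_that("forced motifs land inside the trimmed interior", {
  set.seed(12)
  s <- sample_cdr3(2000, 13, 1.2, forced_motif = "QGA")
  in_window <- vapply(seq_along(s), function(i) {
    pos <- gregexpr("QGA", s[i], fixed = TRUE)[[1]]
    any(pos >= 4 & pos + 3 - 1 <= nchar(s[i]) - 3)
  }, logical(1))
  expect_true(all(in_window))
  expect_error(sample_cdr3(5, 9, 0.1, forced_motif = "QGAQGAQGAQGA"),
               "does not fit")
})

test_that("generated repertoires honor richness, depth and determinism", {
  cc <- small_cohort_config(seed = 21, motif_spike_fraction = 0)
  r <- generate_repertoire(cc, "GVHD", "g1")
  expect_equal(nrow(r$clonotypes), 300)
  expect_lte(abs(r$total_reads - 60000), 300)
  r2 <- generate_repertoire(cc, "GVHD", "g1")
  expect_identical(r$clonotypes, r2$clonotypes)
})

test_that("uniform abundances (exponent 0) give ISI equal to richness", {
  cc <- cohort_config(n_per_group = c(GVHD = 1L), richness = c(GVHD = 100L),
                      clone_size_exponent = 0, total_reads = 10000L,
                      motif_spike_fraction = 0, seed = 3)
  r <- generate_repertoire(cc, "GVHD", "g1")
  expect_true(all(r$clonotypes$count == 100L))
  expect_equal(inverse_simpson(r), 100, tolerance = 1e-12)
})

test_that("infeasible richness/depth combinations raise a configuration error", {
  cc <- cohort_config(n_per_group = c(GVHD = 1L), richness = c(GVHD = 1000L),
                      clone_size_exponent = 3, total_reads = 2000L, seed = 1)
  expect_error(generate_repertoire(cc, "GVHD", "g1"), "infeasible")
})

test_that("cohorts carry group labels and per-subject streams are stable", {
  cc <- cohort_config(n_per_group = c(GVHD = 2L, NO_GVHD = 1L, HI = 1L),
                      richness = c(GVHD = 80L, NO_GVHD = 50L, HI = 60L),
                      total_reads = 8000L, seed = 31)
  co <- generate_cohort(cc)
  man <- cohort_manifest(co)
  expect_equal(nrow(man), 4)
  expect_equal(sort(table(man$group), decreasing = TRUE)[["GVHD"]], 2)
  # adding a subject must not perturb existing ones
  cc2 <- cohort_config(n_per_group = c(GVHD = 3L, NO_GVHD = 1L, HI = 1L),
                       richness = c(GVHD = 80L, NO_GVHD = 50L, HI = 60L),
                       total_reads = 8000L, seed = 31)
  co2 <- generate_cohort(cc2)
  expect_identical(co[["GVHD_01"]]$clonotypes, co2[["GVHD_01"]]$clonotypes)
  expect_identical(co[["NO_GVHD_01"]]$clonotypes,
                   co2[["NO_GVHD_01"]]$clonotypes)
})

test_that("different master seeds give essentially disjoint clonotype sets", {
  cc1 <- small_cohort_config(seed = 41)
  cc2 <- small_cohort_config(seed = 42)
  a <- generate_repertoire(cc1, "GVHD", "g1")$clonotypes$cdr3_aa
  b <- generate_repertoire(cc2, "GVHD", "g1")$clonotypes$cdr3_aa
  expect_lt(length(intersect(a, b)) / length(a), 0.01)
})

test_that("motif spiking marks the configured fraction without touching termini", {
  cc <- small_cohort_config(seed = 51)
  r <- generate_repertoire(cc, "GVHD", "g1")
  hits <- lapply(cc$motif_panel, function(m) {
    cdr3 <- r$clonotypes$cdr3_aa
    which(grepl(m, cdr3, fixed = TRUE))
  })
  expect_gte(length(unique(unlist(hits))), round(0.05 * 300) - 3)
  for (i in seq_along(cc$motif_panel)) {
    m <- cc$motif_panel[i]
    cdr3 <- r$clonotypes$cdr3_aa[hits[[i]]]
    in_window <- vapply(cdr3, function(x) {
      pos <- gregexpr(m, x, fixed = TRUE)[[1]]
      any(pos >= 4 & pos + nchar(m) - 1 <= nchar(x) - 3)
    }, logical(1))
    expect_true(all(in_window))
  }
  # unspiked groups stay clean of deliberate panel enrichment
  r_hi <- generate_repertoire(cc, "HI", "h1")
  frac_hi <- mean(grepl(cc$motif_panel[1], r_hi$clonotypes$cdr3_aa,
                        fixed = TRUE))
  expect_lt(frac_hi, 0.02)
})

test_that("configured richness ordering is realized across seeds", {
  med <- sapply(1:5, function(s) {
    cc <- cohort_config(n_per_group = c(GVHD = 2L, NO_GVHD = 2L),
                        richness = c(GVHD = 200L, NO_GVHD = 80L),
                        total_reads = 20000L, motif_spike_fraction = 0,
                        seed = 100 + s)
    man <- cohort_manifest(generate_cohort(cc))
    tapply(man$richness, man$group, median)
  })
  expect_true(all(med["GVHD", ] > med["NO_GVHD", ]))
})

test_that("stage dynamics: identity, extinction, and configured direction", {
  cc <- small_cohort_config(seed = 61)
  r <- generate_repertoire(cc, "GVHD_PRE", "p1", stage = 0L)
  ident <- apply_stage_dynamics(r, 1L, dominant_n = 0, dominant_fold = 1,
                                jitter_sd = 0)
  expect_equal(ident$clonotypes, r$clonotypes)
  expect_equal(ident$stage, 1L)

  top20 <- top_n_clonotypes(r, 20)
  gone <- apply_stage_dynamics(r, 1L, dominant_n = 20, dominant_fold = 0,
                               jitter_sd = 0)
  expect_error(apply_stage_dynamics(r, 1L, dominant_fold = -1), "non-negative")
  expect_length(intersect(top20, top_n_clonotypes(gone, nrow(gone$clonotypes))),
                0)
})

test_that("subject courses contract dominants and lose diversity at resolution", {
  cc <- small_cohort_config(seed = 71)
  course <- generate_subject_course(cc, "p1")
  isi <- vapply(course, inverse_simpson, numeric(1))
  expect_lt(isi[["2"]], isi[["1"]])
  top20 <- top_n_clonotypes(course[["1"]], 20)
  freq2 <- setNames(course[["2"]]$clonotypes$count / course[["2"]]$total_reads,
                    paste(course[["2"]]$clonotypes$cdr3_aa,
                          course[["2"]]$clonotypes$v_gene,
                          course[["2"]]$clonotypes$j_gene, sep = "|"))
  freq1 <- setNames(course[["1"]]$clonotypes$count / course[["1"]]$total_reads,
                    paste(course[["1"]]$clonotypes$cdr3_aa,
                          course[["1"]]$clonotypes$v_gene,
                          course[["1"]]$clonotypes$j_gene, sep = "|"))
  f2 <- freq2[top20]
  f2[is.na(f2)] <- 0
  expect_true(all(f2 < freq1[top20]))  # dominant clones contracted
})

test_that("reference repertoires are unique, motif-free and deterministic", {
  cc <- small_cohort_config(seed = 81)
  ref <- generate_reference(2000, cc)
  expect_length(ref, 2000)
  expect_false(any(duplicated(ref)))
  for (m in cc$motif_panel) expect_false(any(grepl(m, ref, fixed = TRUE)))
  expect_identical(ref, generate_reference(2000, cc))
})

test_that("cohorts round-trip through manifest files", {
  cc <- cohort_config(n_per_group = c(GVHD = 2L, NO_GVHD = 1L),
                      richness = c(GVHD = 60L, NO_GVHD = 40L),
                      total_reads = 5000L, seed = 91)
  co <- generate_cohort(cc)
  dir <- tempfile()
  write_cohort(co, dir)
  co2 <- read_cohort(file.path(dir, "manifest.tsv"))
  expect_equal(names(co2), names(co))
  for (nm in names(co)) {
    expect_equal(co2[[nm]]$clonotypes, co[[nm]]$clonotypes)
    expect_equal(co2[[nm]]$group, co[[nm]]$group)
  }
})
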