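# Helper: repertoire at exactly 1e6 reads with chosen foreground clones.
floor_fixture <- function(counts, cdr3s) {
  df <- data.frame(cdr3_aa = cdr3s, v_gene = "TRBV15", j_gene = "TRBJ2-1",
                   count = counts)
  pad <- 1000000L - sum(counts)
  df <- rbind(df, data.frame(cdr3_aa = "CWWWWYWWWWF", v_gene = "TRBV2",
                             j_gene = "TRBJ1-1", count = pad))
  new_repertoire(df, sample_id = "FX")
}

test_that("interior trimming drops the germline-dominated termini", {
  expect_equal(cdr3_interior("CASSIRSSYEQYF"), "SIRSSYE")
  expect_equal(cdr3_interior("CASSIRSSYEQYF", trim = c(0L, 0L)),
               "CASSIRSSYEQYF")
  expect_equal(nchar(cdr3_interior("CASSIRF")), 1)  # length == trim sum + 1
  expect_error(cdr3_interior("CASSF"), "pre-filter")
})

test_that("pool selection applies the strict 0.01% floor and length cutoff", {
  r <- floor_fixture(c(101L, 100L, 102L),
                     c("CASSLGDTQYF", "CASSLGDTQEF", "CASSLDF"))
  pool <- select_input_clonotypes(list(r))
  expect_true("CASSLGDTQYF" %in% pool$cdr3_aa)    # 0.0101% > floor
  expect_false("CASSLGDTQEF" %in% pool$cdr3_aa)   # exactly 0.01%: excluded
  expect_false("CASSLDF" %in% pool$cdr3_aa)       # length 7 < cutoff 8
  empty <- floor_fixture(50L, "CASSLGDTQYF")
  cfg_high <- gliph_config(frequency_floor = 0.99999)
  expect_error(select_input_clonotypes(list(empty), cfg_high), "pass")
})

test_that("k-mer tables use presence semantics per distinct CDR3", {
  tab <- kmer_table("CASSIRSSYEQYF", 3)  # interior SIRSSYE
  expect_setequal(tab$kmer, c("SIR", "IRS", "RSS", "SSY", "SYE"))
  expect_true(all(tab$support == 1))

  rep_kmer <- kmer_table("CASSSSSQYF", 3)  # interior SSSS
  expect_equal(rep_kmer$kmer, "SSS")
  expect_equal(rep_kmer$support, 1)        # presence, not multiplicity

  shared <- kmer_table(c("CASQGAYEQYF", "CARQGAYTEQF"), 3)
  expect_equal(shared$support[shared$kmer == "QGA"], 2)
  expect_length(shared$supporters[shared$kmer == "QGA"][[1]], 2)

  # interiors shorter than k contribute nothing
  expect_equal(nrow(kmer_table("CASSIRF", 4)), 0)
})

test_that("a motif absent from the reference gets the minimal empirical p", {
  cc <- small_cohort_config(seed = 201)
  set.seed(201)
  plain <- sample_cdr3(95, 13, 1)
  spiked <- sample_cdr3(5, 13, 1, forced_motif = "QGA")
  pool <- tibble::tibble(sample_id = "S1", cdr3_aa = c(plain, spiked),
                         v_gene = "TRBV15")
  ref <- generate_reference(2000, cc, exclude_motifs = "QGA")
  cfg <- gliph_config(simulation_depth = 500, seed = 7)
  res <- local_motif_enrichment(pool, ref, cfg, keep_all = TRUE)
  qga <- res[res$signature == "QGA", ]
  expect_equal(nrow(qga), 1)
  expect_gte(qga$support, 5)
  expect_equal(qga$p_empirical, 1 / 501)
  expect_true(qga$retained)
  # support below kmer_min_depth is never tested
  expect_false(any(res$support < cfg$kmer_min_depth))
})

test_that("empirical p agrees with an explicit subset-resampling oracle", {
  cc <- small_cohort_config(seed = 202)
  ref <- generate_reference(400, cc, exclude_motifs = character(0))
  set.seed(202)
  pool_cdr3 <- sample(ref, 60)
  pool <- tibble::tibble(sample_id = "S1", cdr3_aa = pool_cdr3,
                         v_gene = "TRBV15")
  cfg <- gliph_config(simulation_depth = 2000, kmer_lengths = 2L, seed = 9)
  res <- suppressWarnings(local_motif_enrichment(pool, ref, cfg,
                                                 keep_all = TRUE))
  expect_gt(nrow(res), 5)
  trim <- cfg$interior_trim
  ref_int <- cdr3_interior(ref, trim)
  set.seed(99)
  for (i in sample(nrow(res), 5)) {
    motif <- res$signature[i]
    obs <- res$support[i]
    sims <- replicate(2000, {
      sub <- sample(ref_int, length(unique(pool_cdr3)))
      sum(grepl(motif, sub, fixed = TRUE))
    })
    p_oracle <- (1 + sum(sims >= obs)) / 2001
    expect_lt(abs(res$p_empirical[i] - p_oracle), 0.06)
  }
})

test_that("global grouping matches brute-force all-pairs Hamming clustering", {
  # constrained alphabet/length to force near-identical CDR3s
  set.seed(203)
  letters4 <- c("A", "G", "S", "T")
  cdr3s <- unique(vapply(1:300, function(i) {
    paste0("CAS", paste(sample(letters4, 6, replace = TRUE), collapse = ""),
           "QYF")
  }, character(1)))
  pool <- tibble::tibble(sample_id = "S1", cdr3_aa = cdr3s,
                         v_gene = "TRBV15")
  cfg <- gliph_config()
  got <- global_similarity_groups(pool, cfg)

  # O(n^2) oracle
  ints <- cdr3_interior(cdr3s, cfg$interior_trim)
  n <- length(cdr3s)
  edges <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (nchar(cdr3s[i]) != nchar(cdr3s[j])) next
      a <- strsplit(ints[i], "")[[1]]
      b <- strsplit(ints[j], "")[[1]]
      if (sum(a != b) <= 1) edges <- rbind(edges, c(i, j))
    }
  }
  expect_false(is.null(edges))
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  comp <- igraph::components(g)
  oracle_groups <- lapply(split(as.integer(igraph::V(g)$name),
                                comp$membership),
                          function(ix) sort(cdr3s[ix]))
  oracle_groups <- oracle_groups[order(vapply(oracle_groups, `[`,
                                              character(1), 1))]
  expect_equal(length(got$members_cdr3), length(oracle_groups))
  expect_equal(unname(got$members_cdr3), unname(oracle_groups))
})

test_that("global grouping joins Hamming-1 interiors and separates lengths", {
  pool <- tibble::tibble(
    sample_id = "S1",
    cdr3_aa = c("CASSIRSSYEQYF", "CASSIRSTYEQYF", "CASSIRSSYEQYAF"),
    v_gene = "TRBV15")
  got <- global_similarity_groups(pool, gliph_config())
  expect_equal(nrow(got), 1)
  expect_setequal(got$members_cdr3[[1]],
                  c("CASSIRSSYEQYF", "CASSIRSTYEQYF"))  # length 14 excluded
})

test_that("group building is deterministic and order-invariant", {
  cc <- small_cohort_config(seed = 204, n_per_group = c(GVHD = 3L),
                            richness = c(GVHD = 150L), total_reads = 30000L)
  co <- generate_cohort(cc)
  ref <- generate_reference(5000, cc)
  cfg <- gliph_config(simulation_depth = 100, seed = 5)
  g1 <- build_gliph_groups(co, ref, cfg)
  g2 <- build_gliph_groups(rev(co), ref, cfg)
  expect_identical(g1$groups, g2$groups)
  expect_identical(g1$members, g2$members)
  expect_true(all(g1$groups$n_members > 0))
  loc <- g1$groups[g1$groups$kind == "local", ]
  sup <- table(g1$members$group_id)
  # every retained local motif is supported by >= kmer_min_depth CDR3s
  for (gid in loc$group_id) {
    n_cdr3 <- length(unique(
      g1$members$cdr3_aa[g1$members$group_id == gid]))
    expect_gte(n_cdr3, cfg$kmer_min_depth)
  }
})

test_that("a reference smaller than the pool is rejected", {
  pool <- tibble::tibble(sample_id = "S1",
                         cdr3_aa = sample_cdr3(50, 13, 1),
                         v_gene = "TRBV15")
  expect_error(
    suppressWarnings(local_motif_enrichment(pool, sample_cdr3(10, 13, 1),
                                            gliph_config())),
    "smaller than the sample pool")
})
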