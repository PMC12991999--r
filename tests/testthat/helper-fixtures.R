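# Programmatic fixtures shared across the suite. Everything is generated
# in code under explicit seeds; no data files.

# Small random repertoire with arbitrary counts (not power-law): used for
# property tests of the statistics and I/O round trips.
random_repertoire <- function(richness = 20, max_count = 50,
                              sample_id = "RND") {
  cdr3 <- unique(sample_cdr3(richness * 2, 13, 1.5))[seq_len(richness)]
  new_repertoire(
    data.frame(cdr3_aa = cdr3,
               v_gene = sample(c("TRBV2", "TRBV15", "TRBV27"), richness,
                               replace = TRUE),
               j_gene = sample(c("TRBJ1-1", "TRBJ2-7"), richness,
                               replace = TRUE),
               count = sample.int(max_count, richness, replace = TRUE)),
    sample_id = sample_id)
}

# Repertoire from an explicit count vector (CDR3s generated deterministically
# from the counts' index, valid alphabet).
counts_repertoire <- function(counts, sample_id = "CTS", total_pad = NULL) {
  aa <- c("A", "D", "E", "G", "H", "I", "K", "L", "M", "N")
  cdr3 <- vapply(seq_along(counts), function(i) {
    paste0("CASS", paste(aa[(i %% 10) + 1], collapse = ""),
           sprintf("%s", paste0(aa[((i %/% 10) %% 10) + 1],
                                aa[((i %/% 100) %% 10) + 1])), "QYF")
  }, character(1))
  df <- data.frame(cdr3_aa = cdr3, v_gene = "TRBV15", j_gene = "TRBJ2-1",
                   count = counts)
  if (!is.null(total_pad) && total_pad > sum(counts)) {
    df <- rbind(df, data.frame(cdr3_aa = "CWWWWWWWWF", v_gene = "TRBV2",
                               j_gene = "TRBJ1-1",
                               count = total_pad - sum(counts)))
  }
  new_repertoire(df, sample_id = sample_id)
}

# Write a data.frame as a TSV in a temp file and return the path.
tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Independent brute-force oracles (kept deliberately naive).
oracle_chao1 <- function(counts) {
  s <- sum(counts >= 1)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s + f1 * f1 / (2 * f2) else s + f1 * (f1 - 1) / 2
}

oracle_isi <- function(counts) {
  p <- counts / sum(counts)
  acc <- 0
  for (pi in p) acc <- acc + pi * pi
  1 / acc
}

oracle_morisita_horn <- function(x, y) {
  X <- sum(x); Y <- sum(y)
  num <- 0
  for (i in seq_along(x)) num <- num + x[i] * y[i]
  dx <- sum((x / X)^2); dy <- sum((y / Y)^2)
  2 * num / ((dx + dy) * X * Y)
}

oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- sum(a %in% b)
  uni <- length(a) + length(b) - inter
  if (uni == 0) 0 else inter / uni
}

oracle_rank_band <- function(counts) {
  s <- sort(counts, decreasing = TRUE)
  total <- sum(s)
  pick <- function(lo, hi) sum(s[seq_along(s) >= lo & seq_along(s) <= hi])
  c(top1_10 = pick(1, 10) / total,
    top11_100 = pick(11, 100) / total,
    top101_1000 = pick(101, 1000) / total,
    rest = pick(1001, length(s)) / total)
}

# Scaled-down cohort configuration used wherever a full study-sized cohort
# is unnecessary.
small_cohort_config <- function(seed = 1L, ...) {
  args <- list(n_per_group = c(GVHD = 4L, NO_GVHD = 4L, HI = 2L),
               richness = c(GVHD = 300L, NO_GVHD = 120L, HI = 250L),
               total_reads = 60000L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}
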