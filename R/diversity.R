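# Per-repertoire diversity and clonal-expansion statistics, and the
# between-group tests used to compare them.

#' Clonotype richness
#'
#' Number of unique (CDR3, V, J) clonotypes with at least one read.
#'
#' @param rep A `tcr_repertoire`.
#' @return Integer richness.
#' @export
richness <- function(rep) {
  stopifnot(is_repertoire(rep))
  sum(rep$clonotypes$count >= 1L)
}

#' Chao1 richness estimator
#'
#' Classical nonparametric richness estimator from singleton (`f1`) and
#' doubleton (`f2`) counts: `S_obs + f1^2 / (2 f2)` when `f2 > 0`, and the
#' bias-corrected fallback `S_obs + f1 (f1 - 1) / 2` when `f2 == 0`.
#'
#' @param rep A `tcr_repertoire`.
#' @return Estimated richness (real, `>= S_obs`).
#' @export
chao1 <- function(rep) {
  stopifnot(is_repertoire(rep))
  counts <- rep$clonotypes$count
  s_obs <- sum(counts >= 1L)
  f1 <- sum(counts == 1L)
  f2 <- sum(counts == 2L)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Inverse Simpson index
#'
#' `1 / sum(p_i^2)` with `p_i` the clonotype read frequencies: the
#' evenness-weighted effective number of clonotypes. Invariant to uniform
#' count rescaling and bounded by `1 <= ISI <= richness`.
#'
#' @param rep A `tcr_repertoire`.
#' @return Real-valued diversity.
#' @export
inverse_simpson <- function(rep) {
  stopifnot(is_repertoire(rep))
  p <- rep$clonotypes$count / rep$total_reads
  1 / sum(p^2)
}

#' Count expanded clonotypes by z-score
#'
#' Standardizes clonotype counts (`z_i = (count_i - mean) / sd`, sample
#' standard deviation with the `n - 1` denominator by default) and counts
#' clones with `z_i` strictly greater than the threshold. Frequencies give
#' identical z-scores by affine invariance, so counts are used directly.
#'
#' @param rep A `tcr_repertoire`.
#' @param z_threshold Threshold (default 2, strict inequality).
#' @param population_sd Use the `n` denominator instead of `n - 1`.
#' @return Integer count of expanded clonotypes; 0 with a warning when
#'   richness < 2 or the counts are constant.
#' @export
expanded_count_z2 <- function(rep, z_threshold = 2, population_sd = FALSE) {
  stopifnot(is_repertoire(rep))
  counts <- rep$clonotypes$count
  n <- length(counts)
  if (n < 2) {
    warning("richness < 2: no clonotype can be z-expanded", call. = FALSE)
    return(0L)
  }
  s <- sd(counts)
  if (population_sd) s <- s * sqrt((n - 1) / n)
  if (!is.finite(s) || s == 0) {
    warning("constant counts: no clonotype can be z-expanded", call. = FALSE)
    return(0L)
  }
  z <- (counts - mean(counts)) / s
  sum(z > z_threshold)
}

#' Count low-frequency clonotypes
#'
#' Number of clonotypes with read count strictly below `max_count`
#' (default 100). Only comparable across samples normalized to a common
#' depth.
#'
#' @param rep A `tcr_repertoire`.
#' @param max_count Exclusive upper bound on the read count.
#' @return Integer count.
#' @export
low_freq_count <- function(rep, max_count = 100L) {
  stopifnot(is_repertoire(rep))
  sum(rep$clonotypes$count < max_count)
}

#' Read-mass held by clonotype rank bands
#'
#' Fractions of total reads held by the clonotypes ranked 1-10, 11-100,
#' 101-1000 and beyond 1000 by count (ties broken by CDR3 then V gene,
#' lexicographically). Empty bands contribute 0; the four fractions sum
#' to 1.
#'
#' @param rep A `tcr_repertoire`.
#' @return Named numeric vector `top1_10`, `top11_100`, `top101_1000`,
#'   `rest`.
#' @export
rank_band_mass <- function(rep) {
  stopifnot(is_repertoire(rep))
  cl <- rep$clonotypes
  ord <- order(-cl$count, cl$cdr3_aa, cl$v_gene, method = "radix")
  counts <- cl$count[ord]
  r <- seq_along(counts)
  total <- sum(counts)
  c(top1_10 = sum(counts[r <= 10]) / total,
    top11_100 = sum(counts[r > 10 & r <= 100]) / total,
    top101_1000 = sum(counts[r > 100 & r <= 1000]) / total,
    rest = sum(counts[r > 1000]) / total)
}

#' Clonotype richness by frequency band
#'
#' Splits clonotypes into a low-frequency band `(0, boundary]` and a
#' high-frequency band `(boundary, 1]`; the default boundary 0.001 is the
#' 0.1% line, with clones exactly at the boundary assigned to the low band.
#'
#' @param rep A `tcr_repertoire`.
#' @param boundary Frequency boundary (default 0.001).
#' @return Named integer vector `low`, `high`.
#' @export
freq_band_richness <- function(rep, boundary = 0.001) {
  stopifnot(is_repertoire(rep))
  p <- rep$clonotypes$count / rep$total_reads
  c(low = sum(p <= boundary), high = sum(p > boundary))
}

#' CDR3 amino-acid length distribution
#'
#' Fraction of reads (default, "across all productive reads") or of
#' clonotypes at each CDR3 amino-acid length.
#'
#' @param rep A `tcr_repertoire`.
#' @param weighting `"reads"` or `"clonotypes"`.
#' @return Named numeric vector (names = lengths), summing to 1.
#' @export
cdr3_length_distribution <- function(rep,
                                     weighting = c("reads", "clonotypes")) {
  weighting <- match.arg(weighting)
  stopifnot(is_repertoire(rep))
  len <- nchar(rep$clonotypes$cdr3_aa)
  w <- if (weighting == "reads") rep$clonotypes$count else rep(1L, length(len))
  tab <- tapply(w, len, sum)
  out <- as.numeric(tab) / sum(w)
  names(out) <- names(tab)
  out
}

#' V / J gene segment usage
#'
#' Fraction of reads (default) or clonotypes per allele-stripped gene
#' segment.
#'
#' @param rep A `tcr_repertoire`.
#' @param segment `"V"` or `"J"`.
#' @param weighting `"reads"` or `"clonotypes"`.
#' @return Named numeric vector summing to 1.
#' @export
gene_usage <- function(rep, segment = c("V", "J"),
                       weighting = c("reads", "clonotypes")) {
  segment <- match.arg(segment)
  weighting <- match.arg(weighting)
  stopifnot(is_repertoire(rep))
  g <- if (segment == "V") rep$clonotypes$v_gene else rep$clonotypes$j_gene
  w <- if (weighting == "reads") rep$clonotypes$count else rep(1L, length(g))
  tab <- tapply(w, g, sum)
  out <- as.numeric(tab) / sum(w)
  names(out) <- names(tab)
  out
}

#' One-row diversity summary of a repertoire
#'
#' @param rep A `tcr_repertoire`.
#' @param z_threshold,low_freq_max,freq_boundary Thresholds passed to the
#'   individual statistics.
#' @return One-row tibble with sample metadata and all scalar diversity
#'   statistics (richness, Chao1, inverse Simpson, z-expanded count and
#'   expanded-clone read mass, low-frequency count, rank-band masses,
#'   frequency-band richness).
#' @export
diversity_summary <- function(rep, z_threshold = 2, low_freq_max = 100L,
                              freq_boundary = 0.001) {
  stopifnot(is_repertoire(rep))
  bands <- rank_band_mass(rep)
  fb <- freq_band_richness(rep, freq_boundary)
  counts <- rep$clonotypes$count
  expanded_mass <- if (length(counts) >= 2 && sd(counts) > 0) {
    z <- (counts - mean(counts)) / sd(counts)
    sum(counts[z > z_threshold]) / rep$total_reads
  } else 0
  tibble::tibble(
    sample_id = rep$sample_id, subject_id = rep$subject_id,
    chain = rep$chain, group = rep$group, stage = rep$stage,
    total_reads = rep$total_reads,
    richness = richness(rep), chao1 = chao1(rep),
    inverse_simpson = inverse_simpson(rep),
    expanded_count_z2 = suppressWarnings(expanded_count_z2(rep, z_threshold)),
    expanded_mass_z2 = expanded_mass,
    low_freq_count = low_freq_count(rep, low_freq_max),
    top1_10 = bands[["top1_10"]], top11_100 = bands[["top11_100"]],
    top101_1000 = bands[["top101_1000"]], rest = bands[["rest"]],
    richness_low_band = fb[["low"]], richness_high_band = fb[["high"]])
}

#' Diversity summaries for a whole cohort
#'
#' @param cohort List of `tcr_repertoire`s.
#' @param ... Passed to [diversity_summary()].
#' @return Tibble, one row per sample.
#' @export
cohort_diversity <- function(cohort, ...) {
  dplyr::bind_rows(lapply(cohort, diversity_summary, ...))
}

#' Compare a statistic between groups
#'
#' Thin, explicit wrapper over the standard two-group tests used for
#' repertoire statistics: Wilcoxon rank-sum, Wilcoxon signed-rank (paired),
#' two-sample Kolmogorov-Smirnov, and Fisher's exact test on a 2x2 table.
#' All tests are two-sided.
#'
#' @param values_by_group For the first three tests, a named list of exactly
#'   two numeric vectors; for `fisher_exact`, a 2x2 integer matrix.
#' @param test Which test to run.
#' @return One-row tibble with `test`, `statistic`, `p`, `n1`, `n2`.
#' @export
compare_groups <- function(values_by_group,
                           test = c("wilcoxon_rank_sum",
                                    "wilcoxon_signed_rank",
                                    "ks_two_sample", "fisher_exact")) {
  test <- match.arg(test)
  if (test == "fisher_exact") {
    m <- as.matrix(values_by_group)
    if (!all(dim(m) == c(2, 2))) {
      stop("fisher_exact requires a 2x2 table", call. = FALSE)
    }
    ht <- stats::fisher.test(m)
    return(tibble::tibble(test = test, statistic = unname(ht$estimate),
                          p = ht$p.value, n1 = sum(m[1, ]), n2 = sum(m[2, ])))
  }
  if (!is.list(values_by_group) || length(values_by_group) != 2) {
    stop(test, " requires a named list of exactly two numeric vectors",
         call. = FALSE)
  }
  x <- values_by_group[[1]]
  y <- values_by_group[[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  ht <- switch(test,
    wilcoxon_rank_sum = suppressWarnings(stats::wilcox.test(x, y)),
    wilcoxon_signed_rank = {
      if (length(x) != length(y)) {
        stop("signed-rank test requires paired equal-length vectors",
             call. = FALSE)
      }
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    },
    ks_two_sample = suppressWarnings(stats::ks.test(x, y)))
  tibble::tibble(test = test, statistic = unname(ht$statistic),
                 p = ht$p.value, n1 = length(x), n2 = length(y))
}
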