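# Cross-sample sharing of specificity groups: Jaccard similarity over
# group-membership sets, group contrasts, and classification of a query
# sample against GVHD / no-GVHD libraries.

#' Per-sample group-membership profiles
#'
#' The set of specificity-group identifiers in which each sample has at
#' least one member clonotype. Samples with no memberships get an empty
#' set (retained, with a warning) so downstream matrices keep the full
#' cohort. A clonotype-set mode is available: profiles are then the
#' member CDR3 sets instead of group-id sets.
#'
#' @param gliph A `gliph_result` from [build_gliph_groups()].
#' @param cohort The cohort the groups were built on (fixes the sample set
#'   and ordering).
#' @param mode `"groups"` (default) or `"clonotypes"`.
#' @return Named list of character vectors (sets), one per sample.
#' @export
membership_profiles <- function(gliph, cohort,
                                mode = c("groups", "clonotypes")) {
  mode <- match.arg(mode)
  sample_ids <- sort(vapply(cohort, function(r) r$sample_id, character(1)))
  mem <- gliph$members
  profiles <- lapply(sample_ids, function(s) {
    rows <- mem[mem$sample_id == s, , drop = FALSE]
    if (mode == "groups") sort(unique(rows$group_id))
    else sort(unique(rows$cdr3_aa))
  })
  names(profiles) <- sample_ids
  empty <- vapply(profiles, length, integer(1)) == 0
  if (any(empty)) {
    warning(sum(empty), " sample(s) have empty membership profiles: ",
            paste(sample_ids[empty], collapse = ", "), call. = FALSE)
  }
  profiles
}

#' Jaccard index of two sets
#'
#' `|a intersect b| / |a union b|`; two empty sets give 0 by convention (an
#' uninformative sample should not look similar to anything).
#'
#' @param a,b Vectors treated as sets.
#' @return Value in \[0, 1\].
#' @export
#' @examples
#' jaccard(c("g1", "g2", "g3"), c("g2", "g3", "g4"))  # 0.5
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard similarity matrix
#'
#' @param profiles Named list of sets from [membership_profiles()]
#'   (at least 2).
#' @return Symmetric numeric matrix with unit diagonal, rows/columns
#'   ordered by sample id.
#' @export
pairwise_similarity <- function(profiles) {
  if (length(profiles) < 2) {
    stop("need at least 2 profiles", call. = FALSE)
  }
  ids <- sort(names(profiles))
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- jaccard(profiles[[ids[i]]], profiles[[ids[j]]])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

# Rank-sum p with degenerate-tie handling: two samples from the same
# point mass are identically distributed, p = 1 (wilcox.test returns NaN).
wilcox_p <- function(a, b) {
  if (length(unique(c(a, b))) == 1) return(1)
  suppressWarnings(stats::wilcox.test(a, b)$p.value)
}

# Off-diagonal values of a similarity matrix restricted to two id sets;
# within-group calls exclude self-pairs and count each unordered pair once.
pair_values <- function(mat, ids_a, ids_b = NULL) {
  if (is.null(ids_b)) {
    if (length(ids_a) < 2) return(numeric(0))
    sub <- mat[ids_a, ids_a, drop = FALSE]
    sub[upper.tri(sub)]
  } else {
    as.vector(mat[ids_a, ids_b, drop = FALSE])
  }
}

#' Contrast similarity values between groups
#'
#' Collects within-group pair similarities for every label (self-pairs
#' excluded, `n (n - 1) / 2` pairs for a group of `n`) plus the pooled
#' cross-group pairs, and compares every pair of these value sets by the
#' Wilcoxon rank-sum test. Labels with fewer than 2 samples are skipped
#' with a warning.
#'
#' @param mat Similarity matrix from [pairwise_similarity()].
#' @param labels Named character vector: group label per sample id.
#' @return Tibble with one row per contrast: `set_a`, `set_b`, medians,
#'   pair counts and rank-sum `p`.
#' @export
group_contrast <- function(mat, labels) {
  ids <- rownames(mat)
  labels <- labels[ids]
  sets <- list()
  for (g in sort(unique(labels))) {
    g_ids <- ids[labels == g]
    if (length(g_ids) < 2) {
      warning("label ", g, " has < 2 samples; contrast skipped",
              call. = FALSE)
      next
    }
    sets[[paste0("within_", g)]] <- pair_values(mat, g_ids)
  }
  cross <- numeric(0)
  gl <- sort(unique(labels))
  if (length(gl) >= 2) {
    for (i in seq_len(length(gl) - 1)) {
      for (j in (i + 1):length(gl)) {
        cross <- c(cross, pair_values(mat, ids[labels == gl[i]],
                                      ids[labels == gl[j]]))
      }
    }
    sets[["cross_group"]] <- cross
  }
  if (length(sets) < 2) {
    stop("fewer than two contrastable similarity sets", call. = FALSE)
  }
  nm <- names(sets)
  out <- list()
  for (i in seq_len(length(nm) - 1)) {
    for (j in (i + 1):length(nm)) {
      a <- sets[[nm[i]]]
      b <- sets[[nm[j]]]
      p <- if (length(a) >= 2 && length(b) >= 2) wilcox_p(a, b)
           else NA_real_
      out[[length(out) + 1]] <- tibble::tibble(
        set_a = nm[i], set_b = nm[j],
        median_a = median(a), median_b = median(b),
        n_pairs_a = length(a), n_pairs_b = length(b), p = p)
    }
  }
  dplyr::bind_rows(out)
}

#' Classify a query sample against GVHD and no-GVHD libraries
#'
#' Scores the query by the median Jaccard similarity of its membership
#' profile against each library's profiles and labels it by the larger
#' median (ties, including an empty query profile, give
#' `"indeterminate"`). The p-value is a Wilcoxon rank-sum test between the
#' two sets of query-vs-library similarities.
#'
#' @param query_profile Set (character vector) for the query sample.
#' @param gvhd_profiles,nogvhd_profiles Named lists of library profiles
#'   (at least 2 each).
#' @return One-row tibble: `label` (`"GVHD"`, `"NO_GVHD"` or
#'   `"indeterminate"`), `score_gvhd`, `score_nogvhd`, `p`.
#' @export
classify_query <- function(query_profile, gvhd_profiles, nogvhd_profiles) {
  if (length(gvhd_profiles) < 2 || length(nogvhd_profiles) < 2) {
    stop("need at least 2 profiles per library", call. = FALSE)
  }
  if (length(query_profile) == 0) {
    warning("empty query profile: classification indeterminate",
            call. = FALSE)
    return(tibble::tibble(label = "indeterminate", score_gvhd = 0,
                          score_nogvhd = 0, p = NA_real_))
  }
  sims_g <- vapply(gvhd_profiles, jaccard, numeric(1), b = query_profile)
  sims_n <- vapply(nogvhd_profiles, jaccard, numeric(1), b = query_profile)
  score_g <- median(sims_g)
  score_n <- median(sims_n)
  label <- if (score_g > score_n) "GVHD"
           else if (score_n > score_g) "NO_GVHD"
           else "indeterminate"
  p <- wilcox_p(sims_g, sims_n)
  tibble::tibble(label = label, score_gvhd = score_g, score_nogvhd = score_n,
                 p = p)
}
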