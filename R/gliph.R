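# GLIPH-style specificity-group clustering.
#
# Two kinds of group are built over the pooled high-frequency CDR3s of a
# cohort: "local" groups share an interior k-mer motif enriched relative to
# a naive reference repertoire, "global" groups are connected components of
# near-identical CDR3s (equal length, interior Hamming distance <= 1).
# This is a faithful-in-spirit re-implementation, not a port of GLIPH2:
# the enrichment rule is a resampled reference null with fold and p
# thresholds, with every threshold exposed in the configuration.

#' GLIPH-style clustering configuration
#'
#' @param simulation_depth Number of reference resamples for the empirical
#'   null (default 1000).
#' @param kmer_min_depth Minimum number of distinct pool CDR3s supporting a
#'   k-mer before it is tested (default 3).
#' @param cdr3_length_cutoff Minimum CDR3 length admitted to the pool
#'   (default 8).
#' @param kmer_lengths k-mer lengths scanned (default 2, 3, 4; interiors
#'   shorter than k contribute no k-mers of that length).
#' @param min_fold_enrichment Minimum observed/expected support fold for a
#'   motif to be retained (default 10).
#' @param p_threshold Maximum empirical p (default 0.05).
#' @param interior_trim Integer pair: residues trimmed from each CDR3 end
#'   before k-mer extraction and Hamming comparison (default 3 and 3, the
#'   germline-dominated termini).
#' @param frequency_floor Per-sample clonotype frequency a clone must
#'   strictly exceed to enter the pool (default 1e-4, i.e. 0.01%).
#' @param seed RNG seed for the empirical null.
#' @return A validated list of class `gliph_config`.
#' @export
gliph_config <- function(simulation_depth = 1000L, kmer_min_depth = 3L,
                         cdr3_length_cutoff = 8L, kmer_lengths = c(2L, 3L, 4L),
                         min_fold_enrichment = 10, p_threshold = 0.05,
                         interior_trim = c(3L, 3L), frequency_floor = 1e-4,
                         seed = 1L) {
  stopifnot(simulation_depth >= 1, kmer_min_depth >= 1,
            length(interior_trim) == 2, all(interior_trim >= 0),
            all(kmer_lengths >= 1), frequency_floor >= 0,
            p_threshold > 0, p_threshold <= 1)
  if (cdr3_length_cutoff < sum(interior_trim) + 1) {
    stop("cdr3_length_cutoff must leave a non-empty interior after trimming",
         call. = FALSE)
  }
  structure(
    list(simulation_depth = as.integer(simulation_depth),
         kmer_min_depth = as.integer(kmer_min_depth),
         cdr3_length_cutoff = as.integer(cdr3_length_cutoff),
         kmer_lengths = sort(as.integer(kmer_lengths)),
         min_fold_enrichment = min_fold_enrichment,
         p_threshold = p_threshold,
         interior_trim = as.integer(interior_trim),
         frequency_floor = frequency_floor,
         seed = as.integer(seed)),
    class = "gliph_config")
}

#' Interior of a CDR3
#'
#' Drops the germline-dominated termini: the first `trim[1]` and last
#' `trim[2]` residues.
#'
#' @param cdr3_aa Character vector of CDR3 strings.
#' @param trim Integer pair (left, right).
#' @return Character vector of interiors.
#' @export
#' @examples
#' cdr3_interior("CASSIRSSYEQYF")  # "SIRSSYE"
cdr3_interior <- function(cdr3_aa, trim = c(3L, 3L)) {
  n <- nchar(cdr3_aa)
  if (any(n < sum(trim) + 1)) {
    stop("CDR3 shorter than trim + 1; callers must pre-filter by length",
         call. = FALSE)
  }
  substr(cdr3_aa, trim[1] + 1L, n - trim[2])
}

#' Select the clonotype pool for clustering
#'
#' Pools, across all samples, the clonotypes whose per-sample frequency is
#' strictly above the frequency floor (0.01% by default) and whose CDR3 is
#' at least `cdr3_length_cutoff` long.
#'
#' @param cohort List of normalized `tcr_repertoire`s.
#' @param config A [gliph_config()].
#' @return Tibble with `sample_id`, `cdr3_aa`, `v_gene`.
#' @export
select_input_clonotypes <- function(cohort, config = gliph_config()) {
  pool <- dplyr::bind_rows(lapply(cohort, function(r) {
    cl <- r$clonotypes
    keep <- cl$count / r$total_reads > config$frequency_floor &
      nchar(cl$cdr3_aa) >= config$cdr3_length_cutoff
    tibble::tibble(sample_id = r$sample_id, cdr3_aa = cl$cdr3_aa[keep],
                   v_gene = cl$v_gene[keep])
  }))
  if (nrow(pool) == 0) {
    stop("no clonotypes pass the frequency floor and length cutoff",
         call. = FALSE)
  }
  dplyr::arrange(pool, .data$sample_id, .data$cdr3_aa, .data$v_gene)
}

# Unique k-mers of one interior string (presence semantics: each k-mer at
# most once per CDR3).
kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

# (kmer, cdr3) presence pairs over a set of distinct CDR3s.
kmer_instances <- function(u_cdr3, k, trim) {
  ints <- cdr3_interior(u_cdr3, trim)
  km <- lapply(ints, kmers_of, k = k)
  lens <- lengths(km)
  list(kmer = unlist(km), cdr3 = rep.int(u_cdr3, lens))
}

# Occurrence counts of a character vector, radix-sorted (fast at millions
# of entries, unlike table()).
fast_count <- function(x) {
  if (length(x) == 0) return(integer(0))
  r <- rle(sort(x, method = "radix"))
  setNames(r$lengths, r$values)
}

#' Tabulate interior k-mers over a CDR3 pool
#'
#' Each distinct CDR3 contributes each of its interior k-mers once
#' (presence, not multiplicity). Interiors shorter than `k` contribute
#' nothing.
#'
#' @param cdr3s Character vector of CDR3s (duplicates collapsed).
#' @param k k-mer length.
#' @param trim Interior trim passed to [cdr3_interior()].
#' @return Tibble with `kmer`, `support` (number of distinct CDR3s) and a
#'   list-column `supporters` of the supporting CDR3 sets.
#' @export
kmer_table <- function(cdr3s, k, trim = c(3L, 3L)) {
  u <- unique(cdr3s)
  ints <- cdr3_interior(u, trim)
  km <- lapply(ints, kmers_of, k = k)
  lens <- lengths(km)
  if (sum(lens) == 0) {
    return(tibble::tibble(kmer = character(0), support = integer(0),
                          supporters = list()))
  }
  df <- tibble::tibble(kmer = unlist(km),
                       cdr3 = rep.int(u, lens))
  out <- df |>
    dplyr::group_by(.data$kmer) |>
    dplyr::summarise(support = dplyr::n(),
                     supporters = list(.data$cdr3), .groups = "drop") |>
    dplyr::arrange(.data$kmer)
  out
}

#' Local motif enrichment against a reference repertoire
#'
#' For every interior k-mer supported by at least `kmer_min_depth` distinct
#' pool CDR3s, compares the observed support with its distribution over
#' `simulation_depth` random reference subsets of the same CDR3 count as
#' the pool. Because subset support for a single motif is exactly
#' hypergeometric in the number of reference CDR3s carrying the motif, the
#' subset supports are drawn directly from that distribution (one stream of
#' `simulation_depth` draws per motif, in deterministic motif order).
#' The empirical p uses the add-one rule
#' `p = (1 + #(sim >= obs)) / (simulation_depth + 1)`, so `p` is never 0;
#' the fold is `obs / max(mean(sim), 1/simulation_depth)`. Motifs with
#' `fold >= min_fold_enrichment` and `p <= p_threshold` become local groups.
#'
#' @param pool Tibble from [select_input_clonotypes()] (columns
#'   `sample_id`, `cdr3_aa`, `v_gene`).
#' @param reference Character vector of reference CDR3s (e.g. from
#'   [generate_reference()]), or a `tcr_repertoire`.
#' @param config A [gliph_config()].
#' @param keep_all Return every tested motif (with `retained` flag) instead
#'   of only the retained ones — used for null-calibration diagnostics.
#' @return Tibble of motifs: `signature`, `k`, `support`,
#'   `enrichment_fold`, `p_empirical`, `retained`, plus list-column
#'   `supporters` of supporting CDR3s. Only retained rows are returned
#'   unless `keep_all = TRUE`.
#' @export
local_motif_enrichment <- function(pool, reference, config = gliph_config(),
                                   keep_all = FALSE) {
  if (is_repertoire(reference)) reference <- reference$clonotypes$cdr3_aa
  reference <- unique(reference[nchar(reference) >= config$cdr3_length_cutoff])
  u_pool <- unique(pool$cdr3_aa)
  m <- length(u_pool)
  n_ref <- length(reference)
  if (n_ref < m) {
    stop("reference (", n_ref, " CDR3s) is smaller than the sample pool (",
         m, "); cannot subsample the null", call. = FALSE)
  }
  if (n_ref < 10 * m) {
    warning("reference is less than 10x the sample pool; ",
            "empirical null will be coarse", call. = FALSE)
  }
  depth <- config$simulation_depth
  trim <- config$interior_trim

  res <- list()
  supporter_pool <- list()
  for (k in config$kmer_lengths) {
    inst <- kmer_instances(u_pool, k, trim)
    sup <- fast_count(inst$kmer)
    sup <- sup[sup >= config$kmer_min_depth]
    if (length(sup) == 0) next
    K <- fast_count(kmer_instances(reference, k, trim)$kmer)[names(sup)]
    K[is.na(K)] <- 0L
    res[[as.character(k)]] <- tibble::tibble(
      signature = names(sup), k = k, support = as.integer(sup),
      ref_carriers = as.integer(K))
    supporter_pool[[as.character(k)]] <- inst
  }
  res <- dplyr::bind_rows(res)
  if (is.null(res) || nrow(res) == 0) {
    return(tibble::tibble(signature = character(0), k = integer(0),
                          support = integer(0), ref_carriers = integer(0),
                          enrichment_fold = numeric(0),
                          p_empirical = numeric(0), retained = logical(0),
                          supporters = list()))
  }
  res <- dplyr::arrange(res, .data$k, .data$signature)
  stats_ <- with_seed(config$seed, {
    t(vapply(seq_len(nrow(res)), function(i) {
      sim <- rhyper(depth, res$ref_carriers[i], n_ref - res$ref_carriers[i], m)
      p <- (1 + sum(sim >= res$support[i])) / (depth + 1)
      fold <- res$support[i] / max(mean(sim), 1 / depth)
      c(p = p, fold = fold)
    }, c(p = 0, fold = 0)))
  })
  res$enrichment_fold <- stats_[, "fold"]
  res$p_empirical <- stats_[, "p"]
  res$retained <- res$enrichment_fold >= config$min_fold_enrichment &
    res$p_empirical <= config$p_threshold
  # supporters are materialized for retained motifs only (the ones that
  # become groups); keep_all callers get the statistics for every motif
  res$supporters <- vector("list", nrow(res))
  for (k in unique(res$k[res$retained])) {
    inst <- supporter_pool[[as.character(k)]]
    want <- res$signature[res$retained & res$k == k]
    sel <- inst$kmer %in% want
    sets <- split(inst$cdr3[sel], inst$kmer[sel])
    # signatures are globally unique (a k-mer string has length k)
    res$supporters[match(names(sets), res$signature)] <- sets
  }
  if (!keep_all) res <- res[res$retained, , drop = FALSE]
  res
}

#' Global similarity groups
#'
#' Connects CDR3s of equal length whose interiors differ at no more than
#' one position (Hamming distance <= 1 after terminal trimming); connected
#' components with at least two distinct CDR3s become groups. The
#' implementation buckets interiors by single-position wildcard masks, so
#' it is exactly equivalent to all-pairs Hamming comparison.
#'
#' @param pool Tibble from [select_input_clonotypes()].
#' @param config A [gliph_config()].
#' @return Tibble of groups: `signature` (lexicographically smallest member
#'   CDR3) and list-column `members_cdr3` of the component's CDR3s.
#' @export
global_similarity_groups <- function(pool, config = gliph_config()) {
  u <- sort(unique(pool$cdr3_aa))
  if (length(u) < 2) {
    return(tibble::tibble(signature = character(0), members_cdr3 = list()))
  }
  ints <- cdr3_interior(u, config$interior_trim)
  len <- nchar(u)
  li <- nchar(ints)
  # one masked key per interior position; same full length required
  keys <- unlist(lapply(seq_along(u), function(i) {
    L <- li[i]
    masked <- vapply(seq_len(L), function(j) {
      s <- ints[i]
      substr(s, j, j) <- "*"
      s
    }, character(1))
    paste0(len[i], ":", seq_len(L), ":", masked)
  }))
  ids <- rep.int(seq_along(u), li)
  o <- order(keys, method = "radix")
  keys <- keys[o]
  ids <- ids[o]
  first <- !duplicated(keys)
  head_id <- ids[first][cumsum(first)]
  sel <- head_id != ids
  if (!any(sel)) {
    return(tibble::tibble(signature = character(0), members_cdr3 = list()))
  }
  g <- igraph::graph_from_edgelist(
    cbind(as.character(head_id[sel]), as.character(ids[sel])),
    directed = FALSE)
  comp <- igraph::components(g)
  member_ids <- split(as.integer(igraph::V(g)$name), comp$membership)
  member_ids <- member_ids[lengths(member_ids) >= 2]
  groups <- lapply(member_ids, function(idx) sort(u[idx]))
  sigs <- vapply(groups, `[`, character(1), 1)
  ord <- order(sigs, method = "radix")
  tibble::tibble(signature = sigs[ord], members_cdr3 = groups[ord])
}

#' Build GLIPH-style specificity groups for a cohort
#'
#' Runs pool selection, local motif enrichment against the reference, and
#' global near-identity clustering, and returns the union with stable
#' deterministic group identifiers (`local:<motif>` / `global:<signature>`)
#' plus a long membership table.
#'
#' @param cohort List of normalized `tcr_repertoire`s.
#' @param reference Reference CDR3 pool (character vector or
#'   `tcr_repertoire`).
#' @param config A [gliph_config()].
#' @return List of class `gliph_result` with `groups` (one row per group:
#'   `group_id`, `kind`, `signature`, `enrichment_fold`, `p_empirical`,
#'   `n_members`) and `members` (`group_id`, `sample_id`, `cdr3_aa`,
#'   `v_gene`).
#' @export
build_gliph_groups <- function(cohort, reference, config = gliph_config()) {
  pool <- select_input_clonotypes(cohort, config)
  local <- local_motif_enrichment(pool, reference, config)
  global <- global_similarity_groups(pool, config)

  trim <- config$interior_trim
  members_local <- if (nrow(local) > 0) {
    dplyr::bind_rows(lapply(seq_len(nrow(local)), function(i) {
      sup <- local$supporters[[i]]
      rows <- pool[pool$cdr3_aa %in% sup, , drop = FALSE]
      rows$group_id <- paste0("local:", local$signature[i])
      rows
    }))
  } else NULL
  members_global <- if (nrow(global) > 0) {
    dplyr::bind_rows(lapply(seq_len(nrow(global)), function(i) {
      rows <- pool[pool$cdr3_aa %in% global$members_cdr3[[i]], , drop = FALSE]
      rows$group_id <- paste0("global:", global$signature[i])
      rows
    }))
  } else NULL
  members <- dplyr::bind_rows(members_local, members_global)
  if (is.null(members) || nrow(members) == 0) {
    members <- tibble::tibble(group_id = character(0),
                              sample_id = character(0),
                              cdr3_aa = character(0), v_gene = character(0))
  } else {
    members <- members |>
      dplyr::distinct(.data$group_id, .data$sample_id, .data$cdr3_aa,
                      .data$v_gene) |>
      dplyr::arrange(.data$group_id, .data$sample_id, .data$cdr3_aa,
                     .data$v_gene)
  }
  groups <- dplyr::bind_rows(
    if (nrow(local) > 0) tibble::tibble(
      group_id = paste0("local:", local$signature), kind = "local",
      signature = local$signature,
      enrichment_fold = local$enrichment_fold,
      p_empirical = local$p_empirical),
    if (nrow(global) > 0) tibble::tibble(
      group_id = paste0("global:", global$signature), kind = "global",
      signature = global$signature,
      enrichment_fold = NA_real_, p_empirical = NA_real_))
  if (is.null(groups) || nrow(groups) == 0) {
    groups <- tibble::tibble(group_id = character(0), kind = character(0),
                             signature = character(0),
                             enrichment_fold = numeric(0),
                             p_empirical = numeric(0))
  }
  n_members <- table(members$group_id)
  groups$n_members <- as.integer(n_members[groups$group_id])
  groups$n_members[is.na(groups$n_members)] <- 0L
  groups <- dplyr::arrange(groups, .data$group_id)
  structure(list(groups = groups, members = members, config = config),
            class = "gliph_result")
}

#' @export
print.gliph_result <- function(x, ...) {
  cat(sprintf("<gliph_result> %d groups (%d local, %d global), %d memberships\n",
              nrow(x$groups), sum(x$groups$kind == "local"),
              sum(x$groups$kind == "global"), nrow(x$members)))
  invisible(x)
}
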