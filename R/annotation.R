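# Intersection of high-frequency clones with annotated CDR3 databases
# (tissue-derived GVHD sets, pathogen-specific sets) and per-sample clonal
# sharing scores.

#' High-frequency clones of a repertoire
#'
#' Clonotypes whose frequency is strictly above `floor` (0.01% by
#' default).
#'
#' @param rep A `tcr_repertoire`.
#' @param floor Exclusive frequency floor.
#' @return Tibble of clonotypes (with a derived `frequency` column).
#' @export
high_frequency_clones <- function(rep, floor = 1e-4) {
  stopifnot(is_repertoire(rep))
  cl <- rep$clonotypes
  cl$frequency <- cl$count / rep$total_reads
  cl[cl$frequency > floor, , drop = FALSE]
}

#' Score clonal sharing with an annotation set
#'
#' Intersects the repertoire's high-frequency clone CDR3s with the
#' annotation CDR3s (exact, case-normalized string match; no substring
#' matching) and sums the matched clones' read frequencies. With
#' `match_on = "cdr3_v"` the V segment must also agree.
#'
#' @param rep A normalized `tcr_repertoire`.
#' @param annotations Tibble from [read_annotation_table()] (columns
#'   `cdr3_aa`, `antigen_species`, optionally `v_gene`).
#' @param match_on `"cdr3"` (default) or `"cdr3_v"`.
#' @param floor Frequency floor for [high_frequency_clones()].
#' @return List with `n_shared` (matched clonotypes), `summed_frequency`
#'   (total matched read fraction), `matched` (tibble of matched clones
#'   with their species), and `by_species` (per-antigen-species breakdown).
#' @export
shared_clone_score <- function(rep, annotations,
                               match_on = c("cdr3", "cdr3_v"),
                               floor = 1e-4) {
  match_on <- match.arg(match_on)
  hf <- high_frequency_clones(rep, floor)
  if (nrow(annotations) == 0) {
    warning("empty annotation set: score 0", call. = FALSE)
    return(list(n_shared = 0L, summed_frequency = 0,
                matched = hf[0, ],
                by_species = tibble::tibble(antigen_species = character(0),
                                            n_shared = integer(0),
                                            summed_frequency = numeric(0))))
  }
  ann <- annotations
  ann$cdr3_aa <- toupper(ann$cdr3_aa)
  matched <- if (match_on == "cdr3") {
    dplyr::inner_join(hf, dplyr::distinct(ann, .data$cdr3_aa,
                                          .data$antigen_species),
                      by = "cdr3_aa", relationship = "many-to-many")
  } else {
    dplyr::inner_join(hf,
                      dplyr::distinct(ann, .data$cdr3_aa, .data$v_gene,
                                      .data$antigen_species),
                      by = c("cdr3_aa", "v_gene"),
                      relationship = "many-to-many")
  }
  uniq <- dplyr::distinct(matched, .data$cdr3_aa, .data$v_gene,
                          .data$j_gene, .keep_all = TRUE)
  by_species <- matched |>
    dplyr::group_by(.data$antigen_species) |>
    dplyr::summarise(n_shared = dplyr::n_distinct(.data$cdr3_aa, .data$v_gene,
                                                  .data$j_gene),
                     summed_frequency = sum(.data$frequency[!duplicated(
                       paste(.data$cdr3_aa, .data$v_gene, .data$j_gene))]),
                     .groups = "drop")
  list(n_shared = nrow(uniq),
       summed_frequency = sum(uniq$frequency),
       matched = matched,
       by_species = by_species)
}

#' Cohort-level annotation report
#'
#' Scores every sample against every annotation set and, when group labels
#' are available, adds a Wilcoxon rank-sum comparison of the summed shared
#' frequencies between the requested pair of groups.
#'
#' @param cohort List of normalized `tcr_repertoire`s.
#' @param annotation_sets Named list of annotation tibbles.
#' @param match_on,floor Passed to [shared_clone_score()].
#' @param contrast Character pair of group labels to test (default GVHD vs
#'   NO_GVHD); skipped when either group has fewer than 2 samples.
#' @return List with `per_sample` (one row per sample x set: `n_shared`,
#'   `summed_frequency`) and `tests` (one row per set: rank-sum statistic
#'   and p for the contrast, or zero rows when not testable).
#' @export
cohort_annotation_report <- function(cohort, annotation_sets,
                                     match_on = "cdr3", floor = 1e-4,
                                     contrast = c("GVHD", "NO_GVHD")) {
  stopifnot(length(annotation_sets) > 0, !is.null(names(annotation_sets)))
  per_sample <- dplyr::bind_rows(lapply(cohort, function(r) {
    dplyr::bind_rows(lapply(names(annotation_sets), function(set) {
      sc <- shared_clone_score(r, annotation_sets[[set]],
                               match_on = match_on, floor = floor)
      tibble::tibble(sample_id = r$sample_id, group = r$group,
                     annotation_set = set, n_shared = sc$n_shared,
                     summed_frequency = sc$summed_frequency)
    }))
  }))
  tests <- list()
  for (set in names(annotation_sets)) {
    sub <- per_sample[per_sample$annotation_set == set, , drop = FALSE]
    a <- sub$summed_frequency[!is.na(sub$group) & sub$group == contrast[1]]
    b <- sub$summed_frequency[!is.na(sub$group) & sub$group == contrast[2]]
    if (length(a) >= 2 && length(b) >= 2) {
      ht <- suppressWarnings(stats::wilcox.test(a, b))
      tests[[set]] <- tibble::tibble(
        annotation_set = set, group_a = contrast[1], group_b = contrast[2],
        median_a = median(a), median_b = median(b),
        statistic = unname(ht$statistic), p = ht$p.value)
    }
  }
  tests <- if (length(tests) > 0) dplyr::bind_rows(tests) else
    tibble::tibble(annotation_set = character(0), group_a = character(0),
                   group_b = character(0), median_a = numeric(0),
                   median_b = numeric(0), statistic = numeric(0),
                   p = numeric(0))
  list(per_sample = per_sample, tests = tests)
}
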