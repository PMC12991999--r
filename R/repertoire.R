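# The repertoire container: one sample's clonotype table plus metadata.
# Clonotype identity key is (cdr3_aa, v_gene, j_gene); frequency is never
# stored, always derived from counts, so downsampling and merging stay exact.

#' Construct a TCR repertoire
#'
#' A repertoire is one sample's collection of clonotypes — unique
#' (CDR3 amino acid, V segment, J segment) keys with read counts — plus the
#' subject/group/stage metadata every downstream statistic needs. Duplicate
#' keys in `clonotypes` are merged by summing counts; gene names are
#' allele-stripped; total reads are derived.
#'
#' @param clonotypes Data frame with columns `cdr3_aa`, `v_gene`, `j_gene`,
#'   `count` (non-negative integers). An optional `cdr3_nt` column is carried
#'   through.
#' @param sample_id Sample identifier.
#' @param subject_id Subject identifier (defaults to `sample_id`).
#' @param chain `"TRA"` or `"TRB"`.
#' @param group Cohort group label, one of `"GVHD"`, `"NO_GVHD"`, `"HI"`,
#'   `"GVHD_PRE"`, or `NA`.
#' @param stage Optional disease stage (0 = pre-GVHD, 1 = active GVHD,
#'   2 = resolved), or `NA`.
#' @param donor_age Optional donor age in years.
#' @return An object of class `tcr_repertoire`: a list with the clonotype
#'   tibble (`clonotypes`), `total_reads`, and the metadata fields.
#' @export
#' @examples
#' rep <- new_repertoire(
#'   data.frame(cdr3_aa = c("CASSLGQYF", "CASSLGQYF", "CARDSNQPQHF"),
#'              v_gene = "TRBV15", j_gene = "TRBJ2-1", count = c(10, 5, 1)),
#'   sample_id = "S1")
#' rep$total_reads
new_repertoire <- function(clonotypes, sample_id, subject_id = sample_id,
                           chain = c("TRB", "TRA"), group = NA_character_,
                           stage = NA_integer_, donor_age = NA_integer_) {
  chain <- match.arg(chain)
  stopifnot(is.data.frame(clonotypes))
  required <- c("cdr3_aa", "v_gene", "j_gene", "count")
  missing_cols <- setdiff(required, names(clonotypes))
  if (length(missing_cols) > 0) {
    stop("clonotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cl <- tibble::as_tibble(clonotypes[intersect(
    c("cdr3_aa", "cdr3_nt", "v_gene", "j_gene", "count"), names(clonotypes))])
  if (!all(valid_cdr3(cl$cdr3_aa))) {
    stop("invalid CDR3 amino-acid string(s) in clonotype table", call. = FALSE)
  }
  if (any(is.na(cl$count)) || any(cl$count < 0)) {
    stop("clonotype counts must be non-negative", call. = FALSE)
  }
  cl$count <- as.integer(round(cl$count))
  cl$v_gene <- strip_allele(cl$v_gene)
  cl$j_gene <- strip_allele(cl$j_gene)
  cl <- cl |>
    dplyr::group_by(.data$cdr3_aa, .data$v_gene, .data$j_gene) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$count > 0) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$cdr3_aa, .data$v_gene,
                   .data$j_gene)
  if (nrow(cl) == 0) {
    stop("repertoire '", sample_id, "' has no clonotypes with positive counts",
         call. = FALSE)
  }
  if (!is.na(group)) {
    group <- match.arg(group, c("GVHD", "NO_GVHD", "HI", "GVHD_PRE"))
  }
  structure(
    list(sample_id = sample_id,
         subject_id = subject_id,
         chain = chain,
         group = group,
         stage = if (is.na(stage)) NA_integer_ else as.integer(stage),
         donor_age = donor_age,
         clonotypes = cl,
         total_reads = sum(cl$count)),
    class = "tcr_repertoire")
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> %s (%s)\n", x$sample_id, x$chain))
  cat(sprintf("  subject: %s  group: %s  stage: %s\n",
              x$subject_id, x$group,
              ifelse(is.na(x$stage), "-", x$stage)))
  cat(sprintf("  clonotypes: %d  total reads: %d\n",
              nrow(x$clonotypes), x$total_reads))
  invisible(x)
}

is_repertoire <- function(x) inherits(x, "tcr_repertoire")

# Replace the clonotype table of a repertoire, revalidating derived fields.
update_clonotypes <- function(rep, clonotypes) {
  new_repertoire(clonotypes, sample_id = rep$sample_id,
                 subject_id = rep$subject_id, chain = rep$chain,
                 group = rep$group, stage = rep$stage,
                 donor_age = rep$donor_age)
}

# Fast path for operations that only rescale existing counts (keys stay
# unique): drop zeros, re-sort, recompute the total. No re-validation.
rebuild_counts <- function(rep, counts) {
  cl <- rep$clonotypes
  cl$count <- as.integer(counts)
  cl <- cl[cl$count > 0, , drop = FALSE]
  if (nrow(cl) == 0) {
    stop("repertoire '", rep$sample_id, "' lost all clonotypes",
         call. = FALSE)
  }
  ord <- order(-cl$count, cl$cdr3_aa, cl$v_gene, cl$j_gene, method = "radix")
  rep$clonotypes <- cl[ord, , drop = FALSE]
  rep$total_reads <- sum(rep$clonotypes$count)
  rep
}

#' Cohort manifest
#'
#' Summarise a cohort (a list of repertoires) as one row per sample, the
#' table every pipeline stage passes to the next.
#'
#' @param cohort List of `tcr_repertoire` objects.
#' @return A tibble with `sample_id`, `subject_id`, `chain`, `group`, `stage`,
#'   `richness` (unique clonotypes) and `total_reads`.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(all(vapply(cohort, is_repertoire, logical(1))))
  dplyr::bind_rows(lapply(cohort, function(r) {
    tibble::tibble(sample_id = r$sample_id, subject_id = r$subject_id,
                   chain = r$chain, group = r$group, stage = r$stage,
                   richness = nrow(r$clonotypes), total_reads = r$total_reads)
  }))
}
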