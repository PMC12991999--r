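# Ingestion and serialization of clonotype and annotation tables.
# Two clonotype dialects are supported: the AIRR Rearrangement TSV standard
# (junction_aa / v_call / j_call / duplicate_count / productive) and a
# simplified 5-column dialect (cdr3_aa, v_gene, j_gene, count, chain).
# All files are UTF-8, tab-delimited, header mandatory.

read_tsv_quiet <- function(path, col_types = readr::cols()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = c("", "NA"))
}

airr_truthy <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(trimws(as.character(x))) %in% c("t", "true", "yes", "y", "1")
}

#' Read an AIRR Rearrangement table
#'
#' Ingests one sample's clonotypes from an AIRR Rearrangement TSV. Only
#' productive rows whose `junction_aa` passes the amino-acid alphabet check
#' are kept; duplicate (CDR3, V, J) keys are merged by summing counts; gene
#' calls are allele-stripped. Counts are taken from `duplicate_count`,
#' falling back to `consensus_count`. The number of rows dropped by the
#' productive and alphabet filters is reported via a message.
#'
#' @param path Path to the TSV file.
#' @param sample_id Sample identifier (defaults to the file name without
#'   extension).
#' @param chain_filter Optional `"TRA"` or `"TRB"`: keep only rows whose
#'   V call has that locus prefix.
#' @param ... Further metadata passed to [new_repertoire()] (`subject_id`,
#'   `group`, `stage`, `donor_age`).
#' @return A [new_repertoire()] object.
#' @export
read_airr_table <- function(path, sample_id = NULL, chain_filter = NULL, ...) {
  tab <- read_tsv_quiet(path)
  count_col <- intersect(c("duplicate_count", "consensus_count"), names(tab))[1]
  required <- c("junction_aa", "v_call", "j_call", "productive")
  missing_cols <- setdiff(required, names(tab))
  if (is.na(count_col)) missing_cols <- c(missing_cols, "duplicate_count")
  if (length(missing_cols) > 0) {
    stop("AIRR table ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (count_col == "consensus_count") {
    message("read_airr_table: using consensus_count (no duplicate_count in ",
            basename(path), ")")
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))

  n_in <- nrow(tab)
  tab <- tab[airr_truthy(tab$productive), , drop = FALSE]
  if (nrow(tab) == 0) {
    stop("AIRR table ", path, " contains no productive rows", call. = FALSE)
  }
  n_productive <- nrow(tab)
  keep <- valid_cdr3(tab$junction_aa)
  tab <- tab[keep, , drop = FALSE]
  n_dropped <- (n_in - n_productive) + sum(!keep)
  if (n_dropped > 0) {
    message("read_airr_table: dropped ", n_dropped, " row(s) (",
            n_in - n_productive, " non-productive, ", sum(!keep),
            " failing the CDR3 alphabet check) from ", basename(path))
  }
  if (nrow(tab) == 0) {
    stop("AIRR table ", path, " has no rows left after CDR3 alphabet check",
         call. = FALSE)
  }

  chain <- "TRB"
  if (!is.null(chain_filter)) {
    chain_filter <- match.arg(chain_filter, c("TRA", "TRB"))
    tab <- tab[startsWith(strip_allele(tab$v_call), chain_filter), ,
               drop = FALSE]
    if (nrow(tab) == 0) {
      stop("AIRR table ", path, " has no ", chain_filter, " rows",
           call. = FALSE)
    }
    chain <- chain_filter
  } else if (all(startsWith(strip_allele(tab$v_call), "TRA"))) {
    chain <- "TRA"
  }

  new_repertoire(
    data.frame(cdr3_aa = tab$junction_aa, v_gene = tab$v_call,
               j_gene = tab$j_call, count = tab[[count_col]]),
    sample_id = sample_id, chain = chain, ...)
}

#' Read a simplified clonotype table
#'
#' The simplified dialect has exactly the columns `cdr3_aa`, `v_gene`,
#' `j_gene`, `count`, `chain` and assumes every row is productive. Counts
#' must be non-negative integers.
#'
#' @inheritParams read_airr_table
#' @return A [new_repertoire()] object.
#' @export
read_simple_table <- function(path, sample_id = NULL, ...) {
  tab <- read_tsv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("cdr3_aa", "v_gene", "j_gene", "count", "chain")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("simple clonotype table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- suppressWarnings(as.numeric(tab$count))
  bad <- is.na(n) | n < 0 | n != floor(n)
  if (any(bad)) {
    stop("simple clonotype table ", path, ": invalid count '",
         tab$count[which(bad)[1]], "' at line ", which(bad)[1] + 1L,
         call. = FALSE)
  }
  chain <- unique(tab$chain)
  if (length(chain) != 1 || !chain %in% c("TRA", "TRB")) {
    stop("simple clonotype table ", path,
         " must have a single chain, TRA or TRB", call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  new_repertoire(
    data.frame(cdr3_aa = tab$cdr3_aa, v_gene = tab$v_gene,
               j_gene = tab$j_gene, count = as.integer(n)),
    sample_id = sample_id, chain = chain, ...)
}

#' Write a repertoire as a simplified clonotype table
#'
#' Serializes to the 5-column dialect so that
#' `read_simple_table(write_repertoire(R))` reproduces `R` up to clonotype
#' order.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  stopifnot(is_repertoire(rep))
  out <- tibble::tibble(cdr3_aa = rep$clonotypes$cdr3_aa,
                        v_gene = rep$clonotypes$v_gene,
                        j_gene = rep$clonotypes$j_gene,
                        count = rep$clonotypes$count,
                        chain = rep$chain)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an annotated TCR table
#'
#' Reads antigen- or tissue-annotated CDR3 tables in either the VDJdb export
#' dialect (columns `cdr3`, `antigen.species`, `gene`, optional `v.segm` /
#' `j.segm`) or a simple dialect (`cdr3_aa`, `antigen_species`, optional
#' `v_gene`, `j_gene`). Records are deduplicated on
#' (`cdr3_aa`, `antigen_species`); rows failing the CDR3 alphabet check are
#' dropped with a message.
#'
#' @param path Path to the TSV file.
#' @param dialect `"vdjdb"` or `"simple"`.
#' @return A tibble of annotation records with columns `cdr3_aa`,
#'   `antigen_species`, `v_gene`, `j_gene`, `source`.
#' @export
read_annotation_table <- function(path, dialect = c("vdjdb", "simple")) {
  dialect <- match.arg(dialect)
  tab <- read_tsv_quiet(path)
  if (dialect == "vdjdb") {
    required <- c("cdr3", "antigen.species")
    if (length(setdiff(required, names(tab))) > 0) {
      stop("VDJdb table ", path, " is missing column(s): ",
           paste(setdiff(required, names(tab)), collapse = ", "),
           call. = FALSE)
    }
    rec <- tibble::tibble(
      cdr3_aa = toupper(as.character(tab$cdr3)),
      antigen_species = as.character(tab$antigen.species),
      v_gene = if ("v.segm" %in% names(tab)) strip_allele(as.character(tab$v.segm)) else NA_character_,
      j_gene = if ("j.segm" %in% names(tab)) strip_allele(as.character(tab$j.segm)) else NA_character_,
      source = "vdjdb")
  } else {
    required <- c("cdr3_aa", "antigen_species")
    if (length(setdiff(required, names(tab))) > 0) {
      stop("simple annotation table ", path, " is missing column(s): ",
           paste(setdiff(required, names(tab)), collapse = ", "),
           call. = FALSE)
    }
    rec <- tibble::tibble(
      cdr3_aa = toupper(as.character(tab$cdr3_aa)),
      antigen_species = as.character(tab$antigen_species),
      v_gene = if ("v_gene" %in% names(tab)) strip_allele(as.character(tab$v_gene)) else NA_character_,
      j_gene = if ("j_gene" %in% names(tab)) strip_allele(as.character(tab$j_gene)) else NA_character_,
      source = "simple")
  }
  if (nrow(rec) == 0) {
    warning("annotation table ", path, " is empty", call. = FALSE)
    return(rec)
  }
  keep <- valid_cdr3(rec$cdr3_aa)
  if (any(!keep)) {
    message("read_annotation_table: dropped ", sum(!keep),
            " record(s) failing the CDR3 alphabet check")
  }
  rec <- rec[keep, , drop = FALSE]
  dplyr::distinct(rec, .data$cdr3_aa, .data$antigen_species,
                  .keep_all = TRUE)
}
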