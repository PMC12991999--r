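# Depth normalization: every repertoire is down-sampled to a common number
# of productive reads before any diversity statistic is computed. Sampling
# is without replacement (multivariate hypergeometric over clonotype
# counts — realized by sampling read indices directly), the exact model of
# resampling real reads; a multinomial mode is available for speed
# comparison but is not the default.

#' Downsample a repertoire to a fixed read depth
#'
#' Draws `target_reads` reads without replacement from the repertoire's
#' reads (a multivariate hypergeometric draw over clonotype counts),
#' realized by uniformly sampling distinct read indices and mapping them
#' back to clonotypes. Clonotypes reaching zero are removed. A repertoire
#' already at or below the target is returned unchanged with a warning.
#'
#' @param rep A `tcr_repertoire`.
#' @param target_reads Target productive-read depth (default 1e6).
#' @param seed RNG seed.
#' @param method `"hypergeometric"` (without replacement, default) or
#'   `"multinomial"` (with replacement).
#' @return A `tcr_repertoire` with `total_reads == target_reads` (when the
#'   input exceeded the target).
#' @export
downsample_repertoire <- function(rep, target_reads = 1000000L, seed = 1L,
                                  method = c("hypergeometric",
                                             "multinomial")) {
  stopifnot(is_repertoire(rep))
  method <- match.arg(method)
  if (target_reads <= 0) {
    stop("target_reads must be a positive integer", call. = FALSE)
  }
  if (rep$total_reads <= target_reads) {
    if (rep$total_reads < target_reads) {
      warning("repertoire ", rep$sample_id, " has only ", rep$total_reads,
              " reads ( < target ", target_reads, "); returned unchanged",
              call. = FALSE)
    }
    return(rep)
  }
  counts <- rep$clonotypes$count
  new_counts <- with_seed(seed, {
    if (method == "multinomial") {
      as.integer(stats::rmultinom(1, target_reads, counts))
    } else {
      # draw target_reads distinct read indices uniformly and map each back
      # to its clonotype interval: an exact multivariate hypergeometric draw
      breaks <- cumsum(as.numeric(counts))
      idx <- sample.int(sum(counts), target_reads)
      tabulate(findInterval(idx - 1, breaks) + 1L, nbins = length(counts))
    }
  })
  rebuild_counts(rep, new_counts)
}

#' Normalize a cohort to a common read depth
#'
#' Applies [downsample_repertoire()] to every sample with a per-sample seed
#' derived from `(seed, sample_id)`, so results do not depend on sample
#' order. Under the `"fixed"` policy every sample is brought to
#' `target_reads` (samples below the target are retained unchanged and
#' flagged, not dropped — exclusion is the analyst's call); under `"min"`
#' the target is the smallest depth in the cohort at or above
#' `min_acceptable`.
#'
#' @param cohort List of `tcr_repertoire`s.
#' @param target_reads Fixed target depth (policy `"fixed"`).
#' @param policy `"fixed"` or `"min"`.
#' @param seed Master seed.
#' @param min_acceptable Depth below which a sample is ignored when
#'   computing the `"min"` target (no default judgment: 0 keeps everything).
#' @return A `tcr_cohort` with attribute `"normalization"`: a tibble with
#'   per-sample input/output depths and a `below_target` flag.
#' @export
normalize_cohort <- function(cohort, target_reads = 1000000L,
                             policy = c("fixed", "min"), seed = 1L,
                             min_acceptable = 0L) {
  policy <- match.arg(policy)
  depths <- vapply(cohort, function(r) r$total_reads, numeric(1))
  target <- if (policy == "fixed") {
    as.integer(target_reads)
  } else {
    eligible <- depths[depths >= min_acceptable]
    if (length(eligible) == 0) {
      stop("no sample reaches min_acceptable depth", call. = FALSE)
    }
    as.integer(min(eligible))
  }
  out <- lapply(cohort, function(r) {
    suppressWarnings(
      downsample_repertoire(r, target, seed = derive_seed(seed, r$sample_id)))
  })
  names(out) <- names(cohort)
  flags <- tibble::tibble(
    sample_id = vapply(cohort, function(r) r$sample_id, character(1)),
    reads_in = as.integer(depths),
    reads_out = vapply(out, function(r) as.integer(r$total_reads), integer(1)),
    target = target,
    below_target = as.integer(depths) < target)
  if (any(flags$below_target)) {
    warning(sum(flags$below_target),
            " sample(s) below the target depth were retained and flagged",
            call. = FALSE)
  }
  structure(out, class = c("tcr_cohort", "list"), normalization = flags)
}
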