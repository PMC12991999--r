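# Longitudinal clonotype tracking across disease stages and between-stage
# repertoire overlap (Morisita-Horn).

clonotype_keys <- function(rep) {
  paste(rep$clonotypes$cdr3_aa, rep$clonotypes$v_gene,
        rep$clonotypes$j_gene, sep = "|")
}

#' Top-N clonotypes of a repertoire
#'
#' Clonotype keys (`cdr3|v|j`) ordered by count descending, ties broken by
#' CDR3 then V gene lexicographically; returns all clonotypes when fewer
#' than `n` exist.
#'
#' @param rep A `tcr_repertoire`.
#' @param n Number of clonotypes (default 100).
#' @return Character vector of at most `n` keys, in rank order.
#' @export
top_n_clonotypes <- function(rep, n = 100L) {
  stopifnot(is_repertoire(rep))
  cl <- rep$clonotypes
  ord <- order(-cl$count, cl$cdr3_aa, cl$v_gene, method = "radix")
  keys <- paste(cl$cdr3_aa[ord], cl$v_gene[ord], cl$j_gene[ord], sep = "|")
  head(keys, n)
}

#' Track top clonotypes across stages
#'
#' Looks up the frequencies of the reference stage's top-`n` clonotypes in
#' every stage of a subject; clones absent from a stage get frequency 0 and
#' status `"absent"`. Either stage can serve as reference, mirroring
#' tracking from onset forward or from resolution backward.
#'
#' @param subject_repertoires Named list of `tcr_repertoire`s, one per
#'   stage (names are the stage labels; at least 2).
#' @param reference_stage Name of the stage supplying the top-`n` keys.
#' @param n Number of tracked clonotypes (default 100).
#' @return List of class `tracking_table`: `subject_id`,
#'   `reference_stage`, `keys` (rank-ordered), `frequencies` and `statuses`
#'   (clonotype x stage matrices), and `long` (tidy tibble with one row per
#'   key and stage).
#' @export
track_clonotypes <- function(subject_repertoires, reference_stage,
                             n = 100L) {
  stages <- names(subject_repertoires)
  if (length(stages) < 2) stop("need at least 2 stages", call. = FALSE)
  if (!reference_stage %in% stages) {
    stop("unknown reference stage '", reference_stage, "' (have: ",
         paste(stages, collapse = ", "), ")", call. = FALSE)
  }
  keys <- top_n_clonotypes(subject_repertoires[[reference_stage]], n)
  freq <- matrix(0, nrow = length(keys), ncol = length(stages),
                 dimnames = list(keys, stages))
  for (s in stages) {
    r <- subject_repertoires[[s]]
    f <- setNames(r$clonotypes$count / r$total_reads, clonotype_keys(r))
    hit <- keys %in% names(f)
    freq[hit, s] <- f[keys[hit]]
  }
  status <- ifelse(freq > 0, "present", "absent")
  long <- tibble::tibble(
    subject_id = subject_repertoires[[1]]$subject_id,
    reference_stage = reference_stage,
    rank = rep(seq_along(keys), times = length(stages)),
    clonotype = rep(keys, times = length(stages)),
    stage = rep(stages, each = length(keys)),
    frequency = as.vector(freq),
    status = as.vector(status))
  structure(list(subject_id = subject_repertoires[[1]]$subject_id,
                 reference_stage = reference_stage, keys = keys,
                 frequencies = freq, statuses = status, long = long),
            class = "tracking_table")
}

#' @export
print.tracking_table <- function(x, ...) {
  cat(sprintf("<tracking_table> subject %s, %d clonotypes (reference stage %s) x %d stages\n",
              x$subject_id, length(x$keys), x$reference_stage,
              ncol(x$frequencies)))
  invisible(x)
}

#' Morisita-Horn overlap of two count vectors
#'
#' `C = 2 sum(x_i y_i) / ((d_x + d_y) X Y)` with `X = sum(x)`,
#' `Y = sum(y)`, `d_x = sum(x^2)/X^2`, `d_y = sum(y^2)/Y^2`: the
#' frequency-based Morisita-Horn variant, in \[0, 1\], scale-invariant and
#' 1 exactly when relative abundances are identical. The classical
#' count-based Morisita index is available via `classical = TRUE`.
#'
#' @param x,y Non-negative count vectors over the same (union) clonotype
#'   keys, positionally aligned.
#' @param classical Use the classical Morisita index denominator
#'   `(sum(x(x-1))/(X(X-1)) + sum(y(y-1))/(Y(Y-1)))`.
#' @return Overlap value.
#' @export
#' @examples
#' morisita(c(2, 2), c(1, 3))  # 8/9
morisita <- function(x, y, classical = FALSE) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  X <- sum(x)
  Y <- sum(y)
  if (X == 0 || Y == 0) stop("zero-total count vector", call. = FALSE)
  num <- 2 * sum(x * y)
  if (classical) {
    if (X < 2 || Y < 2) stop("classical Morisita needs totals >= 2",
                             call. = FALSE)
    d <- sum(x * (x - 1)) / (X * (X - 1)) + sum(y * (y - 1)) / (Y * (Y - 1))
  } else {
    d <- sum(x^2) / X^2 + sum(y^2) / Y^2
  }
  num / (d * X * Y)
}

#' Between-stage Morisita-Horn similarity matrix
#'
#' Aligns every pair of stages on the union of their clonotype keys and
#' computes the Morisita-Horn overlap.
#'
#' @param subject_repertoires Named list of `tcr_repertoire`s by stage
#'   (at least 2).
#' @param classical Passed to [morisita()].
#' @return Symmetric matrix with unit diagonal, one row/column per stage.
#' @export
stage_similarity <- function(subject_repertoires, classical = FALSE) {
  stages <- names(subject_repertoires)
  if (length(stages) < 2) stop("need at least 2 stages", call. = FALSE)
  counts <- lapply(subject_repertoires, function(r) {
    setNames(r$clonotypes$count, clonotype_keys(r))
  })
  m <- diag(1, length(stages))
  dimnames(m) <- list(stages, stages)
  for (i in seq_len(length(stages) - 1)) {
    for (j in (i + 1):length(stages)) {
      keys <- union(names(counts[[i]]), names(counts[[j]]))
      x <- counts[[i]][keys]
      y <- counts[[j]][keys]
      x[is.na(x)] <- 0
      y[is.na(y)] <- 0
      v <- morisita(x, y, classical = classical)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}
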