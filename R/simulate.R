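# Synthetic cohort generator.
#
# Emulates the statistical structure the study-shaped comparisons assume:
# per-sample repertoires with power-law clone sizes, group-structured
# richness differences (GVHD > no-GVHD), shared CDR3 k-mer motifs spiked
# across designated GVHD samples, and per-subject stage dynamics in which
# the dominant clones of active disease contract upon resolution while a
# small emergent set expands. Everything is deterministic under the master
# seed; per-subject seeds are derived by hashing so adding a subject never
# perturbs the others.

#' Synthetic cohort configuration
#'
#' Builds and validates the configuration consumed by [generate_cohort()]
#' and friends. Defaults follow the study design the package targets:
#' 15 GVHD / 13 no-GVHD / 15 healthy-individual samples, a pre-normalization
#' depth of 1.2 million reads (normalized to 1 million downstream), and
#' richness ordering GVHD > HI > no-GVHD.
#'
#' @param n_per_group Named integer vector: samples per group.
#' @param richness Named integer vector: unique clonotypes per sample, by
#'   group (`GVHD_PRE` falls back to the `GVHD` value when absent).
#' @param clone_size_exponent Power-law exponent of the rank-abundance curve
#'   (`count(r)` proportional to `r^-exponent`); 0 gives a uniform repertoire.
#' @param total_reads Pre-normalization read depth per sample.
#' @param cdr3_length_mean,cdr3_length_sd CDR3 amino-acid length distribution
#'   (normal, rounded, floored at 8).
#' @param v_gene_freqs,j_gene_freqs Named probability vectors over segment
#'   names; must sum to 1 within 1e-9.
#' @param motif_panel Character vector of interior k-mers spiked into
#'   spiked-group samples (shared specificity signal).
#' @param motif_spike_fraction Fraction of each spiked sample's clonotypes
#'   carrying a panel motif.
#' @param spiked_groups Groups receiving the motif panel.
#' @param stage_dynamics List with `dominant_n`, `dominant_fold`,
#'   `emergent_n`, `emergent_fold`, `jitter_sd`: stage-transition model for
#'   [apply_stage_dynamics()].
#' @param seed Master seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(GVHD = 15L, NO_GVHD = 13L, HI = 15L),
                          richness = c(GVHD = 30000L, NO_GVHD = 10000L,
                                       HI = 25000L),
                          clone_size_exponent = 1,
                          total_reads = 1200000L,
                          cdr3_length_mean = 14.5,
                          cdr3_length_sd = 1.8,
                          v_gene_freqs = NULL,
                          j_gene_freqs = NULL,
                          motif_panel = c("QGAD", "RLWS", "NTYK"),
                          motif_spike_fraction = 0.05,
                          spiked_groups = c("GVHD", "GVHD_PRE"),
                          stage_dynamics = list(dominant_n = 20L,
                                                dominant_fold = 0.05,
                                                emergent_n = 5L,
                                                emergent_fold = 200,
                                                jitter_sd = 0.1),
                          seed = 42L) {
  if (is.null(v_gene_freqs)) {
    w <- 1 / seq_along(DEFAULT_TRBV)
    v_gene_freqs <- setNames(w / sum(w), DEFAULT_TRBV)
  }
  if (is.null(j_gene_freqs)) {
    w <- 1 / seq_along(DEFAULT_TRBJ)
    j_gene_freqs <- setNames(w / sum(w), DEFAULT_TRBJ)
  }
  stopifnot(clone_size_exponent >= 0, total_reads >= 1,
            motif_spike_fraction >= 0, motif_spike_fraction <= 1,
            cdr3_length_mean >= 8)
  if (abs(sum(v_gene_freqs) - 1) > 1e-9 || abs(sum(j_gene_freqs) - 1) > 1e-9) {
    stop("gene-frequency vectors must sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  if (length(motif_panel) > 0 && !all(valid_cdr3(motif_panel))) {
    stop("motif_panel entries must be amino-acid strings", call. = FALSE)
  }
  structure(
    list(n_per_group = n_per_group, richness = richness,
         clone_size_exponent = clone_size_exponent,
         total_reads = as.integer(total_reads),
         cdr3_length_mean = cdr3_length_mean,
         cdr3_length_sd = cdr3_length_sd,
         v_gene_freqs = v_gene_freqs, j_gene_freqs = j_gene_freqs,
         motif_panel = motif_panel,
         motif_spike_fraction = motif_spike_fraction,
         spiked_groups = spiked_groups,
         stage_dynamics = stage_dynamics,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Sample synthetic CDR3 amino-acid strings
#'
#' Draws CDR3s framed by the conserved cysteine/phenylalanine (first residue
#' `C`, last residue `F`), with interior residues from a fixed junctional
#' amino-acid profile and lengths from a rounded normal floored at 8. When
#' `forced_motif` is given it is placed at a uniformly random offset that
#' never touches the first or last 3 residues (the germline-dominated
#' termini GLIPH-style clustering trims away).
#'
#' Uses the current RNG state; wrap in `set.seed()` (or let the generator
#' functions derive seeds) for reproducibility.
#'
#' @param n Number of strings.
#' @param length_mean,length_sd Length distribution parameters.
#' @param forced_motif Optional interior motif to embed in every string.
#' @return Character vector of length `n`.
#' @export
#' @examples
#' set.seed(1)
#' sample_cdr3(3, 14, 2, forced_motif = "QGA")
sample_cdr3 <- function(n, length_mean = 14.5, length_sd = 1.8,
                        forced_motif = NULL) {
  k <- if (is.null(forced_motif)) 0L else nchar(forced_motif)
  if (!is.null(forced_motif) && !valid_cdr3(forced_motif)) {
    stop("forced_motif must be an amino-acid string", call. = FALSE)
  }
  min_len <- max(8L, k + 6L)
  if (min_len > length_mean + 4 * length_sd) {
    stop("forced_motif of length ", k,
         " does not fit the interior at the configured CDR3 lengths",
         call. = FALSE)
  }
  len <- as.integer(round(rnorm(n, length_mean, length_sd)))
  while (any(bad <- len < min_len)) {
    len[bad] <- as.integer(round(rnorm(sum(bad), length_mean, length_sd)))
  }
  chars <- sample(AA20, sum(len) - 2L * n, replace = TRUE,
                  prob = CDR3_AA_PROFILE[AA20])
  big <- paste(chars, collapse = "")
  ends <- cumsum(len - 2L)
  interiors <- substring(big, ends - (len - 2L) + 1L, ends)
  s <- paste0("C", interiors, "F")
  if (!is.null(forced_motif)) {
    # offsets 4 .. len - k - 2 keep the motif inside positions 4 .. len - 3
    off <- 4L + as.integer(floor(runif(n) * (len - k - 5L)))
    substr(s, off, off + k - 1L) <- forced_motif
  }
  s
}

# Power-law rank-abundance counts for `richness` clones summing close to
# `total_reads` (within +/- richness after rounding).
power_law_counts <- function(richness, exponent, total_reads) {
  r <- seq_len(richness)
  p <- r^(-exponent)
  p <- p / sum(p)
  counts <- round(total_reads * p)
  if (any(counts < 1)) {
    stop("infeasible richness/total_reads combination: ",
         sum(counts < 1), " rank(s) round to zero reads; ",
         "lower clone_size_exponent or richness, or raise total_reads",
         call. = FALSE)
  }
  as.integer(counts)
}

# Draw `n` clonotypes unique on (cdr3_aa, v_gene, j_gene); `motifs` is an
# optional per-clone character vector (NA = unconstrained).
draw_unique_clonotypes <- function(n, config, motifs = NULL) {
  draw <- function(m, motif) {
    if (is.na(motif)) {
      cdr3 <- sample_cdr3(m, config$cdr3_length_mean, config$cdr3_length_sd)
    } else {
      cdr3 <- sample_cdr3(m, config$cdr3_length_mean, config$cdr3_length_sd,
                          forced_motif = motif)
    }
    tibble::tibble(
      cdr3_aa = cdr3,
      v_gene = sample(names(config$v_gene_freqs), m, replace = TRUE,
                      prob = config$v_gene_freqs),
      j_gene = sample(names(config$j_gene_freqs), m, replace = TRUE,
                      prob = config$j_gene_freqs))
  }
  if (is.null(motifs)) motifs <- rep(NA_character_, n)
  cl <- tibble::tibble(cdr3_aa = character(n), v_gene = character(n),
                       j_gene = character(n))
  for (mo in unique(motifs)) {
    idx <- if (is.na(mo)) which(is.na(motifs)) else which(!is.na(motifs) & motifs == mo)
    cl[idx, ] <- draw(length(idx), mo)
  }
  key <- paste(cl$cdr3_aa, cl$v_gene, cl$j_gene, sep = "|")
  while (anyDuplicated(key) > 0) {
    dup <- which(duplicated(key))
    redraw <- dplyr::bind_rows(lapply(dup, function(i) draw(1L, motifs[i])))
    cl[dup, ] <- redraw
    key <- paste(cl$cdr3_aa, cl$v_gene, cl$j_gene, sep = "|")
  }
  cl
}

#' Generate one synthetic repertoire
#'
#' Draws `richness[group]` unique clonotypes with power-law rank-abundance
#' counts summing to the configured depth (within rounding), and — for
#' samples in a spiked group — embeds the motif panel into
#' `round(motif_spike_fraction * richness)` clonotypes at ranks chosen
#' uniformly at random (panel motifs cycled over the spiked clones).
#'
#' @param config A [cohort_config()].
#' @param group Group label (must be a name of `config$richness`, or
#'   `"GVHD_PRE"` which falls back to the `GVHD` richness).
#' @param subject_id Subject identifier.
#' @param stage Optional stage label.
#' @param seed Seed for this repertoire (default derived from the master
#'   seed and the subject/stage labels).
#' @return A `tcr_repertoire`.
#' @export
generate_repertoire <- function(config, group, subject_id,
                                stage = NA_integer_,
                                seed = derive_seed(config$seed,
                                                   paste(group, subject_id,
                                                         stage))) {
  stopifnot(inherits(config, "cohort_config"))
  rich_group <- if (group %in% names(config$richness)) group
                else if (group == "GVHD_PRE") "GVHD"
                else stop("no richness configured for group ", group,
                          call. = FALSE)
  richness <- as.integer(config$richness[[rich_group]])
  counts <- power_law_counts(richness, config$clone_size_exponent,
                             config$total_reads)
  with_seed(seed, {
    motifs <- rep(NA_character_, richness)
    if (group %in% config$spiked_groups && length(config$motif_panel) > 0 &&
        config$motif_spike_fraction > 0) {
      n_spike <- round(config$motif_spike_fraction * richness)
      if (n_spike > 0) {
        at <- sample.int(richness, n_spike)
        # motifs drawn with replacement so each sample carries its own
        # random subset of the panel (public motifs, private composition)
        motifs[at] <- sample(config$motif_panel, n_spike, replace = TRUE)
      }
    }
    cl <- draw_unique_clonotypes(richness, config, motifs)
    cl$count <- counts
    sample_id <- if (is.na(stage)) subject_id
                 else paste0(subject_id, "_s", stage)
    new_repertoire(cl, sample_id = sample_id, subject_id = subject_id,
                   chain = "TRB", group = group, stage = stage)
  })
}

#' Generate a labeled synthetic cohort
#'
#' One repertoire per (group, subject), with per-subject RNG streams derived
#' from the master seed by hashing, so adding or removing a subject never
#' changes any other subject's repertoire.
#'
#' @param config A [cohort_config()].
#' @return A named list of `tcr_repertoire` objects (class `tcr_cohort`),
#'   keyed by sample id.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  reps <- list()
  for (group in names(config$n_per_group)) {
    n <- config$n_per_group[[group]]
    if (n <= 0) next
    for (i in seq_len(n)) {
      subject_id <- sprintf("%s_%02d", group, i)
      r <- generate_repertoire(config, group, subject_id)
      reps[[r$sample_id]] <- r
    }
  }
  structure(reps, class = c("tcr_cohort", "list"))
}

#' @export
print.tcr_cohort <- function(x, ...) {
  m <- cohort_manifest(x)
  cat(sprintf("<tcr_cohort> %d samples\n", nrow(m)))
  print(table(m$group))
  invisible(x)
}

#' Advance a repertoire one disease stage
#'
#' Models the longitudinal dynamics seen across GVHD progression and
#' resolution: the current dominant clone set (top `dominant_n` by count)
#' is multiplied by `dominant_fold` (e.g. 0.05 for contraction at
#' resolution), a small emergent set — the `emergent_n` ranks immediately
#' below the dominants — is multiplied by `emergent_fold` (new expansions
#' after resolution), all remaining clones get mild lognormal jitter, and
#' the result is rescaled to `total_reads`. Clones whose count rounds to
#' zero are removed.
#'
#' With `dominant_fold = 1`, `emergent_fold = 1`, `jitter_sd = 0` the
#' repertoire is returned unchanged apart from the stage label.
#'
#' @param rep A `tcr_repertoire`.
#' @param stage_to Stage label of the output.
#' @param dominant_n,dominant_fold Size and fold-change of the dominant set.
#' @param emergent_n,emergent_fold Size and fold-change of the emergent set.
#' @param jitter_sd Lognormal sigma applied to all other clones.
#' @param total_reads Target depth of the output (default: input depth).
#' @param seed RNG seed.
#' @return A `tcr_repertoire` at `stage_to`.
#' @export
apply_stage_dynamics <- function(rep, stage_to,
                                 dominant_n = 20L, dominant_fold = 0.05,
                                 emergent_n = 0L, emergent_fold = 1,
                                 jitter_sd = 0.1,
                                 total_reads = rep$total_reads,
                                 seed = derive_seed(1L, paste(rep$sample_id,
                                                              stage_to))) {
  stopifnot(is_repertoire(rep))
  if (dominant_fold < 0 || emergent_fold < 0) {
    stop("fold-changes must be non-negative", call. = FALSE)
  }
  cl <- rep$clonotypes  # already sorted by count desc, deterministic ties
  n <- nrow(cl)
  dn <- min(dominant_n, n)
  em <- if (emergent_n > 0) seq_len(min(emergent_n, max(0, n - dn))) + dn
        else integer(0)
  with_seed(seed, {
    w <- as.numeric(cl$count)
    w[seq_len(dn)] <- w[seq_len(dn)] * dominant_fold
    if (length(em) > 0) w[em] <- w[em] * emergent_fold
    rest <- setdiff(seq_len(n), c(seq_len(dn), em))
    if (jitter_sd > 0 && length(rest) > 0) {
      w[rest] <- w[rest] * exp(rnorm(length(rest), 0, jitter_sd))
    }
    if (sum(w) == 0) stop("all clones extinguished", call. = FALSE)
    new_counts <- round(w * total_reads / sum(w))
    out <- cl
    out$count <- as.integer(new_counts)
    out <- out[out$count > 0, , drop = FALSE]
    r <- update_clonotypes(rep, out)
    r$stage <- as.integer(stage_to)
    r$sample_id <- paste0(rep$subject_id, "_s", stage_to)
    r
  })
}

#' Generate a subject's multi-stage course
#'
#' Produces the stage-0 (pre-GVHD), stage-1 (active GVHD) and stage-2
#' (resolved) repertoires of one subject: stage 1 is stage 0 with mild
#' jitter only (the pre-onset and active repertoires share their dominant
#' clones), and stage 2 applies the configured stage dynamics (dominant
#' contraction plus emergent expansion).
#'
#' @param config A [cohort_config()].
#' @param subject_id Subject identifier.
#' @param seed Seed (default derived from the master seed).
#' @return Named list of three `tcr_repertoire`s (`"0"`, `"1"`, `"2"`).
#' @export
generate_subject_course <- function(config, subject_id,
                                    seed = derive_seed(config$seed,
                                                       subject_id)) {
  sd_ <- config$stage_dynamics
  s0 <- generate_repertoire(config, "GVHD_PRE", subject_id, stage = 0L,
                            seed = seed)
  s1 <- apply_stage_dynamics(s0, stage_to = 1L, dominant_n = 0L,
                             dominant_fold = 1, emergent_n = 0L,
                             emergent_fold = 1, jitter_sd = sd_$jitter_sd,
                             seed = derive_seed(seed, "stage1"))
  s2 <- apply_stage_dynamics(s1, stage_to = 2L,
                             dominant_n = sd_$dominant_n,
                             dominant_fold = sd_$dominant_fold,
                             emergent_n = sd_$emergent_n,
                             emergent_fold = sd_$emergent_fold,
                             jitter_sd = sd_$jitter_sd,
                             seed = derive_seed(seed, "stage2"))
  list("0" = s0, "1" = s1, "2" = s2)
}

#' Generate a naive reference repertoire
#'
#' Large, motif-free pool of unique CDR3s used as the enrichment null for
#' GLIPH-style local motif testing. Any CDR3 containing one of
#' `exclude_motifs` (by default the configured spike panel) is rejected, so
#' the reference is guaranteed free of the cohort's shared-specificity
#' signal.
#'
#' @param n Number of unique CDR3s.
#' @param config A [cohort_config()] supplying length parameters and the
#'   default exclusion panel.
#' @param exclude_motifs Motifs that must not occur in the reference.
#' @param seed RNG seed.
#' @return Character vector of `n` unique CDR3 strings.
#' @export
generate_reference <- function(n, config = cohort_config(),
                               exclude_motifs = config$motif_panel,
                               seed = derive_seed(config$seed, "reference")) {
  with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      cand <- sample_cdr3(n - length(out) + 1000L, config$cdr3_length_mean,
                          config$cdr3_length_sd)
      if (length(exclude_motifs) > 0) {
        hit <- Reduce(`|`, lapply(exclude_motifs, function(m)
          grepl(m, cand, fixed = TRUE)))
        cand <- cand[!hit]
      }
      out <- unique(c(out, cand))
    }
    out[seq_len(n)]
  })
}

#' Write a cohort to disk
#'
#' One simplified clonotype TSV per sample plus a `manifest.tsv`
#' (sample_id, subject_id, group, stage, path). Paths in the manifest are
#' relative to `dir` so the output tree is relocatable.
#'
#' @param cohort List of `tcr_repertoire`s.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort_manifest(cohort)
  man$path <- paste0(man$sample_id, ".tsv")
  for (r in cohort) {
    write_repertoire(r, file.path(dir, paste0(r$sample_id, ".tsv")))
  }
  readr::write_tsv(man, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(man)
}

#' Read a cohort from a manifest
#'
#' Inverse of [write_cohort()]: reads every simplified clonotype table listed
#' in a manifest TSV and restores sample metadata.
#'
#' @param manifest_path Path to `manifest.tsv`.
#' @return A `tcr_cohort` list.
#' @export
read_cohort <- function(manifest_path) {
  man <- read_tsv_quiet(manifest_path)
  base <- dirname(manifest_path)
  reps <- lapply(seq_len(nrow(man)), function(i) {
    read_simple_table(file.path(base, man$path[i]),
                      sample_id = man$sample_id[i],
                      subject_id = man$subject_id[i],
                      group = if (is.na(man$group[i])) NA_character_ else man$group[i],
                      stage = if ("stage" %in% names(man)) man$stage[i] else NA_integer_)
  })
  names(reps) <- man$sample_id
  structure(reps, class = c("tcr_cohort", "list"))
}
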