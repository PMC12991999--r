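# End-to-end study-shaped workflow:
# simulate -> normalize -> diversity -> specificity groups -> similarity /
# classification -> longitudinal tracking -> antigen annotation -> report.
# Every stage derives its seed from the master seed and writes its outputs
# under the run directory, so a run is reproducible byte-for-byte and each
# stage can be re-run from persisted tables.

#' Default pipeline configuration
#'
#' Nested list understood by [run_pipeline()]. `cohort` holds
#' [cohort_config()] arguments; `n_course_subjects` is the number of
#' pre-GVHD subjects followed over stages 0/1/2 (default 3, the number of
#' pre-symptomatic subjects the study design follows); `normalize`,
#' `gliph`, `track` and `annotation` hold the per-stage parameters with
#' the field-standard defaults (target depth 1e6, z threshold 2,
#' low-frequency bound 100, frequency floor 0.01%, top-100 tracking,
#' GLIPH 1000/3/8).
#'
#' @param seed Master seed.
#' @return Configuration list.
#' @export
default_pipeline_config <- function(seed = 42L) {
  list(
    seed = as.integer(seed),
    cohort = list(),                      # overrides for cohort_config()
    n_course_subjects = 3L,
    normalize = list(target_reads = 1000000L, policy = "fixed"),
    diversity = list(z_threshold = 2, low_freq_max = 100L,
                     freq_boundary = 0.001),
    gliph = list(),                       # overrides for gliph_config()
    reference_multiple = 10,
    track = list(top_n = 100L, reference_stage = "1"),
    annotation = list(match_on = "cdr3", floor = 1e-4))
}

# Merge user overrides into the default configuration (shallow per section).
merge_config <- function(config) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  for (nm in names(config)) {
    if (nm %in% c("cohort", "normalize", "diversity", "gliph", "track",
                  "annotation") && is.list(config[[nm]])) {
      base[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  base
}

# Synthetic tissue-derived annotation set: the motif-carrying
# high-frequency CDR3s of the cohort's GVHD samples, standing in for an
# externally curated GVHD-associated table when none is supplied.
synthetic_gvhd_annotations <- function(cohort, motif_panel, floor = 1e-4) {
  rows <- dplyr::bind_rows(lapply(cohort, function(r) {
    if (is.na(r$group) || r$group != "GVHD") return(NULL)
    hf <- high_frequency_clones(r, floor)
    hit <- Reduce(`|`, lapply(motif_panel, function(m)
      grepl(m, hf$cdr3_aa, fixed = TRUE)))
    if (!any(hit)) return(NULL)
    tibble::tibble(cdr3_aa = hf$cdr3_aa[hit], v_gene = hf$v_gene[hit])
  }))
  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble::tibble(cdr3_aa = character(0),
                          antigen_species = character(0),
                          v_gene = character(0), j_gene = NA_character_,
                          source = character(0)))
  }
  out <- dplyr::distinct(rows, .data$cdr3_aa, .keep_all = TRUE)
  tibble::tibble(cdr3_aa = out$cdr3_aa,
                 antigen_species = "gvhd_tissue_synthetic",
                 v_gene = out$v_gene, j_gene = NA_character_,
                 source = "synthetic")
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full repertoire-analysis pipeline
#'
#' Executes every stage on a synthetic cohort (or a cohort read from a
#' manifest when `config$manifest` is set): generation, depth
#' normalization, per-sample diversity with between-group rank-sum tests
#' (raw and Benjamini-Hochberg adjusted), GLIPH-style specificity groups
#' against a generated naive reference, Jaccard similarity with group
#' contrasts and pre-GVHD query classification, per-subject top-clone
#' tracking with Morisita-Horn stage similarity, and annotation scoring.
#' All tables are written as TSV under `out_dir` together with a JSON
#' summary; reruns with the same configuration and seed are byte-identical.
#'
#' @param config Configuration list (see [default_pipeline_config()]), or a
#'   path to a YAML file holding one.
#' @param out_dir Output directory (created; existing files overwritten).
#' @param seed Master seed override (defaults to `config$seed`).
#' @return Invisibly, a list with every stage's in-memory result
#'   (`cohort`, `diversity`, `group_tests`, `gliph`, `similarity`,
#'   `classification`, `tracking`, `annotation`, `report`).
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config <- merge_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## ---- simulate ----------------------------------------------------------
  cc_args <- config$cohort
  cc_args$seed <- derive_seed(config$seed, "cohort")
  cc <- do.call(cohort_config, cc_args)
  cohort <- generate_cohort(cc)
  courses <- list()
  if (config$n_course_subjects > 0) {
    for (i in seq_len(config$n_course_subjects)) {
      sid <- sprintf("GVHD_PRE_%02d", i)
      courses[[sid]] <- generate_subject_course(cc, sid)
    }
  }
  stage_reps <- unlist(unname(lapply(courses, unname)), recursive = FALSE)
  all_samples <- c(cohort, setNames(stage_reps, vapply(stage_reps, function(r)
    r$sample_id, character(1))))
  class(all_samples) <- c("tcr_cohort", "list")

  ## ---- normalize ---------------------------------------------------------
  normalized <- normalize_cohort(all_samples,
                                 target_reads = config$normalize$target_reads,
                                 policy = config$normalize$policy,
                                 seed = derive_seed(config$seed, "normalize"))
  man <- cohort_manifest(normalized)
  readr::write_tsv(man, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  readr::write_tsv(attr(normalized, "normalization"),
                   file.path(out_dir, "normalization.tsv"), progress = FALSE)

  ## ---- diversity ---------------------------------------------------------
  dv <- config$diversity
  div <- cohort_diversity(normalized, z_threshold = dv$z_threshold,
                          low_freq_max = dv$low_freq_max,
                          freq_boundary = dv$freq_boundary)
  readr::write_tsv(div, file.path(out_dir, "diversity.tsv"), progress = FALSE)

  baseline <- div[is.na(div$stage) | div$stage == 0, , drop = FALSE]
  metrics <- c("richness", "chao1", "inverse_simpson", "expanded_count_z2",
               "low_freq_count", "top1_10")
  contrasts <- list(c("GVHD", "NO_GVHD"), c("GVHD", "HI"), c("NO_GVHD", "HI"))
  tests <- list()
  for (metric in metrics) {
    for (ctr in contrasts) {
      a <- baseline[[metric]][!is.na(baseline$group) & baseline$group == ctr[1]]
      b <- baseline[[metric]][!is.na(baseline$group) & baseline$group == ctr[2]]
      if (length(a) < 2 || length(b) < 2) next
      res <- compare_groups(setNames(list(a, b), ctr), "wilcoxon_rank_sum")
      tests[[length(tests) + 1]] <- tibble::tibble(
        metric = metric, group_a = ctr[1], group_b = ctr[2],
        median_a = median(a), median_b = median(b),
        statistic = res$statistic, p = res$p)
    }
  }
  group_tests <- dplyr::bind_rows(tests)
  if (nrow(group_tests) > 0) {
    group_tests$p_adj <- p.adjust(group_tests$p, method = "BH")
  }
  readr::write_tsv(group_tests, file.path(out_dir, "group_tests.tsv"),
                   progress = FALSE)

  ## ---- specificity groups ------------------------------------------------
  gl_args <- config$gliph
  gl_args$seed <- derive_seed(config$seed, "gliph")
  gcfg <- do.call(gliph_config, gl_args)
  pool <- select_input_clonotypes(normalized, gcfg)
  ref_n <- ceiling(config$reference_multiple * length(unique(pool$cdr3_aa)))
  reference <- generate_reference(ref_n, cc,
                                  seed = derive_seed(config$seed, "reference"))
  gl <- build_gliph_groups(normalized, reference, gcfg)
  readr::write_tsv(gl$groups, file.path(out_dir, "gliph_groups.tsv"),
                   progress = FALSE)
  readr::write_tsv(gl$members, file.path(out_dir, "gliph_members.tsv"),
                   progress = FALSE)

  ## ---- similarity + classification --------------------------------------
  profiles <- suppressWarnings(membership_profiles(gl, normalized))
  sim <- pairwise_similarity(profiles)
  sim_out <- tibble::as_tibble(sim, rownames = "sample_id")
  readr::write_tsv(sim_out, file.path(out_dir, "similarity_matrix.tsv"),
                   progress = FALSE)
  labels <- setNames(man$group, man$sample_id)
  labels[man$sample_id %in% vapply(stage_reps, function(r) r$sample_id,
                                   character(1))] <- NA
  base_labels <- labels[!is.na(labels) & labels %in% c("GVHD", "NO_GVHD", "HI")]
  contrasts_tab <- suppressWarnings(
    group_contrast(sim[names(base_labels), names(base_labels)], base_labels))
  readr::write_tsv(contrasts_tab, file.path(out_dir,
                                            "similarity_contrasts.tsv"),
                   progress = FALSE)

  gvhd_ids <- man$sample_id[!is.na(man$group) & man$group == "GVHD"]
  nogvhd_ids <- man$sample_id[!is.na(man$group) & man$group == "NO_GVHD"]
  query_ids <- man$sample_id[!is.na(man$group) & man$group == "GVHD_PRE" &
                               !is.na(man$stage) & man$stage == 0]
  classification <- dplyr::bind_rows(lapply(query_ids, function(q) {
    res <- suppressWarnings(
      classify_query(profiles[[q]], profiles[gvhd_ids],
                     profiles[nogvhd_ids]))
    dplyr::bind_cols(tibble::tibble(sample_id = q), res)
  }))
  readr::write_tsv(classification, file.path(out_dir, "classification.tsv"),
                   progress = FALSE)

  ## ---- longitudinal tracking ---------------------------------------------
  tracking_long <- list()
  stage_sims <- list()
  for (sid in names(courses)) {
    norm_course <- lapply(courses[[sid]], function(r)
      normalized[[r$sample_id]])
    names(norm_course) <- names(courses[[sid]])
    tr <- track_clonotypes(norm_course, config$track$reference_stage,
                           config$track$top_n)
    tracking_long[[sid]] <- tr$long
    ss <- stage_similarity(norm_course)
    stage_sims[[sid]] <- tibble::as_tibble(ss, rownames = "stage") |>
      dplyr::mutate(subject_id = sid, .before = 1)
  }
  tracking_tab <- dplyr::bind_rows(tracking_long)
  stage_sim_tab <- dplyr::bind_rows(stage_sims)
  if (nrow(tracking_tab) > 0) {
    readr::write_tsv(tracking_tab, file.path(out_dir, "tracking.tsv"),
                     progress = FALSE)
    readr::write_tsv(stage_sim_tab, file.path(out_dir,
                                              "stage_similarity.tsv"),
                     progress = FALSE)
  }

  ## ---- annotation --------------------------------------------------------
  ann_sets <- list()
  if (!is.null(config$annotation$sets)) {
    for (nm in names(config$annotation$sets)) {
      spec_ <- config$annotation$sets[[nm]]
      ann_sets[[nm]] <- read_annotation_table(spec_$path, spec_$dialect)
    }
  } else {
    ann_sets$gvhd_tissue_synthetic <-
      synthetic_gvhd_annotations(normalized, cc$motif_panel,
                                 config$annotation$floor)
  }
  annotation <- cohort_annotation_report(
    normalized[names(base_labels)], ann_sets,
    match_on = config$annotation$match_on, floor = config$annotation$floor)
  readr::write_tsv(annotation$per_sample,
                   file.path(out_dir, "annotation_per_sample.tsv"),
                   progress = FALSE)
  readr::write_tsv(annotation$tests,
                   file.path(out_dir, "annotation_tests.tsv"),
                   progress = FALSE)

  ## ---- consolidated report ----------------------------------------------
  report <- list(
    seed = config$seed,
    n_samples = nrow(man),
    groups = as.list(table(man$group)),
    target_reads = config$normalize$target_reads,
    median_richness = lapply(split(baseline$richness, baseline$group),
                             median),
    median_isi = lapply(split(baseline$inverse_simpson, baseline$group),
                        median),
    n_gliph_groups = nrow(gl$groups),
    n_local_groups = sum(gl$groups$kind == "local"),
    n_global_groups = sum(gl$groups$kind == "global"),
    classification = if (nrow(classification) > 0)
      as.list(setNames(classification$label, classification$sample_id))
    else list(),
    effective_parameters = list(
      gliph = unclass(gcfg)[c("simulation_depth", "kmer_min_depth",
                              "cdr3_length_cutoff", "min_fold_enrichment",
                              "p_threshold", "frequency_floor")],
      diversity = config$diversity,
      track = config$track))
  write_json_stable(report, file.path(out_dir, "report.json"))

  invisible(list(cohort = normalized, manifest = man, diversity = div,
                 group_tests = group_tests, gliph = gl, similarity = sim,
                 similarity_contrasts = contrasts_tab,
                 classification = classification, tracking = tracking_tab,
                 stage_similarity = stage_sim_tab, annotation = annotation,
                 report = report))
}
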