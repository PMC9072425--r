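#' Pipeline run configuration
#'
#' Collects everything a pipeline stage needs: output directory, detection
#' criteria, working-grid target, and the master seed. All defaults equal
#' the detector's standard constants (0.5 mm grid; 3/4 mm spheres; 15%
#' contrast; 5th percentile; 1 mm^3; 16.41 mm; linearity 0.8).
#'
#' @param out_dir Output directory (created if absent).
#' @param criteria A [pvs_criteria()].
#' @param target_mm Working-grid voxel size in mm.
#' @param seed Master integer seed for every stochastic stage.
#' @return List of class `pvs_config`.
#' @export
pvs_config <- function(out_dir, criteria = pvs_criteria(), target_mm = 0.5,
                       seed = 1L) {
  stopifnot(inherits(criteria, "pvs_criteria"), target_mm > 0)
  structure(list(out_dir = out_dir, criteria = criteria,
                 target_mm = target_mm, seed = as.integer(seed)),
            class = "pvs_config")
}

.config_hash <- function(config) {
  key <- c(unlist(config$criteria), target_mm = config$target_mm,
           seed = config$seed)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(key), format(key, digits = 15), sep = "="), f)
  unname(tools::md5sum(f))
}

.write_provenance <- function(config, stage, inputs, path) {
  prov <- list(stage = stage,
               package_version = as.character(packageVersion("pvsmorph")),
               config_hash = .config_hash(config),
               seed = config$seed,
               criteria = unclass(config$criteria),
               target_mm = config$target_mm,
               input_md5 = {
                 h <- tools::md5sum(inputs[file.exists(inputs)])
                 as.list(setNames(unname(h), basename(names(h))))
               })
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.tsv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) trimws(formatC(v, digits = 10,
                                                        format = "g")))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stage: detect PVS in one subject-session
#'
#' Reads a T1 volume plus brain and white-matter masks, reslices all three
#' to the isotropic working grid (skipped when already there), conditions
#' the white-matter mask, runs candidate detection, clustering, shape
#' descriptors and the morphological constraints, and writes the cluster
#' table (TSV), label map (NIfTI), review table, and a provenance sidecar.
#'
#' @param t1_path,brain_path,wm_path Input NIfTI paths.
#' @param config A [pvs_config()].
#' @param tag Output filename prefix (e.g. `"A01_L-60"`).
#' @param condition_wm Apply [condition_wm_mask()]? Disable for phantom
#'   masks that are already clean and eroded.
#' @return The filtered cluster record table (invisibly); files are
#'   written under `config$out_dir`.
#' @export
run_detect <- function(t1_path, brain_path, wm_path, config,
                       tag = "session", condition_wm = TRUE) {
  for (p in c(t1 = t1_path, brain = brain_path, wm = wm_path))
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
  vol <- read_volume(t1_path)
  brain <- read_mask(brain_path)
  wm <- read_mask(wm_path)
  .stopifnot_same_grid(vol, brain); .stopifnot_same_grid(vol, wm)
  if (max(abs(vol$spacing - config$target_mm)) > 1e-6) {
    vol <- reslice_isotropic(vol, config$target_mm, "linear")
    brain <- reslice_isotropic(brain, config$target_mm, "nearest")
    wm <- reslice_isotropic(wm, config$target_mm, "nearest")
  }
  if (condition_wm) wm <- condition_wm_mask(wm)
  cand <- detect_candidates(vol, wm, brain, config$criteria)
  cl <- cluster_candidates(cand, config$criteria)
  rec <- cluster_records(cl)
  out <- apply_morphological_constraints(rec, config$criteria)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(config$out_dir, tag)
  .tsv(out, paste0(base, "_clusters.tsv"))
  lab <- pvs_mask(cl$labels > 0, cl$spacing)
  lab$data[] <- cl$labels  # label map written as integers
  img <- RNifti::asNifti(lab$data)
  RNifti::pixdim(img) <- cl$spacing
  RNifti::writeNifti(img, paste0(base, "_labels.nii.gz"), datatype = "int16")
  export_review_table(out, paste0(base, "_review.tsv"))
  .write_provenance(config, "detect", c(t1_path, brain_path, wm_path),
                    paste0(base, "_provenance.json"))
  invisible(out)
}

#' Stage: subject-session metrics from cluster tables
#'
#' Reduces per-session cluster TSVs (from [run_detect()]) to the five PVS
#' outcomes, attaches the scalar volumes, normalizes, and writes one
#' metrics TSV.
#'
#' @param sessions Data.frame with one row per subject-session: columns
#'   `subject_id`, `session`, `cluster_tsv` (path), `wm_volume_cm3`,
#'   `ventricular_volume_mL`, `tiv_mL`, and optionally `review_tsv`.
#' @param config A [pvs_config()].
#' @return The metrics data.frame (also written to `metrics.tsv`).
#' @export
run_metrics <- function(sessions, config) {
  stopifnot(is.data.frame(sessions))
  rows <- lapply(seq_len(nrow(sessions)), function(i) {
    s <- sessions[i, ]
    rec <- read.delim(s$cluster_tsv, stringsAsFactors = FALSE)
    if (!is.null(s$review_tsv) && !is.na(s$review_tsv) &&
        nzchar(s$review_tsv))
      rec <- apply_review_table(rec, s$review_tsv)
    session_metrics(rec, s$wm_volume_cm3, s$ventricular_volume_mL, s$tiv_mL,
                    subject_id = s$subject_id, session = s$session)
  })
  m <- do.call(rbind, rows)
  ## per-subject baseline denominators: average over pre-flight sessions
  pre_sess <- c("L-180", "L-60", "C1", "pre", "ses1")
  out <- do.call(rbind, lapply(split(m, m$subject_id), function(sm) {
    pre <- sm[sm$session %in% pre_sess, , drop = FALSE]
    if (nrow(pre) == 0L) pre <- sm
    normalize_metrics(sm, mean(pre$wm_volume_cm3), mean(pre$tiv_mL))
  }))
  rownames(out) <- NULL
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .tsv(out, file.path(config$out_dir, "metrics.tsv"))
  .write_provenance(config, "metrics", sessions$cluster_tsv,
                    file.path(config$out_dir, "metrics_provenance.json"))
  out
}

#' Stage: cohort statistics with reliability gating
#'
#' Runs [analyze_cohort()] on a cohort table (or TSV path) and writes the
#' reliability report, per-metric change-model coefficient tables, the
#' exclusion log and a JSON bundle of all results. Metrics failing the
#' ICC gate never reach a model.
#'
#' @param cohort A cohort data.frame or TSV path.
#' @param config A [pvs_config()].
#' @return The `pvs_cohort_analysis` object (invisibly).
#' @export
run_stats <- function(cohort, config) {
  tab <- if (is.character(cohort))
    read.delim(cohort, stringsAsFactors = FALSE, check.names = FALSE)
  else cohort
  an <- analyze_cohort(tab)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .tsv(an$reliability, file.path(config$out_dir, "reliability.tsv"))
  cm <- do.call(rbind, lapply(names(an$change_models), function(m) {
    sw <- an$change_models[[m]]$stepwise
    cbind(outcome = m, sw$coefficients,
          r_squared = sw$r_squared, adj_r_squared = sw$adj_r_squared,
          shapiro_p = sw$shapiro_p)
  }))
  if (!is.null(cm)) .tsv(cm, file.path(config$out_dir, "change_models.tsv"))
  gate_rows <- if (length(attr(an$reliability, "excluded")))
    data.frame(context = "reliability_gate", subject_id = NA_character_,
               reason = paste("metric excluded:",
                              attr(an$reliability, "excluded")))
  else
    data.frame(context = character(), subject_id = character(),
               reason = character())
  excl <- do.call(rbind, c(
    list(gate_rows),
    lapply(names(an$exclusion_log), function(m) {
      e <- an$exclusion_log[[m]]
      if (nrow(e)) cbind(context = m, e) else NULL
    })))
  .tsv(excl, file.path(config$out_dir, "exclusion_log.tsv"))
  report <- list(
    reliability = an$reliability,
    excluded_metrics = attr(an$reliability, "excluded"),
    change_models = lapply(an$change_models, function(x) list(
      whole_group = x$whole_group$coefficients,
      stepwise = x$stepwise$coefficients,
      selected = x$stepwise$predictors)),
    experience = lapply(an$experience, function(e)
      e[c("metric", "r", "df", "p", "partial_r", "partial_p", "n")]),
    demographics = an$demographics)
  jsonlite::write_json(report, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, dataframe = "rows")
  .write_provenance(config, "stats",
                    if (is.character(cohort)) cohort else character(0),
                    file.path(config$out_dir, "stats_provenance.json"))
  invisible(an)
}

#' Stage: simulate phantom and cohort bundles
#'
#' Writes (i) a small image-level cohort — per subject a fixed phantom
#' rendered at two sessions with independent noise — as NIfTI volumes and
#' masks with a ground-truth JSON, and (ii) a metric-level longitudinal
#' cohort TSV with a sidecar recording the seed.
#'
#' @param config A [pvs_config()].
#' @param n_subjects Image-level subjects.
#' @param dim Phantom grid size.
#' @param sim_spec A [cohort_sim_spec()]; its seed is overridden by
#'   `config$seed`.
#' @return List with `image_dir`, `cohort_tsv`, `subjects` (the image
#'   cohort), invisibly.
#' @export
run_simulate <- function(config, n_subjects = 4, dim = c(48, 48, 48),
                         sim_spec = cohort_sim_spec()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(config$out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  subjects <- simulate_image_cohort(n_subjects, seed = config$seed,
                                    dim = dim)
  for (s in subjects) {
    for (k in seq_along(s$sessions)) {
      b <- s$sessions[[k]]
      base <- file.path(img_dir, sprintf("%s_ses%d", s$subject_id, k))
      write_volume(b$vol, paste0(base, "_t1.nii.gz"))
      write_mask(b$brain, paste0(base, "_brain.nii.gz"))
      write_mask(b$wm, paste0(base, "_wm.nii.gz"))
    }
    truth <- list(subject_id = s$subject_id,
                  n_tubules = length(s$truth$tubules),
                  tubules = lapply(s$truth$tubules, unclass),
                  noise_sd = s$truth$noise_sd, seed = s$truth$seed)
    jsonlite::write_json(truth,
                         file.path(img_dir,
                                   paste0(s$subject_id, "_truth.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  sim_spec$seed <- config$seed
  cohort <- simulate_cohort(sim_spec)
  cohort_tsv <- file.path(config$out_dir, "cohort.tsv")
  .tsv(cohort, cohort_tsv)
  jsonlite::write_json(list(seed = config$seed,
                            n_novice = sim_spec$n_novice,
                            n_experienced = sim_spec$n_experienced,
                            n_control = sim_spec$n_control),
                       file.path(config$out_dir, "cohort_sidecar.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(image_dir = img_dir, cohort_tsv = cohort_tsv,
                 subjects = subjects))
}

#' End-to-end pipeline run
#'
#' Simulates an image-level cohort and a metric-level cohort, runs
#' detection and session metrics on every rendered session, and the full
#' gated statistics on the metric-level table. Every output carries a
#' provenance sidecar; reruns with the same config and seed are
#' bit-identical.
#'
#' @param config A [pvs_config()].
#' @param n_subjects Image-level subjects.
#' @param dim Phantom grid size.
#' @return List with `metrics` (image-cohort session metrics),
#'   `analysis` (the `pvs_cohort_analysis`), invisibly.
#' @export
run_all <- function(config, n_subjects = 4, dim = c(48, 48, 48)) {
  sim <- run_simulate(config, n_subjects = n_subjects, dim = dim)
  det_cfg <- config
  det_cfg$out_dir <- file.path(config$out_dir, "detect")
  sessions <- list()
  for (s in sim$subjects) {
    for (k in seq_along(s$sessions)) {
      tag <- sprintf("%s_ses%d", s$subject_id, k)
      base <- file.path(sim$image_dir, tag)
      run_detect(paste0(base, "_t1.nii.gz"), paste0(base, "_brain.nii.gz"),
                 paste0(base, "_wm.nii.gz"), det_cfg, tag = tag,
                 condition_wm = FALSE)
      sessions[[tag]] <- data.frame(
        subject_id = s$subject_id, session = paste0("ses", k),
        cluster_tsv = file.path(det_cfg$out_dir,
                                paste0(tag, "_clusters.tsv")),
        wm_volume_cm3 = 480, ventricular_volume_mL = 25, tiv_mL = 1500)
    }
  }
  met_cfg <- config
  met_cfg$out_dir <- file.path(config$out_dir, "metrics")
  metrics <- run_metrics(do.call(rbind, sessions), met_cfg)
  stats_cfg <- config
  stats_cfg$out_dir <- file.path(config$out_dir, "stats")
  analysis <- run_stats(sim$cohort_tsv, stats_cfg)
  invisible(list(metrics = metrics, analysis = analysis))
}
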