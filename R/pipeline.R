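# End-to-end orchestration: simulate -> preprocess -> features -> train ->
# predict -> validate, driven by a single JSON-serializable configuration.
# Every stage writes its artifacts plus a manifest (config snapshot, seed,
# input checksums) sufficient to re-run it.

#' Run one stage of the prognostic pipeline
#'
#' Commands:
#' \describe{
#'   \item{simulate}{generate a synthetic cohort; writes `cohort.csv`,
#'     `features.csv`, `truth.json` and optionally per-subject NIfTI runs
#'     with motion TSVs.}
#'   \item{preprocess}{preprocess every subject's BOLD run; writes
#'     preprocessed runs and `qc_report.json` (exclusions included).}
#'   \item{features}{build control templates and per-subject connectivity
#'     features from preprocessed runs; writes `features.csv`.}
#'   \item{train}{fit the prognostic pipeline on a feature table; writes
#'     `model.json`, `training_predictions.csv`.}
#'   \item{predict}{score a feature table with a stored model; writes
#'     `predictions.csv`.}
#'   \item{validate}{internal validation (optimism bootstrap, permutation
#'     test, Bland-Altman); writes `validation_report.json`.}
#' }
#' All stages are deterministic under `config$seed`. Errors are classed
#' conditions whose `status` field distinguishes configuration errors (2),
#' missing/invalid inputs (3) and generation failures (4); inputs are
#' validated before any artifact is written.
#'
#' @param config a named list (or path to a JSON file): `out_dir`, `seed`,
#'   and per-stage blocks `cohort`, `preprocess`, `model`, `validation`,
#'   `paths` (see the vignette for the schema).
#' @param command one of the stages above.
#' @return invisibly, a list with `status = 0L` and the written `artifacts`.
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "preprocess", "features",
                                     "train", "predict", "validate")) {
  command <- match.arg(command)
  if (is.character(config)) {
    if (!file.exists(config)) input_error(paste0("config not found: ", config))
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  out_dir <- config$out_dir %||% config_error("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  artifacts <- switch(command,
    simulate = stage_simulate(config, out_dir, seed),
    preprocess = stage_preprocess(config, out_dir, seed),
    features = stage_features(config, out_dir, seed),
    train = stage_train(config, out_dir, seed),
    predict = stage_predict(config, out_dir, seed),
    validate = stage_validate(config, out_dir, seed)
  )
  write_manifest(out_dir, command, config, seed, artifacts)
  invisible(list(status = 0L, artifacts = artifacts))
}

write_manifest <- function(out_dir, command, config, seed, artifacts) {
  existing <- artifacts[file.exists(artifacts)]
  manifest <- list(
    command = command,
    seed = seed,
    package_version = as.character(utils::packageVersion("docprog")),
    config = config,
    artifacts = as.list(stats::setNames(
      vapply(existing, function(p) unname(tools::md5sum(p)), ""),
      basename(existing)))
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", command, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

resolve_path <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    input_error(sprintf("%s not found: %s", what, path %||% "<unset>"))
  path
}

cohort_from_config <- function(config, seed) {
  args <- config$cohort %||% list()
  roiset <- if (!is.null(config$paths$roi_config))
    read_roi_config(resolve_path(config$paths$roi_config, "ROI configuration"))
  else default_roi_set()
  args <- args[setdiff(names(args), c("write_nifti", "n_volumes", "tr",
                                      "grid_dim", "n_bold_subjects"))]
  args$roiset <- roiset
  args$seed <- seed
  do.call(cohort_spec, args)
}

stage_simulate <- function(config, out_dir, seed) {
  spec <- cohort_from_config(config, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- gen_cohort(spec)
  paths <- write_cohort(cohort, out_dir)
  cc <- config$cohort %||% list()
  if (isTRUE(cc$write_nifti)) {
    nvol <- cc$n_volumes %||% 80
    tr <- cc$tr %||% 2
    grid <- list(dim = cc$grid_dim %||% c(44, 54, 28))
    subjects <- cohort$subjects
    n_bold <- min(cc$n_bold_subjects %||% nrow(subjects), nrow(subjects))
    for (s in seq_len(n_bold)) {
      subj <- subjects[s, ]
      ts <- gen_roi_timeseries(subj, spec, nvol, tr,
                               seed = derive_seed(seed, 5000L + s))
      motion <- gen_motion_trace(nvol, spec$motion_spike_rate,
                                 seed = derive_seed(seed, 6000L + s))
      run <- gen_bold_nifti(ts, spec$roiset, grid, noise_sd = 0.5, tr = tr,
                            motion = motion, seed = derive_seed(seed, 7000L + s))
      paths <- c(paths, write_bold(run, file.path(out_dir, subj$id)))
    }
  }
  paths
}

stage_preprocess <- function(config, out_dir, seed) {
  in_dir <- resolve_path(config$paths$bold_dir %||% out_dir, "BOLD directory")
  ids <- config$subjects %||%
    sub("_meta\\.json$", "",
        basename(Sys.glob(file.path(in_dir, "*_meta.json"))))
  ids <- ids[!grepl("_preproc$", ids)]
  if (length(ids) == 0) input_error("no BOLD runs found to preprocess")
  pc <- do.call(preprocess_config, config$preprocess %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qc <- list()
  paths <- character(0)
  for (id in ids) {
    run <- read_bold(file.path(in_dir, id))
    out <- preprocess_run(run, pc, subject_id = id)
    if (is_excluded(out)) {
      qc[[id]] <- c(unclass(out), excluded = TRUE)
    } else {
      qc[[id]] <- c(attr(out, "qc"), excluded = FALSE)
      paths <- c(paths, write_bold(out, file.path(out_dir, paste0(id, "_preproc"))))
    }
  }
  qc_path <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(qc, qc_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(paths, qc = qc_path)
}

stage_features <- function(config, out_dir, seed) {
  in_dir <- resolve_path(config$paths$preproc_dir %||% out_dir,
                         "preprocessed directory")
  roiset <- if (!is.null(config$paths$roi_config))
    read_roi_config(resolve_path(config$paths$roi_config, "ROI configuration"))
  else default_roi_set()
  cohort_csv <- resolve_path(config$paths$cohort_csv %||%
                               file.path(in_dir, "cohort.csv"), "cohort table")
  subjects <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
  have <- file.exists(file.path(in_dir, paste0(subjects$id, "_preproc.nii.gz")))
  subjects <- subjects[have, ]
  controls <- subjects[subjects$group == "control", ]
  patients <- subjects[subjects$group == "patient", ]
  if (nrow(controls) < 3) input_error("at least 3 preprocessed controls are required")
  if (nrow(patients) < 1) input_error("no preprocessed patients found")
  czmaps <- lapply(controls$id, function(id)
    control_network_zmaps(read_bold(file.path(in_dir, paste0(id, "_preproc"))),
                          roiset))
  templates <- build_network_templates(czmaps)
  rows <- lapply(seq_len(nrow(patients)), function(s) {
    subj <- patients[s, ]
    run <- read_bold(file.path(in_dir, paste0(subj$id, "_preproc")))
    prof <- compute_connectivity_profile(run, roiset, templates, id = subj$id)
    assemble_feature_vector(prof, subj)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- patients$id
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fpath <- file.path(out_dir, "features.csv")
  utils::write.csv(data.frame(id = rownames(X), X, check.names = FALSE),
                   fpath, row.names = FALSE)
  c(features = fpath)
}

read_feature_table <- function(path) {
  df <- utils::read.csv(resolve_path(path, "feature table"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  rownames(X) <- df$id
  X
}

split_feature_blocks <- function(X) {
  clin <- intersect(CLINICAL_FEATURES, colnames(X))
  list(imaging = X[, setdiff(colnames(X), clin), drop = FALSE],
       clinical = X[, clin, drop = FALSE])
}

training_data_from_config <- function(config) {
  X <- read_feature_table(config$paths$features_csv)
  subjects <- utils::read.csv(resolve_path(config$paths$cohort_csv, "cohort table"),
                              stringsAsFactors = FALSE)
  subjects <- subjects[match(rownames(X), subjects$id), ]
  if (any(is.na(subjects$id))) input_error("feature table ids missing from cohort table")
  blocks <- split_feature_blocks(X)
  list(imaging = blocks$imaging, clinical = blocks$clinical,
       y = subjects$crsr_t1, recovery = subjects$gos_t1 >= 3, X = X)
}

stage_train <- function(config, out_dir, seed) {
  dat <- training_data_from_config(config)
  mc <- do.call(pipeline_config, config$model %||% list())
  model <- fit_prognostic_pipeline(dat$imaging, dat$clinical, dat$y,
                                   recovery = dat$recovery, config = mc,
                                   seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mpath <- file.path(out_dir, "model.json")
  model_to_json(model, mpath)
  pred <- predict_score(model, dat$X)
  ppath <- file.path(out_dir, "training_predictions.csv")
  utils::write.csv(pred, ppath, row.names = FALSE)
  c(model = mpath, training_predictions = ppath)
}

stage_predict <- function(config, out_dir, seed) {
  model <- model_from_json(resolve_path(config$paths$model_json, "model file"))
  X <- read_feature_table(config$paths$features_csv)
  pred <- predict_score(model, X)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ppath <- file.path(out_dir, "predictions.csv")
  utils::write.csv(pred, ppath, row.names = FALSE)
  c(predictions = ppath)
}

stage_validate <- function(config, out_dir, seed) {
  dat <- training_data_from_config(config)
  mc <- do.call(pipeline_config, config$model %||% list())
  vc <- config$validation %||% list()
  B_opt <- vc$optimism_B %||% 100
  B_perm <- vc$permutation_B %||% 99
  opt <- optimism_bootstrap(dat$imaging, dat$clinical, dat$y, config = mc,
                            B = B_opt, seed = derive_seed(seed, 1L))
  stat_fn <- function(X, y) {
    m <- fit_pipeline_or_null(X$imaging, X$clinical, y, NULL, mc,
                              derive_seed(seed, 2L))
    if (is.null(m)) 0 else m$apparent_r2
  }
  perm <- permutation_test(stat_fn,
                           list(imaging = dat$imaging, clinical = dat$clinical),
                           dat$y, B = B_perm, seed = derive_seed(seed, 3L))
  full <- fit_prognostic_pipeline(dat$imaging, dat$clinical, dat$y,
                                  recovery = dat$recovery, config = mc,
                                  seed = derive_seed(seed, 2L))
  ba <- bland_altman(full$train_scores, dat$y)
  report <- list(
    n = length(dat$y),
    apparent_r2 = opt$apparent_r2, optimism = opt$optimism,
    corrected_r2 = opt$corrected_r2, optimism_B_effective = opt$B_effective,
    permutation_p = perm$p, permutation_observed = perm$observed,
    auc = full$auc, cutoff = full$cutoff,
    bland_altman = ba[c("mean_diff", "lower", "upper", "t_test_p")],
    seed = seed
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rpath <- file.path(out_dir, "validation_report.json")
  jsonlite::write_json(report, rpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(validation_report = rpath)
}
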