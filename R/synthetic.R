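# Synthetic-data generators: cohorts with a planted sparse outcome model,
# ROI time series with six-network block covariance, and motion traces.
#
# The generators emulate the structure the analysis assumes: a latent
# "recovery capacity" per patient drives (a) template-resemblance features,
# (b) the default-mode/executive anti-correlation (low-capacity subjects
# lose it), and (c) through a sparse linear model, the follow-up CRS-R score.

#' Specification of a synthetic cohort
#'
#' @param n_patients number of patients (>= 2). Default 63, the size of the
#'   training cohort the design targets.
#' @param n_controls number of healthy controls (capacity fixed at 1).
#' @param roiset ROI configuration defining networks and the feature space.
#' @param effect_weights named or plain numeric vector of ground-truth linear
#'   weights over the full feature vector (resemblance, FC, clinical); length
#'   must equal `length(canonical_feature_names(roiset))`. Default: a sparse
#'   set mirroring the expected physiology (positive resemblance weights for
#'   default-mode/executive seeds, a negative weight on the default-mode x
#'   executive connectivity, negative age and anoxia weights).
#' @param intercept intercept of the outcome model on the CRS-R scale.
#' @param noise_sd SD of the Gaussian outcome noise (CRS-R points).
#' @param anticorrelation_strength default-mode x executive coupling at full
#'   capacity, in `[-1, 0]`.
#' @param rho_within within-network time-series correlation.
#' @param motion_spike_rate per-volume probability of a motion spike.
#' @param capacity_loadings per-feature linear loading of the latent capacity
#'   on the feature mean (default: 0.5 on every resemblance feature, 0.25 on
#'   the auditory-MCC x visual-R.V1 connectivity when present).
#' @param recovery_threshold CRS-R at follow-up at or above which the GOS
#'   label is "recovery" (GOS 3; GOS 4 from 18).
#' @param seed master seed; the same seed reproduces the cohort bit for bit.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 63, n_controls = 30,
                        roiset = default_roi_set(),
                        effect_weights = NULL,
                        intercept = 3,
                        noise_sd = 1,
                        anticorrelation_strength = -0.3,
                        rho_within = 0.4,
                        motion_spike_rate = 0.02,
                        capacity_loadings = NULL,
                        recovery_threshold = 14,
                        seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 2)
    config_error("n_patients must be >= 2")
  if (!is.numeric(n_controls) || n_controls < 0)
    config_error("n_controls must be >= 0")
  roiset <- roi_set(roiset)
  nm <- canonical_feature_names(roiset)
  if (is.null(effect_weights)) effect_weights <- default_effect_weights(roiset)
  if (length(effect_weights) != length(nm))
    config_error(sprintf("effect_weights has length %d; expected %d",
                         length(effect_weights), length(nm)))
  w <- as.numeric(effect_weights)
  names(w) <- nm
  if (is.null(capacity_loadings)) capacity_loadings <- default_capacity_loadings(roiset)
  if (length(capacity_loadings) != length(nm))
    config_error("capacity_loadings length must equal the feature count")
  if (anticorrelation_strength < -1 || anticorrelation_strength > 0)
    config_error("anticorrelation_strength must lie in [-1, 0]")
  if (motion_spike_rate < 0 || motion_spike_rate > 1)
    config_error("motion_spike_rate must lie in [0, 1]")
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    roiset = roiset, feature_names = nm, effect_weights = w,
    intercept = intercept, noise_sd = noise_sd,
    anticorrelation_strength = anticorrelation_strength,
    rho_within = rho_within, motion_spike_rate = motion_spike_rate,
    capacity_loadings = as.numeric(capacity_loadings),
    recovery_threshold = recovery_threshold,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default sparse ground-truth weights
#'
#' Non-zero weights are planted on the features the prognostic physiology
#' singles out: resemblance of the anterior-medial-prefrontal, posterior
#' cingulate and dorsomedial-prefrontal seeds, the default-mode x executive
#' connectivity (negative: recovering patients re-acquire the
#' anti-correlation, which lowers that Fisher-z value), one auditory-visual
#' connectivity, plus negative age and anoxic-etiology effects. For ROI sets
#' other than the shipped default the vector is all zero and should be
#' supplied explicitly.
#'
#' @param roiset an `roi_set`.
#' @return named numeric vector over the canonical feature order.
#' @export
default_effect_weights <- function(roiset) {
  nm <- canonical_feature_names(roiset)
  w <- stats::setNames(numeric(length(nm)), nm)
  planted <- c(res_DMN.aMPFC = 6, res_DMN.PCC = 6, res_ExecuContr.DMPFC = 5,
               fc_DMN.aMPFC__ExecuContr.DMPFC = -14,
               fc_Auditory.MCC__Visual.R.V1 = 8,
               age = -0.03, dummy_anoxia = -1.5)
  hit <- intersect(names(planted), nm)
  w[hit] <- planted[hit]
  w
}

#' @rdname default_effect_weights
#' @export
default_capacity_loadings <- function(roiset) {
  nm <- canonical_feature_names(roiset)
  load <- stats::setNames(numeric(length(nm)), nm)
  load[resemblance_names(roiset)] <- 0.5
  if ("fc_Auditory.MCC__Visual.R.V1" %in% nm)
    load["fc_Auditory.MCC__Visual.R.V1"] <- 0.25
  load
}

# Monotone increasing capacity link for the default-mode x executive block:
# full anti-correlation at capacity 1, none at capacity 0.
capacity_link <- function(capacity) clip(capacity, 0, 1)

# Feature-noise scales (Fisher-z / correlation units), fixed by design.
RES_NOISE_SD <- 0.08
FC_NOISE_SD <- 0.10
RES_BASE <- 0.10

# Per-feature baseline means for the imaging block of the feature table.
imaging_feature_baseline <- function(spec) {
  roiset <- spec$roiset
  idx <- fc_pairs(nrow(roiset))
  same <- roiset$network[idx[, "i"]] == roiset$network[idx[, "j"]]
  fc_base <- ifelse(same, fisher_z(spec$rho_within), 0)
  list(res = rep(RES_BASE, nrow(roiset)), fc = fc_base,
       dmn_ec = roiset$network[idx[, "i"]] == "default_mode" &
                roiset$network[idx[, "j"]] == "executive_control" |
                roiset$network[idx[, "i"]] == "executive_control" &
                roiset$network[idx[, "j"]] == "default_mode")
}

#' Generate a synthetic cohort with a planted outcome model
#'
#' Draws patients (latent capacity uniform on (0, 1)) and controls (capacity
#' 1), builds the per-patient feature table in canonical order, and generates
#' the follow-up CRS-R as
#' `clip(round(intercept + features %*% effect_weights + noise), 3, 23)`,
#' with the GOS label thresholded on that score. Deterministic under
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a `doc_cohort` list: `subjects` (one row per patient then
#'   control: id, group, age, duration, etiology, crsr_t0, crsr_t1, gos_t1,
#'   latent_capacity), `features` (patients x features matrix, canonical
#'   column order), `effect_weights`, `intercept`, and the `spec`.
#' @export
gen_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  with_seed(spec$seed, {
    np <- spec$n_patients
    nc <- spec$n_controls
    roiset <- spec$roiset
    nm <- spec$feature_names
    m <- nrow(roiset)

    capacity <- stats::runif(np)
    age <- round(stats::runif(np, 18, 71))
    duration <- round(clip(stats::rlnorm(np, log(3.5), 0.9), 1, 77), 1)
    etiology <- sample(c("trauma", "stroke", "anoxia"), np, replace = TRUE,
                       prob = c(17, 21, 25) / 63)
    crsr_t0 <- as.integer(clip(round(4 + 6 * capacity + stats::rnorm(np, 0, 2)), 3, 18))

    base <- imaging_feature_baseline(spec)
    n_res <- m
    n_fc <- m * (m - 1) / 2
    X <- matrix(NA_real_, np, length(nm), dimnames = list(NULL, nm))
    res_block <- matrix(rep(base$res, each = np), np, n_res) +
      outer(capacity, spec$capacity_loadings[seq_len(n_res)]) +
      matrix(stats::rnorm(np * n_res, 0, RES_NOISE_SD), np, n_res)
    X[, seq_len(n_res)] <- clip(res_block, -0.999, 0.999)

    fc_block <- matrix(rep(base$fc, each = np), np, n_fc)
    if (any(base$dmn_ec))
      fc_block[, base$dmn_ec] <- fisher_z(
        spec$anticorrelation_strength * capacity_link(capacity))
    fc_load <- spec$capacity_loadings[n_res + seq_len(n_fc)]
    fc_block <- fc_block + outer(capacity, fc_load) +
      matrix(stats::rnorm(np * n_fc, 0, FC_NOISE_SD), np, n_fc)
    X[, n_res + seq_len(n_fc)] <- fc_block

    X[, "age"] <- age
    X[, "duration"] <- duration
    X[, "dummy_stroke"] <- as.numeric(etiology == "stroke")
    X[, "dummy_anoxia"] <- as.numeric(etiology == "anoxia")

    lin <- spec$intercept + drop(X %*% spec$effect_weights)
    crsr_t1 <- as.integer(clip(round(lin + stats::rnorm(np, 0, spec$noise_sd)), 3, 23))
    gos_t1 <- ifelse(crsr_t1 >= 18, 4L,
                     ifelse(crsr_t1 >= spec$recovery_threshold, 3L, 2L))

    subjects <- data.frame(
      id = c(sprintf("P%03d", seq_len(np)),
             if (nc > 0) sprintf("C%03d", seq_len(nc))),
      group = c(rep("patient", np), rep("control", nc)),
      age = c(age, if (nc > 0) round(stats::runif(nc, 20, 60))),
      duration = c(duration, rep(NA_real_, nc)),
      etiology = c(etiology, rep(NA_character_, nc)),
      crsr_t0 = c(crsr_t0, rep(NA_integer_, nc)),
      crsr_t1 = c(crsr_t1, rep(NA_integer_, nc)),
      gos_t1 = c(gos_t1, rep(NA_integer_, nc)),
      latent_capacity = c(capacity, rep(1, nc)),
      stringsAsFactors = FALSE
    )
    rownames(X) <- subjects$id[seq_len(np)]
    structure(list(subjects = subjects, features = X,
                   effect_weights = spec$effect_weights,
                   intercept = spec$intercept, spec = spec),
              class = "doc_cohort")
  })
}

#' Recovery labels of a cohort
#' @param cohort a `doc_cohort`.
#' @return logical vector over patients: `gos_t1 >= 3`.
#' @export
recovery_labels <- function(cohort) {
  s <- cohort$subjects[cohort$subjects$group == "patient", ]
  s$gos_t1 >= 3
}

#' Generate ROI time series with six-network block covariance
#'
#' Draws a multivariate normal series for the ROIs of `spec$roiset`:
#' unit variances, correlation `spec$rho_within` within each network, zero
#' between networks except the default-mode x executive block, whose
#' correlation is `anticorrelation_strength * g(capacity)` with the monotone
#' increasing link `g(c) = c`: low-capacity subjects lose the
#' anti-correlation.
#'
#' @param subject one row of a cohort's `subjects` table (a list with at
#'   least `latent_capacity`), or a bare capacity value in `[0, 1]`.
#' @param spec a [cohort_spec()].
#' @param n_volumes number of time points (>= 2).
#' @param tr repetition time in seconds (recorded downstream, default 2).
#' @param seed seed for this draw (default derived from the spec seed).
#' @return matrix ROI x time with rownames from the ROI set.
#' @export
gen_roi_timeseries <- function(subject, spec, n_volumes, tr = 2,
                               seed = derive_seed(spec$seed, 7001L)) {
  if (n_volumes < 2) config_error("n_volumes must be >= 2")
  capacity <- if (is.numeric(subject) && length(subject) == 1) subject
              else subject$latent_capacity
  Sigma <- network_block_covariance(spec$roiset, spec$rho_within,
                                    spec$anticorrelation_strength *
                                      capacity_link(capacity))
  L <- tryCatch(chol(Sigma), error = function(e) {
    generation_error(sprintf(
      paste0("implied ROI covariance is not positive definite ",
             "(rho_within = %.3f, default_mode x executive_control block = %.3f)"),
      spec$rho_within,
      spec$anticorrelation_strength * capacity_link(capacity)))
  })
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_volumes * nrow(Sigma)), n_volumes)
    ts <- t(Z %*% L)
    rownames(ts) <- spec$roiset$name
    attr(ts, "tr") <- tr
    ts
  })
}

# Block covariance over ROIs from their network memberships.
network_block_covariance <- function(roiset, rho_within, dmn_ec_rho) {
  m <- nrow(roiset)
  net <- roiset$network
  Sigma <- matrix(0, m, m)
  same <- outer(net, net, "==")
  Sigma[same] <- rho_within
  cross <- outer(net == "default_mode", net == "executive_control") |
           outer(net == "executive_control", net == "default_mode")
  Sigma[cross] <- dmn_ec_rho
  diag(Sigma) <- 1
  Sigma
}

#' Generate a six-parameter motion trace
#'
#' Smooth low-amplitude random-walk drift plus Bernoulli motion spikes of a
#' fixed magnitude on the first translation axis. Spike signs alternate so
#' that consecutive spiked volumes still produce super-threshold framewise
#' displacement. Deterministic under `seed`.
#'
#' @param n_volumes number of volumes (>= 1).
#' @param spike_rate per-volume spike probability in `[0, 1]`.
#' @param spike_magnitude_mm spike displacement in mm (default 2).
#' @param drift_sd per-step SD of the translational drift in mm (rotational
#'   drift uses `drift_sd / 50`); 0 gives a perfectly still trace.
#' @param seed integer seed.
#' @return matrix `n_volumes` x 6 (`trans_x/y/z` in mm, `rot_x/y/z` in
#'   radians) with attribute `spikes` (logical per volume).
#' @export
gen_motion_trace <- function(n_volumes, spike_rate = 0.02, spike_magnitude_mm = 2,
                             drift_sd = 0.02, seed = 1L) {
  if (n_volumes < 1) config_error("n_volumes must be >= 1")
  if (spike_rate < 0 || spike_rate > 1)
    config_error("spike_rate must lie in [0, 1]")
  with_seed(seed, {
    trace <- cbind(
      apply(matrix(stats::rnorm(n_volumes * 3, 0, drift_sd), n_volumes), 2, cumsum),
      apply(matrix(stats::rnorm(n_volumes * 3, 0, drift_sd / 50), n_volumes), 2, cumsum)
    )
    if (n_volumes == 1) trace <- matrix(trace, 1)
    spikes <- stats::runif(n_volumes) < spike_rate
    if (any(spikes)) {
      signs <- rep_len(c(1, -1), sum(spikes))
      trace[spikes, 1] <- trace[spikes, 1] + signs * spike_magnitude_mm
    }
    colnames(trace) <- c("trans_x", "trans_y", "trans_z",
                         "rot_x", "rot_y", "rot_z")
    attr(trace, "spikes") <- spikes
    trace
  })
}

#' Write / read a motion trace as 6-column TSV
#'
#' Dialect: one row per volume, columns `trans_x trans_y trans_z` (mm) then
#' `rot_x rot_y rot_z` (radians), with a header line.
#'
#' @param motion matrix n x 6.
#' @param path TSV path.
#' @return `path` (write) or the motion matrix (read).
#' @export
write_motion_tsv <- function(motion, path) {
  utils::write.table(motion, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  if (!file.exists(path)) input_error(paste0("motion file not found: ", path))
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  if (ncol(m) != 6) input_error("motion TSV must have 6 columns")
  if (any(!is.finite(m))) input_error("non-finite motion parameters")
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Write a cohort to plain-text artifacts
#'
#' `cohort.csv` (subject table), `features.csv` (patient feature table with
#' canonical header) and `truth.json` (ground-truth weights, intercept,
#' seed).
#'
#' @param cohort a `doc_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cohort = file.path(dir, "cohort.csv"),
    features = file.path(dir, "features.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(cohort$subjects, paths["cohort"], row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(cohort$features),
                              cohort$features, check.names = FALSE),
                   paths["features"], row.names = FALSE)
  jsonlite::write_json(
    list(effect_weights = as.list(cohort$effect_weights),
         intercept = cohort$intercept, seed = cohort$spec$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  paths
}
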