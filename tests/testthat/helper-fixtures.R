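# Shared fixtures: small ROI sets and planted designs, all built in code.

# Four well-separated ROIs on a 16 x 16 x 8 grid (3 mm voxels).
tiny_roi_set <- function(radius = 4) {
  roi_set(data.frame(
    name = c("A", "B", "C", "D"),
    network = c("default_mode", "executive_control", "auditory", "visual"),
    x = c(-12, 12, -12, 12), y = c(-12, -12, 12, 12), z = 0,
    radius = radius))
}

tiny_grid <- function() list(dim = c(16, 16, 8), voxel_dim = c(3, 3, 3))

# Eight ROIs spanning all six networks: 8 + 28 + 4 = 40 features.
roi_set8 <- function() {
  roi_set(data.frame(
    name = c("D1", "D2", "E1", "E2", "S1", "M1", "A1", "V1"),
    network = c("default_mode", "default_mode", "executive_control",
                "executive_control", "salience", "sensorimotor",
                "auditory", "visual"),
    x = c(-30, 30, -30, 30, -30, 30, -30, 30),
    y = c(-30, -30, 0, 0, 30, 30, 60, 60), z = 0, radius = 5))
}

# Sparse ground-truth weights over the 8-ROI feature space (5 non-zero).
planted_weights8 <- function() {
  nm <- canonical_feature_names(roi_set8())
  w <- stats::setNames(numeric(length(nm)), nm)
  w[c("res_D1", "res_E1")] <- c(5, 4)
  w["fc_D1__E1"] <- -8
  w["fc_A1__V1"] <- 6
  w["age"] <- -0.05
  w
}

# iid-Gaussian design with k informative features of p: y = rowSums(X[, 1:k]) + noise.
planted_design <- function(n = 100, p = 50, k = 5, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n)
  colnames(X) <- paste0("f", seq_len(p))
  y <- drop(X[, seq_len(k), drop = FALSE] %*% rep(1, k)) +
    stats::rnorm(n, 0, noise_sd)
  list(X = X, y = y, informative = paste0("f", seq_len(k)))
}

# Feature-table cohort with imaging signal and uninformative clinical block.
signal_cohort <- function(n, seed, sd_im = 0.1, sd_y = 1) {
  set.seed(seed)
  cap <- stats::runif(n)
  im <- cbind(i1 = cap + stats::rnorm(n, 0, sd_im),
              i2 = -cap + stats::rnorm(n, 0, sd_im),
              i3 = stats::rnorm(n), i4 = stats::rnorm(n),
              i5 = stats::rnorm(n), i6 = stats::rnorm(n))
  cl <- cbind(age = round(stats::runif(n, 18, 70)),
              duration = stats::runif(n, 1, 40),
              dummy_stroke = stats::rbinom(n, 1, 0.3),
              dummy_anoxia = stats::rbinom(n, 1, 0.3))
  y <- 3 + 17 * cap + stats::rnorm(n, 0, sd_y)
  list(imaging = im, clinical = cl, y = y, recovery = y >= 14)
}

# Default-ROI cohort split into imaging / clinical blocks plus outcome.
cohort_blocks <- function(cohort) {
  pat <- cohort$subjects[cohort$subjects$group == "patient", ]
  n_im <- n_imaging_features(cohort$spec$roiset)
  list(imaging = cohort$features[, seq_len(n_im), drop = FALSE],
       clinical = cohort$features[, -seq_len(n_im), drop = FALSE],
       y = pat$crsr_t1, recovery = pat$gos_t1 >= 3)
}
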