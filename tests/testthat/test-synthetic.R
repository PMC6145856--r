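# Synthetic-data generators: determinism, the planted outcome model, the
# block-covariance time series and the motion model.

test_that("cohort generation is deterministic and respects its invariants", {
  spec <- cohort_spec(n_patients = 25, n_controls = 5, seed = 11)
  a <- gen_cohort(spec)
  b <- gen_cohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$features, b$features)

  pat <- a$subjects[a$subjects$group == "patient", ]
  expect_true(all(pat$crsr_t1 >= 3 & pat$crsr_t1 <= 23))
  expect_true(all(pat$crsr_t0 >= 0 & pat$crsr_t0 <= 23))
  expect_true(all(!is.na(pat$etiology) & !is.na(pat$duration)))
  expect_identical(pat$gos_t1 >= 3, recovery_labels(a))
  expect_identical(colnames(a$features),
                   canonical_feature_names(spec$roiset))
  ctrl <- a$subjects[a$subjects$group == "control", ]
  expect_true(all(ctrl$latent_capacity == 1))
})

test_that("zero effect weights and zero noise give a constant outcome", {
  rs <- roi_set8()
  nm <- canonical_feature_names(rs)
  spec <- cohort_spec(n_patients = 10, n_controls = 0, roiset = rs,
                      effect_weights = numeric(length(nm)),
                      intercept = 9.4, noise_sd = 0, seed = 3)
  coh <- gen_cohort(spec)
  expect_true(all(coh$subjects$crsr_t1 == 9))  # clip(round(9.4), 3, 23)
})

test_that("invalid cohort specifications are configuration errors", {
  expect_error(cohort_spec(n_patients = 1), class = "docprog_config_error")
  expect_error(cohort_spec(n_patients = -5), class = "docprog_config_error")
  expect_error(cohort_spec(anticorrelation_strength = 0.2),
               class = "docprog_config_error")
  expect_error(cohort_spec(motion_spike_rate = 1.5),
               class = "docprog_config_error")
  expect_error(cohort_spec(roiset = roi_set8(), effect_weights = 1:3),
               class = "docprog_config_error")
})

test_that("OLS on the full table recovers the planted weights within 3 SE", {
  w <- planted_weights8()
  spec <- cohort_spec(n_patients = 200, n_controls = 0, roiset = roi_set8(),
                      effect_weights = w, intercept = 8, noise_sd = 1,
                      seed = 1)
  coh <- gen_cohort(spec)
  y <- coh$subjects$crsr_t1
  expect_false(any(y %in% c(3, 23)))  # clipping never active here
  fit <- stats::lm(y ~ coh$features)
  co <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  names(co) <- names(se) <- colnames(coh$features)
  nz <- names(w)[w != 0]
  expect_true(all(abs(co[nz] - w[nz]) / se[nz] < 3))
})

test_that("ROI time series realize the specified block covariance", {
  spec <- cohort_spec(rho_within = 0.5, seed = 2)
  ts <- gen_roi_timeseries(1, spec, n_volumes = 5000, seed = 8)
  r <- stats::cor(t(ts))
  net <- spec$roiset$network
  same <- outer(net, net, "==") & upper.tri(r)
  expect_lt(max(abs(r[same] - 0.5)), 0.05)

  # full-capacity subject carries the default-mode x executive anti-correlation
  cross <- (outer(net == "default_mode", net == "executive_control") |
            outer(net == "executive_control", net == "default_mode")) &
           upper.tri(r)
  expect_lt(max(abs(r[cross] - (-0.3))), 0.05)

  # zero coupling: independent blocks
  spec0 <- cohort_spec(anticorrelation_strength = 0, seed = 2)
  ts0 <- gen_roi_timeseries(1, spec0, n_volumes = 2000, seed = 8)
  r0 <- stats::cor(t(ts0))
  expect_lt(max(abs(r0[cross])), 0.1)

  # determinism under an explicit seed
  expect_identical(ts, gen_roi_timeseries(1, spec, n_volumes = 5000, seed = 8))
})

test_that("low capacity removes the anti-correlation", {
  spec <- cohort_spec(seed = 2)
  ts <- gen_roi_timeseries(0.02, spec, n_volumes = 3000, seed = 9)
  r <- stats::cor(t(ts))
  net <- spec$roiset$network
  cross <- (outer(net == "default_mode", net == "executive_control")) & upper.tri(r)
  expect_lt(max(abs(r[cross])), 0.1)
})

test_that("an impossible covariance is reported as a generation error", {
  spec <- cohort_spec(rho_within = 0.05, anticorrelation_strength = -0.9,
                      seed = 1)
  expect_error(gen_roi_timeseries(1, spec, n_volumes = 10),
               class = "docprog_generation_error")
})

test_that("motion traces follow the spike model", {
  still <- gen_motion_trace(50, spike_rate = 0, drift_sd = 0, seed = 1)
  expect_true(all(compute_fd(still) == 0))

  spiky <- gen_motion_trace(60, spike_rate = 1, spike_magnitude_mm = 2,
                            drift_sd = 0, seed = 2)
  expect_true(all(compute_fd(spiky)[-1] >= 2))

  big <- gen_motion_trace(10000, spike_rate = 0.1, seed = 3)
  expect_lt(abs(mean(attr(big, "spikes")) - 0.1), 0.01)

  expect_identical(gen_motion_trace(100, seed = 7),
                   gen_motion_trace(100, seed = 7))
  expect_error(gen_motion_trace(10, spike_rate = 2),
               class = "docprog_config_error")
})

test_that("synthetic BOLD round-trips planted series at zero noise", {
  rs <- tiny_roi_set()
  spec <- cohort_spec(n_patients = 2, n_controls = 0, roiset = rs,
                      effect_weights = numeric(14),
                      capacity_loadings = numeric(14), seed = 4)
  ts <- gen_roi_timeseries(1, spec, n_volumes = 30, seed = 5)
  run <- gen_bold_nifti(ts, rs, tiny_grid(), noise_sd = 0)
  expect_equal(extract_roi_timeseries(run, rs), ts, ignore_attr = TRUE)
})

test_that("ROI mean over k voxels has residual variance about noise_sd^2 / k", {
  rs <- tiny_roi_set()
  ts <- matrix(0, 4, 4000)
  rownames(ts) <- rs$name
  run <- gen_bold_nifti(ts, rs, tiny_grid(), noise_sd = 0.5, seed = 6)
  k <- length(docprog:::sphere_voxel_indices(c(16, 16, 8), c(3, 3, 3),
                                             run$origin, c(-12, -12, 0), 4))
  ex <- extract_roi_timeseries(run, rs)
  expect_lt(abs(stats::var(ex[1, ]) - 0.25 / k), 0.25 / k * 0.3)
})

test_that("degenerate grids and overlapping spheres are rejected", {
  rs <- tiny_roi_set()
  ts <- matrix(0, 4, 5)
  expect_error(gen_bold_nifti(ts, rs, list(dim = c(0, 16, 8))),
               class = "docprog_generation_error")
  rs_overlap <- rs
  rs_overlap$radius <- 15
  expect_error(gen_bold_nifti(ts, rs_overlap,
                              list(dim = c(32, 32, 16), voxel_dim = c(3, 3, 3))),
               regexp = "overlapping",
               class = "docprog_generation_error")
  expect_error(gen_bold_nifti(ts, rs, list(dim = c(4, 4, 4))),
               regexp = "too small",
               class = "docprog_generation_error")
})

test_that("BOLD runs survive a disk round trip", {
  rs <- tiny_roi_set()
  ts <- matrix(stats::rnorm(4 * 20), 4)
  rownames(ts) <- rs$name
  run <- gen_bold_nifti(ts, rs, tiny_grid(), noise_sd = 0.1,
                        motion = gen_motion_trace(20, seed = 2), seed = 7)
  prefix <- file.path(withr::local_tempdir(), "sub01")
  write_bold(run, prefix)
  back <- read_bold(prefix)
  expect_equal(back$data, run$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back$mask, run$mask)
  expect_equal(back$motion, run$motion, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back$kept_volumes, run$kept_volumes)
})
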