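# Feature construction: structural counts, Fisher-z connectivity, seed
# maps, control templates and template resemblance.

test_that("22 ROIs yield 231 pairwise and 253 imaging features", {
  rs <- default_roi_set()
  expect_equal(nrow(rs), 22)
  expect_equal(length(docprog:::fc_pair_names(rs)), 231)
  expect_equal(docprog:::n_imaging_features(rs), 253)
  expect_equal(length(canonical_feature_names(rs)), 257)

  ts <- gen_roi_timeseries(1, cohort_spec(seed = 1), n_volumes = 50, seed = 2)
  expect_length(pairwise_fc(ts), 231)
})

test_that("pairwise connectivity matches a direct correlation oracle", {
  set.seed(5)
  ts <- matrix(stats::rnorm(4 * 60), 4)
  rownames(ts) <- letters[1:4]
  z <- pairwise_fc(ts)
  expect_equal(unname(z[1]), atanh(stats::cor(ts[1, ], ts[2, ])),
               tolerance = 1e-12)
  expect_equal(unname(z[6]), atanh(stats::cor(ts[3, ], ts[4, ])),
               tolerance = 1e-12)
  expect_named(z, c("fc_a__b", "fc_a__c", "fc_a__d", "fc_b__c", "fc_b__d",
                    "fc_c__d"))

  # duplicated rows: r = 1 is clipped, not infinite
  ts2 <- rbind(ts, e = ts[1, ])
  z2 <- pairwise_fc(ts2)
  expect_true(is.finite(z2["fc_a__e"]))
  expect_equal(unname(z2["fc_a__e"]), atanh(1 - 1e-7))

  ts3 <- ts; ts3[2, ] <- 3
  expect_error(pairwise_fc(ts3), regexp = "constant",
               class = "docprog_input_error")
  expect_error(pairwise_fc(ts[, 1:2]), class = "docprog_input_error")
})

test_that("independent series give near-zero connectivity at long T", {
  set.seed(6)
  ts <- matrix(stats::rnorm(22 * 5000), 22)
  expect_lt(max(abs(pairwise_fc(ts))), 0.05)
})

test_that("connectivity is equivariant under ROI permutation", {
  set.seed(7)
  ts <- matrix(stats::rnorm(6 * 80), 6)
  rownames(ts) <- paste0("r", 1:6)
  z <- pairwise_fc(ts)
  perm <- sample(6)
  zp <- pairwise_fc(ts[perm, ])
  # map permuted names back: same pair -> same value
  canon <- function(nm) {
    parts <- sub("^fc_", "", nm)
    vapply(strsplit(parts, "__"), function(p)
      paste(sort(p), collapse = "__"), "")
  }
  expect_equal(unname(z[match(canon(names(zp)), canon(names(z)))]),
               unname(zp), tolerance = 1e-12)
})

test_that("seed z-maps match the closed form and flag degenerate input", {
  rs <- tiny_roi_set()
  ts <- gen_roi_timeseries(1, cohort_spec(n_patients = 2, n_controls = 0,
                                          roiset = rs,
                                          effect_weights = numeric(14),
                                          seed = 1),
                           n_volumes = 40, seed = 3)
  run <- gen_bold_nifti(ts, rs, tiny_grid(), noise_sd = 0.3, seed = 4)
  zm <- seed_zmap(run, ts[1, ])
  idx <- which(run$mask, arr.ind = TRUE)[25, ]
  v <- run$data[idx[1], idx[2], idx[3], ]
  expect_equal(zm[idx[1], idx[2], idx[3]], fisher_z(stats::cor(v, ts[1, ])),
               tolerance = 1e-12)
  expect_true(all(is.na(zm[!run$mask])))

  # a voxel identical to the seed hits the clipped maximum; negated, the minimum
  run2 <- run
  run2$data[idx[1], idx[2], idx[3], ] <- ts[1, ]
  zm2 <- seed_zmap(run2, ts[1, ])
  expect_equal(zm2[idx[1], idx[2], idx[3]], atanh(1 - 1e-7))
  run2$data[idx[1], idx[2], idx[3], ] <- -ts[1, ]
  zm3 <- seed_zmap(run2, ts[1, ])
  expect_equal(zm3[idx[1], idx[2], idx[3]], -atanh(1 - 1e-7))

  expect_error(seed_zmap(run, rep(1, 40)), class = "docprog_input_error")
})

test_that("network templates implement the one-sample t with a degenerate cap", {
  # hand-computable 3-control case at one voxel
  mk <- function(v) list(net = array(v, c(1, 1, 1)))
  tmpl <- build_network_templates(list(mk(0.1), mk(0.2), mk(0.3)))
  expect_equal(tmpl$net$statistic[1, 1, 1], 0.2 / (0.1 / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(tmpl$net$n, 3)

  # identical non-zero maps: capped t everywhere
  same <- lapply(1:3, function(i) list(net = array(0.4, c(2, 2, 1))))
  expect_true(all(build_network_templates(same)$net$statistic == 100))

  # null calibration: fraction of |t| above the critical value is about alpha
  set.seed(8)
  null_maps <- lapply(1:20, function(i)
    list(net = array(stats::rnorm(500), c(10, 10, 5))))
  tmap <- build_network_templates(null_maps)$net$statistic
  frac <- mean(abs(tmap) > stats::qt(0.975, df = 19))
  expect_lt(abs(frac - 0.05), 0.03)

  expect_error(build_network_templates(list(mk(1), mk(2))),
               class = "docprog_input_error")
})

test_that("resemblance is a bounded, affine-invariant spatial correlation", {
  set.seed(9)
  tmap <- array(stats::rnorm(200), c(10, 10, 2))
  templates <- list(default_mode = list(statistic = tmap, n = 5))
  rs <- roi_set(data.frame(name = c("A", "B"), network = "default_mode",
                           x = c(-6, 6), y = 0, z = 0, radius = 3))
  expect_equal(unname(resemblance_features(list(tmap, tmap), templates, rs)),
               c(1, 1))
  expect_equal(unname(resemblance_features(list(-tmap, -tmap), templates, rs)),
               c(-1, -1))
  noisy <- tmap + array(stats::rnorm(200, 0, 0.5), dim(tmap))
  r0 <- resemblance_features(list(noisy, noisy), templates, rs)
  r1 <- resemblance_features(list(3 * noisy + 2, noisy), templates, rs)
  expect_equal(r0, r1, tolerance = 1e-12)
  expect_true(all(abs(r0) <= 1))
  expect_error(resemblance_features(list(tmap * 0 + 1, tmap), templates, rs),
               class = "docprog_input_error")
})

test_that("degraded subjects lose template resemblance on every ROI", {
  rs <- tiny_roi_set()
  spec <- cohort_spec(n_patients = 2, n_controls = 4, roiset = rs,
                      effect_weights = numeric(14), seed = 2)
  czm <- lapply(1:4, function(i) {
    tsc <- gen_roi_timeseries(1, spec, 60, seed = 100 + i)
    control_network_zmaps(
      gen_bold_nifti(tsc, rs, tiny_grid(), noise_sd = 0.2, seed = 200 + i), rs)
  })
  tmpl <- build_network_templates(czm)
  prof_hi <- compute_connectivity_profile(
    gen_bold_nifti(gen_roi_timeseries(1, spec, 60, seed = 11), rs,
                   tiny_grid(), noise_sd = 0.2, seed = 12), rs, tmpl, "hi")
  prof_lo <- compute_connectivity_profile(
    gen_bold_nifti(gen_roi_timeseries(0.05, spec, 60, seed = 11), rs,
                   tiny_grid(), noise_sd = 2, seed = 12), rs, tmpl, "lo")
  expect_true(all(prof_hi$resemblance > prof_lo$resemblance))
  expect_length(prof_hi$fc, 6)
})

test_that("ROI extraction handles single-voxel and duplicated-series ROIs", {
  # centres on voxel centres (grid axis values are -22.5 + 3k)
  rs1 <- roi_set(data.frame(name = c("P", "Q"), network = "auditory",
                            x = c(-10.5, 10.5), y = 1.5, z = 1.5, radius = 1))
  ts <- matrix(stats::rnorm(2 * 15), 2)
  ts[2, ] <- ts[1, ]
  rownames(ts) <- rs1$name
  run <- gen_bold_nifti(ts, rs1, tiny_grid(), noise_sd = 0)
  ex <- extract_roi_timeseries(run, rs1)
  expect_equal(ex["P", ], ex["Q", ])        # disjoint ROIs, equal series
  # a one-voxel ROI equals that voxel's series
  idx <- docprog:::sphere_voxel_indices(c(16, 16, 8), c(3, 3, 3), run$origin,
                                        c(-10.5, 1.5, 1.5), 1)
  expect_length(idx, 1)
  vox <- matrix(run$data, prod(dim(run$data)[1:3]))[idx, ]
  expect_equal(unname(ex["P", ]), unname(vox))

  far <- roi_set(data.frame(name = c("P", "X"), network = "auditory",
                            x = c(-10.5, 19.5), y = c(1.5, 19.5),
                            z = 1.5, radius = 1))
  run$mask[docprog:::sphere_voxel_indices(c(16, 16, 8), c(3, 3, 3),
                                          run$origin, c(19.5, 19.5, 1.5), 1)] <- FALSE
  expect_error(extract_roi_timeseries(run, far), regexp = "X",
               class = "docprog_input_error")
})

test_that("feature vectors assemble in the canonical order with dummy coding", {
  rs <- tiny_roi_set()
  prof <- structure(list(
    fc = stats::setNames(stats::rnorm(6), docprog:::fc_pair_names(rs)),
    resemblance = stats::setNames(stats::runif(4, -1, 1),
                                  docprog:::resemblance_names(rs)),
    id = "s1"), class = "connectivity_profile")
  v <- assemble_feature_vector(prof, list(age = 40, duration = 3,
                                          etiology = "trauma"))
  expect_identical(names(v), canonical_feature_names(rs))
  expect_equal(unname(v[c("dummy_stroke", "dummy_anoxia")]), c(0, 0))
  v2 <- assemble_feature_vector(prof, list(age = 40, duration = 3,
                                           etiology = "anoxia"))
  expect_equal(unname(v2[c("dummy_stroke", "dummy_anoxia")]), c(0, 1))
  expect_error(assemble_feature_vector(prof, list(age = 40, duration = NA,
                                                  etiology = "trauma")),
               regexp = "duration", class = "docprog_input_error")
})
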