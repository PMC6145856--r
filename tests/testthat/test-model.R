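# PLS regression, latent-variable choice, scoring, sMC importance and the
# ROC cutoff.

test_that("PLS1 at full rank reproduces the normal-equations solution", {
  set.seed(41)
  X <- matrix(stats::rnorm(20 * 3), 20)
  y <- stats::rnorm(20)
  fit <- fit_plsr(X, y, n_latent = 3)
  beta <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(unname(fit$coefficients), beta[-1], tolerance = 1e-8)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-8)
  expect_equal(fit$fitted, drop(cbind(1, X) %*% beta), tolerance = 1e-8)
})

test_that("degenerate PLS inputs behave as documented", {
  set.seed(42)
  X <- matrix(stats::rnorm(30 * 4), 30)
  fit <- fit_plsr(X, rep(2.5, 30), n_latent = 3)
  expect_equal(unname(fit$coefficients), rep(0, 4))
  expect_equal(fit$intercept, 2.5)

  x1 <- stats::rnorm(25)
  fit2 <- fit_plsr(matrix(3 * x1, ncol = 1), 3 * x1 + 1, n_latent = 1)
  expect_equal(stats::cor(fit2$fitted, 3 * x1 + 1)^2, 1, tolerance = 1e-12)

  Xc <- cbind(x1, x1)                         # rank 1: reduce with warning
  expect_warning(fit_plsr(Xc, stats::rnorm(25), n_latent = 2),
                 regexp = "rank")
})

test_that("cross-validation picks a parsimonious latent dimension", {
  set.seed(43)
  n <- 200
  basis <- matrix(stats::rnorm(n * 2), n)
  X <- cbind(basis %*% matrix(stats::rnorm(10), 2),
             basis %*% matrix(stats::rnorm(10), 2))
  y <- drop(basis %*% c(1, -2))               # exactly rank-2 signal
  expect_lte(choose_n_latent(X, y, max_lv = 6, seed = 2), 2)

  ynoise <- stats::rnorm(n)
  expect_equal(choose_n_latent(X, ynoise, max_lv = 6, seed = 2), 1L)

  expect_error(choose_n_latent(X, y, max_lv = 0), class = "docprog_input_error")
  expect_error(docprog:::plsr_cv_rmse(X[1:4, ], y[1:4], folds = 10),
               class = "docprog_input_error")
})

test_that("scoring is the documented affine form with the >= cutoff rule", {
  model <- structure(list(
    feature_names = c("a", "b", "c"),
    imaging_feature_names = c("a", "b"),
    train_means = c(a = 1, b = 2, c = 3),
    train_sds = c(a = 2, b = 0.5, c = 1),
    coefficients = c(a = 1.5, b = -2, c = 0.25),
    intercept = 10, cutoff = 11, auc = NA_real_,
    n_latent = 3), class = "prognostic_model")
  x <- c(a = 2, b = 1, c = 5)
  expected <- 10 + 1.5 * (2 - 1) / 2 - 2 * (1 - 2) / 0.5 + 0.25 * (5 - 3) / 1
  pr <- predict_score(model, x)
  expect_equal(pr$predicted_score, expected, tolerance = 1e-12)
  expect_equal(pr$imaging_subscore, 1.5 * 0.5 - 2 * (-2), tolerance = 1e-12)
  expect_identical(pr$label, "recovery")      # 5.25 + ... >= 11

  # a subject at the training means scores exactly the intercept
  at_means <- predict_score(model, c(a = 1, b = 2, c = 3))
  expect_equal(at_means$predicted_score, 10, tolerance = 1e-12)

  # score exactly equal to the cutoff classifies as recovery
  model$cutoff <- at_means$predicted_score
  expect_identical(predict_score(model, c(a = 1, b = 2, c = 3))$label,
                   "recovery")

  expect_error(predict_score(model, c(a = 1, b = 2)), regexp = "c",
               class = "docprog_input_error")
})

test_that("training scores are reproduced bit for bit from stored constants", {
  d <- planted_design(n = 60, p = 30, k = 3, seed = 8)
  m <- suppressMessages(fit_prognostic_pipeline(d$X, NULL, d$y, seed = 3))
  again <- predict_score(m, d$X)$predicted_score
  expect_identical(again, m$train_scores)

  # prediction is monotone in each feature, in the coefficient's direction
  base <- d$X[1, , drop = FALSE]
  f1 <- m$imaging_feature_names[1]
  up <- base; up[, f1] <- up[, f1] + 1
  delta <- predict_score(m, up)$predicted_score -
    predict_score(m, base)$predicted_score
  expect_equal(sign(delta), sign(m$coefficients[[f1]]))
})

test_that("sMC importance partitions variance along the prediction direction", {
  set.seed(44)
  n <- 50
  yhat_dir <- stats::rnorm(n)
  orth <- stats::residuals(stats::lm(stats::rnorm(n) ~ yhat_dir))
  X <- cbind(a = yhat_dir, b = orth, c = stats::rnorm(n))
  Fv <- smc_importance(X, yhat = yhat_dir)
  expect_true(is.infinite(Fv["a"]))           # collinear with the direction
  expect_lt(Fv["b"], 1e-10)                   # orthogonal -> F = 0

  # hand check of the F form for a generic predictor
  xc <- X[, "c"] - mean(X[, "c"])
  yh <- yhat_dir - mean(yhat_dir)
  xhat <- yh * sum(yh * xc) / sum(yh^2)
  expect_equal(unname(Fv["c"]),
               sum(xhat^2) / (sum((xc - xhat)^2) / (n - 2)),
               tolerance = 1e-10)

  expect_equal(unname(suppressMessages(
    smc_importance(X, coefficients = c(0, 0, 0)))), rep(0, 3))
})

test_that("sMC separates informative from noise predictors across seeds", {
  hits <- 0
  for (s in 1:20) {
    d <- planted_design(n = 100, p = 50, k = 5, noise_sd = 0.5, seed = s)
    f <- fit_plsr(scale(d$X), d$y, n_latent = 3)
    Fv <- smc_importance(scale(d$X), f$coefficients)
    if (stats::median(Fv[1:5]) > max(Fv[6:50])) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the planted anti-correlation feature gets a negative weight", {
  neg <- 0
  for (s in 1:20) {
    coh <- gen_cohort(cohort_spec(seed = s))
    blk <- cohort_blocks(coh)
    m <- suppressMessages(fit_prognostic_pipeline(
      blk$imaging, blk$clinical, blk$y, recovery = blk$recovery,
      seed = derive_seed(s, 1)))
    cf <- m$coefficients["fc_DMN.aMPFC__ExecuContr.DMPFC"]
    if (!is.na(cf) && cf < 0) neg <- neg + 1
  }
  expect_gte(neg, 18)
})

test_that("the ROC cutoff matches an exhaustive threshold search", {
  set.seed(45)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    sc <- round(stats::rnorm(n), sample(0:2, 1))
    lb <- stats::runif(n) < 0.5
    if (length(unique(lb)) < 2) next
    r <- roc_cutoff(sc, lb)
    cand <- c(-Inf, sort(unique(sc)) - 1e-9, sort(unique(sc)) + 1e-9, Inf)
    J <- vapply(cand, function(th) {
      pred <- sc >= th
      sum(pred & lb) / sum(lb) + sum(!pred & !lb) / sum(!lb)
    }, numeric(1))
    pred <- sc >= r$cutoff
    J_star <- sum(pred & lb) / sum(lb) + sum(!pred & !lb) / sum(!lb)
    expect_equal(J_star, max(J), tolerance = 1e-9)
  }
})

test_that("AUC matches an independent implementation and known boundaries", {
  set.seed(46)
  sc <- stats::rnorm(60)
  lb <- stats::runif(60) < 0.4
  mine <- roc_cutoff(sc, lb)$auc
  skip_if_not_installed("pROC")
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(lb, sc, direction = "<", levels = c(FALSE, TRUE)))))
  expect_equal(mine, ref, tolerance = 1e-12)

  # perfectly separated classes
  r <- roc_cutoff(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_true(r$cutoff > 3 && r$cutoff <= 10)

  # labels independent of scores: AUC near 1/2
  set.seed(47)
  sc2 <- stats::rnorm(4000); lb2 <- stats::runif(4000) < 0.5
  expect_lt(abs(roc_cutoff(sc2, lb2)$auc - 0.5), 0.05)

  expect_error(roc_cutoff(1:5, rep(TRUE, 5)), class = "docprog_input_error")
})

test_that("prognostic models survive a lossless JSON round trip", {
  coh <- gen_cohort(cohort_spec(n_patients = 30, n_controls = 0, seed = 5))
  blk <- cohort_blocks(coh)
  m <- suppressMessages(fit_prognostic_pipeline(
    blk$imaging, blk$clinical, blk$y, recovery = blk$recovery, seed = 2))
  path <- file.path(withr::local_tempdir(), "model.json")
  model_to_json(m, path)
  back <- model_from_json(path)
  for (f in c("feature_names", "train_means", "train_sds", "coefficients",
              "intercept", "cutoff", "auc", "n_latent")) {
    expect_identical(back[[f]], m[[f]])
  }
  expect_identical(predict_score(back, cbind(blk$imaging, blk$clinical))$predicted_score,
                   m$train_scores)
})
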