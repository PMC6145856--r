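# Model validation: confusion-matrix arithmetic, optimism-corrected
# bootstrap (with feature selection re-run inside every replicate),
# out-of-bag majority voting, permutation tests, Bland-Altman agreement,
# and the single-domain vs multidomain model comparison.

#' Confusion counts from predicted and true labels
#'
#' @param predicted logical (or "recovery"/"non_recovery") predictions.
#' @param truth logical truth (`TRUE` = recovery, i.e. GOS >= 3).
#' @return a `confusion_counts` list: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (is.character(predicted)) predicted <- predicted == "recovery"
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  structure(list(tp = sum(predicted & truth), fp = sum(predicted & !truth),
                 tn = sum(!predicted & !truth), fn = sum(!predicted & truth)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Standard definitions; `f1 = 2 tp / (2 tp + fp + fn)`. A rate whose
#' denominator is zero is reported as `NA` (absent), never as 0.
#'
#' @param counts a `confusion_counts`, or a list/vector with `tp`, `fp`,
#'   `tn`, `fn`.
#' @return list: `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `f1`.
#' @export
confusion_metrics <- function(counts) {
  cc <- lapply(counts[c("tp", "fp", "tn", "fn")], as.numeric)
  if (any(vapply(cc, function(x) length(x) != 1 || is.na(x) || x < 0,
                 logical(1))))
    input_error("counts must be four non-negative numbers")
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  with(cc, list(
    accuracy = rate(tp + tn, tp + tn + fp + fn),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    f1 = rate(2 * tp, 2 * tp + fp + fn)
  ))
}

# Fit the pipeline and return NULL instead of erroring (used inside
# resampling loops, where degenerate replicates abstain).
fit_pipeline_or_null <- function(imaging, clinical, y, recovery, config, seed) {
  tryCatch(
    suppressWarnings(suppressMessages(
      fit_prognostic_pipeline(imaging, clinical, y, recovery = recovery,
                              config = config, seed = seed))),
    error = function(e) NULL)
}

#' Optimism-corrected bootstrap of the apparent R-squared
#'
#' Draws B bootstrap samples of the training rows; on each, the *entire*
#' pipeline (correlation filter, CARS-PLSR, PLS fit) is re-run, and the
#' optimism is the bootstrap-sample R-squared minus the R-squared of that
#' same model applied to the original data. The corrected estimate is the
#' apparent R-squared minus the mean optimism. Replicates with a constant
#' resampled response are skipped and counted. With `refit_selection =
#' FALSE` the feature subset is frozen to the full-data selection
#' (diagnostic only: this is the classic leakage shortcut whose optimism is
#' biased low).
#'
#' @param imaging,clinical,y training blocks as in
#'   [fit_prognostic_pipeline()].
#' @param config a [pipeline_config()].
#' @param B bootstrap replicates (default 1000).
#' @param seed master seed.
#' @param refit_selection re-run selection inside every replicate
#'   (default `TRUE`).
#' @return list: `apparent_r2`, `optimism`, `corrected_r2`, `B_effective`,
#'   `optimisms`.
#' @export
optimism_bootstrap <- function(imaging, clinical, y, config = pipeline_config(),
                               B = 1000, seed = 1L, refit_selection = TRUE) {
  n <- length(y)
  full <- fit_prognostic_pipeline(imaging, clinical, y, recovery = NULL,
                                  config = config, seed = seed)
  apparent <- full$apparent_r2
  frozen_imaging <- if (!refit_selection && !is.null(imaging))
    imaging[, full$imaging_feature_names, drop = FALSE] else imaging
  frozen_config <- if (!refit_selection) {
    cfg <- config; cfg$alpha <- 1; cfg$cars_runs <- 0; cfg
  } else config

  opt <- rep(NA_real_, B)
  skipped <- 0
  for (b in seq_len(B)) {
    sb <- derive_seed(seed, 10000L + b)
    idx <- with_seed(sb, sample(n, n, replace = TRUE))
    if (stats::sd(y[idx]) == 0) { skipped <- skipped + 1; next }
    im_b <- if (!is.null(frozen_imaging))
      frozen_imaging[idx, , drop = FALSE] else NULL
    cl_b <- if (!is.null(clinical)) clinical[idx, , drop = FALSE] else NULL
    mb <- if (refit_selection)
      fit_pipeline_or_null(im_b, cl_b, y[idx], NULL, config, sb)
    else
      fit_pipeline_or_null(im_b, cl_b, y[idx], NULL, frozen_config, sb)
    if (is.null(mb)) { skipped <- skipped + 1; next }
    newdat <- cbind(if (!is.null(frozen_imaging)) frozen_imaging,
                    if (!is.null(clinical)) clinical)
    r2_boot <- mb$apparent_r2
    r2_orig <- rsq(predict_score(mb, newdat)$predicted_score, y)
    opt[b] <- r2_boot - r2_orig
  }
  optimism <- mean(opt, na.rm = TRUE)
  list(apparent_r2 = apparent, optimism = optimism,
       corrected_r2 = apparent - optimism,
       B_effective = B - skipped, optimisms = opt)
}

#' Out-of-bag classification estimate by bootstrap majority vote
#'
#' For each subject i, B bootstrap learning sets of size n-1 are drawn from
#' the remaining rows; on each, the full pipeline (selection included) and
#' its ROC cutoff are re-fit and vote recovery / non-recovery for subject
#' i. The majority label (ties and all-abstain default to non-recovery,
#' the conservative call) is compared with the GOS truth.
#'
#' @param imaging,clinical,y training blocks.
#' @param recovery logical truth labels (GOS >= 3).
#' @param config a [pipeline_config()].
#' @param B bootstrap learning sets per subject (default 1000).
#' @param seed master seed.
#' @return list: `metrics`, `counts`, `predicted` (per-subject labels),
#'   `votes` (per-subject recovery-vote fraction), `abstained`.
#' @export
oob_accuracy <- function(imaging, clinical, y, recovery,
                         config = pipeline_config(), B = 1000, seed = 1L) {
  n <- length(y)
  if (n < 10) input_error("at least 10 subjects are required")
  predicted <- logical(n)
  votes <- numeric(n)
  abstained <- 0L
  for (i in seq_len(n)) {
    pool <- setdiff(seq_len(n), i)
    rec_votes <- 0L; valid <- 0L
    for (b in seq_len(B)) {
      sb <- derive_seed(seed, i * 4096L + b)
      rows <- with_seed(sb, sample(pool, n - 1, replace = TRUE))
      if (length(unique(recovery[rows])) < 2) { abstained <- abstained + 1L; next }
      im_b <- if (!is.null(imaging)) imaging[rows, , drop = FALSE] else NULL
      cl_b <- if (!is.null(clinical)) clinical[rows, , drop = FALSE] else NULL
      mb <- fit_pipeline_or_null(im_b, cl_b, y[rows], recovery[rows], config, sb)
      if (is.null(mb) || is.na(mb$cutoff)) { abstained <- abstained + 1L; next }
      newrow <- cbind(if (!is.null(imaging)) imaging[i, , drop = FALSE],
                      if (!is.null(clinical)) clinical[i, , drop = FALSE])
      lab <- predict_score(mb, newrow)$label
      valid <- valid + 1L
      if (lab == "recovery") rec_votes <- rec_votes + 1L
    }
    votes[i] <- if (valid > 0) rec_votes / valid else NA_real_
    predicted[i] <- valid > 0 && rec_votes > valid / 2
  }
  counts <- confusion_counts(predicted, recovery)
  list(metrics = confusion_metrics(counts), counts = counts,
       predicted = predicted, votes = votes, abstained = abstained)
}

#' Permutation test of a pipeline-level statistic
#'
#' Permutes the response, recomputes `statistic_fn(X, y_perm)` B times, and
#' reports `p = (1 + #{permuted >= observed}) / (1 + B)`; the smallest
#' attainable p is `1 / (1 + B)`.
#'
#' @param statistic_fn function of `(X, y)` returning a scalar; for a
#'   pipeline-level test, pass a closure that re-runs selection and fitting.
#' @param X the (fixed) predictor object handed to `statistic_fn`.
#' @param y response to permute.
#' @param B permutations (default 1000).
#' @param seed master seed.
#' @return list: `p`, `observed`, `permuted`.
#' @export
permutation_test <- function(statistic_fn, X, y, B = 1000, seed = 1L) {
  if (B < 1) input_error("B must be >= 1")
  observed <- statistic_fn(X, y)
  permuted <- vapply(seq_len(B), function(b) {
    yp <- with_seed(derive_seed(seed, 20000L + b), sample(y))
    statistic_fn(X, yp)
  }, numeric(1))
  list(p = (1 + sum(permuted >= observed)) / (1 + B),
       observed = observed, permuted = permuted)
}

#' Bland-Altman agreement between predicted and observed scores
#'
#' Differences `d = predicted - observed`; limits of agreement are
#' `mean(d) +/- 1.96 sd(d)`; the p-value is a one-sample t-test of the
#' differences against zero (reported as 1, with a note, when the
#' differences have zero variance).
#'
#' @param predicted,observed equal-length numeric vectors (n >= 3).
#' @return list: `mean_diff`, `sd_diff`, `lower`, `upper`, `t_test_p`,
#'   `note`.
#' @export
bland_altman <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3)
    input_error("predicted and observed must have equal length >= 3")
  d <- predicted - observed
  m <- mean(d); s <- stats::sd(d)
  if (s < 1e-12) {
    return(list(mean_diff = m, sd_diff = s, lower = m, upper = m,
                t_test_p = 1,
                note = "zero-variance differences; p reported as 1"))
  }
  list(mean_diff = m, sd_diff = s,
       lower = m - 1.96 * s, upper = m + 1.96 * s,
       t_test_p = stats::t.test(d, mu = 0)$p.value, note = NULL)
}

# Signed root-mean-square standardized effect between two accuracy
# distributions: RMS of per-replicate differences standardized by the
# pooled SD, carrying the sign of the mean difference.
psi_effect <- function(a, b) {
  d <- a - b
  sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
  if (!is.finite(sp) || sp < 1e-12) return(0)
  sign_d <- if (mean(d) == 0) 1 else sign(mean(d))
  sign_d * sqrt(mean((d / sp)^2))
}

#' Compare clinical-only, imaging-only and combined models by bootstrap
#'
#' Per bootstrap resample of the training rows, all three domain models are
#' re-fit (selection included) and their classification accuracies recorded
#' on each test table. Reports, per test table: mean and SD of each model's
#' accuracy distribution, a repeated-measures ANOVA p across the three
#' models, pairwise paired t-tests, and the signed RMS standardized effect
#' Psi for each pair. Replicates where a domain cannot be fit (degenerate
#' resample, empty selection) are excluded pairwise and counted.
#'
#' @param train list with `imaging`, `clinical`, `y`, `recovery`.
#' @param test_tables named list of test sets, each a list with `imaging`,
#'   `clinical`, `recovery`.
#' @param config a [pipeline_config()].
#' @param B bootstrap replicates (default 1000).
#' @param seed master seed.
#' @return nested list, one element per test table: `accuracies` (B x 3),
#'   `mean`, `sd`, `anova_p`, `paired_p`, `psi`, `n_failed`.
#' @export
compare_models <- function(train, test_tables, config = pipeline_config(),
                           B = 1000, seed = 1L) {
  domains <- c("clinical", "imaging", "combined")
  n <- length(train$y)
  acc <- lapply(test_tables, function(.)
    matrix(NA_real_, B, 3, dimnames = list(NULL, domains)))
  for (b in seq_len(B)) {
    sb <- derive_seed(seed, 30000L + b)
    idx <- with_seed(sb, sample(n, n, replace = TRUE))
    if (length(unique(train$recovery[idx])) < 2 ||
        stats::sd(train$y[idx]) == 0) next
    fits <- list(
      clinical = fit_pipeline_or_null(NULL, train$clinical[idx, , drop = FALSE],
                                      train$y[idx], train$recovery[idx],
                                      config, sb),
      imaging = fit_pipeline_or_null(train$imaging[idx, , drop = FALSE], NULL,
                                     train$y[idx], train$recovery[idx],
                                     config, sb),
      combined = fit_pipeline_or_null(train$imaging[idx, , drop = FALSE],
                                      train$clinical[idx, , drop = FALSE],
                                      train$y[idx], train$recovery[idx],
                                      config, sb)
    )
    for (tt in names(test_tables)) {
      tab <- test_tables[[tt]]
      newdat <- cbind(tab$imaging, tab$clinical)
      for (d in domains) {
        if (is.null(fits[[d]]) || is.na(fits[[d]]$cutoff)) next
        lab <- predict_score(fits[[d]], newdat)$label
        acc[[tt]][b, d] <- mean((lab == "recovery") == tab$recovery)
      }
    }
  }
  out <- lapply(names(test_tables), function(tt) {
    A <- acc[[tt]]
    complete <- stats::complete.cases(A)
    Ac <- A[complete, , drop = FALSE]
    pairs <- utils::combn(domains, 2, simplify = FALSE)
    paired_p <- psi <- stats::setNames(numeric(length(pairs)),
                                       vapply(pairs, paste, "", collapse = "_vs_"))
    for (k in seq_along(pairs)) {
      a <- Ac[, pairs[[k]][1]]; b2 <- Ac[, pairs[[k]][2]]
      paired_p[k] <- if (stats::sd(a - b2) < 1e-12) 1
                     else stats::t.test(a, b2, paired = TRUE)$p.value
      psi[k] <- psi_effect(a, b2)
    }
    long <- data.frame(acc = as.vector(Ac),
                       model = factor(rep(domains, each = nrow(Ac))),
                       rep = factor(rep(seq_len(nrow(Ac)), 3)))
    anova_p <- if (stats::sd(long$acc) < 1e-12 ||
                   all(abs(Ac - Ac[, 1]) < 1e-12)) 1 else {
      fit <- stats::aov(acc ~ model + Error(rep), data = long)
      summary(fit)[["Error: Within"]][[1]]["model", "Pr(>F)"]
    }
    list(accuracies = A, mean = colMeans(Ac), sd = apply(Ac, 2, stats::sd),
         anova_p = anova_p, paired_p = paired_p, psi = psi,
         n_failed = sum(!complete))
  })
  names(out) <- names(test_tables)
  out
}
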