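# The prognostic model: two-stage selection on the imaging block, z-scored
# predictors, a 3-latent-variable PLS regression of the follow-up CRS-R,
# sMC predictor importance, and an ROC-derived classification cutoff
# (score >= cutoff => predicted consciousness recovery).

#' Modelling hyper-parameters
#'
#' @param alpha stage-1 correlation-filter significance level.
#' @param cars_runs CARS iteration count N.
#' @param cars_fraction CARS row-sampling fraction.
#' @param cv_folds folds for CARS RMSECV and latent-variable CV.
#' @param n_latent PLS latent variables: a count (default 3) or `"cv"` to
#'   choose by cross-validation.
#' @param max_lv cap on latent variables in CV searches.
#' @param cutoff_method classification-threshold criterion; `"youden"`
#'   (maximal sensitivity + specificity) is the only shipped criterion.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, cars_runs = 50, cars_fraction = 0.8,
                            cv_folds = 5, n_latent = 3, max_lv = 10,
                            cutoff_method = "youden") {
  if (!identical(cutoff_method, "youden"))
    config_error("unknown cutoff_method")
  if (alpha < 0 || alpha > 1) config_error("alpha must lie in [0, 1]")
  structure(list(alpha = alpha, cars_runs = cars_runs,
                 cars_fraction = cars_fraction, cv_folds = cv_folds,
                 n_latent = n_latent, max_lv = max_lv,
                 cutoff_method = cutoff_method),
            class = "pipeline_config")
}

#' Fit the full prognostic pipeline
#'
#' Runs the correlation filter and CARS-PLSR on the imaging block, appends
#' the clinical covariates, z-scores every retained predictor with training
#' constants, fits the PLS regression of the follow-up CRS-R (left on its
#' natural 0-23 scale), computes sMC importances, and -- when recovery
#' labels with both classes are supplied -- derives the ROC cutoff on the
#' training scores.
#'
#' @param imaging n x p imaging feature matrix (canonical column names), or
#'   `NULL` for a clinical-only model.
#' @param clinical n x 4 clinical covariate matrix (`age`, `duration`,
#'   `dummy_stroke`, `dummy_anoxia`), or `NULL` for an imaging-only model.
#' @param y follow-up CRS-R scores.
#' @param recovery optional logical recovery labels (GOS >= 3).
#' @param config a [pipeline_config()].
#' @param seed master seed for the stochastic selection stage.
#' @return a `prognostic_model`: selected `feature_names`, standardization
#'   constants, PLS `coefficients` (standardized scale) and `intercept`
#'   (CRS-R scale), `n_latent`, `cutoff`, `auc`, `smc_f`, training scores,
#'   the `selection` audit trail, `config` and `seed`.
#' @export
fit_prognostic_pipeline <- function(imaging = NULL, clinical = NULL, y,
                                    recovery = NULL,
                                    config = pipeline_config(), seed = 1L) {
  n <- length(y)
  selection <- NULL
  kept_imaging <- character(0)
  Xi <- NULL
  if (!is.null(imaging) && ncol(imaging) > 0) {
    imaging <- as.matrix(imaging)
    filt <- correlation_filter(imaging, y, config$alpha)
    kept_idx <- filt$kept
    cars <- NULL
    if (length(kept_idx) >= 2 && config$cars_runs >= 2) {
      cars <- cars_plsr_select(imaging[, kept_idx, drop = FALSE], y,
                               runs = config$cars_runs,
                               sample_fraction = config$cars_fraction,
                               max_lv = min(config$max_lv, n - 2),
                               cv_folds = config$cv_folds,
                               seed = derive_seed(seed, 101L))
      kept_idx <- kept_idx[cars$kept]
    }
    selection <- list(filter = filt, cars = cars,
                      kept = colnames(imaging)[kept_idx] %||% kept_idx)
    Xi <- imaging[, kept_idx, drop = FALSE]
    kept_imaging <- colnames(Xi) %||% character(0)
  }
  X <- cbind(Xi, if (!is.null(clinical)) as.matrix(clinical))
  if (is.null(X) || ncol(X) == 0)
    input_error("no predictors: selection removed every imaging feature and no clinical block was supplied")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance predictor(s)", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) == 0) input_error("all predictors are constant")
  }
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  Z <- sweep(sweep(X, 2, means), 2, sds, "/")

  nl <- config$n_latent
  if (identical(nl, "cv"))
    nl <- choose_n_latent(Z, y, folds = config$cv_folds,
                          max_lv = min(config$max_lv, ncol(Z)),
                          seed = derive_seed(seed, 202L))
  fit <- fit_plsr(Z, y, n_latent = min(nl, ncol(Z), n - 1), quiet = TRUE)

  model <- structure(list(
    feature_names = colnames(X),
    imaging_feature_names = intersect(colnames(X), kept_imaging),
    train_means = means, train_sds = sds,
    n_latent = as.integer(fit$n_latent),
    coefficients = fit$coefficients,
    intercept = fit$intercept,
    cutoff = NA_real_, auc = NA_real_,
    smc_f = smc_importance(Z, fit$coefficients),
    selection = selection,
    config = config, seed = as.integer(seed)
  ), class = "prognostic_model")

  train_pred <- predict_score(model, X)
  model$train_scores <- train_pred$predicted_score
  model$apparent_r2 <- rsq(model$train_scores, y)

  if (!is.null(recovery) && length(unique(recovery[!is.na(recovery)])) == 2) {
    roc <- roc_cutoff(model$train_scores, recovery)
    model$cutoff <- roc$cutoff
    model$auc <- roc$auc
  }
  model
}

#' @export
print.prognostic_model <- function(x, ...) {
  cat(sprintf("<prognostic_model> %d predictors (%d imaging), %d latent variables\n",
              length(x$feature_names), length(x$imaging_feature_names),
              x$n_latent))
  cat(sprintf("  apparent R2 %.3f | AUC %s | cutoff %s\n", x$apparent_r2,
              formatC(x$auc, digits = 3), formatC(x$cutoff, digits = 3)))
  invisible(x)
}

#' Score and classify subjects with a fitted prognostic model
#'
#' `score = intercept + sum_j coef_j * (x_j - mean_j) / sd_j`; the imaging
#' subscore is the same sum restricted to the imaging features (no
#' intercept). The label is `recovery` iff `score >= cutoff` ("higher than
#' or equal to" the threshold).
#'
#' @param model a `prognostic_model`.
#' @param newdata matrix or data frame containing every model feature as a
#'   named column.
#' @param ids optional subject identifiers (defaults to rownames).
#' @return data frame: `id`, `predicted_score`, `imaging_subscore`,
#'   `label` (`"recovery"` / `"non_recovery"`, `NA` if the model carries no
#'   cutoff).
#' @export
predict_score <- function(model, newdata, ids = NULL) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  missing_f <- setdiff(model$feature_names, colnames(newdata))
  if (length(missing_f))
    input_error(paste0("missing feature(s): ", paste(missing_f, collapse = ", ")))
  X <- newdata[, model$feature_names, drop = FALSE]
  Z <- sweep(sweep(X, 2, model$train_means), 2, model$train_sds, "/")
  score <- drop(Z %*% model$coefficients) + model$intercept
  im <- model$imaging_feature_names
  sub <- if (length(im))
    drop(Z[, im, drop = FALSE] %*% model$coefficients[im]) else rep(0, nrow(Z))
  label <- if (is.na(model$cutoff)) rep(NA_character_, length(score))
           else ifelse(score >= model$cutoff, "recovery", "non_recovery")
  data.frame(id = ids %||% rownames(newdata) %||% seq_along(score),
             predicted_score = score, imaging_subscore = sub,
             label = label, row.names = NULL, stringsAsFactors = FALSE)
}

#' sMC predictor importance
#'
#' Significant-multivariate-correlation F-values: each (centred) predictor
#' is regressed on the model's fitted-value direction `y_hat = X b`;
#' with `SSR_j` the explained and `SSE_j` the residual sum of squares,
#' `F_j = SSR_j / (SSE_j / (n - 2))`. Predictors collinear with the
#' prediction direction give `Inf`; an all-zero coefficient vector gives
#' all-zero F-values.
#'
#' The importance of *any* variable with respect to a fitted model can be
#' assessed by supplying the model's predicted scores through `yhat`
#' (centring is internal); this is how unselected features are ranked
#' against selected ones.
#'
#' @param X predictor matrix on the scale the coefficients act on
#'   (standardized training matrix), or any feature matrix when `yhat` is
#'   supplied.
#' @param coefficients the PLS coefficient vector (ignored when `yhat` is
#'   given).
#' @param yhat optional prediction direction to project on.
#' @return named numeric vector of F-values.
#' @export
smc_importance <- function(X, coefficients = NULL, yhat = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) input_error("at least 3 observations are required")
  if (is.null(yhat)) yhat <- drop(X %*% coefficients)
  yhat <- yhat - mean(yhat)
  ss <- sum(yhat^2)
  out <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (ss < 1e-300) {
    message("all-zero prediction direction; sMC F-values set to 0")
    return(out)
  }
  Xc <- sweep(X, 2, colMeans(X))
  proj_coef <- drop(crossprod(Xc, yhat)) / ss
  SSR <- proj_coef^2 * ss
  SSE <- colSums(Xc^2) - SSR
  SSE <- pmax(SSE, 0)
  F <- ifelse(SSE < 1e-12 * pmax(SSR, 1), Inf, SSR / (SSE / (n - 2)))
  stats::setNames(F, colnames(X))
}

#' ROC curve, AUC and optimal classification cutoff
#'
#' Threshold candidates are `-Inf`, the midpoints between consecutive
#' sorted unique scores, and `+Inf` (which makes an exhaustive search over
#' thresholds exact). The cutoff maximizes sensitivity + specificity
#' (Youden's J); ties resolve to the higher specificity, then to the lower
#' threshold. AUC is the trapezoidal area under the (FPR, TPR) curve.
#'
#' @param scores numeric predicted scores.
#' @param labels logical (or 0/1) recovery labels; both classes required.
#' @return a list: `cutoff`, `auc`, `curve` (data frame of threshold,
#'   sensitivity, specificity).
#' @export
roc_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (any(is.na(scores)) || any(is.na(labels)))
    input_error("scores and labels must be complete")
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0) input_error("both classes must be present")
  us <- sort(unique(scores))
  thr <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, Inf)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    sens[i] <- sum(pred & labels) / P
    spec[i] <- sum(!pred & !labels) / N
  }
  J <- sens + spec
  best <- which(J >= max(J) - 1e-12)
  best <- best[order(-spec[best], thr[best])][1]
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  list(cutoff = thr[best], auc = auc,
       curve = data.frame(threshold = thr, sensitivity = sens,
                          specificity = spec))
}

#' Serialize / restore a prognostic model as JSON
#'
#' Numeric fields are written at full precision so the round trip is
#' lossless.
#'
#' @param model a `prognostic_model`.
#' @param path JSON path.
#' @return `path` (write) or the restored model (read).
#' @export
model_to_json <- function(model, path) {
  payload <- list(
    schema = "docprog_prognostic_model_v1",
    feature_names = model$feature_names,
    imaging_feature_names = model$imaging_feature_names,
    train_means = as.list(model$train_means),
    train_sds = as.list(model$train_sds),
    n_latent = model$n_latent,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    cutoff = model$cutoff, auc = model$auc,
    apparent_r2 = model$apparent_r2,
    smc_f = as.list(model$smc_f),
    train_scores = model$train_scores,
    seed = model$seed,
    config = unclass(model$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  if (!file.exists(path)) input_error(paste0("model file not found: ", path))
  p <- jsonlite::fromJSON(path)
  if (!identical(p$schema, "docprog_prognostic_model_v1"))
    input_error("unrecognized model schema")
  structure(list(
    feature_names = p$feature_names,
    imaging_feature_names = as.character(p$imaging_feature_names),
    train_means = vapply(p$train_means, as.numeric, numeric(1)),
    train_sds = vapply(p$train_sds, as.numeric, numeric(1)),
    n_latent = as.integer(p$n_latent),
    coefficients = vapply(p$coefficients, as.numeric, numeric(1)),
    intercept = as.numeric(p$intercept),
    cutoff = as.numeric(p$cutoff %||% NA_real_),
    auc = as.numeric(p$auc %||% NA_real_),
    apparent_r2 = as.numeric(p$apparent_r2),
    smc_f = vapply(p$smc_f, as.numeric, numeric(1)),
    train_scores = as.numeric(p$train_scores),
    seed = p$seed,
    config = do.call(pipeline_config, p$config)
  ), class = "prognostic_model")
}
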