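# Two-stage imaging feature selection: a univariate correlation screen,
# then competitive adaptive reweighted sampling wrapped around PLS
# regression (CARS-PLSR), which prunes variables along an exponentially
# decreasing retention schedule and keeps the subset with minimal
# cross-validated error.

#' Stage 1: univariate correlation filter
#'
#' Keeps feature j iff the two-sided p-value of the Pearson correlation
#' between feature j and the response is below `alpha` (uncorrected, the
#' permissive screen preceding the subset search). Constant features are
#' assigned r = 0, p = 1 and are never kept.
#'
#' @param X n x p feature matrix.
#' @param y response (follow-up CRS-R), non-constant.
#' @param alpha significance level (default 0.05, two-sided).
#' @return a `selection_result`: `kept` (column indices), `stats` (per
#'   feature r, p, kept flag), `n`.
#' @export
correlation_filter <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) input_error("at least 4 observations are required")
  if (stats::sd(y) == 0) input_error("constant response")
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0
  r <- rep(0, ncol(X))
  r[!const] <- drop(stats::cor(X[, !const, drop = FALSE], y))
  # two-sided t-test on the correlation, df = n - 2
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p[const] <- 1
  r[const] <- 0
  if (any(const))
    message(sprintf("%d constant feature(s) assigned r = 0, p = 1", sum(const)))
  kept <- which(p < alpha & !const)
  structure(list(kept = kept,
                 stats = data.frame(feature = colnames(X) %||%
                                      paste0("V", seq_len(ncol(X))),
                                    r = r, p = p,
                                    kept = seq_len(ncol(X)) %in% kept),
                 n = n, alpha = alpha),
            class = "selection_result")
}

#' Stage 2: CARS-PLSR feature subset selection
#'
#' At iteration i of N: (1) fit a PLS1 model on a random `sample_fraction`
#' of rows using the currently retained variables; (2) compute normalized
#' weights `w_j = |b_j| / sum|b_j|` from the coefficient vector; (3) apply
#' the enforced exponentially decreasing retention schedule, keeping the top
#' `ceiling(p * a * exp(-k i))` variables by `|b_j|` (the schedule runs from
#' p at i = 1 down to 2 at i = N, so `a = (p/2)^(1/(N-1))` and
#' `k = log(p/2)/(N-1)`); (4) adaptive reweighted sampling: draw p
#' candidates with replacement with probability `w_j` and retain the unique
#' set; (5) record the K-fold cross-validated RMSE of a PLS refit on the
#' retained set. The variable set with minimal RMSECV wins. If the retained
#' set collapses below 2 variables the search stops early and returns the
#' best set so far. Deterministic under `seed` (each iteration draws
#' through a derived sub-seed).
#'
#' @param X n x p matrix of stage-1 survivors (p >= 2). Columns are
#'   standardized internally so coefficient magnitudes are comparable.
#' @param y response.
#' @param runs number of CARS iterations N (default 50).
#' @param sample_fraction row fraction used per Monte-Carlo fit
#'   (default 0.8).
#' @param max_lv cap on latent variables (default `min(10, n - 2)`).
#' @param cv_folds folds for the RMSECV evaluation (default 5).
#' @param seed master seed.
#' @return a `selection_result`: `kept` (column indices into `X`),
#'   `history` (per-iteration retained count and RMSECV), `best_iter`,
#'   `seed`.
#' @export
cars_plsr_select <- function(X, y, runs = 50, sample_fraction = 0.8,
                             max_lv = NULL, cv_folds = 5, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) config_error("CARS needs at least 2 candidate variables")
  if (n < cv_folds) config_error("fewer observations than CV folds")
  if (runs < 2) config_error("runs must be >= 2")
  max_lv <- max_lv %||% min(10, n - 2)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) config_error("constant columns must be filtered out first")
  Z <- scale(X)

  kcoef <- log(p / 2) / (runs - 1)
  a <- (p / 2)^(1 / (runs - 1))
  n_sub <- max(2, ceiling(sample_fraction * n))

  retained <- seq_len(p)
  # baseline: evaluate the full candidate set so an early collapse still
  # has a best-so-far subset to return
  history <- data.frame(iter = 0L, n_retained = p,
                        rmsecv = plsr_cv_rmse(Z, y, folds = cv_folds,
                                              n_latent = min(max_lv, p),
                                              seed = derive_seed(seed, 0L)))
  sets <- list(retained)
  early_stop <- FALSE
  for (i in seq_len(runs)) {
    si <- derive_seed(seed, i)
    rows <- with_seed(si, sample(n, n_sub))
    fit <- fit_plsr(Z[rows, retained, drop = FALSE], y[rows],
                    n_latent = min(max_lv, length(retained), n_sub - 2),
                    quiet = TRUE)
    b <- abs(fit$coefficients)
    w <- if (sum(b) > 0) b / sum(b) else rep(1 / length(b), length(b))

    n_keep <- min(length(retained), max(2, ceiling(p * a * exp(-kcoef * i))))
    ord <- order(b, decreasing = TRUE)
    keep <- retained[ord[seq_len(n_keep)]]
    w_keep <- w[ord[seq_len(n_keep)]]
    if (sum(w_keep) == 0) w_keep <- rep(1, n_keep)
    drawn <- with_seed(derive_seed(si, 1L),
                       unique(sample(keep, p, replace = TRUE,
                                     prob = w_keep / sum(w_keep))))
    if (length(drawn) < 2) {
      early_stop <- TRUE
      break
    }
    retained <- sort(drawn)
    rmsecv <- plsr_cv_rmse(Z[, retained, drop = FALSE], y, folds = cv_folds,
                           n_latent = min(max_lv, length(retained)),
                           seed = derive_seed(si, 2L))
    history <- rbind(history, data.frame(iter = i,
                                         n_retained = length(retained),
                                         rmsecv = rmsecv))
    sets[[length(sets) + 1]] <- retained
  }
  if (early_stop)
    message(sprintf("CARS stopped early at iteration %d; returning best subset so far",
                    nrow(history)))
  best <- which.min(history$rmsecv)
  structure(list(kept = sets[[best]], history = history, best_iter = best,
                 early_stop = early_stop, seed = seed),
            class = "selection_result")
}
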