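# Univariate-response partial least squares regression (PLS1, NIPALS).
# With as many latent variables as the predictor rank, the fit coincides
# with ordinary least squares; with fewer it shrinks along the directions of
# low covariance with the response, which is what makes it robust to the
# strong collinearity of connectivity features.

#' Fit a PLS1 regression
#'
#' NIPALS algorithm on column-centred predictors and response. The returned
#' coefficients act on the original (uncentred) predictor scale;
#' `intercept` absorbs the centring, and equals `mean(y)` when the columns
#' of `X` are centred. Extraction stops early (with a warning unless
#' `quiet`) when the residual predictor matrix is rank-exhausted, so
#' `n_latent` never exceeds `rank(X)`.
#'
#' @param X predictor matrix (n x q), typically standardized columns.
#' @param y numeric response.
#' @param n_latent number of latent variables (default 3).
#' @param tol rank-exhaustion tolerance on squared score norms.
#' @param quiet suppress the rank-reduction warning.
#' @return a `plsr_fit`: `coefficients` (named), `intercept`, `n_latent`
#'   (used), `fitted`.
#' @export
fit_plsr <- function(X, y, n_latent = 3, tol = 1e-12, quiet = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); q <- ncol(X)
  if (length(y) != n) input_error("length(y) must equal nrow(X)")
  n_latent <- min(n_latent, n - 1, q)
  if (n_latent < 1) input_error("n_latent must be >= 1 (and n > n_latent)")
  xm <- colMeans(X)
  E <- sweep(X, 2, xm)
  ym <- mean(y)
  f <- y - ym
  sc0 <- sum(E^2)
  W <- P <- matrix(0, q, n_latent)
  qv <- numeric(n_latent)
  used <- 0
  for (a in seq_len(n_latent)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    if (wn < tol * max(1, sc0)) break
    w <- w / wn
    tsc <- drop(E %*% w)
    tt <- sum(tsc^2)
    if (tt < tol * max(1, sc0)) break
    p <- crossprod(E, tsc) / tt
    qa <- sum(f * tsc) / tt
    E <- E - tcrossprod(tsc, p)
    f <- f - qa * tsc
    W[, a] <- w; P[, a] <- p; qv[a] <- qa
    used <- a
  }
  if (used == 0) {
    beta <- stats::setNames(numeric(q), colnames(X))
  } else {
    if (used < n_latent && !quiet)
      warning(sprintf("n_latent reduced from %d to predictor rank %d",
                      n_latent, used))
    W <- W[, seq_len(used), drop = FALSE]
    P <- P[, seq_len(used), drop = FALSE]
    beta <- drop(W %*% solve(crossprod(P, W), qv[seq_len(used)]))
    names(beta) <- colnames(X)
  }
  intercept <- ym - sum(xm * beta)
  structure(list(coefficients = beta, intercept = intercept,
                 n_latent = used,
                 fitted = drop(X %*% beta) + intercept),
            class = "plsr_fit")
}

#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients) + object$intercept
}

# K-fold cross-validated RMSE of a PLS1 fit. Deterministic fold assignment
# under `seed`.
plsr_cv_rmse <- function(X, y, folds = 5, n_latent = 3, seed = 1L) {
  n <- nrow(X)
  if (folds > n) input_error("more folds than observations")
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- numeric(n)
  for (k in seq_len(folds)) {
    te <- fold_id == k
    fit <- fit_plsr(X[!te, , drop = FALSE], y[!te],
                    n_latent = min(n_latent, sum(!te) - 1, ncol(X)),
                    quiet = TRUE)
    pred[te] <- predict(fit, X[te, , drop = FALSE])
  }
  sqrt(mean((pred - y)^2))
}

#' Choose the number of latent variables by cross-validation
#'
#' Returns the smallest latent-variable count whose K-fold cross-validated
#' RMSE is within one part in 1e6 of the minimum (exact ties, and plateaus
#' where extra components add nothing, resolve to the smaller model).
#'
#' @param X predictor matrix.
#' @param y response.
#' @param folds number of CV folds (default 5).
#' @param max_lv largest count considered.
#' @param seed fold-assignment seed.
#' @return integer latent-variable count.
#' @export
choose_n_latent <- function(X, y, folds = 5, max_lv = min(10, ncol(X)),
                            seed = 1L) {
  if (max_lv < 1) input_error("max_lv must be >= 1")
  max_lv <- min(max_lv, ncol(X), nrow(X) - 2)
  rmse <- vapply(seq_len(max_lv), function(a)
    plsr_cv_rmse(X, y, folds = folds, n_latent = a, seed = seed), numeric(1))
  as.integer(which(rmse <= min(rmse) * (1 + 1e-6))[1])
}
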