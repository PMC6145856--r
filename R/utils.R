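# Shared helpers: condition classes, seed management, small numeric utilities.

#' Signal a docprog error
#'
#' All package errors are classed conditions carrying an integer `status`
#' so that orchestration code (and shells wrapping it) can distinguish
#' configuration problems, bad inputs and generation failures.
#'
#' @param message error message.
#' @param class subclass, e.g. `"docprog_config_error"`.
#' @param status integer status code associated with the subclass.
#' @keywords internal
docprog_error <- function(message, class, status = 1L) {
  stop(structure(
    class = c(class, "docprog_error", "error", "condition"),
    list(message = message, call = NULL, status = as.integer(status))
  ))
}

config_error <- function(message) docprog_error(message, "docprog_config_error", 2L)
input_error <- function(message) docprog_error(message, "docprog_input_error", 3L)
generation_error <- function(message) docprog_error(message, "docprog_generation_error", 4L)

#' Exclusion signal for subjects failing motion quality control
#'
#' Returned (not thrown) by [censor_frames()] and [preprocess_run()] when a
#' scan retains fewer usable volumes than the minimum required for stable
#' connectivity estimates.
#'
#' @param n_remaining number of volumes that survived censoring.
#' @param min_required the threshold that was not met.
#' @param subject_id optional subject identifier.
#' @param fd the framewise-displacement series that triggered the exclusion.
#' @return an object of class `doc_exclusion`.
#' @export
exclusion_signal <- function(n_remaining, min_required, subject_id = NA_character_,
                             fd = NULL) {
  structure(
    list(n_remaining = as.integer(n_remaining),
         min_required = as.integer(min_required),
         subject_id = subject_id,
         fd_max = if (is.null(fd)) NA_real_ else max(fd),
         fd_mean = if (is.null(fd)) NA_real_ else mean(fd)),
    class = "doc_exclusion"
  )
}

#' Test whether an object is an exclusion signal
#' @param x any object.
#' @return logical scalar.
#' @export
is_excluded <- function(x) inherits(x, "doc_exclusion")

#' @export
print.doc_exclusion <- function(x, ...) {
  cat(sprintf("<doc_exclusion> %s: %d volumes remaining (< %d required)\n",
              ifelse(is.na(x$subject_id), "subject", x$subject_id),
              x$n_remaining, x$min_required))
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Linear-congruential mix kept strictly below 2^31 so derived seeds remain
#' valid R integers. Every stochastic routine in the package draws its
#' replicate-level seeds through this function, which makes each replicate
#' independently re-runnable.
#'
#' @param seed master seed (integer-like scalar).
#' @param index replicate / stage index.
#' @return integer seed.
#' @export
derive_seed <- function(seed, index) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + as.numeric(index) * 1009) %% 2147483647)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Fisher z-transform with clipping at the boundary
#'
#' `atanh` applied to Pearson correlations after clipping at
#' `+/-(1 - 1e-7)`, so degenerate (r = +/-1) inputs stay finite.
#'
#' @param r correlations.
#' @param clip_at magnitude at which `|r|` is clipped before `atanh`.
#' @return Fisher z values.
#' @export
fisher_z <- function(r, clip_at = 1 - 1e-7) atanh(clip(r, -clip_at, clip_at))

# Squared Pearson correlation between predictions and observations; the
# package-wide definition of R^2. Returns 0 when either side is constant.
rsq <- function(predicted, observed) {
  if (stats::sd(predicted) < 1e-12 || stats::sd(observed) < 1e-12) return(0)
  stats::cor(predicted, observed)^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
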