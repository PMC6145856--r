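# The BoldRun container (4D data + geometry + motion + bookkeeping of which
# acquisition volumes are still present) and the synthetic volume generator.

#' Construct a BOLD run
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr repetition time, seconds.
#' @param voxel_dim voxel edge lengths in mm, length 3.
#' @param mask 3D logical array matching the spatial grid.
#' @param motion t x 6 motion-parameter matrix aligned with the current
#'   volumes (translations mm, rotations radians).
#' @param origin mm coordinate of the centre of voxel `[1, 1, 1]`; defaults
#'   to centring the grid on the origin.
#' @param kept_volumes indices of the current volumes in the original
#'   acquisition (strictly increasing).
#' @return a `bold_run`.
#' @export
bold_run <- function(data, tr, voxel_dim = c(3, 3, 3), mask = NULL,
                     motion = NULL, origin = NULL, kept_volumes = NULL) {
  if (length(dim(data)) != 4) input_error("BOLD data must be a 4D array")
  nt <- dim(data)[4]
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  if (!identical(dim(mask), dim(data)[1:3]))
    input_error("mask shape must match the spatial grid")
  if (is.null(motion)) motion <- matrix(0, nt, 6)
  motion <- as.matrix(motion)
  if (nrow(motion) != nt)
    input_error("motion trace length must equal the number of volumes")
  if (is.null(origin)) origin <- -(dim(data)[1:3] - 1) / 2 * voxel_dim
  if (is.null(kept_volumes)) kept_volumes <- seq_len(nt)
  kept_volumes <- as.integer(kept_volumes)
  if (length(kept_volumes) != nt || is.unsorted(kept_volumes, strictly = TRUE))
    input_error("kept_volumes must be strictly increasing and match the data")
  structure(list(data = data, tr = tr, voxel_dim = as.numeric(voxel_dim),
                 mask = mask, motion = motion, origin = as.numeric(origin),
                 kept_volumes = kept_volumes),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d grid, %d volumes (TR %.3g s), %d in-mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

n_volumes <- function(run) dim(run$data)[4]

# mm coordinates of voxel centres along each axis.
grid_axis_mm <- function(run, axis) {
  run$origin[axis] + (seq_len(dim(run$data)[axis]) - 1) * run$voxel_dim[axis]
}

# Linear (spatial) indices of voxels within `radius` mm of `center`.
sphere_voxel_indices <- function(dims, voxel_dim, origin, center, radius) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * voxel_dim[a])
  d2 <- outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, "+"),
              (ax[[3]] - center[3])^2, "+")
  which(d2 <= radius^2)
}

#' Synthesize a 4D BOLD run from planted ROI time series
#'
#' Every voxel receives white noise; voxels inside ROI sphere i additionally
#' carry `roi_ts[i, ]`. The brain mask is the union of a filled ellipsoid
#' containing every ROI sphere and the spheres themselves, so
#' [extract_roi_timeseries()] on a noise-free run returns `roi_ts` exactly.
#'
#' @param roi_ts ROI x time matrix (one row per ROI of `roiset`).
#' @param roiset an `roi_set`.
#' @param grid list with `dim` (3 positive integers), `voxel_dim` (mm,
#'   default `c(3, 3, 3)`) and optional `origin`.
#' @param noise_sd SD of the additive white noise (0 = noise free).
#' @param tr repetition time, seconds.
#' @param motion optional motion trace (defaults to all zero).
#' @param seed seed for the noise draw.
#' @return a `bold_run`.
#' @export
gen_bold_nifti <- function(roi_ts, roiset, grid = list(dim = c(32, 32, 24)),
                           noise_sd = 0, tr = 2, motion = NULL, seed = 1L) {
  dims <- as.integer(grid$dim)
  if (length(dims) != 3 || any(dims <= 0))
    generation_error("grid dimensions must be 3 positive integers")
  voxel_dim <- grid$voxel_dim %||% c(3, 3, 3)
  origin <- grid$origin %||% (-(dims - 1) / 2 * voxel_dim)
  roiset <- roi_set(roiset)
  if (nrow(roi_ts) != nrow(roiset))
    input_error("roi_ts must have one row per ROI")
  nt <- ncol(roi_ts)

  centers <- as.matrix(roiset[, c("x", "y", "z")])
  # spheres must fit inside the grid
  lo <- origin - voxel_dim / 2
  hi <- origin + (dims - 0.5) * voxel_dim
  for (i in seq_len(nrow(roiset))) {
    if (any(centers[i, ] - roiset$radius[i] < lo) ||
        any(centers[i, ] + roiset$radius[i] > hi))
      generation_error(sprintf("grid too small to contain ROI '%s'",
                               roiset$name[i]))
  }
  # no overlapping spheres (centre-distance criterion)
  dd <- as.matrix(stats::dist(centers))
  rsum <- outer(roiset$radius, roiset$radius, "+")
  bad <- which(dd < rsum & upper.tri(dd), arr.ind = TRUE)
  if (nrow(bad) > 0)
    generation_error(sprintf("overlapping ROI spheres: '%s' and '%s'",
                             roiset$name[bad[1, 1]], roiset$name[bad[1, 2]]))

  vox_idx <- lapply(seq_len(nrow(roiset)), function(i)
    sphere_voxel_indices(dims, voxel_dim, origin, centers[i, ], roiset$radius[i]))
  if (any(lengths(vox_idx) == 0))
    generation_error(sprintf("ROI '%s' contains no voxels on this grid",
                             roiset$name[which(lengths(vox_idx) == 0)[1]]))

  nv <- prod(dims)
  dat <- with_seed(seed, {
    if (noise_sd > 0) matrix(stats::rnorm(nv * nt, 0, noise_sd), nv, nt)
    else matrix(0, nv, nt)
  })
  for (i in seq_along(vox_idx))
    dat[vox_idx[[i]], ] <- dat[vox_idx[[i]], , drop = FALSE] +
      matrix(roi_ts[i, ], length(vox_idx[[i]]), nt, byrow = TRUE)

  # mask: filled ellipsoid around the grid centre covering all spheres,
  # unioned with the spheres themselves
  center_mm <- origin + (dims - 1) / 2 * voxel_dim
  semi <- pmax(abs(t(centers) - center_mm) + roiset$radius, voxel_dim)
  semi <- apply(semi, 1, max) * 1.1
  ax <- lapply(1:3, function(a)
    ((origin[a] + (seq_len(dims[a]) - 1) * voxel_dim[a]) - center_mm[a]) / semi[a])
  e2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  mask <- array(e2 <= 1, dims)
  mask[unlist(vox_idx)] <- TRUE

  bold_run(array(dat, c(dims, nt)), tr = tr, voxel_dim = voxel_dim,
           mask = mask, motion = motion, origin = origin)
}

#' Write / read a BOLD run as NIfTI plus sidecars
#'
#' Writes `<prefix>.nii.gz` (4D data, voxel size and TR in `pixdim`),
#' `<prefix>_mask.nii.gz`, `<prefix>_motion.tsv` and `<prefix>_meta.json`
#' (origin, TR, kept volumes).
#'
#' @param run a `bold_run`.
#' @param prefix output path prefix.
#' @return named vector of written paths (write) or a `bold_run` (read).
#' @export
write_bold <- function(run, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(data = paste0(prefix, ".nii.gz"),
             mask = paste0(prefix, "_mask.nii.gz"),
             motion = paste0(prefix, "_motion.tsv"),
             meta = paste0(prefix, "_meta.json"))
  img <- RNifti::asNifti(run$data)
  img$pixdim <- c(0, run$voxel_dim, run$tr, 0, 0, 0)
  RNifti::writeNifti(img, paths["data"])
  RNifti::writeNifti(RNifti::asNifti(run$mask + 0), paths["mask"])
  write_motion_tsv(run$motion, paths["motion"])
  jsonlite::write_json(list(tr = run$tr, voxel_dim = run$voxel_dim,
                            origin = run$origin,
                            kept_volumes = run$kept_volumes),
                       paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_bold
#' @export
read_bold <- function(prefix) {
  paths <- c(data = paste0(prefix, ".nii.gz"),
             mask = paste0(prefix, "_mask.nii.gz"),
             motion = paste0(prefix, "_motion.tsv"),
             meta = paste0(prefix, "_meta.json"))
  for (p in paths) if (!file.exists(p)) input_error(paste0("missing file: ", p))
  meta <- jsonlite::fromJSON(paths["meta"])
  dat <- as.array(RNifti::readNifti(paths["data"]))
  mask <- as.array(RNifti::readNifti(paths["mask"])) > 0.5
  bold_run(dat, tr = meta$tr, voxel_dim = meta$voxel_dim, mask = mask,
           motion = read_motion_tsv(paths["motion"]), origin = meta$origin,
           kept_volumes = meta$kept_volumes)
}
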