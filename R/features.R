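# Imaging feature construction: ROI time-series extraction, pairwise
# Fisher-z functional connectivity, voxelwise seed maps, healthy-control
# network templates, and template-resemblance features.

#' Extract mean ROI time series from a BOLD run
#'
#' Row i is the mean over in-mask voxels within `radius` mm of ROI i's
#' centre, per retained volume.
#'
#' @param run a `bold_run`.
#' @param roiset an `roi_set`.
#' @return ROI x time matrix with rownames from the ROI set.
#' @export
extract_roi_timeseries <- function(run, roiset) {
  roiset <- roi_set(roiset)
  d <- dim(run$data)
  vox <- matrix(run$data, prod(d[1:3]), d[4])
  mask_idx <- which(run$mask)
  ts <- matrix(NA_real_, nrow(roiset), d[4],
               dimnames = list(roiset$name, NULL))
  for (i in seq_len(nrow(roiset))) {
    idx <- sphere_voxel_indices(d[1:3], run$voxel_dim, run$origin,
                                as.numeric(roiset[i, c("x", "y", "z")]),
                                roiset$radius[i])
    idx <- intersect(idx, mask_idx)
    if (length(idx) == 0)
      input_error(sprintf("ROI '%s' has no in-mask voxels", roiset$name[i]))
    ts[i, ] <- colMeans(vox[idx, , drop = FALSE])
  }
  ts
}

#' Pairwise Fisher-z functional connectivity
#'
#' Pearson correlations between every ROI pair, Fisher z-transformed, in the
#' canonical row-major upper-triangle order (i < j, ROI-configuration
#' order). For m ROIs the vector has length m(m-1)/2 (231 for the 22-ROI
#' design). Perfect correlations are clipped at `|r| = 1 - 1e-7` before the
#' transform.
#'
#' @param ts ROI x time matrix (time points >= 3, no constant row).
#' @return named numeric vector of Fisher-z connectivities.
#' @export
pairwise_fc <- function(ts) {
  if (ncol(ts) < 3) input_error("at least 3 time points are required")
  sds <- apply(ts, 1, stats::sd)
  if (any(sds == 0))
    input_error(sprintf("constant time series for ROI '%s'",
                        rownames(ts)[which(sds == 0)[1]] %||% which(sds == 0)[1]))
  r <- stats::cor(t(ts))
  idx <- fc_pairs(nrow(ts))
  z <- fisher_z(r[idx])
  names(z) <- if (!is.null(rownames(ts)))
    paste0("fc_", rownames(ts)[idx[, "i"]], "__", rownames(ts)[idx[, "j"]])
  z
}

#' Voxelwise seed connectivity z-map
#'
#' Pearson correlation between the seed series and every in-mask voxel
#' series, Fisher z-transformed. Out-of-mask voxels are `NA`; in-mask voxels
#' with constant series are `NA` as well (flagged, not zeroed).
#'
#' @param run a `bold_run`.
#' @param seed_ts numeric vector aligned with the run's retained volumes.
#' @return 3D array of z values on the run's grid.
#' @export
seed_zmap <- function(run, seed_ts) {
  nt <- n_volumes(run)
  if (length(seed_ts) != nt)
    input_error("seed series is not aligned with the run's volumes")
  if (stats::sd(seed_ts) == 0) input_error("seed series has zero variance")
  d <- dim(run$data)
  vox <- matrix(run$data, prod(d[1:3]), nt)
  inmask <- which(run$mask)
  Y <- vox[inmask, , drop = FALSE]
  Yc <- Y - rowMeans(Y)
  sc <- seed_ts - mean(seed_ts)
  denom <- sqrt(rowSums(Yc^2)) * sqrt(sum(sc^2))
  r <- drop(Yc %*% sc) / denom
  r[denom == 0 | !is.finite(r)] <- NA_real_
  zmap <- array(NA_real_, d[1:3])
  zmap[inmask] <- fisher_z(r)
  zmap
}

#' Average member-ROI series per network
#'
#' The seed series of a network template is the average of the time series
#' of that network's ROIs.
#'
#' @param roi_ts ROI x time matrix (rows in ROI-configuration order).
#' @param roiset an `roi_set`.
#' @return network x time matrix (one row per network present).
#' @export
network_seed_ts <- function(roi_ts, roiset) {
  nets <- unique(roiset$network)
  out <- t(vapply(nets, function(nw)
    colMeans(roi_ts[roiset$network == nw, , drop = FALSE]),
    numeric(ncol(roi_ts))))
  rownames(out) <- nets
  out
}

#' Per-network seed z-maps for one (control) run
#'
#' Convenience wrapper: extracts ROI series, averages them per network, and
#' maps each network seed against the whole brain.
#'
#' @param run a `bold_run`.
#' @param roiset an `roi_set`.
#' @return named list of 3D z-map arrays, one per network.
#' @export
control_network_zmaps <- function(run, roiset) {
  ts <- extract_roi_timeseries(run, roiset)
  seeds <- network_seed_ts(ts, roiset)
  out <- lapply(rownames(seeds), function(nw) seed_zmap(run, seeds[nw, ]))
  names(out) <- rownames(seeds)
  out
}

#' Build healthy-control network templates by one-sample t-test
#'
#' Per network and voxel, `t = mean(z) / (sd(z) / sqrt(n))` across the
#' control z-maps. The signed, unthresholded t-map is stored. Voxels with
#' zero across-control variance get a capped value `sign(mean) * cap`
#' (the template is only ever used through spatial correlation, which is
#' insensitive to the cap magnitude).
#'
#' @param control_zmaps list over controls; each element a named list of 3D
#'   z-maps, one per network (as from [control_network_zmaps()]).
#' @param cap magnitude assigned at zero-variance voxels (default 100).
#' @return named list per network: `statistic` (3D t-map) and `n`.
#' @export
build_network_templates <- function(control_zmaps, cap = 100) {
  n <- length(control_zmaps)
  if (n < 3) input_error("at least 3 controls are required for templates")
  nets <- names(control_zmaps[[1]])
  out <- lapply(nets, function(nw) {
    maps <- lapply(control_zmaps, function(cz) cz[[nw]])
    stacked <- array(unlist(maps), c(dim(maps[[1]]), n))
    mu <- apply(stacked, 1:3, mean)
    sdv <- apply(stacked, 1:3, stats::sd)
    tmap <- mu / (sdv / sqrt(n))
    degen <- is.finite(mu) & sdv == 0
    tmap[degen] <- sign(mu[degen]) * cap
    list(statistic = tmap, n = n)
  })
  names(out) <- nets
  out
}

#' Template-resemblance features
#'
#' Feature i is the Pearson correlation, across voxels valid in both maps,
#' between ROI i's seed z-map and the control template of ROI i's network.
#' By construction each value lies in `[-1, 1]`; an intact network yields
#' high resemblance, a degraded one a low or negative value.
#'
#' @param subject_zmaps list of 3D z-maps, one per ROI, in ROI order.
#' @param templates template list from [build_network_templates()].
#' @param roiset an `roi_set`.
#' @return named numeric vector of length `nrow(roiset)`.
#' @export
resemblance_features <- function(subject_zmaps, templates, roiset) {
  roiset <- roi_set(roiset)
  if (length(subject_zmaps) != nrow(roiset))
    input_error("one z-map per ROI is required")
  out <- stats::setNames(numeric(nrow(roiset)), resemblance_names(roiset))
  for (i in seq_len(nrow(roiset))) {
    tmpl <- templates[[roiset$network[i]]]
    if (is.null(tmpl))
      input_error(sprintf("no template for network '%s'", roiset$network[i]))
    a <- as.vector(subject_zmaps[[i]])
    b <- as.vector(tmpl$statistic)
    ok <- is.finite(a) & is.finite(b)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      input_error(sprintf("constant map for ROI '%s'", roiset$name[i]))
    out[i] <- stats::cor(a[ok], b[ok])
  }
  out
}

#' Full connectivity profile of one subject
#'
#' Extracts ROI series, computes the 22-choose-2 pairwise Fisher-z
#' connectivities, maps every ROI seed against the whole brain, and
#' correlates each map with its network template.
#'
#' @param run a preprocessed `bold_run`.
#' @param roiset an `roi_set`.
#' @param templates template list from [build_network_templates()].
#' @param id subject identifier.
#' @return a `connectivity_profile`: `fc`, `resemblance`, `id`.
#' @export
compute_connectivity_profile <- function(run, roiset, templates,
                                         id = NA_character_) {
  ts <- extract_roi_timeseries(run, roiset)
  fc <- pairwise_fc(ts)
  zmaps <- lapply(seq_len(nrow(ts)), function(i) seed_zmap(run, ts[i, ]))
  res <- resemblance_features(zmaps, templates, roiset)
  structure(list(fc = fc, resemblance = res, id = id),
            class = "connectivity_profile")
}

#' Assemble the full per-subject feature vector
#'
#' Canonical order: the per-ROI resemblance features, the pairwise
#' connectivities, then `age`, `duration`, and the two etiology dummies
#' (`dummy_stroke`, `dummy_anoxia`; traumatic injury is the reference
#' level). 22 + 231 imaging features plus 4 clinical covariates = 257 for
#' the default design.
#'
#' @param profile a `connectivity_profile`.
#' @param subject list or one-row data frame with `age`, `duration`,
#'   `etiology` (one of `"trauma"`, `"stroke"`, `"anoxia"`).
#' @return named numeric feature vector.
#' @export
assemble_feature_vector <- function(profile, subject) {
  for (f in c("age", "duration", "etiology")) {
    v <- subject[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v))
      input_error(sprintf("missing clinical field '%s'", f))
  }
  if (!subject$etiology %in% c("trauma", "stroke", "anoxia"))
    input_error(sprintf("unknown etiology '%s'", subject$etiology))
  c(profile$resemblance, profile$fc,
    age = as.numeric(subject$age), duration = as.numeric(subject$duration),
    dummy_stroke = as.numeric(subject$etiology == "stroke"),
    dummy_anoxia = as.numeric(subject$etiology == "anoxia"))
}
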