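# Seed-region configuration: named spherical ROIs grouped into six canonical
# resting-state networks, plus the canonical ordering of derived features.

NETWORK_LEVELS <- c("default_mode", "executive_control", "salience",
                    "sensorimotor", "auditory", "visual")

#' Construct and validate a set of seed regions
#'
#' An ROI set is a data frame with one spherical seed region per row. The
#' study design uses 22 ROIs spanning six networks (default-mode, executive
#' control, salience, sensorimotor, auditory, visual); the constructor also
#' accepts smaller sets, which are convenient for focused simulations.
#'
#' @param df data frame with columns `name`, `network`, `x`, `y`, `z`
#'   (sphere centre, mm, MNI convention) and `radius` (mm).
#' @return a validated `roi_set` data frame.
#' @export
roi_set <- function(df) {
  req <- c("name", "network", "x", "y", "z", "radius")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    config_error(paste0("ROI configuration lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df)[req]
  df$name <- as.character(df$name)
  df$network <- as.character(df$network)
  if (nrow(df) < 2) config_error("an ROI set needs at least 2 ROIs")
  if (anyDuplicated(df$name)) config_error("duplicated ROI names")
  if (!all(df$network %in% NETWORK_LEVELS))
    config_error(paste0("unknown network label(s): ",
                        paste(setdiff(df$network, NETWORK_LEVELS), collapse = ", ")))
  if (any(!is.finite(as.matrix(df[c("x", "y", "z", "radius")]))))
    config_error("non-finite ROI geometry")
  if (any(df$radius <= 0)) config_error("ROI radii must be > 0")
  class(df) <- c("roi_set", "data.frame")
  df
}

#' Example 22-ROI configuration
#'
#' A synthetic, literature-inspired example of the 22-seed / six-network
#' layout used throughout the package: 4 default-mode, 5 executive-control,
#' 4 salience, 3 sensorimotor, 3 auditory and 3 visual seeds with plausible
#' MNI-style coordinates. Coordinates for a real study are supplied by the
#' user via [read_roi_config()]; this set exists so that simulations and
#' examples run out of the box.
#'
#' @param radius sphere radius in mm (default 6).
#' @return an `roi_set` with 22 rows.
#' @export
default_roi_set <- function(radius = 6) {
  df <- data.frame(
    name = c("DMN.aMPFC", "DMN.PCC", "DMN.L.LatParietal", "DMN.R.LatParietal",
             "ExecuContr.DMPFC", "ExecuContr.L.antPFC", "ExecuContr.R.antPFC",
             "ExecuContr.L.SupParietal", "ExecuContr.R.SupParietal",
             "Salience.dACC", "Salience.L.antInsula", "Salience.R.antInsula",
             "Salience.R.dlPFC",
             "Sensorimotor.L.M1", "Sensorimotor.R.M1", "Sensorimotor.SMA",
             "Auditory.L.A1", "Auditory.R.A1", "Auditory.MCC",
             "Visual.L.V1", "Visual.R.V1", "Visual.Extrastriate"),
    network = c(rep("default_mode", 4), rep("executive_control", 5),
                rep("salience", 4), rep("sensorimotor", 3),
                rep("auditory", 3), rep("visual", 3)),
    x = c(-1, -1, -46, 49,   0, -44, 44, -50, 50,   -2, -40, 42, 32,
          -39, 38, 0,   -54, 54, 0,   -10, 13, 0),
    y = c(49, -52, -66, -63,   24, 45, 45, -51, -51,   14, 18, 10, 45,
          -26, -26, -21,   -14, -14, -8,   -83, -80, -93),
    z = c(-2, 26, 30, 33,   46, 0, 0, 45, 45,   28, -2, -12, 30,
          51, 51, 48,   8, 8, 40,   3, 6, 20),
    radius = radius
  )
  roi_set(df)
}

#' Read an ROI configuration from CSV or JSON
#'
#' @param path file with fields `name`, `network`, `x`, `y`, `z`, `radius`.
#' @return an `roi_set`.
#' @export
read_roi_config <- function(path) {
  if (!file.exists(path)) input_error(paste0("ROI configuration not found: ", path))
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  roi_set(df)
}

#' Write an ROI configuration to CSV
#' @param roiset an `roi_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_config <- function(roiset, path) {
  utils::write.csv(as.data.frame(roiset), path, row.names = FALSE)
  invisible(path)
}

# Upper-triangle (i < j) pair index in canonical row-major order.
fc_pairs <- function(m) {
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

fc_pair_names <- function(roiset) {
  idx <- fc_pairs(nrow(roiset))
  paste0("fc_", roiset$name[idx[, "i"]], "__", roiset$name[idx[, "j"]])
}

resemblance_names <- function(roiset) paste0("res_", roiset$name)

CLINICAL_FEATURES <- c("age", "duration", "dummy_stroke", "dummy_anoxia")

#' Canonical feature ordering for a given ROI set
#'
#' The fixed, documented feature order used by every table in the package:
#' first one template-resemblance feature per ROI, then the pairwise
#' functional connectivities in row-major upper-triangle order
#' (`fc_<roi_i>__<roi_j>` with i < j in ROI-configuration order), then the
#' four clinical covariates `age`, `duration`, `dummy_stroke`,
#' `dummy_anoxia` (trauma is the etiology reference level). For the 22-ROI
#' default set this yields 22 + 231 + 4 = 257 names.
#'
#' @param roiset an `roi_set`.
#' @param clinical include the clinical covariates (default `TRUE`).
#' @return character vector of feature names.
#' @export
canonical_feature_names <- function(roiset, clinical = TRUE) {
  nm <- c(resemblance_names(roiset), fc_pair_names(roiset))
  if (clinical) nm <- c(nm, CLINICAL_FEATURES)
  nm
}

# Number of imaging features for an ROI set: m resemblance + m(m-1)/2 FC.
n_imaging_features <- function(roiset) {
  m <- nrow(roiset)
  m + m * (m - 1) / 2
}
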